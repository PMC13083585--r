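test_that("percentages are rounded half-up to two decimals", {
  expect_equal(round_half_up(2.675, 2), 2.68)  # round() would give 2.67
  expect_equal(round_half_up(-2.675, 2), -2.68)
  expect_equal(report_percent(1, 3), 33.33)
  expect_equal(report_percent(2, 3), 66.67)
})

demo_cases_fixture <- function() {
  data.frame(
    primaryid = as.character(1:8),
    caseid = as.character(1:8),
    fda_dt = "20230101", event_dt = "",
    sex = c("F", "F", "M", NA, "UNK", "F", "M", "F"),
    age = c("30", "6", "70", NA, "55", "2", "88", "40"),
    age_cod = c("YR", "MON", "YR", NA, "YR", "DEC", "YR", "FORTNIGHT"),
    occp_cod = c("LW", "MD", "CN", NA, "HP", "PH", "OT", "LW"),
    reporter_country = c("US", "US", "GB", "CA", "US", "IT", "GB", "DE"))
}

test_that("descriptive blocks count against the case total", {
  outc <- data.frame(primaryid = c("1", "1", "2", "3"),
                     outc_cod = c("HO", "DS", "HO", "OT"))
  expect_warning(ds <- descriptive_table(demo_cases_fixture(), outc),
                 "age unit")
  expect_equal(ds$total, 8)
  sex <- ds$sex
  expect_equal(sex$count[sex$category == "Female"], 4L)
  expect_equal(sex$count[sex$category == "Not specified"], 2L)
  expect_equal(sum(sex$count), 8L)

  age <- ds$age
  expect_equal(age$count[age$category == "< 18"], 1L)   # 6 months
  expect_equal(age$count[age$category == "18-44"], 2L)  # 30y, 2 decades->20y
  expect_equal(age$count[age$category == ">= 85"], 1L)
  expect_equal(age$count[age$category == "Unknown"], 2L) # NA + bad unit
  expect_equal(sum(age$count), 8L)

  rep <- ds$reporter
  expect_equal(rep$count[rep$category == "Lawyer"], 2L)
  expect_equal(rep$count[rep$category == "Not specified"], 2L) # OT + NA
  expect_equal(sum(rep$count), 8L)

  # outcome percentages are per code over the case total, not normalised
  oc <- ds$outcomes
  expect_equal(oc$count[oc$category ==
                          "Hospitalization: initial or prolonged"], 2L)
  expect_equal(oc$pct[oc$category ==
                        "Hospitalization: initial or prolonged"],
               report_percent(2, 8))

  expect_equal(ds$countries$category[1], "US")
})

test_that("all-unknown ages collapse into one band", {
  d <- demo_cases_fixture()
  d$age <- NA; d$age_cod <- NA
  ds <- descriptive_table(d)
  expect_equal(ds$age$pct[ds$age$category == "Unknown"], 100)
})

test_that("excluding an absent occupation changes nothing", {
  cfg <- quiet_config(c("druga", "backgrounda"), c(.2, .5), n_cases = 400,
                      seed = 43, signal_pairs = c(druga = 8),
                      occupation_mix = c(MD = .5, PH = .2, LW = 0, CN = .1,
                                         HP = .2, OT = 0))
  sim <- simulate_faers(cfg)
  si <- screen_inputs(sim, cfg)
  sd <- sensitivity_exclude("LW", si$bundle$demo, si$bundle$reac,
                            si$bundle$drug, si$norm, si$query, si$retained,
                            roles = c("PS", "SS", "C"))
  expect_equal(sd$n_excluded, 0L)
  expect_setequal(sd$baseline_positive, sd$filtered_positive)
  expect_length(sd$gained, 0)
  expect_length(sd$lost, 0)
  expect_equal(sd$deltas$d_a, rep(0L, nrow(sd$deltas)))
})

test_that("lawyer-driven volume deflates other drugs until excluded", {
  cfg <- masking_config(4)
  sim <- simulate_faers(cfg)
  si <- screen_inputs(sim, cfg)
  sd <- sensitivity_exclude("LW", si$bundle$demo, si$bundle$reac,
                            si$bundle$drug, si$norm, si$query, si$retained,
                            roles = c("PS", "SS", "C"))
  expect_gt(sd$n_excluded, 0)
  expect_length(intersect(sd$gained, sd$lost), 0)
  base_m <- sd$baseline[sd$baseline$drug == "masked", ]
  filt_m <- sd$filtered[sd$filtered$drug == "masked", ]
  expect_gt(filt_m$ror, base_m$ror)  # exclusion lifts the masked signal
  expect_true("masked" %in% sd$gained)
})

test_that("the pipeline writes its artifacts and a reconciling manifest", {
  out1 <- file.path(withr::local_tempdir(), "r1")
  cfg <- list(synth = list(n_cases = 800, seed = 12), out = out1)
  run_pipeline(cfg)
  want <- c("retained_ids.txt", "contingency.csv", "signals.csv",
            "tto_summary.csv", "tto_bins.csv", "triplets.csv",
            "descriptive.csv", "sensitivity.csv", "manifest.json")
  expect_true(all(file.exists(file.path(out1, want))))

  man <- jsonlite::read_json(file.path(out1, "manifest.json"),
                             simplifyVector = TRUE)
  cnt <- man$counts
  expect_equal(cnt$parsed,
               cnt$retained + cnt$removed_as_duplicate +
                 cnt$removed_by_deletion)
  expect_lte(cnt$retained, cnt$parsed)   # stage chain is non-increasing
  expect_lte(cnt$cases, cnt$retained)

  # determinism: a rerun is byte-identical on every table
  out2 <- file.path(withr::local_tempdir(), "r2")
  run_pipeline(list(synth = list(n_cases = 800, seed = 12), out = out2))
  for (f in want)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = f)
})
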