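# hand-built single-quarter bundle exercising every exclusion reason
tto_bundle <- function() {
  demo <- data.frame(
    primaryid = as.character(1:7), caseid = as.character(1:7),
    fda_dt = "20230601",
    event_dt = c("20230106", "20230110", "20230110", "202301",
                 "", "20230110", "20230105"))
  drug <- data.frame(
    primaryid = as.character(c(1:7, 1)),
    drug_seq = c(rep("1", 7), "2"),
    role_cod = "PS",
    drugname = "DRUGX", prod_ai = "DRUGX")
  drug$drugname[8] <- "DRUGY"; drug$prod_ai[8] <- "DRUGY"
  ther <- data.frame(
    primaryid = as.character(c(1, 1, 2, 3, 4, 5, 6, 7, 1)),
    dsg_drug_seq = c("1", "1", "1", "1", "1", "1", "1", "1", "2"),
    start_dt = c("20230103", "20230101", "20230120", "202301",
                 "20230101", "20230101", "", "20230101", "20230104"),
    end_dt = c("", "", "", "", "", "", "", "20221220", ""))
  reac <- data.frame(primaryid = as.character(1:7), pt = "Dystonia")
  faers_bundle("T", demo, drug, reac, ther)
}

tto_map <- drug_map(c("DRUGX", "DRUGY"), c("drugx", "drugy"))

test_that("onset extraction applies the date rules and exclusion reasons", {
  b <- tto_bundle()
  tt <- extract_tto(b, case_ids = as.character(1:7), norm = tto_map)
  tx <- tt[tt$drug == "drugx", ]
  get <- function(pid) tx[tx$primaryid == pid, ]
  # earliest day-precision start wins: 20230101 -> 5 days
  expect_equal(get("1")$tto_days, 5)
  expect_true(get("1")$included)
  # event before start
  expect_equal(get("2")$exclusion_reason, "negative")
  # month-precision event date
  expect_equal(get("3")$exclusion_reason, "partial_precision")
  # missing event date
  expect_equal(get("5")$exclusion_reason, "missing_event")
  # start present but never day-precision vs start absent entirely
  expect_equal(get("4")$exclusion_reason, "partial_precision")
  expect_equal(get("6")$exclusion_reason, "missing_start")
  # therapy end before start
  expect_equal(get("7")$exclusion_reason, "inconsistent")
  # second drug on report 1: start 20230104, event 20230106 -> 2 days
  expect_equal(tt$tto_days[tt$drug == "drugy"], 2)
})

test_that("same-day onset is a valid zero-day interval", {
  b <- tto_bundle()
  b$ther$start_dt[2] <- "20230106"  # replaces the earliest start for case 1
  b$ther$start_dt[1] <- "20230107"
  tt <- extract_tto(b, "1", tto_map)
  expect_equal(tt$tto_days[tt$drug == "drugx"], 0)
  expect_true(tt$included[tt$drug == "drugx"])
})

test_that("inclusion matches the generator's complete-date ledger", {
  nms <- c("drugy", "backgrounde")
  cfg <- synth_config(
    n_cases = 2000, drug_catalog = mini_catalog(nms, c(.25, .6)),
    tto_models = mini_tto(nms, median = 3),
    signal_pairs = c(drugy = 10), interaction_triplets = NULL,
    lawyer_bias = NULL, base_event_prob = .03, duplicate_rate = 0,
    deletion_rate = 0, missing_date_rate = 0.3, seed = 6)
  sim <- simulate_faers(cfg)
  si <- screen_inputs(sim, cfg)
  tt <- extract_tto(si$bundle, si$cases, si$norm, roles = c("PS", "SS", "C"))
  led <- sim$ledger$tto
  expect_equal(nrow(tt), nrow(led))
  expect_equal(sum(tt$included),
               sum(led$start_complete & led$event_complete))
  # and the included intervals are exactly the drawn ones
  key <- function(df, id) paste(id, df$drug)
  case_of <- si$bundle$demo$caseid[match(tt$primaryid,
                                         si$bundle$demo$primaryid)]
  m <- match(key(tt, case_of), key(led, led$caseid))
  expect_equal(tt$tto_days[tt$included], led$tto_days[m][tt$included])
})

test_that("onset summaries report quartiles and closed bins", {
  s <- summarize_tto(c(0, 2, 5, 91, 400))
  expect_equal(s$median, 5)
  expect_equal(s$min, 0)
  expect_equal(s$max, 400)
  expect_equal(s$bins$count,
               c(3L, 0L, 0L, 1L, 0L, 1L))   # 0-30 closed on both ends
  expect_equal(s$bins$bin[1], "0-30")
  expect_lt(abs(sum(s$bins$pct) - 100), 0.05)

  s1 <- summarize_tto(5)
  expect_equal(unname(c(s1$q1, s1$median, s1$q3)), c(5, 5, 5))

  # boundary days land in the closed bins
  sb <- summarize_tto(c(30, 31, 360, 361))
  expect_equal(sb$bins$count, c(1L, 1L, 0L, 0L, 1L, 1L))
})

test_that("KM without censoring is the complement of the empirical CDF", {
  k <- km_fit(c(1, 2, 3))
  expect_equal(k$curves$survival, c(2 / 3, 1 / 3, 0))
  set.seed(55)
  x <- round(rexp(201, 1 / 10))  # odd n: KM median = sample median
  k2 <- km_fit(x)
  ec <- stats::ecdf(x)
  expect_equal(k2$curves$survival, 1 - ec(k2$curves$time))
  expect_equal(k2$medians$median, stats::median(x))
})

test_that("log-rank behaves at the null, counts df, and ignores rescaling", {
  set.seed(66)
  x <- rexp(100, 1 / 5)
  g <- rep(c("a", "b"), 50)
  lr <- logrank_test(c(x, x), rep(c("p", "q"), each = 100))
  expect_lt(lr$chi2, 1e-10)
  expect_gt(lr$p, 0.99)

  g5 <- sample(letters[1:5], 300, TRUE)
  expect_equal(logrank_test(rexp(300), g5)$df, 4)

  l1 <- logrank_test(x, g)
  l2 <- logrank_test(7 * x, g)
  expect_equal(l1$chi2, l2$chi2)
  expect_equal(l1$p, l2$p)
})

test_that("Kruskal-Wallis separates shifted groups and handles ties", {
  kw <- kruskal_wallis_test(c(1, 2, 3, 101, 102, 103),
                            rep(c("a", "b"), each = 3))
  expect_lt(kw$p, 0.05)
  id <- kruskal_wallis_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_lt(id$H, 1e-10)
  tied <- kruskal_wallis_test(rep(4, 8), rep(c("a", "b"), each = 4))
  expect_equal(tied$H, 0)
})
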