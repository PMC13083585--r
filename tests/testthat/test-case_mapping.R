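test_that("PT query files load, deduplicate, and normalise case", {
  f <- withr::local_tempfile(fileext = ".txt")
  terms <- c("Dystonia", "Torticollis", "Oculogyric crisis",
             "Oromandibular dystonia", "Opisthotonus", "Blepharospasm",
             "Trismus", "Muscle contractions involuntary", "Dystonic tremor",
             "Meige syndrome", "Laryngospasm", "Risus sardonicus",
             "Emprosthotonus", "Torsion dystonia")
  writeLines(terms, f)
  q <- load_pt_query(f)
  expect_s3_class(q, "pt_query")
  expect_length(q$pts, 14)

  writeLines(c("DYSTONIA", "Dystonia", "  dystonia ", "Nausea"), f)
  expect_length(load_pt_query(f)$pts, 2)

  writeLines(character(0), f)
  expect_error(load_pt_query(f), "empty")

  # CSV dialect with scope column: narrow is a subset of broad
  fcsv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pt,code,scope", "Dystonia,10013916,narrow",
               "Torticollis,10044074,narrow", "Muscle spasms,10028334,broad"),
             fcsv)
  expect_length(load_pt_query(fcsv, scope = "narrow")$pts, 2)
  expect_length(load_pt_query(fcsv, scope = "broad")$pts, 3)
})

test_that("a report is one case regardless of how many PTs match", {
  q <- pt_query(c("Dystonia", "Torticollis"))
  reac <- data.frame(
    primaryid = c("1", "1", "1", "2", "3"),
    pt = c("Dystonia", "Torticollis", "Nausea", "Headache", "dystonia "))
  cases <- flag_cases(reac, retained = c("1", "2", "3"), q)
  expect_setequal(cases, c("1", "3"))       # report 1 counted once
  cases2 <- flag_cases(reac, retained = c("2", "3"), q)
  expect_setequal(cases2, "3")              # non-retained ignored
})

test_that("drug normalisation honours roles and reports unmapped names", {
  nm <- drug_map(c("METOCLOPRAMIDE", "METOCLOPRAMIDE HCL", "REGLAN"),
                 rep("metoclopramide", 3), atc = rep("A03FA01", 3))
  drug <- data.frame(
    primaryid = c("1", "1", "2", "3"),
    drug_seq = c("1", "2", "1", "1"),
    role_cod = c("PS", "C", "PS", "PS"),
    drugname = c("METOCLOPRAMIDE HCL", "METOCLOPRAMIDE", "Reglan",
                 "MYSTERYDRUG"),
    prod_ai = c("", "", "", ""))
  expect_warning(ex <- normalize_drugs(drug, nm, roles = "PS"), "unmapped")
  expect_equal(ex$drug, c("metoclopramide", "metoclopramide"))
  expect_setequal(ex$primaryid, c("1", "2")) # role C excluded; unmapped dropped
  expect_equal(attr(ex, "unmapped"), "MYSTERYDRUG")

  # per-report set: report 1's two metoclopramide rows collapse to one
  ex2 <- suppressWarnings(normalize_drugs(drug, nm, roles = c("PS", "C")))
  expect_equal(nrow(ex2), 2)
  expect_setequal(ex2$primaryid, c("1", "2"))
})

test_that("contingency cells are computed at report level", {
  expo <- data.frame(primaryid = c("1", "3"), drug = "drugx")
  t <- build_contingency(case_ids = c("1", "2"), drug_exposure = expo,
                         all_retained = c("1", "2", "3", "4"), drug = "drugx")
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))

  t0 <- build_contingency(c("1", "2"), expo[0, ], c("1", "2", "3", "4"),
                          "absent")
  expect_equal(unlist(t0[c("a", "b", "c", "d")]),
               c(a = 0, b = 0, c = 2, d = 2))
})

test_that("vectorised cells match the brute-force oracle and conserve N", {
  cfg <- quiet_config(c("druga", "drugb", "drugc", "backgrounda"),
                      c(.1, .08, .05, .5), n_cases = 1500, seed = 11,
                      signal_pairs = c(druga = 8, drugb = 3))
  sim <- simulate_faers(cfg)
  si <- screen_inputs(sim, cfg)
  cells <- contingency_all(si$cases, si$expo, si$retained)
  expect_true(all(cells$a + cells$b + cells$c + cells$d ==
                    length(si$retained)))
  expect_true(all(cells$a <= length(si$cases)))
  for (d in cells$drug) {
    bf <- bf_contingency(si$cases, si$expo, si$retained, d)
    row <- cells[cells$drug == d, ]
    expect_equal(c(a = row$a, b = row$b, c = row$c, d = row$d), bf)
    one <- build_contingency(si$cases, si$expo, si$retained, d)
    expect_equal(unlist(one[c("a", "b", "c", "d")]), bf)
  }
})

test_that("case flags and exposures equal the generator's ground truth", {
  cfg <- quiet_config(c("druga", "drugb", "backgrounda"), c(.1, .08, .5),
                      n_cases = 1200, seed = 19,
                      signal_pairs = c(druga = 5))
  sim <- simulate_faers(cfg)
  si <- screen_inputs(sim, cfg)
  led <- sim$ledger
  b <- si$bundle
  case_of <- function(pids) b$demo$caseid[match(pids, b$demo$primaryid)]
  expect_setequal(case_of(si$cases), led$cases$caseid[led$cases$event])
  got <- unique(data.frame(caseid = case_of(si$expo$primaryid),
                           drug = si$expo$drug))
  want <- unique(led$exposures[c("caseid", "drug")])
  expect_setequal(paste(got$caseid, got$drug),
                  paste(want$caseid, want$drug))
})
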