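test_that("triplet counting enumerates strata at report level", {
  # reports: {A,B,event}, {A,B,event}, {A}, {B,event}
  expo <- data.frame(
    primaryid = c("1", "1", "2", "2", "3", "4"),
    drug = c("a", "b", "a", "b", "a", "b"))
  tt <- count_triplets(case_ids = c("1", "2", "4"), expo,
                       all_retained = as.character(1:4))
  expect_equal(nrow(tt), 1)
  expect_equal(tt$n111, 2L)
  expect_equal(tt$n11plus, 2L)
  expect_equal(tt$f10, 0)        # report 3: A only, no event
  expect_equal(tt$f01, 1)        # report 4: B only, event
  expect_equal(tt$n00, 0L)       # no neither-drug stratum
  expect_true(is.na(tt$f00))

  # pairs that never co-occur are absent
  expo2 <- data.frame(primaryid = c("1", "2"), drug = c("a", "b"))
  expect_equal(nrow(count_triplets("1", expo2, c("1", "2"))), 0)
})

test_that("triplet counts match a brute-force triple loop", {
  cfg <- quiet_config(c("druga", "drugb", "drugc", "backgrounda"),
                      c(.15, .12, .10, .5), n_cases = 1200, seed = 29,
                      signal_pairs = c(druga = 4, drugb = 4),
                      base_event_prob = .04)
  sim <- simulate_faers(cfg)
  si <- screen_inputs(sim, cfg)
  tt <- count_triplets(si$cases, si$expo, si$retained, min_n111 = 1)
  bf <- bf_triplets(si$cases, si$expo, si$retained)
  bf <- bf[bf$n111 >= 1, ]
  m <- merge(tt, bf, by = c("drugA", "drugB"),
             suffixes = c("", "_bf"))
  expect_equal(nrow(m), nrow(tt))
  expect_equal(nrow(m), nrow(bf))
  expect_equal(m$n111, m$n111_bf)
  expect_equal(m$n11plus, m$n11plus_bf)
  # stratum accounting reconciles with the retained total
  expect_true(all(m$n11plus + m$n10 + m$n01 + m$n00 ==
                    length(si$retained)))
})

test_that("identical stratum proportions mean no expected excess", {
  tl <- data.frame(drugA = "a", drugB = "b", n111 = 10L, n11plus = 100L,
                   f10 = .07, f01 = .07, f00 = .07,
                   n10 = 50L, n01 = 50L, n00 = 500L)
  for (m in c("odds_additive", "multiplicative", "max_single")) {
    e <- expected_e111(tl, model = m)
    expect_equal(e$E111, 7, tolerance = 1e-12)
    expect_equal(e$model_used, m)
  }
})

test_that("the additive-odds baseline reproduces the hand-worked case", {
  tl <- data.frame(drugA = "a", drugB = "b", n111 = 30L, n11plus = 100L,
                   f10 = 0.2, f01 = 1 / 90, f00 = 1 / 90,
                   n10 = 100L, n01 = 90L, n00 = 900L)
  e <- expected_e111(tl, model = "odds_additive")
  expect_equal(e$E111, 20)       # odds 0.25 -> g = 0.2 -> 20 of 100
})

test_that("degenerate strata fall back to simpler baselines", {
  tl <- data.frame(drugA = "a", drugB = "b", n111 = 5L, n11plus = 20L,
                   f10 = 0.3, f01 = 0.1, f00 = NA_real_,
                   n10 = 10L, n01 = 10L, n00 = 0L)
  e <- expected_e111(tl, model = "odds_additive")
  expect_equal(e$model_used, "max_single")
  expect_equal(e$E111, 0.3 * 20)

  # baseline saturated at 1: odds undefined, survival ratio undefined
  tl$f00 <- 1
  e2 <- expected_e111(tl)
  expect_equal(e2$model_used, "max_single")

  # nothing to fall back on
  tl$f10 <- NA; tl$f01 <- NA; tl$f00 <- NA
  e3 <- expected_e111(tl)
  expect_true(is.na(e3$E111))
})

test_that("omega is monotone and its interval width scales as 1/sqrt(n)", {
  expect_equal(omega_stat(20, 20)$omega, 0)
  o1 <- omega_stat(c(10, 20, 40), c(10, 10, 10))
  expect_true(all(diff(o1$omega) > 0))
  o2 <- omega_stat(c(20, 20), c(10, 40))
  expect_lt(o2$omega[2], o2$omega[1])

  w <- function(n) {
    o <- omega_stat(n, 10)
    o$omega975 - o$omega025
  }
  expect_equal(w(16), 2 * 1.96 / (log(2) * 4))
  expect_equal(w(64), w(16) / 2)     # quadrupling n halves the width

  o0 <- omega_stat(0, 5)
  expect_true(is.finite(o0$omega) && is.na(o0$omega025))
})

test_that("screening ranks by count then omega and flags the lower bound", {
  tl <- data.frame(drugA = c("a", "a", "b"), drugB = c("b", "c", "c"),
                   n111 = c(49L, 48L, 49L), n11plus = c(80, 80, 80),
                   E111 = c(35.48, 10, 60), model_used = "odds_additive")
  sc <- screen_interactions(tl)
  # (a,b) and (b,c) share n111 = 49: the larger omega breaks the tie
  expect_equal(paste(sc$drugA, sc$drugB),
               c("a b", "b c", "a c"))
  expect_equal(sc$flag, c(TRUE, FALSE, TRUE))
  expect_equal(nrow(screen_interactions(tl, top_n = 2)), 2)
})

test_that("an injected interaction is detected with high power", {
  flagged <- 0L
  for (s in 1:25) {
    cfg <- synth_config(
      n_cases = 1800,
      drug_catalog = mini_catalog(c("drga", "drgb", "backgroundc",
                                    "fillerx"), c(.25, .25, .5, .2)),
      tto_models = mini_tto(c("drga", "drgb", "backgroundc", "fillerx")),
      signal_pairs = c(drga = 2, drgb = 2),
      interaction_triplets = data.frame(drugA = "drga", drugB = "drgb",
                                        mult = 5),
      lawyer_bias = NULL, base_event_prob = .05,
      duplicate_rate = 0, deletion_rate = 0, missing_date_rate = 0,
      seed = 1000 + s)
    sim <- simulate_faers(cfg)
    si <- screen_inputs(sim, cfg)
    tt <- expected_e111(count_triplets(si$cases, si$expo, si$retained),
                        model = "multiplicative")
    sc <- screen_interactions(tt)
    hit <- sc[sc$drugA == "drga" & sc$drugB == "drgb", ]
    if (nrow(hit) && hit$flag) flagged <- flagged + 1L
  }
  expect_gte(flagged, 24)
})

test_that("no-interaction triplets are rarely flagged under independence", {
  # pure null: exposure and event independent, so every baseline model
  # coincides on average and the nominal 2.5% one-sided rate applies
  flags <- ns <- integer(0)
  for (s in 1:14) {
    nms <- c(paste0("drug", letters[1:8]), "backgroundd")
    cfg <- quiet_config(nms, c(rep(.22, 8), .6), n_cases = 4000,
                        seed = 500 + s, signal_pairs = NULL,
                        base_event_prob = .18)
    sim <- simulate_faers(cfg)
    si <- screen_inputs(sim, cfg)
    tt <- expected_e111(count_triplets(si$cases, si$expo, si$retained),
                        model = "multiplicative")
    sc <- screen_interactions(tt)
    sc <- sc[sc$n111 >= 20, ]
    flags <- c(flags, sc$flag)
    ns <- c(ns, sc$n111)
  }
  expect_gte(length(flags), 400)
  expect_lte(mean(flags), 0.075)
})
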