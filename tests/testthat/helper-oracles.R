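# Shared fixtures and independent brute-force oracles.

mini_catalog <- function(names, p) {
  data.frame(name = names, p = p, atc = "N00XX00", stringsAsFactors = FALSE)
}

mini_tto <- function(names, family = "exponential", median = 5) {
  stats::setNames(rep(list(list(family = family, median = median)),
                      length(names)), names)
}

# clean single-quarter config: no duplicates/deletions/bias unless asked
quiet_config <- function(names, p, n_cases, seed, signal_pairs = NULL, ...) {
  synth_config(
    n_cases = n_cases, drug_catalog = mini_catalog(names, p),
    tto_models = mini_tto(names), signal_pairs = signal_pairs,
    interaction_triplets = NULL, lawyer_bias = NULL,
    duplicate_rate = 0, deletion_rate = 0, missing_date_rate = 0,
    seed = seed, ...
  )
}

# dedup -> case flags -> exposure for one simulated bundle
screen_inputs <- function(sim, cfg, roles = c("PS", "SS", "C")) {
  b <- combine_bundles(sim$bundles)
  dd <- deduplicate(b$demo)
  dd <- apply_deletions(dd, b$demo, b$deletion_caseids)
  ret <- dd$retained_primaryids
  q <- pt_query(sim$ledger$target_pts)
  nm <- synth_drug_map(cfg)
  cases <- flag_cases(b$reac, ret, q)
  expo <- suppressWarnings(normalize_drugs(b$drug, nm, roles = roles))
  expo <- expo[expo$primaryid %in% ret, , drop = FALSE]
  list(bundle = b, dedup = dd, retained = ret, query = q, norm = nm,
       cases = cases, expo = expo)
}

## --- brute-force oracles (kept deliberately naive) -------------------

bf_dedup <- function(demo) {
  unname(vapply(split(demo, demo$caseid), function(g) {
    pd <- parse_date(g$fda_dt)
    key <- ifelse(pd$precision == "day", as.numeric(pd$ordinal), -Inf)
    pid <- as.numeric(g$primaryid)
    best <- which(key == max(key))
    g$primaryid[best[which.max(pid[best])]]
  }, ""))
}

bf_contingency <- function(case_ids, expo, retained, drug) {
  a <- b <- c_ <- d <- 0L
  exposed <- unique(expo$primaryid[expo$drug == drug])
  for (pid in retained) {
    e <- pid %in% exposed
    ca <- pid %in% case_ids
    if (e && ca) a <- a + 1L else if (e) b <- b + 1L
    else if (ca) c_ <- c_ + 1L else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}

bf_triplets <- function(case_ids, expo, retained) {
  drugs <- sort(unique(expo$drug))
  by_pid <- split(expo$drug, expo$primaryid)
  rows <- list()
  for (i in seq_along(drugs)) for (j in seq_along(drugs)) {
    if (i >= j) next
    A <- drugs[i]; B <- drugs[j]
    n111 <- n11 <- 0L
    for (pid in retained) {
      ds <- by_pid[[pid]]
      if (!is.null(ds) && A %in% ds && B %in% ds) {
        n11 <- n11 + 1L
        if (pid %in% case_ids) n111 <- n111 + 1L
      }
    }
    if (n11 > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        drugA = A, drugB = B, n111 = n111, n11plus = n11,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# empirical presence odds ratio for one drug, straight from the ledger
ledger_or <- function(ledger, drug) {
  ev <- ledger$cases$event
  ex <- unique(ledger$exposures[c("caseid", "drug")])
  has <- ledger$cases$caseid %in% ex$caseid[ex$drug == drug]
  (sum(has & ev) * sum(!has & !ev)) / (sum(has & !ev) * sum(!has & ev))
}

# the lawyer-masking study configuration used by the sensitivity tests:
# one true signal suppressed at baseline by litigation-driven event
# reports concentrated on another (also truly positive) drug
masking_config <- function(seed) {
  nms <- c("masked", "litigated", "backgrounda", "backgroundb",
           "filler1", "filler2")
  synth_config(
    n_cases = 4000,
    drug_catalog = mini_catalog(nms, c(.10, .10, .35, .35, .08, .08)),
    tto_models = mini_tto(nms),
    signal_pairs = c(masked = 20, litigated = 20),
    interaction_triplets = NULL,
    lawyer_bias = c(litigated = 13),
    base_event_prob = 0.02,
    duplicate_rate = 0, deletion_rate = 0, missing_date_rate = 0,
    seed = seed
  )
}
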