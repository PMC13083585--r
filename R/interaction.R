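# Drug-pair--event triplet screening with the Omega shrinkage measure.
#
# For an unordered drug pair (A, B) and the target event, each retained
# report falls in exactly one stratum: both drugs, A only, B only, or
# neither. With n111 the observed event count among both-drug reports and
# E111 the count expected from the single-drug strata under a
# no-interaction baseline:
#
#   Omega    = log2[(n111 + 0.5) / (E111 + 0.5)]
#   Omega025 = Omega - z / (ln 2 * sqrt(n111)),  z = 1.96
#
# Omega025 > 0 flags a possible interaction. The +0.5 shrinkage makes the
# measure conservative for small counts. The expected-count model is
# pluggable (odds-additive with floor by default); the interval depends
# only on n111, not on the E111 model.

.odds <- function(p) p / (1 - p)

#' Count drug-pair--event triplets
#'
#' For every unordered pair of canonical drugs co-occurring on at least
#' `min_n111` event reports: the both-drug counts (`n111` events,
#' `n11plus` total) and the observed event proportions in the three
#' comparison strata — `f10` (drug A only), `f01` (drug B only), `f00`
#' (neither) — all at the retained-report level.
#'
#' @param case_ids case primaryids.
#' @param drug_exposure exposure data.frame from [normalize_drugs()].
#' @param all_retained all retained primaryids.
#' @param min_n111 minimum both-drug event count for a pair to be kept.
#' @return data.frame of class `triplet_table`: `drugA`, `drugB` (A < B
#'   alphabetically), `n111`, `n11plus`, `f10`, `f01`, `f00`, plus the
#'   stratum sizes `n10`, `n01`, `n00` backing the proportions.
#' @export
count_triplets <- function(case_ids, drug_exposure, all_retained,
                           min_n111 = 1) {
  stopifnot(min_n111 >= 1)
  dx <- data.table::as.data.table(
    unique(drug_exposure[c("primaryid", "drug")]))
  dx <- dx[dx$primaryid %in% all_retained]
  case_ids <- unique(case_ids[case_ids %in% all_retained])
  N <- length(all_retained)
  E <- length(case_ids)
  dx$is_case <- dx$primaryid %in% case_ids

  per_drug <- dx[, list(n1 = .N, e1 = sum(is_case)), by = "drug"]

  pairs <- merge(dx, dx, by = "primaryid", allow.cartesian = TRUE,
                 suffixes = c("A", "B"))
  pairs <- pairs[pairs$drugA < pairs$drugB]
  if (!nrow(pairs)) {
    out <- data.frame(drugA = character(), drugB = character(),
                      n111 = integer(), n11plus = integer(),
                      f10 = numeric(), f01 = numeric(), f00 = numeric(),
                      n10 = integer(), n01 = integer(), n00 = integer())
    class(out) <- c("triplet_table", class(out))
    return(out)
  }
  agg <- pairs[, list(n11plus = .N, n111 = sum(is_caseA)),
               by = c("drugA", "drugB")]
  agg <- agg[agg$n111 >= min_n111]

  agg <- merge(agg, per_drug, by.x = "drugA", by.y = "drug")
  data.table::setnames(agg, c("n1", "e1"), c("nA", "eA"))
  agg <- merge(agg, per_drug, by.x = "drugB", by.y = "drug")
  data.table::setnames(agg, c("n1", "e1"), c("nB", "eB"))

  out <- data.frame(
    drugA = agg$drugA, drugB = agg$drugB,
    n111 = as.integer(agg$n111), n11plus = as.integer(agg$n11plus),
    stringsAsFactors = FALSE
  )
  out$n10 <- as.integer(agg$nA - agg$n11plus)
  out$n01 <- as.integer(agg$nB - agg$n11plus)
  out$n00 <- as.integer(N - agg$nA - agg$nB + agg$n11plus)
  e10 <- agg$eA - agg$n111
  e01 <- agg$eB - agg$n111
  e00 <- E - agg$eA - agg$eB + agg$n111
  out$f10 <- ifelse(out$n10 > 0, e10 / out$n10, NA_real_)
  out$f01 <- ifelse(out$n01 > 0, e01 / out$n01, NA_real_)
  out$f00 <- ifelse(out$n00 > 0, e00 / out$n00, NA_real_)
  out <- out[base::order(out$drugA, out$drugB),
             c("drugA", "drugB", "n111", "n11plus",
               "f10", "f01", "f00", "n10", "n01", "n00")]
  rownames(out) <- NULL
  class(out) <- c("triplet_table", class(out))
  out
}

# one-model expected proportion; NA when the model cannot be evaluated
.g111_one <- function(f10, f01, f00, model) {
  floor_p <- suppressWarnings(max(f10, f01, na.rm = TRUE))
  if (model == "odds_additive") {
    if (anyNA(c(f10, f01, f00)) || f00 >= 1) return(NA_real_)
    if (f10 >= 1 || f01 >= 1) return(1)
    os <- .odds(f10) + .odds(f01) - .odds(f00)
    os <- max(os, .odds(f10), .odds(f01))
    return(os / (1 + os))
  }
  if (model == "multiplicative") {
    if (anyNA(c(f10, f01, f00)) || f00 >= 1) return(NA_real_)
    g <- 1 - (1 - f10) * (1 - f01) / (1 - f00)
    return(min(1, max(g, floor_p)))
  }
  if (model == "max_single") {
    if (!is.finite(floor_p)) return(NA_real_)
    return(floor_p)
  }
  stop("unknown E111 model: ", model)
}

#' Expected both-drug event count under a no-interaction baseline
#'
#' Converts the single-drug stratum proportions into an expected event
#' probability among both-drug reports, then scales by `n11plus`. Models:
#' `odds_additive` (default) adds the excess odds of each drug over the
#' neither-drug baseline, floored at the larger single-drug odds;
#' `multiplicative` combines relative risks of remaining event-free;
#' `max_single` takes the larger single-drug proportion. When a model's
#' inputs are degenerate (empty stratum, baseline proportion of 1) the
#' next simpler model in that order is used; the model actually applied is
#' recorded per triplet in `model_used`.
#'
#' @param triplets a `triplet_table` (or a one-row list with `f10`,
#'   `f01`, `f00`, `n11plus`).
#' @param model baseline model.
#' @return the input with columns `E111` and `model_used` added; rows
#'   where no model applies get `E111 = NA`.
#' @export
expected_e111 <- function(triplets,
                          model = c("odds_additive", "multiplicative",
                                    "max_single")) {
  model <- match.arg(model)
  tl <- as.data.frame(triplets)
  if (!nrow(tl)) {
    tl$E111 <- numeric(0); tl$model_used <- character(0)
    return(tl)
  }
  stopifnot(all(c("f10", "f01", "f00", "n11plus") %in% names(tl)))
  chain <- c("odds_additive", "multiplicative", "max_single")
  chain <- chain[match(model, chain):length(chain)]
  g <- rep(NA_real_, nrow(tl))
  used <- rep(NA_character_, nrow(tl))
  for (m in chain) {
    todo <- which(is.na(g))
    if (!length(todo)) break
    gi <- vapply(todo, function(i)
      .g111_one(tl$f10[i], tl$f01[i], tl$f00[i], m), 0)
    hit <- !is.na(gi)
    g[todo[hit]] <- gi[hit]
    used[todo[hit]] <- m
  }
  tl$E111 <- g * tl$n11plus
  tl$model_used <- used
  class(tl) <- unique(c(class(triplets)[1], class(tl)))
  tl
}

#' Omega shrinkage measure with its confidence bounds
#'
#' `omega = log2[(n111+0.5)/(E111+0.5)]`; the interval is symmetric with
#' half-width `z / (ln 2 * sqrt(n111))`. With `n111 = 0` the bounds are
#' undefined and reported as NA (the point estimate remains).
#'
#' @param n111 observed both-drug event count(s).
#' @param E111 expected count(s) from [expected_e111()].
#' @param z normal quantile (1.96 for the 95% interval).
#' @return data.frame `omega`, `omega025`, `omega975`.
#' @export
omega_stat <- function(n111, E111, z = 1.96) {
  stopifnot(length(n111) == length(E111), all(n111 >= 0, na.rm = TRUE),
            all(E111 >= 0, na.rm = TRUE))
  omega <- log2((n111 + 0.5) / (E111 + 0.5))
  half <- ifelse(n111 > 0, z / (log(2) * sqrt(n111)), NA_real_)
  data.frame(omega = omega, omega025 = omega - half,
             omega975 = omega + half)
}

#' Screen and rank interaction triplets
#'
#' Appends the Omega statistics, flags triplets with `omega025 > 0`, and
#' ranks by descending `n111` (ties by descending omega).
#'
#' @param triplets output of [expected_e111()].
#' @param z normal quantile for the Omega interval.
#' @param top_n keep at most this many top triplets.
#' @return data.frame `drugA`, `drugB`, `n111`, `n11plus`, `E111`,
#'   `model_used`, `omega`, `omega025`, `omega975`, `flag`.
#' @export
screen_interactions <- function(triplets, z = 1.96, top_n = Inf) {
  tl <- as.data.frame(triplets)
  stopifnot(all(c("n111", "E111") %in% names(tl)))
  tl <- tl[!is.na(tl$E111), , drop = FALSE]
  om <- omega_stat(tl$n111, tl$E111, z = z)
  out <- cbind(tl[c("drugA", "drugB", "n111", "n11plus", "E111",
                    "model_used")], om)
  out$flag <- !is.na(out$omega025) & out$omega025 > 0
  out <- out[base::order(-out$n111, -out$omega), , drop = FALSE]
  if (is.finite(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
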