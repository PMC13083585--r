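# Four-algorithm disproportionality analysis on 2x2 contingency tables.
#
# For a drug-event pair with cells
#   a (drug & event), b (drug, other events),
#   c (event, other drugs), d (neither), N = a+b+c+d:
#
#   ROR   = (a*d)/(b*c),  95% CI = exp(ln ROR +/- 1.96*sqrt(1/a+1/b+1/c+1/d))
#   PRR   = [a/(a+b)] / [c/(c+d)]
#   chi2  = N*(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]   (Pearson, no continuity
#           correction)
#   IC    = log2[(a+0.5)/(aexp+0.5)], aexp = (a+b)(a+c)/N
#   IC025 = IC - 3.3*(a+0.5)^-1/2 - 2*(a+0.5)^-3/2
#   EBGM  = a*N/[(a+c)(a+b)]  (relative reporting ratio),
#   EBGM05= exp(ln EBGM - 1.64*sqrt(1/a+1/b+1/c+1/d))
#
# Signal thresholds (all require a >= 3): ROR lower CI > 1; PRR >= 2 with
# chi2 >= 4; IC025 > 0; EBGM05 > 2. The combined rule is the conjunction
# of all four — deliberately conservative.
#
# Zero cells: a Haldane-Anscombe +0.5 on every cell is applied, only when
# a zero cell occurs, to the ROR and EBGM computations (whose closed forms
# need all cells positive); the correction is flagged in the output. The
# a >= 3 gate makes the corrected path rare in practice.

.cells <- function(t) {
  if (inherits(t, "contingency")) return(t[c("a", "b", "c", "d")])
  stopifnot(all(c("a", "b", "c", "d") %in% names(t)))
  t[c("a", "b", "c", "d")]
}

# vectorised core over cell vectors; all exported statistics delegate here
.signal_core <- function(a, b, c, d, z_ror = 1.96, z_mgps = 1.64) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  zero <- pmin(a, b, c, d) == 0
  # corrected cells for ROR / EBGM only
  a2 <- a + 0.5 * zero; b2 <- b + 0.5 * zero
  c2 <- c + 0.5 * zero; d2 <- d + 0.5 * zero
  N2 <- a2 + b2 + c2 + d2
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)

  ror <- (a2 * d2) / (b2 * c2)
  ror_lo <- exp(log(ror) - z_ror * se)
  ror_hi <- exp(log(ror) + z_ror * se)

  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  chi2[(a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0] <- NaN

  aexp <- (a + b) * (a + c) / N
  ic <- log2((a + 0.5) / (aexp + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)

  ebgm <- a2 * N2 / ((a2 + c2) * (a2 + b2))
  ebgm05 <- exp(log(ebgm) - z_mgps * se)

  data.frame(a = a, ror = ror, ror_lo = ror_lo, ror_hi = ror_hi,
             prr = prr, chi2 = chi2, ic = ic, ic025 = ic025, aexp = aexp,
             ebgm = ebgm, ebgm05 = ebgm05, corrected = zero)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' @param t a `contingency` table (or list with `a`,`b`,`c`,`d`).
#' @param z normal quantile for the two-sided CI (1.96 for 95%).
#' @return list `ror`, `lo`, `hi`, and `corrected` (TRUE when the
#'   zero-cell +0.5 correction was applied).
#' @export
ror_stat <- function(t, z = 1.96) {
  cl <- .cells(t)
  s <- .signal_core(cl$a, cl$b, cl$c, cl$d, z_ror = z)
  list(ror = s$ror, lo = s$ror_lo, hi = s$ror_hi, corrected = s$corrected)
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' The chi-square is the uncorrected Pearson form (no Yates continuity
#' correction).
#'
#' @param t a `contingency` table.
#' @return list `prr`, `chi2`.
#' @export
prr_stat <- function(t) {
  cl <- .cells(t)
  s <- .signal_core(cl$a, cl$b, cl$c, cl$d)
  list(prr = s$prr, chi2 = s$chi2)
}

#' BCPNN information component with closed-form lower bound
#'
#' The shrunk log2 observed-to-expected measure; `ic025` uses the standard
#' closed-form approximation of the lower 95% credibility bound, not a
#' Monte-Carlo posterior.
#'
#' @param t a `contingency` table.
#' @return list `ic`, `ic025`, `aexp` (expected count under independence).
#' @export
bcpnn_stat <- function(t) {
  cl <- .cells(t)
  s <- .signal_core(cl$a, cl$b, cl$c, cl$d)
  list(ic = s$ic, ic025 = s$ic025, aexp = s$aexp)
}

#' MGPS empirical Bayes geometric mean with normal-approximation bound
#'
#' `ebgm` is the relative reporting ratio `a*N/((a+c)(a+b))`; `ebgm05` its
#' lower bound at quantile `z` (1.64: one-sided 95%).
#'
#' @param t a `contingency` table.
#' @param z normal quantile for the lower bound.
#' @return list `ebgm`, `ebgm05`, `corrected`.
#' @export
mgps_stat <- function(t, z = 1.64) {
  cl <- .cells(t)
  s <- .signal_core(cl$a, cl$b, cl$c, cl$d, z_mgps = z)
  list(ebgm = s$ebgm, ebgm05 = s$ebgm05, corrected = s$corrected)
}

#' Evaluate all four algorithms and the combined signal rule
#'
#' Per-algorithm flags (each requiring at least 3 co-reports):
#' ROR lower 95% bound > 1; PRR >= 2 and chi2 >= 4; IC025 > 0;
#' EBGM05 > 2. `positive` is the conjunction of all four.
#'
#' @param t a `contingency` table.
#' @return one-row data.frame of class `signal_result` with the
#'   statistics, bounds, per-algorithm flags and `positive`.
#' @export
evaluate_signal <- function(t) {
  cl <- .cells(t)
  out <- signal_table(data.frame(drug = if (!is.null(t$drug)) t$drug else NA,
                                 a = cl$a, b = cl$b, c = cl$c, d = cl$d))
  class(out) <- c("signal_result", class(out))
  out
}

#' Disproportionality table for many drugs
#'
#' Vectorised [evaluate_signal()] over a per-drug cell table (the output
#' of [contingency_all()]).
#'
#' @param cells data.frame with columns `drug, a, b, c, d`.
#' @return data.frame: drug, cells, the four statistics with bounds,
#'   per-algorithm flags, `positive`, `corrected`.
#' @export
signal_table <- function(cells) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(cells)))
  s <- .signal_core(cells$a, cells$b, cells$c, cells$d)
  flag_ror <- cells$a >= 3 & s$ror_lo > 1
  flag_prr <- cells$a >= 3 & s$prr >= 2 & !is.na(s$chi2) & s$chi2 >= 4
  flag_bcpnn <- cells$a >= 3 & s$ic025 > 0
  flag_mgps <- cells$a >= 3 & s$ebgm05 > 2
  out <- data.frame(
    drug = if ("drug" %in% names(cells)) cells$drug else NA_character_,
    a = cells$a, b = cells$b, c = cells$c, d = cells$d,
    ror = s$ror, ror_lo = s$ror_lo, ror_hi = s$ror_hi,
    prr = s$prr, chi2 = s$chi2,
    ic = s$ic, ic025 = s$ic025, aexp = s$aexp,
    ebgm = s$ebgm, ebgm05 = s$ebgm05,
    flag_ror = flag_ror, flag_prr = flag_prr,
    flag_bcpnn = flag_bcpnn, flag_mgps = flag_mgps,
    positive = flag_ror & flag_prr & flag_bcpnn & flag_mgps,
    corrected = s$corrected,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Rank a signal table
#'
#' Stable descending sort by reported case count (`a`) or ROR; ties broken
#' alphabetically by drug name.
#'
#' @param results a [signal_table()] data.frame.
#' @param by `"case_count"` or `"ror"`.
#' @return the reordered data.frame.
#' @export
rank_drugs <- function(results, by = c("case_count", "ror")) {
  by <- match.arg(by)
  stopifnot(nrow(results) > 0)
  key <- if (by == "case_count") results$a else results$ror
  out <- results[order(-key, results$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
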