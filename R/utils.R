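# Shared helpers. Kept internal.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all printed percentages.
#' `round()` in R rounds half to even, which disagrees with the reporting
#' convention on exact .005 boundaries.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  # nudge guards against representation error just below .5 boundaries
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Reporting percentage
#'
#' `100 * count / total`, rounded half-up to two decimals; the format in
#' which all descriptive percentages are printed.
#'
#' @param count numerator count(s).
#' @param total denominator count.
#' @return numeric percentage(s), two decimals.
#' @export
report_percent <- function(count, total) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, 2)
}

# whitespace-squish + trim; NA -> ""
squish <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  gsub("\\s+", " ", trimws(x))
}

# case-insensitive normalised key for PT / drug-name matching
norm_key <- function(x) toupper(squish(x))

# FAERS identifiers are numeric-as-text; order numerically when possible,
# otherwise lexicographically after stripping leading zeros.
id_order_key <- function(id) {
  num <- suppressWarnings(as.numeric(id))
  if (!anyNA(num)) return(num)
  stripped <- sub("^0+(?=.)", "", as.character(id), perl = TRUE)
  ord <- order(nchar(stripped), stripped)
  rank <- integer(length(id))
  rank[ord] <- seq_along(id)
  rank
}
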