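# Report deduplication and deletion-list removal.
#
# One FAERS case (CASEID) accumulates report versions (PRIMARYID) over
# time. The cleaning rule keeps, per case, the version with the largest
# FDA_DT; among equal FDA_DT, the largest PRIMARYID (numerically). After
# deduplication, cases named on any quarterly deletion list are removed.

#' Deduplicate report versions by case
#'
#' Retains exactly one DEMO record per `caseid`: the one with maximal
#' `fda_dt`; ties broken by maximal numeric `primaryid`. Records whose
#' `fda_dt` lacks day precision sort below every day-precision value (and
#' among themselves by `primaryid`), so an undated version can never
#' displace a dated one. The result is invariant under row permutation and
#' idempotent.
#'
#' @param demo data.frame with columns `primaryid`, `caseid`, `fda_dt`.
#' @return object of class `dedup_result`: list with
#'   `retained_primaryids`, `removed_as_duplicate`, `removed_by_deletion`
#'   (0 until [apply_deletions()]), and `n_input`.
#' @export
deduplicate <- function(demo) {
  demo <- as.data.frame(demo)
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (anyDuplicated(demo$primaryid)) {
    dup <- demo$primaryid[duplicated(demo$primaryid)][1]
    stop("duplicate primaryid in input (violates FAERS key): ", dup)
  }
  key_dt <- date_sort_key(demo$fda_dt)
  key_pid <- id_order_key(demo$primaryid)
  o <- order(demo$caseid, -key_dt, -key_pid)
  keep <- !duplicated(demo$caseid[o])
  retained <- demo$primaryid[o][keep]
  structure(
    list(
      retained_primaryids = retained,
      removed_as_duplicate = nrow(demo) - length(retained),
      removed_by_deletion = 0L,
      n_input = nrow(demo)
    ),
    class = "dedup_result"
  )
}

#' Remove reports named on deletion lists
#'
#' Applied after [deduplicate()] (the cleaning order is: deduplicate, then
#' delete). Retained reports whose `caseid` appears in any quarter's
#' deletion list are removed and counted; caseids on the list that match
#' no retained report are ignored.
#'
#' @param result a `dedup_result`.
#' @param demo the DEMO table the result was computed from.
#' @param deletion_caseids character vector of caseids (union over quarters).
#' @return the updated `dedup_result`.
#' @export
apply_deletions <- function(result, demo, deletion_caseids) {
  stopifnot(inherits(result, "dedup_result"))
  demo <- as.data.frame(demo)
  caseid <- demo$caseid[match(result$retained_primaryids, demo$primaryid)]
  drop <- caseid %in% deletion_caseids
  result$retained_primaryids <- result$retained_primaryids[!drop]
  result$removed_by_deletion <- result$removed_by_deletion + sum(drop)
  result
}

#' @export
print.dedup_result <- function(x, ...) {
  cat("<dedup_result>\n")
  cat("  input reports      :", x$n_input, "\n")
  cat("  retained           :", length(x$retained_primaryids), "\n")
  cat("  removed (duplicate):", x$removed_as_duplicate, "\n")
  cat("  removed (deletion) :", x$removed_by_deletion, "\n")
  invisible(x)
}

#' Write the retained-id audit list
#'
#' One retained `primaryid` per line, for external audit of the cleaning
#' step.
#'
#' @param result a `dedup_result`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_retained_ids <- function(result, path) {
  stopifnot(inherits(result, "dedup_result"))
  writeLines(result$retained_primaryids, path)
  invisible(path)
}
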