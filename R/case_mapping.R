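# Case definition via MedDRA preferred-term query sets, drug-name
# normalization, and per-drug 2x2 contingency tables.
#
# MedDRA itself is licensed, so the PT query (e.g. the SMQ "dystonia"
# narrow set) is a user-supplied file; matching is by normalised PT text
# (case-insensitive, whitespace-squished), with codes honoured when the
# file carries them.

#' Build a preferred-term query set
#'
#' @param pts character vector of preferred terms.
#' @param name query label.
#' @param scope `"narrow"` or `"broad"`.
#' @return object of class `pt_query` with a deduplicated, normalised
#'   term set.
#' @export
pt_query <- function(pts, name = "query", scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  keys <- unique(norm_key(pts))
  keys <- keys[nzchar(keys)]
  if (!length(keys)) stop("PT query is empty")
  structure(list(name = name, scope = scope, pts = keys),
            class = "pt_query")
}

#' Load a preferred-term query file
#'
#' Accepts a CSV with a `pt` column (optional `code`, `scope` columns) or a
#' bare one-term-per-line text file. Terms are normalised (case and
#' whitespace) and deduplicated.
#'
#' @param path file path.
#' @param scope query scope; when the file has a `scope` column, rows are
#'   filtered to it (a narrow query is a subset of the broad one).
#' @return a [pt_query()].
#' @export
load_pt_query <- function(path, scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  first <- readLines(path, n = 1, warn = FALSE)
  if (!length(first)) stop("PT query file '", path, "' is empty")
  if (grepl(",", first) || tolower(trimws(first)) == "pt") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!"pt" %in% names(df))
      stop("PT query file '", path, "' has no 'pt' column")
    if ("scope" %in% names(df)) {
      keep <- tolower(df$scope) == scope |
        (scope == "broad") # narrow terms belong to broad too
      df <- df[keep, , drop = FALSE]
    }
    pts <- df$pt
  } else {
    pts <- readLines(path, warn = FALSE)
  }
  pts <- pts[nzchar(trimws(pts))]
  if (!length(pts)) stop("PT query file '", path, "' is empty")
  pt_query(pts, name = tools::file_path_sans_ext(basename(path)),
           scope = scope)
}

#' @export
print.pt_query <- function(x, ...) {
  cat(sprintf("<pt_query> %s (%s): %d preferred terms\n",
              x$name, x$scope, length(x$pts)))
  invisible(x)
}

#' Flag case reports by preferred-term membership
#'
#' A retained report is a case iff at least one of its reaction PTs belongs
#' to the query set; several matching PTs on one report still yield one
#' case.
#'
#' @param reac REAC table (`primaryid`, `pt`).
#' @param retained character vector of retained primaryids (post-dedup).
#' @param query a [pt_query()].
#' @return character vector of case primaryids.
#' @export
flag_cases <- function(reac, retained, query) {
  stopifnot(inherits(query, "pt_query"))
  reac <- as.data.frame(reac)
  hit <- norm_key(reac$pt) %in% query$pts & reac$primaryid %in% retained
  unique(reac$primaryid[hit])
}

#' Build a drug-name normalizer
#'
#' Maps verbatim/synonym drug names to canonical names (and optionally an
#' ATC class), standing in for the licensed WHO Drug Dictionary mapping.
#'
#' @param verbatim character vector of verbatim names (matching is
#'   case/whitespace-insensitive).
#' @param canonical canonical name for each verbatim entry.
#' @param atc optional ATC class per entry.
#' @return object of class `drug_map`.
#' @export
drug_map <- function(verbatim, canonical, atc = NULL) {
  stopifnot(length(verbatim) == length(canonical))
  key <- norm_key(verbatim)
  if (anyDuplicated(key)) {
    dup <- !duplicated(key)
    key <- key[dup]; canonical <- canonical[dup]
    if (!is.null(atc)) atc <- atc[dup]
  }
  canonical <- tolower(squish(canonical))
  atc_by_canonical <- NULL
  if (!is.null(atc)) {
    atc_by_canonical <- atc[!duplicated(canonical)]
    names(atc_by_canonical) <- canonical[!duplicated(canonical)]
  }
  structure(list(mapping = stats::setNames(canonical, key),
                 atc = atc_by_canonical),
            class = "drug_map")
}

#' Load a drug-name normalization table
#'
#' CSV with columns `verbatim,canonical[,atc]`.
#'
#' @param path file path.
#' @return a [drug_map()].
#' @export
load_drug_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("verbatim", "canonical") %in% names(df)))
    stop("drug map '", path, "' needs columns verbatim, canonical")
  drug_map(df$verbatim, df$canonical, df$atc)
}

#' @export
print.drug_map <- function(x, ...) {
  cat(sprintf("<drug_map> %d verbatim names -> %d canonical drugs\n",
              length(x$mapping), length(unique(x$mapping))))
  invisible(x)
}

#' Normalize suspect-drug exposure per report
#'
#' Restricts DRUG records to the requested role codes (default `"PS"`,
#' reading "highest suspicion" as primary suspect; pass `c("PS","SS")` or
#' wider for sensitivity), canonicalizes names through the normalizer, and
#' collapses to one row per (report, canonical drug). Verbatim names
#' missing from the mapping are excluded and reported via a warning and
#' the `unmapped` attribute.
#'
#' @param drug DRUG table (`primaryid`, `drug_seq`, `role_cod`,
#'   `drugname`, `prod_ai`).
#' @param norm a [drug_map()].
#' @param roles subset of `c("PS","SS","C","I")`.
#' @param keep_seq keep the `drug_seq` column (needed to join therapy
#'   dates for time-to-onset).
#' @return data.frame `primaryid`, `drug` (canonical), unique pairs;
#'   with `drug_seq` when `keep_seq = TRUE`.
#' @export
normalize_drugs <- function(drug, norm, roles = "PS", keep_seq = FALSE) {
  stopifnot(inherits(norm, "drug_map"),
            all(roles %in% .role_codes))
  drug <- as.data.frame(drug)
  drug <- drug[drug$role_cod %in% roles, , drop = FALSE]
  canon <- norm$mapping[norm_key(drug$drugname)]
  # verbatim miss: fall back to the active-ingredient field
  miss <- is.na(canon)
  if (any(miss) && "prod_ai" %in% names(drug))
    canon[miss] <- norm$mapping[norm_key(drug$prod_ai[miss])]
  unmapped <- unique(drug$drugname[is.na(canon)])
  unmapped <- unmapped[!is.na(unmapped)]
  if (length(unmapped))
    warning(length(unmapped), " verbatim drug name(s) not in the mapping; ",
            "excluded (see attr 'unmapped')")
  keep <- !is.na(canon)
  out <- data.frame(primaryid = drug$primaryid[keep],
                    drug = unname(canon[keep]),
                    stringsAsFactors = FALSE)
  if (keep_seq) out$drug_seq <- drug$drug_seq[keep]
  out <- unique(out)
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Build the 2x2 contingency table for one drug
#'
#' Cells are counted at the retained-report level: `a` reports with drug
#' and event, `b` with drug only, `c` with event only, `d` with neither;
#' `a+b+c+d` equals the retained report count.
#'
#' @param case_ids character vector of case primaryids.
#' @param drug_exposure exposure data.frame from [normalize_drugs()].
#' @param all_retained character vector of all retained primaryids.
#' @param drug canonical drug name.
#' @return object of class `contingency`: list `a`, `b`, `c`, `d`, `N`,
#'   `drug`.
#' @export
build_contingency <- function(case_ids, drug_exposure, all_retained, drug) {
  exposed <- unique(drug_exposure$primaryid[drug_exposure$drug == drug])
  exposed <- exposed[exposed %in% all_retained]
  case_ids <- unique(case_ids[case_ids %in% all_retained])
  a <- sum(exposed %in% case_ids)
  b <- length(exposed) - a
  c_ <- length(case_ids) - a
  d <- length(all_retained) - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d,
                 N = length(all_retained), drug = drug),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("<contingency> %s: a=%d b=%d c=%d d=%d (N=%d)\n",
              x$drug %||% "?", x$a, x$b, x$c, x$d, x$N))
  invisible(x)
}

#' Contingency cells for every drug at once
#'
#' Vectorised equivalent of [build_contingency()] over all canonical drugs
#' present in the exposure table.
#'
#' @inheritParams build_contingency
#' @return data.frame `drug, a, b, c, d` (one row per drug), ordered by
#'   drug name.
#' @export
contingency_all <- function(case_ids, drug_exposure, all_retained) {
  dx <- data.table::as.data.table(unique(drug_exposure[c("primaryid", "drug")]))
  dx <- dx[dx$primaryid %in% all_retained]
  case_ids <- unique(case_ids[case_ids %in% all_retained])
  n_case <- length(case_ids)
  N <- length(all_retained)
  dx$is_case <- dx$primaryid %in% case_ids
  agg <- dx[, list(a = sum(is_case), exposed = .N), by = "drug"]
  out <- data.frame(
    drug = agg$drug,
    a = as.integer(agg$a),
    b = as.integer(agg$exposed - agg$a),
    stringsAsFactors = FALSE
  )
  out$c <- n_case - out$a
  out$d <- N - out$a - out$b - out$c
  out <- out[order(out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
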