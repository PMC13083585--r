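# Reading and writing FAERS-style quarterly ASCII bundles.
#
# Dialect: post-2012 FAERS ASCII — dollar-delimited text tables with a
# header row (DEMO/DRUG/REAC/THER/OUTC) plus an optional deletion list of
# one CASEID per line. Column names follow the post-2012 schema
# (primaryid, caseid, fda_dt, event_dt, occp_cod, role_cod, drugname,
# prod_ai, dsg_drug_seq, start_dt, end_dt, outc_cod).

# Known columns per table; the first entry of each is mandatory.
.faers_columns <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "occp_cod", "reporter_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  outc = c("primaryid", "outc_cod")
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.occp_codes <- c("MD", "PH", "LW", "CN", "HP", "OT")

#' Parse FAERS date strings into precision-tagged date values
#'
#' FAERS dates come as `YYYYMMDD`, `YYYYMM`, `YYYY`, or blank. Nothing is
#' imputed: each value is tagged with its precision and only day-precision
#' values receive a day ordinal (days since 1970-01-01), so downstream
#' exclusion rules — not imputation — decide what to do with partial dates.
#' Calendar-invalid 8-digit strings (month 13, Feb 30, ...) and 6-digit
#' strings with an invalid month are classed `missing`; the count of such
#' strings is attached as attribute `n_invalid`. The function is total: it
#' never errors on malformed input.
#'
#' @param raw character vector of date strings (NA and "" allowed).
#' @return data.frame of class `faers_date` with columns `raw`,
#'   `precision` (factor: day/month/year/missing) and `ordinal`
#'   (integer day count, NA unless precision is day).
#' @examples
#' parse_date(c("20230106", "202301", "2023", "", "20231350"))$precision
#' @export
parse_date <- function(raw) {
  raw <- squish(raw)
  n <- length(raw)
  precision <- rep("missing", n)
  ordinal <- rep(NA_integer_, n)
  n_invalid <- 0L

  is4 <- grepl("^\\d{4}$", raw)
  precision[is4] <- "year"

  is6 <- grepl("^\\d{6}$", raw)
  if (any(is6)) {
    mo <- as.integer(substr(raw[is6], 5, 6))
    ok <- mo >= 1L & mo <= 12L
    precision[which(is6)[ok]] <- "month"
    n_invalid <- n_invalid + sum(!ok)
  }

  is8 <- grepl("^\\d{8}$", raw)
  if (any(is8)) {
    d <- as.Date(raw[is8], format = "%Y%m%d") # NA for calendar-invalid
    ok <- !is.na(d)
    precision[which(is8)[ok]] <- "day"
    ordinal[which(is8)[ok]] <- as.integer(d[ok])
    n_invalid <- n_invalid + sum(!ok)
  }

  out <- data.frame(
    raw = raw,
    precision = factor(precision, levels = c("day", "month", "year", "missing")),
    ordinal = ordinal,
    stringsAsFactors = FALSE
  )
  attr(out, "n_invalid") <- n_invalid
  class(out) <- c("faers_date", class(out))
  out
}

# day ordinals with non-day precision mapped to -Inf, so that any dated
# value outranks any partial/missing one (used by the dedup sort)
date_sort_key <- function(raw) {
  pd <- parse_date(raw)
  ifelse(pd$precision == "day", as.numeric(pd$ordinal), -Inf)
}

#' Construct a quarterly report bundle
#'
#' Container for one quarter's parsed DEMO/DRUG/REAC/THER/OUTC tables plus
#' the quarter's deletion list. All tables are data.frames keyed by
#' `primaryid`; missing tables default to empty.
#'
#' @param quarter quarter label, e.g. `"23Q1"`.
#' @param demo,drug,reac,ther,outc data.frames with the post-2012 FAERS
#'   columns (see [read_quarter()]); missing known columns are added as NA.
#' @param deletion_caseids character vector of CASEIDs slated for removal.
#' @return object of class `faers_bundle`.
#' @export
faers_bundle <- function(quarter, demo, drug = NULL, reac = NULL, ther = NULL,
                         outc = NULL, deletion_caseids = character()) {
  b <- structure(
    list(
      quarter = as.character(quarter),
      demo = .coerce_table(demo, "demo"),
      drug = .coerce_table(drug, "drug"),
      reac = .coerce_table(reac, "reac"),
      ther = .coerce_table(ther, "ther"),
      outc = .coerce_table(outc, "outc"),
      deletion_caseids = unique(as.character(deletion_caseids))
    ),
    class = "faers_bundle"
  )
  validate_bundle(b)
}

# normalise a user/parsed table to the known-column layout (character cols)
.coerce_table <- function(x, table) {
  cols <- .faers_columns[[table]]
  if (is.null(x)) {
    x <- as.data.frame(stats::setNames(
      rep(list(character()), length(cols)), cols))
    return(x)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  for (cc in setdiff(cols, names(x))) x[[cc]] <- NA_character_
  x <- x[cols]
  for (cc in cols) x[[cc]] <- as.character(x[[cc]])
  rownames(x) <- NULL
  x
}

#' Validate a report bundle
#'
#' Checks the structural invariants: unique `primaryid` within DEMO,
#' non-empty caseids, role codes within the closed FAERS set, and that every
#' drug/reac/ther/outc `primaryid` appears in DEMO. Orphan rows (ids absent
#' from DEMO) are tolerated and recorded in attribute `orphans`, not
#' dropped; the deletion list may reference absent caseids.
#'
#' @param b a `faers_bundle`.
#' @return `b`, invisibly annotated; errors on hard violations.
#' @export
validate_bundle <- function(b) {
  stopifnot(inherits(b, "faers_bundle"))
  if (anyDuplicated(b$demo$primaryid))
    stop("duplicate primaryid in DEMO table of quarter ", b$quarter)
  if (nrow(b$demo) && any(is.na(b$demo$caseid) | b$demo$caseid == ""))
    stop("empty caseid in DEMO table of quarter ", b$quarter)
  bad_role <- setdiff(unique(stats::na.omit(b$drug$role_cod)), .role_codes)
  if (length(bad_role))
    stop("unknown drug role code(s): ", paste(bad_role, collapse = ", "))
  orphans <- lapply(c("drug", "reac", "ther", "outc"), function(tb) {
    setdiff(unique(b[[tb]]$primaryid), b$demo$primaryid)
  })
  names(orphans) <- c("drug", "reac", "ther", "outc")
  attr(b, "orphans") <- orphans
  invisible(b)
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle> quarter", x$quarter, "\n")
  cat(sprintf("  demo %d | drug %d | reac %d | ther %d | outc %d rows\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$ther),
              nrow(x$outc)))
  cat("  deletion caseids:", length(x$deletion_caseids), "\n")
  invisible(x)
}

# find FAERS files in a quarter directory by name prefix
.locate_quarter_files <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  pick <- function(pattern) {
    hit <- files[grepl(pattern, basename(files), ignore.case = TRUE)]
    if (length(hit)) hit[1] else NA_character_
  }
  c(demo = pick("^demo"), drug = pick("^drug"), reac = pick("^reac"),
    ther = pick("^ther"), outc = pick("^outc"), delete = pick("delet"))
}

# read one dollar-delimited table, keep known columns, check mandatory ones
.read_faers_table <- function(path, table) {
  dt <- data.table::fread(
    path, sep = "$", quote = "", header = TRUE,
    colClasses = "character", na.strings = "",
    encoding = "UTF-8", fill = TRUE, showProgress = FALSE
  )
  data.table::setnames(dt, tolower(names(dt)))
  mandatory <- .faers_columns[[table]][1]
  if (table == "demo") mandatory <- c("primaryid", "caseid")
  miss <- setdiff(mandatory, names(dt))
  if (length(miss))
    stop(sprintf("file '%s' lacks mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")))
  .coerce_table(dt, table)
}

#' Read one FAERS-style quarter
#'
#' Ingests the dollar-delimited tables of one quarterly package. `paths`
#' may be a directory (files located by name prefix: DEMO*, DRUG*, REAC*,
#' THER*, OUTC*, *DELET*) or a named character vector with elements
#' `demo`, `drug`, `reac`, `ther`, `outc`, `delete` (demo mandatory, the
#' rest optional). All rows are kept; unknown columns are ignored; rows
#' referencing a `primaryid` absent from DEMO are logged as orphans on the
#' returned bundle, not dropped. Input is treated as UTF-8.
#'
#' @param paths directory or named character vector of file paths.
#' @param quarter quarter label; defaults to the directory/file name stem.
#' @return a [faers_bundle()].
#' @export
read_quarter <- function(paths, quarter = NULL) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    if (is.null(quarter)) quarter <- basename(normalizePath(paths))
    paths <- .locate_quarter_files(paths)
  }
  if (is.na(paths["demo"] %||% NA))
    stop("no DEMO file found: a quarter needs at least a demo table")
  if (is.null(quarter))
    quarter <- sub("^[Dd][Ee][Mm][Oo]", "",
                   tools::file_path_sans_ext(basename(paths[["demo"]])))
  if (!nzchar(quarter)) quarter <- "Q?"

  tabs <- lapply(c(demo = "demo", drug = "drug", reac = "reac",
                   ther = "ther", outc = "outc"), function(tb) {
    p <- paths[tb]
    if (is.na(p) || !nzchar(p)) return(NULL)
    .read_faers_table(p, tb)
  })
  del <- character()
  if (!is.na(paths["delete"] %||% NA) && nzchar(paths[["delete"]])) {
    del <- readLines(paths[["delete"]], warn = FALSE)
    del <- del[nzchar(trimws(del))]
    # tolerate a header line
    del <- setdiff(trimws(del), c("caseid", "CASEID"))
  }
  faers_bundle(quarter, tabs$demo, tabs$drug, tabs$reac, tabs$ther,
               tabs$outc, deletion_caseids = del)
}

#' Write a bundle as FAERS-style ASCII files
#'
#' Emits dollar-delimited files in the same dialect [read_quarter()]
#' accepts (`DEMO<quarter>.txt`, ... ), plus a deletion list
#' (`DELETED<quarter>.txt`, one caseid per line) when the bundle has one.
#' `write_quarter` followed by `read_quarter` is the identity on record
#' content.
#'
#' @param bundle a [faers_bundle()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_quarter <- function(bundle, dir) {
  stopifnot(inherits(bundle, "faers_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  q <- bundle$quarter
  files <- c()
  for (tb in c("demo", "drug", "reac", "ther", "outc")) {
    path <- file.path(dir, paste0(toupper(tb), q, ".txt"))
    data.table::fwrite(bundle[[tb]], path, sep = "$", quote = FALSE, na = "")
    files[tb] <- path
  }
  if (length(bundle$deletion_caseids)) {
    path <- file.path(dir, paste0("DELETED", q, ".txt"))
    writeLines(bundle$deletion_caseids, path)
    files["delete"] <- path
  }
  invisible(files)
}

#' Combine several quarterly bundles into one
#'
#' Row-binds the five tables across quarters and unions the deletion lists
#' (deletions apply cumulatively: a caseid deleted in any quarter is
#' removed). Used before deduplication, which operates on the full DEMO
#' history.
#'
#' @param bundles list of [faers_bundle()] objects.
#' @return a single `faers_bundle` labelled with the joined quarter names.
#' @export
combine_bundles <- function(bundles) {
  if (inherits(bundles, "faers_bundle")) return(bundles)
  stopifnot(length(bundles) >= 1)
  lab <- paste(vapply(bundles, `[[`, "", "quarter"), collapse = "+")
  grab <- function(tb) do.call(rbind, lapply(bundles, `[[`, tb))
  faers_bundle(
    lab, grab("demo"), grab("drug"), grab("reac"), grab("ther"), grab("outc"),
    deletion_caseids = unique(unlist(lapply(bundles, `[[`, "deletion_caseids")))
  )
}
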