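# Descriptive tables, the lawyer-exclusion sensitivity analysis, and the
# end-to-end pipeline driver.

.occp_labels <- c(MD = "Physician", PH = "Pharmacist", LW = "Lawyer",
                  CN = "Consumer", HP = "Other health-professional",
                  OT = "Not specified")
.outcome_labels <- c(
  HO = "Hospitalization: initial or prolonged",
  DS = "Disability",
  LT = "Life-threatening",
  DE = "Death",
  RI = "Required intervention to prevent permanent impairment/damage",
  CA = "Congenital anomaly",
  OT = "Other")
# age-unit factors to years (FAERS age_cod)
.age_unit_years <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 7 / 365.25,
                     DY = 1 / 365.25, HR = 1 / 8766)

.age_band <- function(age, unit) {
  yrs <- as.numeric(age) * .age_unit_years[toupper(squish(unit))]
  band <- rep("Unknown", length(age))
  known <- !is.na(yrs)
  band[known & yrs < 18] <- "< 18"
  band[known & yrs >= 18 & yrs < 45] <- "18-44"
  band[known & yrs >= 45 & yrs < 65] <- "45-64"
  band[known & yrs >= 65 & yrs < 75] <- "65-74"
  band[known & yrs >= 75 & yrs < 85] <- "75-84"
  band[known & yrs >= 85] <- ">= 85"
  n_bad_unit <- sum(!is.na(as.numeric(age)) & is.na(yrs) &
                      nzchar(squish(unit)))
  attr(band, "n_unknown_unit") <- n_bad_unit
  band
}

.count_block <- function(values, levels, total) {
  counts <- table(factor(values, levels = levels))
  data.frame(category = levels, count = as.integer(counts),
             pct = report_percent(as.integer(counts), total),
             stringsAsFactors = FALSE)
}

#' Descriptive characteristics of case reports
#'
#' Counts and percentages by sex, age band (ages normalised to years via
#' the FAERS age unit before banding; unknown units are routed to the
#' Unknown band with a warning), reporter occupation, top reporting
#' countries, and serious-outcome codes. Outcome percentages are computed
#' per code against the case total — a report can carry several outcomes,
#' so they may sum past 100. All percentages are half-up rounded to two
#' decimals against the case total.
#'
#' @param demo_cases DEMO rows of the retained case reports.
#' @param outc OUTC table (optional).
#' @param tto_summary a [summarize_tto()] result to attach (optional).
#' @param top_countries how many countries to list.
#' @return list of class `descriptive_summary`: data.frames `sex`, `age`,
#'   `reporter`, `countries`, `outcomes`, plus `tto` and `total`.
#' @export
descriptive_table <- function(demo_cases, outc = NULL, tto_summary = NULL,
                              top_countries = 5) {
  demo_cases <- as.data.frame(demo_cases)
  total <- nrow(demo_cases)
  stopifnot(total > 0)

  sex <- ifelse(demo_cases$sex %in% c("F", "M"), demo_cases$sex,
                "Not specified")
  sex <- c(F = "Female", M = "Male",
           `Not specified` = "Not specified")[sex]
  sex_block <- .count_block(sex, c("Female", "Male", "Not specified"), total)

  band <- .age_band(demo_cases$age, demo_cases$age_cod)
  if (isTRUE(attr(band, "n_unknown_unit") > 0))
    warning(attr(band, "n_unknown_unit"),
            " record(s) with unknown age unit routed to Unknown band")
  age_block <- .count_block(
    band, c("< 18", "18-44", "45-64", "65-74", "75-84", ">= 85", "Unknown"),
    total)

  occ <- .occp_labels[squish(demo_cases$occp_cod)]
  occ[is.na(occ)] <- "Not specified"
  rep_block <- .count_block(occ, unique(c(unname(.occp_labels))), total)

  ctry <- squish(demo_cases$reporter_country)
  ctry[!nzchar(ctry)] <- "Unknown"
  tab <- sort(table(ctry), decreasing = TRUE)
  top <- utils::head(names(tab), top_countries)
  ctry_block <- data.frame(category = top, count = as.integer(tab[top]),
                           pct = report_percent(as.integer(tab[top]), total),
                           stringsAsFactors = FALSE)

  out_block <- NULL
  if (!is.null(outc) && nrow(as.data.frame(outc))) {
    outc <- as.data.frame(outc)
    outc <- outc[outc$primaryid %in% demo_cases$primaryid, , drop = FALSE]
    per_code <- table(factor(squish(outc$outc_cod),
                             levels = names(.outcome_labels)))
    out_block <- data.frame(
      category = unname(.outcome_labels),
      count = as.integer(per_code),
      pct = report_percent(as.integer(per_code), total),
      stringsAsFactors = FALSE)
  }

  structure(list(total = total, sex = sex_block, age = age_block,
                 reporter = rep_block, countries = ctry_block,
                 outcomes = out_block, tto = tto_summary),
            class = "descriptive_summary")
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat("<descriptive_summary>", x$total, "case reports\n")
  for (bl in c("sex", "age", "reporter", "countries", "outcomes")) {
    if (is.null(x[[bl]])) next
    cat("--", bl, "--\n")
    print(x[[bl]], row.names = FALSE)
  }
  if (!is.null(x$tto)) print(x$tto)
  invisible(x)
}

# flatten a descriptive summary into one stacked data.frame for CSV export
.descriptive_flat <- function(ds) {
  blocks <- c("sex", "age", "reporter", "countries", "outcomes")
  do.call(rbind, lapply(blocks, function(bl) {
    if (is.null(ds[[bl]])) return(NULL)
    cbind(block = bl, ds[[bl]])
  }))
}

# case definition + exposure + per-drug signal screen on a retained set;
# shared by the pipeline and the sensitivity analysis
.signal_screen <- function(retained, demo, reac, drug, norm, query, roles) {
  cases <- flag_cases(reac, retained, query)
  expo <- suppressWarnings(normalize_drugs(drug, norm, roles = roles))
  expo <- expo[expo$primaryid %in% retained, , drop = FALSE]
  cells <- contingency_all(cases, expo, retained)
  sig <- if (nrow(cells)) rank_drugs(signal_table(cells)) else
    signal_table(cells)
  list(cases = cases, exposure = expo, cells = cells, signals = sig)
}

#' Reporter-occupation exclusion sensitivity analysis
#'
#' Re-runs the case definition and four-algorithm screen after removing
#' retained reports filed by the given reporter occupation (the lawyer
#' stratum, `"LW"`, for litigation-bias assessment), and diffs the
#' positive-signal sets and per-drug statistics against the baseline.
#'
#' @param occupation one FAERS occupation code (`MD`, `PH`, `LW`, `CN`,
#'   `HP`, `OT`).
#' @param demo,reac,drug post-ingest tables (combined across quarters).
#' @param norm a [drug_map()].
#' @param query a [pt_query()].
#' @param retained retained primaryids after dedup/deletion.
#' @param roles drug role codes for exposure.
#' @return list of class `sensitivity_diff`: `occupation`, `n_excluded`,
#'   `baseline` and `filtered` signal tables, `baseline_positive`,
#'   `filtered_positive`, `gained`, `lost`, and `deltas` (per-drug changes
#'   in a, ROR and EBGM).
#' @export
sensitivity_exclude <- function(occupation, demo, reac, drug, norm, query,
                                retained, roles = "PS") {
  stopifnot(occupation %in% .occp_codes)
  demo <- as.data.frame(demo)
  excl <- demo$primaryid[squish(demo$occp_cod) == occupation]
  kept <- setdiff(retained, excl)

  base <- .signal_screen(retained, demo, reac, drug, norm, query, roles)
  filt <- .signal_screen(kept, demo, reac, drug, norm, query, roles)

  bpos <- base$signals$drug[base$signals$positive]
  fpos <- filt$signals$drug[filt$signals$positive]
  deltas <- merge(
    base$signals[c("drug", "a", "ror", "ebgm", "positive")],
    filt$signals[c("drug", "a", "ror", "ebgm", "positive")],
    by = "drug", suffixes = c("_base", "_filtered"), all = TRUE)
  deltas$d_a <- deltas$a_filtered - deltas$a_base
  deltas$d_ror <- deltas$ror_filtered - deltas$ror_base

  structure(list(
    occupation = occupation,
    n_excluded = length(intersect(retained, excl)),
    baseline = base$signals, filtered = filt$signals,
    baseline_positive = bpos, filtered_positive = fpos,
    gained = setdiff(fpos, bpos), lost = setdiff(bpos, fpos),
    deltas = deltas
  ), class = "sensitivity_diff")
}

#' @export
print.sensitivity_diff <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_diff> excluding %s (%d reports): positive %d -> %d (gained %d, lost %d)\n",
    x$occupation, x$n_excluded, length(x$baseline_positive),
    length(x$filtered_positive), length(x$gained), length(x$lost)))
  invisible(x)
}

.pipeline_defaults <- list(
  roles = c("PS", "SS"),
  scope = "narrow",
  min_n111 = 5,
  top_n = 30,
  tto_drugs = 5,
  sensitivity_occupation = "LW"
)

#' Run the full screening pipeline
#'
#' Executes ingest (or simulation) -> deduplication -> deletion ->
#' case mapping -> disproportionality signals -> time-to-onset ->
#' interaction screening -> descriptive table -> occupation-exclusion
#' sensitivity, writing every table as CSV plus a JSON run manifest with
#' record counts at each stage. Configuration is a YAML file (or an
#' equivalent named list) with either a `synth:` block of
#' [synth_config()] overrides or an `input: {quarters: [dir, ...]}` block,
#' optional `pt_query:` and `drug_map:` file paths (defaulting, for
#' synthetic runs, to the generator's own target set and name map), and
#' the analysis knobs `roles`, `min_n111`, `top_n`, `tto_drugs`,
#' `sensitivity_occupation`.
#'
#' Reruns with the same configuration produce byte-identical CSVs.
#'
#' @param config path to a YAML file, or a named list.
#' @param out_dir output directory (overrides the config's `out`).
#' @param verbose emit per-stage record counts to stderr.
#' @return invisibly, the output directory; side effect: written tables
#'   and `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.pipeline_defaults, config)
  out <- out_dir %||% cfg$out %||% stop("no output directory configured")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- function(stage, ...) if (verbose)
    message(sprintf("[%s] %s", stage, paste0(...)))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(
    package = as.character(utils::packageVersion("dystosignal")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg[setdiff(names(cfg), c("out"))],
    counts = list(), warnings = list()
  )

  ## ingest -----------------------------------------------------------
  ingest <- run_stage("ingest", {
    if (!is.null(cfg$synth)) {
      sc <- do.call(synth_config, cfg$synth)
      sim <- simulate_faers(sc)
      bdir <- file.path(out, "bundles")
      for (b in sim$bundles) write_quarter(b, bdir)
      # read back through the ASCII layer: the pipeline consumes files
      bl <- lapply(sim$bundles, function(b) {
        fs <- c(demo = file.path(bdir, paste0("DEMO", b$quarter, ".txt")),
                drug = file.path(bdir, paste0("DRUG", b$quarter, ".txt")),
                reac = file.path(bdir, paste0("REAC", b$quarter, ".txt")),
                ther = file.path(bdir, paste0("THER", b$quarter, ".txt")),
                outc = file.path(bdir, paste0("OUTC", b$quarter, ".txt")))
        del <- file.path(bdir, paste0("DELETED", b$quarter, ".txt"))
        if (file.exists(del)) fs["delete"] <- del
        read_quarter(fs, quarter = b$quarter)
      })
      list(bundles = bl, ledger = sim$ledger)
    } else if (!is.null(cfg$input)) {
      list(bundles = lapply(cfg$input$quarters, read_quarter),
           ledger = NULL)
    } else stop("config needs a 'synth' or 'input' block")
  })
  bundles <- ingest$bundles
  ledger <- ingest$ledger
  all <- combine_bundles(bundles)
  manifest$counts$parsed <- nrow(all$demo)
  log("ingest", nrow(all$demo), " demo records in ", length(bundles),
      " quarter(s)")

  ## dedup + deletion --------------------------------------------------
  dd <- run_stage("dedup", {
    r <- deduplicate(all$demo)
    apply_deletions(r, all$demo, all$deletion_caseids)
  })
  retained <- dd$retained_primaryids
  manifest$counts$retained <- length(retained)
  manifest$counts$removed_as_duplicate <- dd$removed_as_duplicate
  manifest$counts$removed_by_deletion <- dd$removed_by_deletion
  write_retained_ids(dd, file.path(out, "retained_ids.txt"))
  log("dedup", length(retained), " retained (",
      dd$removed_as_duplicate, " duplicates, ",
      dd$removed_by_deletion, " deleted)")

  ## case mapping ------------------------------------------------------
  query <- run_stage("case_mapping", {
    if (!is.null(cfg$pt_query)) load_pt_query(cfg$pt_query,
                                              scope = cfg$scope)
    else if (!is.null(ledger)) pt_query(ledger$target_pts,
                                        name = "synthetic-narrow")
    else stop("no PT query configured")
  })
  norm <- run_stage("case_mapping", {
    if (!is.null(cfg$drug_map)) load_drug_map(cfg$drug_map)
    else if (!is.null(cfg$synth))
      synth_drug_map(do.call(synth_config, cfg$synth))
    else stop("no drug map configured")
  })
  scr <- run_stage("case_mapping",
                   .signal_screen(retained, all$demo, all$reac, all$drug,
                                  norm, query, cfg$roles))
  manifest$counts$cases <- length(scr$cases)
  manifest$counts$drugs_screened <- nrow(scr$cells)
  data.table::fwrite(scr$cells, file.path(out, "contingency.csv"))
  log("case_mapping", length(scr$cases), " case reports, ",
      nrow(scr$cells), " drugs")

  ## signals -----------------------------------------------------------
  manifest$counts$positive_signals <- sum(scr$signals$positive)
  data.table::fwrite(scr$signals, file.path(out, "signals.csv"))
  log("signals", sum(scr$signals$positive), " positive of ",
      nrow(scr$signals))

  ## time to onset -----------------------------------------------------
  tto <- run_stage("tto", extract_tto(all, scr$cases, norm,
                                      roles = cfg$roles))
  tto_inc <- tto[tto$included, , drop = FALSE]
  tto_sum <- if (nrow(tto_inc)) summarize_tto(tto) else NULL
  if (!is.null(tto_sum)) {
    flat <- with(tto_sum, data.frame(
      n = n, n_excluded = n_excluded, mean = mean, sd = sd,
      median = median, q1 = q1, q3 = q3, min = min, max = max))
    data.table::fwrite(flat, file.path(out, "tto_summary.csv"))
    data.table::fwrite(tto_sum$bins, file.path(out, "tto_bins.csv"))
  }
  top_drugs <- utils::head(scr$signals$drug[scr$signals$positive],
                           cfg$tto_drugs)
  km_dat <- tto_inc[tto_inc$drug %in% top_drugs, , drop = FALSE]
  km_dat <- km_dat[km_dat$drug %in%
                     names(which(table(km_dat$drug) >= 5)), , drop = FALSE]
  if (nrow(km_dat) && length(unique(km_dat$drug)) >= 1) {
    km <- run_stage("tto", km_fit(km_dat$tto_days, km_dat$drug))
    data.table::fwrite(km$curves, file.path(out, "km_curves.csv"))
    data.table::fwrite(km$medians, file.path(out, "km_medians.csv"))
    if (length(unique(km_dat$drug)) >= 2) {
      lr <- logrank_test(km_dat$tto_days, km_dat$drug)
      kw <- kruskal_wallis_test(km_dat$tto_days, km_dat$drug)
      manifest$tto_tests <- list(logrank = lr, kruskal_wallis = kw)
    }
  }
  manifest$counts$tto_included <- nrow(tto_inc)
  manifest$counts$tto_excluded <- sum(!tto$included)
  log("tto", nrow(tto_inc), " onset records included, ",
      sum(!tto$included), " excluded")

  ## interactions ------------------------------------------------------
  trip <- run_stage("interaction", {
    tt <- count_triplets(scr$cases, scr$exposure, retained,
                         min_n111 = cfg$min_n111)
    if (nrow(tt)) screen_interactions(expected_e111(tt), top_n = cfg$top_n)
    else tt
  })
  manifest$counts$triplets <- nrow(trip)
  data.table::fwrite(trip, file.path(out, "triplets.csv"))
  log("interaction", nrow(trip), " triplets screened")

  ## descriptive -------------------------------------------------------
  desc <- run_stage("descriptive", {
    dc <- all$demo[all$demo$primaryid %in% scr$cases, , drop = FALSE]
    descriptive_table(dc, all$outc, tto_sum)
  })
  data.table::fwrite(.descriptive_flat(desc),
                     file.path(out, "descriptive.csv"))

  ## sensitivity -------------------------------------------------------
  sens <- run_stage("sensitivity",
                    sensitivity_exclude(cfg$sensitivity_occupation,
                                        all$demo, all$reac, all$drug,
                                        norm, query, retained, cfg$roles))
  manifest$sensitivity <- list(
    occupation = sens$occupation, n_excluded = sens$n_excluded,
    baseline_positive = length(sens$baseline_positive),
    filtered_positive = length(sens$filtered_positive),
    gained = sens$gained, lost = sens$lost)
  data.table::fwrite(sens$deltas, file.path(out, "sensitivity.csv"))
  log("sensitivity", length(sens$baseline_positive), " -> ",
      length(sens$filtered_positive), " positive after excluding ",
      sens$occupation)

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
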