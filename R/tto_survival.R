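# Time-to-onset extraction and comparison across drugs.
#
# TTO is the interval in days from drug initiation (earliest day-precision
# therapy start for that drug on the report) to adverse-event occurrence
# (the DEMO event date). Reports with incomplete, implausible or
# inconsistent date information are excluded, never imputed, and the
# exclusion reasons are tallied. Kaplan-Meier estimation, the k-sample
# log-rank test and the Kruskal-Wallis test are delegated to the survival
# and stats packages; with case-only data there is no censoring, so the
# KM curve is the complement of the empirical CDF.

#' Extract time-to-onset records for case reports
#'
#' For each (case report, exposed suspect drug) pair: start is the
#' earliest day-precision `start_dt` among that drug's therapy rows, the
#' event date is the report's `event_dt`, and `tto_days = event - start`.
#' A pair is excluded when the event date is missing
#' (`missing_event`) or partial (`partial_precision`), no therapy start
#' exists (`missing_start`), starts exist but none with day precision
#' (`partial_precision`), the chosen row has `end_dt < start_dt`
#' (`inconsistent`), or the interval is negative (`negative`). Same-day
#' onset (`tto_days = 0`) is valid and included.
#'
#' @param bundle a [faers_bundle()] (combined across quarters).
#' @param case_ids case primaryids from [flag_cases()].
#' @param norm a [drug_map()].
#' @param roles drug role codes defining "suspect" (default `"PS"`).
#' @return data.frame of class `tto_records`: `primaryid`, `drug`,
#'   `tto_days`, `included`, `exclusion_reason`.
#' @export
extract_tto <- function(bundle, case_ids, norm, roles = "PS") {
  stopifnot(inherits(bundle, "faers_bundle"))
  expo <- normalize_drugs(bundle$drug, norm, roles = roles, keep_seq = TRUE)
  expo <- expo[expo$primaryid %in% case_ids, , drop = FALSE]
  ev <- parse_date(bundle$demo$event_dt)
  ev_prec <- as.character(ev$precision)[match(expo$primaryid,
                                              bundle$demo$primaryid)]
  ev_ord <- ev$ordinal[match(expo$primaryid, bundle$demo$primaryid)]

  th <- bundle$ther
  st <- parse_date(th$start_dt)
  en <- parse_date(th$end_dt)
  th_key <- paste(th$primaryid, th$dsg_drug_seq)
  ex_key <- paste(expo$primaryid, expo$drug_seq)

  tdt <- data.table::data.table(
    pair = ex_key, primaryid = expo$primaryid, drug = expo$drug,
    ev_prec = ev_prec, ev_ord = ev_ord
  )
  sdt <- data.table::data.table(
    pair = th_key,
    st_prec = as.character(st$precision), st_ord = st$ordinal,
    en_prec = as.character(en$precision), en_ord = en$ordinal
  )
  j <- merge(tdt, sdt, by = "pair", all.x = TRUE, allow.cartesian = TRUE)
  # per (report, canonical drug): earliest day-precision start, plus enough
  # context to name the exclusion reason when there is none
  agg <- j[, {
    day <- which(st_prec == "day")
    if (length(day)) {
      best <- day[which.min(st_ord[day])]
      list(st_ord = st_ord[best], st_status = "day",
           en_ord = en_ord[best], en_prec = en_prec[best])
    } else if (any(!is.na(st_prec) & st_prec != "missing")) {
      list(st_ord = NA_integer_, st_status = "partial",
           en_ord = NA_integer_, en_prec = NA_character_)
    } else {
      list(st_ord = NA_integer_, st_status = "missing",
           en_ord = NA_integer_, en_prec = NA_character_)
    }
  }, by = c("primaryid", "drug", "ev_prec", "ev_ord")]

  reason <- rep("none", nrow(agg))
  reason[agg$st_status == "partial"] <- "partial_precision"
  reason[agg$st_status == "missing"] <- "missing_start"
  reason[agg$ev_prec %in% c("month", "year")] <- "partial_precision"
  reason[agg$ev_prec == "missing"] <- "missing_event"
  tto <- agg$ev_ord - agg$st_ord
  inconsistent <- reason == "none" & agg$en_prec == "day" &
    !is.na(agg$en_ord) & agg$en_ord < agg$st_ord
  reason[which(inconsistent)] <- "inconsistent"
  reason[reason == "none" & !is.na(tto) & tto < 0] <- "negative"

  out <- data.frame(
    primaryid = agg$primaryid, drug = agg$drug,
    tto_days = ifelse(reason == "none", tto, NA_integer_),
    included = reason == "none",
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
  out <- out[base::order(out$primaryid, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tto_records", class(out))
  out
}

#' Summarize onset times
#'
#' Location/spread summary plus binned counts and percentages. Default
#' bins are 0-30, 31-60, 61-90, 91-180, 181-360 and >360 days, closed on
#' both printed endpoints; quartiles use the SAS-style type-2 definition.
#'
#' @param records a `tto_records` data.frame (or any data.frame with
#'   `tto_days` and `included`), or a bare numeric vector of onset days.
#' @param breaks upper bin endpoints (days), last bin open-ended.
#' @return list of class `tto_summary`: `n`, `n_excluded`,
#'   `exclusion_reasons` (table), `mean`, `sd`, `median`, `q1`, `q3`,
#'   `min`, `max`, `bins` (data.frame bin/count/pct).
#' @export
summarize_tto <- function(records, breaks = c(30, 60, 90, 180, 360)) {
  if (is.numeric(records)) {
    x <- records[!is.na(records)]
    n_excl <- sum(is.na(records))
    reasons <- table(character(0))
  } else {
    x <- records$tto_days[records$included]
    n_excl <- sum(!records$included)
    reasons <- table(records$exclusion_reason[!records$included])
  }
  if (!length(x)) stop("no included onset records to summarize")
  q <- stats::quantile(x, c(.25, .5, .75), type = 2, names = FALSE)
  edges <- c(-0.5, breaks + 0.5, Inf)
  labs <- c(paste0(c(0, breaks[-length(breaks)] + 1), "-", breaks),
            paste0(">", breaks[length(breaks)]))
  counts <- table(cut(x, edges, labels = labs))
  bins <- data.frame(bin = labs, count = as.integer(counts),
                     pct = report_percent(as.integer(counts), length(x)),
                     stringsAsFactors = FALSE)
  structure(list(
    n = length(x), n_excluded = n_excl, exclusion_reasons = reasons,
    mean = mean(x), sd = stats::sd(x),
    median = q[2], q1 = q[1], q3 = q[3],
    min = min(x), max = max(x), bins = bins
  ), class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf(
    "<tto_summary> n=%d (excluded %d)\n  median %.2f (Q1 %.2f, Q3 %.2f), mean %.2f (SD %.2f), range %g-%g\n",
    x$n, x$n_excluded, x$median, x$q1, x$q3, x$mean, x$sd, x$min, x$max))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier onset curves per drug
#'
#' Product-limit estimator per group with Brookmeyer-Crowley median
#' confidence intervals (log-log transformed curve, via
#' [survival::survfit()]). Case-only data carry no censoring, so
#' `1 - survival` is exactly the empirical CDF and the KM median is the
#' smallest time at which survival drops to 0.5 or below.
#'
#' @param times event times in days.
#' @param groups group labels (drug names); single group if NULL.
#' @param conf.level confidence level for the median CI.
#' @return list of class `km_curves`: `curves` (data.frame group, time,
#'   n_risk, survival, lower, upper) and `medians` (data.frame group, n,
#'   median, lcl, ucl).
#' @export
km_fit <- function(times, groups = NULL, conf.level = 0.95) {
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- as.character(groups)
  stopifnot(length(times) == length(groups), length(times) >= 1)
  df <- data.frame(time = times, ev = 1, grp = groups)
  fit <- survival::survfit(survival::Surv(time, ev) ~ grp, data = df,
                           conf.type = "log-log", conf.int = conf.level)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(groups), length(s$time)) else
    sub("^grp=", "", as.character(s$strata))
  curves <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                       survival = s$surv, lower = s$lower, upper = s$upper,
                       stringsAsFactors = FALSE)
  med_one <- function(g) {
    cg <- curves[curves$group == g, ]
    min(cg$time[cg$survival <= 0.5])
  }
  tab <- summary(fit)$table
  if (is.null(dim(tab)))
    tab <- matrix(tab, 1, dimnames = list(unique(groups), names(tab)))
  gl <- sub("^grp=", "", rownames(tab))
  medians <- data.frame(
    group = gl,
    n = as.integer(tab[, "records"]),
    median = vapply(gl, med_one, 0),
    lcl = tab[, grep("LCL", colnames(tab))],
    ucl = tab[, grep("UCL", colnames(tab))],
    stringsAsFactors = FALSE
  )
  rownames(medians) <- NULL
  structure(list(curves = curves, medians = medians),
            class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  cat("<km_curves>", length(unique(x$curves$group)), "group(s)\n")
  print(x$medians, row.names = FALSE)
  invisible(x)
}

#' k-sample log-rank test of onset distributions
#'
#' Standard log-rank (observed vs expected events at each distinct event
#' time, via [survival::survdiff()]); the formal inference for group
#' differences in onset time.
#'
#' @param times event times in days.
#' @param groups group labels (at least two groups).
#' @return list `chi2`, `df` (k-1), `p`.
#' @export
logrank_test <- function(times, groups) {
  groups <- as.character(groups)
  stopifnot(length(unique(groups)) >= 2)
  df <- data.frame(time = times, ev = 1, grp = groups)
  sd <- survival::survdiff(survival::Surv(time, ev) ~ grp, data = df)
  k <- length(sd$n)
  list(chi2 = unname(sd$chisq), df = k - 1,
       p = stats::pchisq(sd$chisq, k - 1, lower.tail = FALSE))
}

#' Kruskal-Wallis comparison of raw onset times
#'
#' Rank-based H with tie correction (via [stats::kruskal.test()]).
#' Descriptive companion to the log-rank test: it describes the raw time
#' distribution rather than serving as the formal inference.
#'
#' @param times event times in days.
#' @param groups group labels (at least two groups, each non-empty).
#' @return list `H`, `df`, `p`.
#' @export
kruskal_wallis_test <- function(times, groups) {
  groups <- as.character(groups)
  stopifnot(length(unique(groups)) >= 2)
  if (length(unique(times)) == 1) # fully tied: H is 0 by convention
    return(list(H = 0, df = length(unique(groups)) - 1, p = 1))
  kt <- stats::kruskal.test(times, factor(groups))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
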