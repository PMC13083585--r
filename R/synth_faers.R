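# Synthetic FAERS-style report generator with a ground-truth ledger.
#
# The generator emulates the structure of a cleaned spontaneous-reporting
# extract: multi-drug multi-PT reports, injected drug-event odds
# multipliers and drug-pair interaction triplets, duplicate report
# versions sharing a CASEID, quarterly deletion lists, a reporter
# occupation mix with an optional litigation (lawyer) stratum biased
# toward configured drugs, therapy/event dates giving drug-specific
# onset-time distributions, and serious-outcome codes. Effects are
# specified on the odds scale, so injected multipliers are directly
# comparable to the reporting odds ratio the pipeline estimates.

.default_drug_catalog <- function() {
  data.frame(
    name = c("metoclopramide", "aripiprazole", "risperidone", "quetiapine",
             "olanzapine", "haloperidol", "fluoxetine", "sertraline",
             "ondansetron", "omeprazole", "metformin", "lisinopril",
             "amoxicillin"),
    p = c(0.06, 0.05, 0.05, 0.05, 0.04, 0.03, 0.05, 0.05, 0.04,
          0.08, 0.08, 0.07, 0.06),
    atc = c("A03FA01", "N05AX12", "N05AX08", "N05AH04", "N05AH03",
            "N05AD01", "N06AB03", "N06AB06", "A04AA01", "A02BC01",
            "A10BA02", "C09AA03", "J01CA04"),
    stringsAsFactors = FALSE
  )
}

# Synthetic stand-in for an SMQ-style narrow PT set plus background terms.
.default_pt_catalog <- function() {
  data.frame(
    pt = c("Dystonia", "Torticollis", "Oculogyric crisis",
           "Oromandibular dystonia", "Opisthotonus", "Blepharospasm",
           "Trismus", "Muscle contractions involuntary",
           "Nausea", "Headache", "Rash", "Dizziness", "Fatigue",
           "Vomiting", "Pruritus", "Insomnia", "Diarrhoea", "Somnolence"),
    p = c(0.45, 0.12, 0.10, 0.05, 0.04, 0.08, 0.08, 0.08,
          0.18, 0.15, 0.12, 0.12, 0.10, 0.08, 0.07, 0.06, 0.07, 0.05),
    target = rep(c(TRUE, FALSE), c(8, 10)),
    stringsAsFactors = FALSE
  )
}

.default_tto_models <- function() {
  list(
    metoclopramide = list(family = "lognormal", median = 2,  sdlog = 1.5),
    aripiprazole   = list(family = "lognormal", median = 5,  sdlog = 1.5),
    risperidone    = list(family = "lognormal", median = 2,  sdlog = 1.5),
    quetiapine     = list(family = "lognormal", median = 19, sdlog = 1.3),
    olanzapine     = list(family = "lognormal", median = 16, sdlog = 1.3),
    haloperidol    = list(family = "exponential", median = 3),
    fluoxetine     = list(family = "lognormal", median = 10, sdlog = 1.2),
    sertraline     = list(family = "weibull", median = 14, shape = 0.9),
    ondansetron    = list(family = "exponential", median = 1),
    omeprazole     = list(family = "lognormal", median = 30, sdlog = 1.2),
    metformin      = list(family = "lognormal", median = 60, sdlog = 1.2),
    lisinopril     = list(family = "lognormal", median = 45, sdlog = 1.2),
    amoxicillin    = list(family = "exponential", median = 7)
  )
}

# one draw_tto family per drug; integer days >= 0
draw_tto <- function(model, n) {
  med <- model$median
  x <- switch(model$family,
    exponential = stats::rexp(n, rate = log(2) / med),
    weibull = {
      shape <- model$shape %||% 1.2
      stats::rweibull(n, shape = shape, scale = med / log(2)^(1 / shape))
    },
    lognormal = stats::rlnorm(n, meanlog = log(med),
                              sdlog = model$sdlog %||% 1.5),
    stop("unknown TTO family: ", model$family)
  )
  pmax(0, round(x))
}

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the reporting landscape of a drug-induced dystonia
#' screen: a catalog led by metoclopramide and antipsychotics with
#' published-scale onset medians (metoclopramide/risperidone 2 d,
#' aripiprazole 5 d, olanzapine 16 d, quetiapine 19 d), an occupation mix
#' with a one-quarter lawyer stratum whose extra reports concentrate on
#' metoclopramide, ~20% of drug-event pairs fully dated, and a modest
#' duplicate-version and deletion-list load. See the methods vignette for
#' the rationale behind each default.
#'
#' @param n_cases number of base cases (before lawyer-bias extras).
#' @param drug_catalog data.frame `name`, `p` (marginal exposure
#'   probability), `atc`.
#' @param pt_catalog data.frame `pt`, `p` (draw weight), `target`
#'   (logical: belongs to the synthetic narrow event set).
#' @param signal_pairs named numeric: drug -> event odds multiplier.
#' @param interaction_triplets data.frame `drugA`, `drugB`, `mult`
#'   (excess odds multiplier on top of both single-drug effects; 1 means
#'   exactly no interaction under the multiplicative-odds baseline).
#' @param tto_models named list per drug: `family`
#'   (exponential/weibull/lognormal), `median` (days), family parameters.
#' @param base_event_prob event probability with all multipliers 1.
#' @param duplicate_rate probability a case gets extra report versions.
#' @param deletion_rate probability a caseid enters a deletion list.
#' @param occupation_mix probabilities over MD, PH, LW, CN, HP, OT.
#' @param lawyer_bias named numeric: drug -> multiplier inflating
#'   lawyer-attributed event-report volume for that drug (1 = no bias).
#' @param missing_date_rate per-date-field blanking probability (half of
#'   blanked dates are truncated to month precision instead).
#' @param date_window character `c(start, end)` as YYYYMMDD.
#' @param quarters number of quarterly bundles to split output into.
#' @param secondary_role_probs role mix for non-primary-suspect drugs.
#' @param extra_pt_rate probability of a second, non-target PT per report.
#' @param prob_cap ceiling for the per-case event probability.
#' @param seed integer seed; the simulation is deterministic given it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_cases = 2000,
                         drug_catalog = .default_drug_catalog(),
                         pt_catalog = .default_pt_catalog(),
                         signal_pairs = c(metoclopramide = 25,
                                          aripiprazole = 12,
                                          risperidone = 10,
                                          quetiapine = 6,
                                          olanzapine = 8,
                                          haloperidol = 20,
                                          fluoxetine = 5,
                                          sertraline = 5,
                                          ondansetron = 10),
                         interaction_triplets = data.frame(
                           drugA = "aripiprazole", drugB = "risperidone",
                           mult = 2),
                         tto_models = .default_tto_models(),
                         base_event_prob = 0.02,
                         duplicate_rate = 0.10,
                         deletion_rate = 0.02,
                         occupation_mix = c(MD = 0.22, PH = 0.13, LW = 0.25,
                                            CN = 0.21, HP = 0.15, OT = 0.04),
                         lawyer_bias = c(metoclopramide = 5),
                         missing_date_rate = 0.55,
                         date_window = c("20190101", "20231231"),
                         quarters = 1,
                         secondary_role_probs = c(SS = 0.7, C = 0.3),
                         extra_pt_rate = 0.25,
                         prob_cap = 0.99,
                         seed = 1) {
  cfg <- mget(names(formals()))
  stopifnot(
    n_cases >= 1,
    all(drug_catalog$p >= 0 & drug_catalog$p <= 1),
    all(pt_catalog$p >= 0), any(pt_catalog$target), any(!pt_catalog$target),
    is.null(signal_pairs) || all(signal_pairs > 0),
    base_event_prob > 0, base_event_prob < 1,
    duplicate_rate >= 0, duplicate_rate <= 1,
    deletion_rate >= 0, deletion_rate <= 1,
    missing_date_rate >= 0, missing_date_rate <= 1,
    abs(sum(occupation_mix) - 1) < 1e-6,
    quarters >= 1
  )
  if (!is.null(signal_pairs) && length(signal_pairs) &&
      !all(names(signal_pairs) %in% drug_catalog$name))
    stop("signal_pairs names must appear in the drug catalog")
  if (!is.null(lawyer_bias) && length(lawyer_bias) &&
      !all(names(lawyer_bias) %in% drug_catalog$name))
    stop("lawyer_bias names must appear in the drug catalog")
  if (!is.null(interaction_triplets) && nrow(interaction_triplets)) {
    stopifnot(all(interaction_triplets$mult > 0),
              all(c(interaction_triplets$drugA, interaction_triplets$drugB)
                  %in% drug_catalog$name))
  }
  miss_tto <- setdiff(drug_catalog$name, names(tto_models))
  if (length(miss_tto))
    stop("tto_models missing for: ", paste(miss_tto, collapse = ", "))
  stopifnot(all(vapply(tto_models, function(m) m$median > 0, TRUE)))
  structure(cfg, class = "synth_config")
}

#' Verbatim-name normalization table matching the generator's output
#'
#' The generator writes each drug under one of four verbatim spellings
#' (upper case, title case, "... HCL", "... TABLETS"); this returns the
#' `verbatim -> canonical[, atc]` table covering all of them, standing in
#' for a WHO-Drug-style dictionary.
#'
#' @param config a [synth_config()].
#' @return a [drug_map()].
#' @export
synth_drug_map <- function(config) {
  nm <- config$drug_catalog$name
  up <- toupper(nm)
  title <- paste0(toupper(substr(nm, 1, 1)), substr(nm, 2, nchar(nm)))
  drug_map(
    verbatim = c(up, paste(up, "HCL"), paste(up, "TABLETS"), title),
    canonical = rep(nm, 4),
    atc = rep(config$drug_catalog$atc, 4)
  )
}

# YYYYMMDD text from a day ordinal, honouring a missingness style
.fmt_ord <- function(ord, style) {
  raw <- format(as.Date(ord, origin = "1970-01-01"), "%Y%m%d")
  raw[style == "partial"] <- substr(raw[style == "partial"], 1, 6)
  raw[style == "blank"] <- ""
  raw
}

.miss_style <- function(u, rate) {
  ifelse(u < rate / 2, "blank", ifelse(u < rate, "partial", "full"))
}

#' Simulate FAERS-style bundles with known ground truth
#'
#' Generative model, per base case: 1-5 drugs drawn from the catalog
#' (independent Bernoulli on each drug's marginal probability, at least
#' one forced, capped at five); the event indicator drawn with probability
#' obtained by passing the base odds through the product of odds
#' multipliers of present signal drugs and fully-present interaction
#' triplets, capped at `prob_cap`; one primary-suspect drug per report,
#' the rest SS/C. Event reports draw a per-drug time-to-onset from that
#' drug's model; therapy start dates are placed so `event - start` equals
#' the drawn onset time; `fda_dt` follows the event by a geometric
#' reporting delay (mean 30 days). Duplicate versions share the CASEID
#' with fresh, larger PRIMARYIDs and strictly later `fda_dt`; deletion
#' lists, reporter occupations (with lawyer-bias extra event reports for
#' configured drugs), and serious-outcome codes round out the bundle.
#' Deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `bundles` (list of [faers_bundle()]) and `ledger`
#'   (class `synth_truth`: the ground truth per drug, triplet, case,
#'   version, exposure and onset time).
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cat_df <- config$drug_catalog
  nd <- nrow(cat_df)
  nb <- config$n_cases

  ## -- exposures ------------------------------------------------------
  expo <- matrix(stats::runif(nb * nd) < rep(cat_df$p, each = nb), nb, nd)
  none <- rowSums(expo) == 0
  if (any(none)) {
    pick <- sample.int(nd, sum(none), replace = TRUE, prob = cat_df$p)
    expo[cbind(which(none), pick)] <- TRUE
  }
  over <- which(rowSums(expo) > 5L)
  for (i in over) {
    on <- which(expo[i, ])
    expo[i, sample(on, length(on) - 5L)] <- FALSE
  }

  ## -- event indicator through the odds model -------------------------
  logm <- stats::setNames(rep(0, nd), cat_df$name)
  if (length(config$signal_pairs))
    logm[names(config$signal_pairs)] <- log(config$signal_pairs)
  log_odds <- log(config$base_event_prob / (1 - config$base_event_prob)) +
    as.vector(expo %*% logm)
  trip <- config$interaction_triplets
  if (!is.null(trip) && nrow(trip)) {
    for (k in seq_len(nrow(trip))) {
      both <- expo[, match(trip$drugA[k], cat_df$name)] &
        expo[, match(trip$drugB[k], cat_df$name)]
      log_odds[both] <- log_odds[both] + log(trip$mult[k])
    }
  }
  p_event <- stats::plogis(log_odds)
  n_capped <- sum(p_event > config$prob_cap)
  if (n_capped > 0.05 * nb)
    warning("event-probability cap hit on ",
            round(100 * n_capped / nb, 1), "% of cases; config too extreme")
  p_event <- pmin(p_event, config$prob_cap)
  event <- stats::runif(nb) < p_event

  ## -- lawyer-bias extra event reports --------------------------------
  lb <- config$lawyer_bias
  lb <- lb[!is.na(lb) & lb > 1]
  pi_lw <- unname(config$occupation_mix["LW"])
  extra_drug <- character(0)
  if (length(lb) && isTRUE(pi_lw > 0)) {
    for (dn in names(lb)) {
      pd <- cat_df$p[match(dn, cat_df$name)]
      m <- stats::rbinom(1, nb, min(1, pd * pi_lw * (lb[[dn]] - 1)))
      extra_drug <- c(extra_drug, rep(dn, m))
    }
  }
  n_extra <- length(extra_drug)
  n <- nb + n_extra
  event <- c(event, rep(TRUE, n_extra))
  lawyer_extra <- c(rep(FALSE, nb), rep(TRUE, n_extra))

  ## -- long exposure table, roles, drug_seq ---------------------------
  idx <- which(expo, arr.ind = TRUE)
  exp_case <- c(idx[, 1], if (n_extra) nb + seq_len(n_extra))
  exp_drug <- c(cat_df$name[idx[, 2]], extra_drug)
  perm <- sample.int(length(exp_case))        # random PS pick via shuffle
  o <- base::order(exp_case[perm])            # stable: keeps shuffle in-case
  exp_case <- exp_case[perm][o]
  exp_drug <- exp_drug[perm][o]
  is_ps <- !duplicated(exp_case)
  role <- sample(names(config$secondary_role_probs), length(exp_case),
                 replace = TRUE, prob = config$secondary_role_probs)
  role[is_ps] <- "PS"
  # PS first within case, then the shuffle order
  o2 <- base::order(exp_case, !is_ps)
  exp_case <- exp_case[o2]; exp_drug <- exp_drug[o2]
  role <- role[o2]; is_ps <- is_ps[o2]
  drug_seq <- stats::ave(seq_along(exp_case), exp_case, FUN = seq_along)
  nrow_exp <- length(exp_case)

  ## -- demographics ---------------------------------------------------
  occp <- sample(names(config$occupation_mix), n, replace = TRUE,
                 prob = config$occupation_mix)
  occp[lawyer_extra] <- "LW"
  sex <- sample(c("F", "M", NA), n, replace = TRUE, prob = c(.55, .36, .09))
  age_known <- stats::runif(n) > 0.45
  age_y <- pmin(95, pmax(0, round(stats::rgamma(n, shape = 2, scale = 20))))
  age <- ifelse(age_known, age_y, NA)
  age_cod <- ifelse(age_known, "YR", NA)
  inf <- which(age_known & age_y < 2)
  age[inf] <- pmax(1, round(age_y[inf] * 12 + stats::runif(length(inf)) * 11))
  age_cod[inf] <- "MON"
  country_probs <- c(US = .56, GB = .08, CA = .05, IT = .03, DE = .03,
                     FR = .03, JP = .03, AU = .02, ES = .02, NL = .02,
                     XX = .13)
  country <- sample(names(country_probs), n, TRUE, country_probs)

  ## -- reaction terms -------------------------------------------------
  tg <- config$pt_catalog[config$pt_catalog$target, ]
  ntg <- config$pt_catalog[!config$pt_catalog$target, ]
  pt_primary <- character(n)
  pt_primary[event] <- sample(tg$pt, sum(event), TRUE, tg$p)
  pt_primary[!event] <- sample(ntg$pt, sum(!event), TRUE, ntg$p)
  has_extra <- stats::runif(n) < config$extra_pt_rate
  pt_extra <- rep(NA_character_, n)
  pt_extra[has_extra] <- sample(ntg$pt, sum(has_extra), TRUE, ntg$p)
  pt_extra[!is.na(pt_extra) & pt_extra == pt_primary] <- NA

  ## -- dates ----------------------------------------------------------
  w <- parse_date(config$date_window)$ordinal
  ev_row <- event[exp_case]
  tto_row <- numeric(nrow_exp)
  for (dn in cat_df$name) {
    sel <- which(exp_drug == dn & ev_row)
    if (length(sel))
      tto_row[sel] <- draw_tto(config$tto_models[[dn]], length(sel))
  }
  gap_row <- round(stats::rexp(nrow_exp, 1 / 45))
  start_ps <- sample.int(w[2] - w[1] + 1L, n, replace = TRUE) + w[1] - 1L
  ps_rows <- which(is_ps)                      # one per case, in case order
  delta_ps <- ifelse(event, tto_row[ps_rows], gap_row[ps_rows])
  event_ord <- start_ps + delta_ps
  start_row <- numeric(nrow_exp)
  start_row[ps_rows] <- start_ps
  nonps <- which(!is_ps)
  start_row[nonps] <- event_ord[exp_case[nonps]] -
    ifelse(ev_row[nonps], tto_row[nonps], gap_row[nonps])
  end_row <- start_row + round(stats::rexp(nrow_exp, 1 / 90))
  fda_ord <- event_ord + stats::rgeom(n, 1 / 31)

  m <- config$missing_date_rate
  start_style <- .miss_style(stats::runif(nrow_exp), m)
  event_style <- .miss_style(stats::runif(n), m)
  start_raw <- .fmt_ord(start_row, start_style)
  end_raw <- .fmt_ord(end_row, rep("full", nrow_exp))
  event_raw <- .fmt_ord(event_ord, event_style)

  ## -- report versions (duplicates) -----------------------------------
  caseid <- as.character(3000000 + seq_len(n))
  n_ver <- rep(1L, n)
  dup <- stats::runif(n) < config$duplicate_rate
  n_ver[dup] <- 1L + pmin(stats::rgeom(sum(dup), 0.6) + 1L, 8L)
  ver_case <- rep(seq_len(n), n_ver)
  ver_num <- sequence(n_ver)
  pid <- paste0(caseid[ver_case], ver_num)
  incr <- sample.int(60, length(ver_case), replace = TRUE)
  incr[ver_num == 1L] <- 0L
  fda_ver <- fda_ord[ver_case] + stats::ave(incr, ver_case, FUN = cumsum)
  fda_raw <- .fmt_ord(fda_ver, rep("full", length(fda_ver)))

  ## -- assemble tables ------------------------------------------------
  demo <- data.frame(
    primaryid = pid, caseid = caseid[ver_case], fda_dt = fda_raw,
    event_dt = event_raw[ver_case], sex = sex[ver_case],
    age = as.character(age[ver_case]), age_cod = age_cod[ver_case],
    occp_cod = occp[ver_case], reporter_country = country[ver_case],
    stringsAsFactors = FALSE
  )
  variant <- sample.int(4, nrow_exp, replace = TRUE)
  up <- toupper(exp_drug)
  title <- paste0(toupper(substr(exp_drug, 1, 1)),
                  substr(exp_drug, 2, nchar(exp_drug)))
  verbatim <- ifelse(variant == 1, up,
              ifelse(variant == 2, paste(up, "HCL"),
              ifelse(variant == 3, paste(up, "TABLETS"), title)))

  vmap <- data.table::data.table(case = ver_case, primaryid = pid)
  edt <- data.table::data.table(
    case = exp_case, drug_seq = as.character(drug_seq), role_cod = role,
    drugname = verbatim, prod_ai = up, start_dt = start_raw, end_dt = end_raw
  )
  dj <- merge(vmap, edt, by = "case", allow.cartesian = TRUE, sort = FALSE)
  data.table::setorder(dj, case, primaryid, drug_seq)
  drug_tab <- data.frame(primaryid = dj$primaryid, drug_seq = dj$drug_seq,
                         role_cod = dj$role_cod, drugname = dj$drugname,
                         prod_ai = dj$prod_ai, stringsAsFactors = FALSE)
  ther_tab <- data.frame(primaryid = dj$primaryid,
                         dsg_drug_seq = dj$drug_seq,
                         start_dt = dj$start_dt, end_dt = dj$end_dt,
                         stringsAsFactors = FALSE)

  reac_tab <- data.frame(primaryid = pid, pt = pt_primary[ver_case],
                         stringsAsFactors = FALSE)
  extra_sel <- !is.na(pt_extra[ver_case])
  if (any(extra_sel))
    reac_tab <- rbind(reac_tab,
                      data.frame(primaryid = pid[extra_sel],
                                 pt = pt_extra[ver_case][extra_sel],
                                 stringsAsFactors = FALSE))

  oc_probs <- c(HO = .33, DS = .26, OT = .62, LT = .037, DE = .029,
                RI = .012, CA = .009)
  outc_list <- lapply(names(oc_probs), function(code) {
    hit <- stats::runif(n) < oc_probs[[code]]
    hit_ver <- hit[ver_case]
    data.frame(primaryid = pid[hit_ver],
               outc_cod = rep(code, sum(hit_ver)),
               stringsAsFactors = FALSE)
  })
  outc_tab <- do.call(rbind, outc_list)

  deleted <- stats::runif(n) < config$deletion_rate
  deletion <- caseid[deleted]

  ## -- split into quarterly bundles -----------------------------------
  if (config$quarters == 1) {
    qlab <- rep("S1", length(pid))
  } else {
    br <- stats::quantile(fda_ver, probs = seq(0, 1, length.out =
                                                 config$quarters + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    qlab <- paste0("S", as.integer(cut(fda_ver, breaks = unique(br),
                                       labels = FALSE, right = TRUE)))
  }
  qs <- sort(unique(qlab))
  bundles <- lapply(qs, function(q) {
    ids <- pid[qlab == q]
    faers_bundle(
      q,
      demo = demo[demo$primaryid %in% ids, ],
      drug = drug_tab[drug_tab$primaryid %in% ids, ],
      reac = reac_tab[reac_tab$primaryid %in% ids, ],
      ther = ther_tab[ther_tab$primaryid %in% ids, ],
      outc = outc_tab[outc_tab$primaryid %in% ids, ],
      deletion_caseids = if (q == qs[length(qs)]) deletion else character()
    )
  })

  ## -- ground-truth ledger --------------------------------------------
  multiplier <- stats::setNames(rep(1, nd), cat_df$name)
  if (length(config$signal_pairs))
    multiplier[names(config$signal_pairs)] <- config$signal_pairs
  ev_exp <- event[exp_case]
  ledger <- structure(list(
    drugs = data.frame(
      name = cat_df$name, marginal_p = cat_df$p,
      odds_multiplier = unname(multiplier),
      tto_median = vapply(cat_df$name,
                          function(d) config$tto_models[[d]]$median, 0),
      atc = cat_df$atc, stringsAsFactors = FALSE),
    triplets = if (!is.null(trip) && nrow(trip)) trip else
      data.frame(drugA = character(), drugB = character(), mult = numeric()),
    cases = data.frame(
      caseid = caseid, event = event, deleted = deleted,
      lawyer_extra = lawyer_extra, occp_cod = occp,
      n_versions = n_ver, event_complete = event_style == "full",
      stringsAsFactors = FALSE),
    versions = data.frame(
      caseid = caseid[ver_case], primaryid = pid, version = ver_num,
      fda_dt = fda_raw, stringsAsFactors = FALSE),
    exposures = data.frame(
      caseid = caseid[exp_case], drug = exp_drug, role = role,
      stringsAsFactors = FALSE),
    tto = data.frame(
      caseid = caseid[exp_case][ev_exp], drug = exp_drug[ev_exp],
      tto_days = tto_row[ev_exp],
      start_complete = (start_style == "full")[ev_exp],
      event_complete = (event_style == "full")[exp_case][ev_exp],
      stringsAsFactors = FALSE),
    target_pts = tg$pt,
    seed = config$seed
  ), class = "synth_truth")

  list(bundles = bundles, ledger = ledger)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("<synth_truth>", nrow(x$cases), "cases,",
      nrow(x$versions), "report versions,",
      sum(x$cases$event), "events,",
      sum(x$cases$deleted), "deleted\n")
  invisible(x)
}

#' Consistency check between bundles and the truth ledger
#'
#' Verifies, per check: (1) every ledger primaryid appears exactly once in
#' the emitted DEMO tables and vice versa; (2) duplicate version chains
#' have strictly increasing `fda_dt`; (3) deletion-list membership equals
#' the ledger's deleted flags; (4) a report carries a target PT iff its
#' case is an event in the ledger; (5) per-case canonical drug sets equal
#' the ledger's draws.
#'
#' @param bundles list of [faers_bundle()] (or one bundle).
#' @param ledger the matching `synth_truth`.
#' @return data.frame `check`, `pass`, with attribute `ok` (all pass).
#' @export
truth_check <- function(bundles, ledger) {
  stopifnot(inherits(ledger, "synth_truth"))
  b <- combine_bundles(bundles)
  checks <- list()

  pid_bundle <- b$demo$primaryid
  checks$primaryids_match <- identical(sort(pid_bundle),
                                       sort(ledger$versions$primaryid)) &&
    !anyDuplicated(pid_bundle)

  v <- ledger$versions[base::order(ledger$versions$caseid,
                                   ledger$versions$version), ]
  ok_chain <- TRUE
  multi <- v$caseid[duplicated(v$caseid)]
  if (length(multi)) {
    vv <- v[v$caseid %in% multi, ]
    key <- date_sort_key(vv$fda_dt)
    ok_chain <- all(tapply(key, vv$caseid, function(k) all(diff(k) > 0)))
  }
  checks$duplicate_fda_increasing <- ok_chain

  checks$deletions_match <- setequal(
    b$deletion_caseids, ledger$cases$caseid[ledger$cases$deleted])

  tgt <- norm_key(ledger$target_pts)
  hit_pid <- unique(b$reac$primaryid[norm_key(b$reac$pt) %in% tgt])
  hit_case <- unique(b$demo$caseid[b$demo$primaryid %in% hit_pid])
  checks$event_flags_match <- setequal(
    hit_case, ledger$cases$caseid[ledger$cases$event])

  bd <- unique(data.frame(
    caseid = b$demo$caseid[match(b$drug$primaryid, b$demo$primaryid)],
    drug = tolower(b$drug$prod_ai), stringsAsFactors = FALSE))
  ld <- unique(ledger$exposures[c("caseid", "drug")])
  checks$exposures_match <- identical(
    sort(paste(bd$caseid, bd$drug)), sort(paste(ld$caseid, ld$drug)))

  out <- data.frame(check = names(checks),
                    pass = unlist(checks, use.names = FALSE))
  attr(out, "ok") <- all(out$pass)
  out
}
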