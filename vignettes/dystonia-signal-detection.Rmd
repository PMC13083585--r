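---
title: "Signal detection for drug-induced dystonia in spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection for drug-induced dystonia in spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dystosignal)
```

# The problem

Spontaneous reporting systems such as FAERS collect adverse-event reports
with no denominator: we observe which drug–event pairs are *reported
together*, never incidence. Disproportionality analysis asks whether a
drug and an event are co-reported more often than expected if they were
independent within the same database. `dystosignal` implements a complete
screen for one clinically serious movement disorder — drug-induced
dystonia — from raw quarterly ASCII bundles to ranked drug signals,
onset-time comparisons, drug–drug interaction screening, and a
reporter-bias sensitivity analysis. Everything is exercised against a
synthetic report generator with a ground-truth ledger, so each stage is
testable at desk scale.

# Data model and cleaning

A FAERS *case* (CASEID) accumulates report *versions* (PRIMARYID) as
follow-ups arrive. The cleaning rule keeps, per case, the version with
the largest FDA receipt date (`fda_dt`), breaking ties by the largest
numeric PRIMARYID; cases named on any quarterly deletion list (issued
from 2019 onward) are then removed. Two design points are the package's
own:

* **Partial dates are never imputed.** `parse_date()` tags every value
  with a precision (`day`, `month`, `year`, `missing`); exclusion rules
  downstream decide what partial precision means for each analysis. In
  the dedup sort, a version without a day-precision `fda_dt` ranks below
  every dated version, so an undated follow-up can never displace a dated
  one.
* **Deletions apply cumulatively across quarters** and strictly *after*
  deduplication, matching the published cleaning order.

Cases are defined at the preferred-term (PT) level by a user-supplied
query file (an SMQ-style narrow set; MedDRA itself is licensed and is not
shipped — the bundled `pt_query_dystonia_synthetic.csv` is a synthetic
stand-in naming the generator's own target terms). Drug names are
canonicalised through a user-supplied verbatim-to-canonical table
standing in for the WHO Drug Dictionary. Exposure defaults to
primary-suspect (`PS`) records — "highest suspicion" read conservatively
— with `c("PS","SS")` and wider selectable; the pipeline default is
`c("PS","SS")`.

# The four disproportionality statistics

For each drug, reports are cross-classified at the retained-report level
into the 2×2 table $(a, b, c, d)$ — drug and event, drug only, event
only, neither — with $N = a+b+c+d$. The screen computes:

* **ROR** $= ad/bc$, with the Wald 95% CI
  $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$;
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with the uncorrected Pearson
  $\chi^2 = \frac{N(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)}$ (no Yates
  correction: the standard printed form has none);
* **BCPNN information component**
  $\mathrm{IC} = \log_2 \frac{a+0.5}{a_{\exp}+0.5}$ with
  $a_{\exp} = (a+b)(a+c)/N$, and the closed-form lower credibility bound
  $\mathrm{IC}_{025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} - 2(a+0.5)^{-3/2}$
  (a closed-form approximation, not a Monte-Carlo posterior);
* **EBGM** $= aN/[(a+c)(a+b)]$ — the relative reporting ratio — with
  $\mathrm{EBGM}_{05} = \exp(\ln \mathrm{EBGM} -
  1.64\sqrt{1/a+1/b+1/c+1/d})$. This is the shrinkage-free geometric-mean
  form with a normal-approximation lower bound, not a full gamma-Poisson
  mixture fit; the exponent on the reciprocal-cell sum is read as a
  square root, the standard form of this bound.

A drug is a **positive signal** only when *all four* algorithms pass
their thresholds simultaneously (each also requiring $a \ge 3$): ROR
lower bound $> 1$; PRR $\ge 2$ with $\chi^2 \ge 4$; IC$_{025} > 0$;
EBGM$_{05} > 2$. The conjunction is deliberately conservative: under a
simulated independence null (1,000 multinomial tables of 20,000 reports)
the combined rule fires on well under 2% of tables, driven by the strict
EBGM$_{05}$ gate.

Numerical choices: cells are promoted to double before the $\chi^2$
product (the integer product overflows 32-bit arithmetic at FAERS
scale); when a zero cell occurs, a Haldane–Anscombe $+0.5$ on every cell
is applied *only* to the ROR and EBGM computations, which need positive
cells, and the correction is flagged per row. The $a \ge 3$ gate makes
the corrected path irrelevant to signal calls in practice.

# Time to onset

TTO is `event_dt - start_dt` in days, per (case report, suspect drug),
using the *earliest day-precision* therapy start for that drug — first
exposure is the conservative clinical convention when several therapy
rows exist. A pair is excluded (with a tallied reason) when either date
is missing or partial, the interval is negative, or the therapy row has
`end_dt < start_dt`; same-day onset (0 days) is valid. The event date is
the AE onset (`event_dt`), not the FDA receipt date, which would inflate
onset times by the reporting delay.

Because case-only data carry no censoring, the Kaplan–Meier curve equals
the complement of the empirical CDF and the KM median is the sample
median; curves are nevertheless computed with the survival package
(log-log transformed Brookmeyer–Crowley median CIs — the package's
choice; the CI method behind the published medians is not stated, so
tests on medians use tolerances, not CI equality). The log-rank test is
the formal k-sample inference (df $= k-1$); Kruskal–Wallis (tie
corrected) is reported only to describe the raw time distribution.
Summaries use SAS-style type-2 quartiles and closed bins
0–30, 31–60, 61–90, 91–180, 181–360, >360 days.

# Drug–drug interaction screening

For an unordered drug pair and the event, each retained report falls in
exactly one stratum: both drugs, A only, B only, neither. With $n_{111}$
observed events among both-drug reports and $E_{111}$ the expected count,
the Ω shrinkage measure is

$$\Omega = \log_2 \frac{n_{111}+0.5}{E_{111}+0.5}, \qquad
\Omega_{025} = \Omega - \frac{1.96}{\ln 2 \cdot \sqrt{n_{111}}},$$

flagged when $\Omega_{025} > 0$. The half-width $z/(\ln 2\sqrt{n_{111}})$
is the reading of the interval that reproduces every published pair
bound we can check to two decimals; a variant using $n_{111}+0.5$ does
not.

The **expected-count model is pluggable** because no single baseline is
canonical. The default, `odds_additive`, adds the excess odds of each
drug over the neither-drug baseline and floors the result at the larger
single-drug odds (the "no interaction means no more than the drugs'
combined excess" convention of the Ω-shrinkage literature);
`multiplicative` combines the probabilities of remaining event-free;
`max_single` takes the larger single-drug proportion. Degenerate strata
(an empty comparison stratum, a saturated baseline) fall back along that
chain, and the model actually used is recorded per triplet. The Ω
interval itself depends only on $n_{111}$, never on the model.

One property worth stating plainly: both usable baselines are
*additive-type* on their scale. A joint effect that is multiplicative in
odds — two strong single-drug signals combining "independently" on the
log-odds scale — is genuinely super-additive and will accumulate
apparent interaction signal under these baselines. This is a property of
the estimand, not a bug; the null-calibration tests therefore use the
pure independence null (all multipliers 1), where the nominal one-sided
2.5% level is observed, and the power tests inject an excess multiplier
an order of magnitude above that baseline discrepancy.

# The synthetic generator

`simulate_faers()` emulates a cleaned spontaneous-reporting extract with
known ground truth (`synth_truth` ledger): per case, 1–5 drugs drawn by
marginal probability (at least one forced, capped at five); an event
indicator drawn by passing base odds through the product of per-drug
odds multipliers and any fully present interaction-triplet multipliers
(capped at 0.99, with a warning when the cap binds on >5% of cases);
per-drug onset times from exponential/Weibull/log-normal models anchored
so the therapy start and event date reproduce the drawn interval; a
geometric reporting delay (mean 30 days — an invented but harmless
device whose only job is ordering duplicate versions); duplicate
versions with strictly increasing `fda_dt`; quarterly deletion lists; a
reporter-occupation mix with a lawyer stratum whose *extra* reports are
event reports concentrated on configured drugs; and serious-outcome
codes.

Defaults are fixed once to mirror the study conditions the package
addresses: a catalog led by metoclopramide and antipsychotics with
published-scale onset medians (metoclopramide and risperidone 2 days,
aripiprazole 5, olanzapine 16, quetiapine 19); an occupation mix of
roughly one quarter lawyers; lawyer bias concentrated on metoclopramide;
and `missing_date_rate = 0.55` per date field so that roughly 20% of
case–drug pairs are fully dated, matching the completeness of real
onset data. Effects are specified on the *odds* scale so injected
multipliers are directly comparable to the ROR the pipeline estimates —
parameter recovery is then a clean test: at 50,000 cases an injected
tenfold drug recovers an empirical OR near 10 and is flagged by all four
algorithms.

What the generator does **not** emulate: realistic co-prescription
structure (drug draws are independent, up to the at-least-one-drug
forcing and the five-drug cap — both of which induce mild negative
dependence between drugs, visible in small catalogs), free-text name
noise beyond four spelling variants, regional or temporal reporting
trends, and indication confounding. Passing tests on synthetic data
therefore demonstrate algorithmic correctness and calibration under a
known model, not robustness to every bias of real spontaneous data.

A note on test configurations with small catalogs: with few drugs, the
at-least-one-drug rule inflates every drug's effective marginal and,
more subtly, enriches the "neither drug" stratum of a pair with other
drugs. Study configurations in the tests therefore include one or two
high-marginal null "background" drugs that absorb the forced draws,
keeping analysis-drug marginals near nominal.

# The lawyer-exclusion sensitivity analysis

Litigation-driven reporting concentrates event reports for a litigated
drug, which inflates the event-only cell $c$ of *every other* drug and
can push borderline true signals below threshold. `sensitivity_exclude()`
re-runs the whole screen on retained reports minus one reporter
occupation and diffs the positive sets. The test configuration plants a
truly positive "litigated" drug with a thirteenfold lawyer-bias
multiplier and a second true signal ("masked"); at baseline the masked
drug fails (its EBGM is diluted by the lawyer-driven background), and
after exclusion the positive set enlarges — the qualitative mechanism by
which removing lawyer reports *increases* the number of detected
signals, as observed in real data.

# Problem sizes and reproducibility

The shipped tests run the generator at 1,000–9,000 cases per scenario
(50,000 for the parameter-recovery and null-OR checks), 100 seeds for
the sensitivity-mechanism replication, and 1,000 simulated tables for
null calibration of the combined rule; these sizes were chosen so the
whole suite documents the statistical claims while remaining quick to
run routinely. Every stochastic test pins its seed, and
`run_pipeline()` reruns are byte-identical CSV for byte: the run
manifest records versions, seeds, per-stage record counts
(`parsed = retained + removed_as_duplicate + removed_by_deletion`), and
warnings.

# Known limitations

* The MGPS column is the printed geometric-mean form, not a fitted
  gamma-Poisson mixture; for small $a$ it shrinks less than a true
  empirical-Bayes fit would.
* IC$_{025}$ is a closed-form approximation; published per-drug IC
  bounds computed with Monte-Carlo posteriors will differ slightly.
* No multiplicity adjustment is applied across drugs — the combined
  four-way rule is the (informal) false-positive control, as is
  conventional in this literature.
* Report-level counting is used throughout (one case may contribute
  several drugs); patient-level collapsing is available by grouping on
  `caseid` but is not the default.
* The legacy pre-2012 AERS column dialect is out of scope; bundles are
  expected in the post-2012 layout.
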