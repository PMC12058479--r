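---
title: "Disproportionality screening and risk modelling for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening and risk modelling for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The problem

Spontaneous adverse-event reporting databases such as FAERS collect
individual case safety reports (ICSRs) submitted after a suspected adverse
drug reaction. They contain no denominator — nobody knows how many patients
took each drug — so absolute risks cannot be estimated. What *can* be
estimated is disproportionality: whether reports naming a drug mention an
event more often than the rest of the database does. `faersignal`
implements the full screening cascade for one event of interest (by
default the MedDRA preferred term *cataract*): report cleaning,
reporting-odds-ratio (ROR) screening, LASSO-then-multivariate logistic
risk modelling, and time-to-onset analysis, together with a synthetic
report generator carrying known ground truth so every stage has a
parameter-recovery test.

## Report cleaning

Raw quarterly files carry several versions of the same case, drugs in four
role codes, and incomplete or implausible demographics. The cascade, in
order:

1. **Normalization** — drug names are upper-cased, whitespace-squeezed,
   stripped of trailing salt/ester words (an editable list, since any
   brand-consolidation dictionary is site-specific), and optionally mapped
   through a brand-to-ingredient table.
2. **Deduplication** — one report per case: the latest `version_date`
   wins, ties broken by the lexicographically greatest `report_id`. This
   is the standard "latest case version supersedes" rule.
3. **Primary-suspect restriction** — only primary-suspect drug entries are
   analysed. An ingredient listed in one report under both primary-suspect
   *and* another role (concomitant, secondary suspect, interacting) has
   ambiguous suspect status and is excluded from that report entirely; the
   count of such conflicts is logged so the effect is auditable.
4. **Demographic filters** — complete-case on age, sex and weight, with
   plausibility bounds: ages above 120 years and weights above 400 kg are
   excluded. The boundary values themselves are retained, following the
   strict-inequality reading of "exceeded 120" / "over 400".

Every stage appends a row to a provenance table whose counters always
equal the actual collection size, so the full flow diagram of any run can
be reconstructed from the output.

Two parsing conventions worth stating: partial dates `YYYYMM` resolve to
the first of the month and bare years to July 1 (the median-unbiased day
within a year), and a report with no outcome rows carries the explicit
category `missing` rather than silently vanishing from outcome tables.

## Disproportionality screening

For each drug \(D\) the cleaned set is cross-tabulated against the event:

|            | event | non-event |
|------------|-------|-----------|
| drug       | a     | b         |
| other drugs| c     | d         |

\[
\mathrm{ROR} = \frac{a/c}{b/d} = \frac{ad}{bc}, \qquad
\mathrm{CI}_{95\%} = \exp\!\left(\ln \mathrm{ROR} \pm 1.96
  \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right).
\]

The interval is symmetric on the log scale, so the point estimate is the
geometric mean of its bounds — `point_from_ci()` exploits this to validate
printed results. Significance comes from the two-sided Fisher exact test,
computed by summing log-space hypergeometric masses over the table support
(never overflowing, whatever the margins), always on the *uncorrected*
counts. When a cell is zero, the ROR and CI use the Haldane–Anscombe
correction (0.5 added to all four cells) and the row is flagged
`zero_corrected`; a `strict` policy that errors instead is available.

Multiplicity is controlled by Bonferroni: `p_adj = min(1, m p)`, with `m`
the number of drugs in the tested family. Because the family is a run-time
property (all drugs with more than `min_cases` case reports, by default),
`m` is recorded in the output's `m` attribute; it can be fixed explicitly
for calibration studies.

Two screening rules are exposed, matching their two roles in the cascade:

* `screen_signals()` — the *signal* rule, all strict inequalities:
  `n_cases > 100`, `ROR > 3`, CI lower bound `> 1`, `p_adj < 0.01`.
* `candidate_drugs()` — the *univariate candidate* rule feeding the
  modelling stage: `n_cases > 100`, CI lower bound `> 1`, `p_adj < 0.01`,
  with no ROR-magnitude threshold.

The distinction matters for recovery experiments. The comparator of a
case/non-case design is "all other reports", so every other elevated drug
in the database contaminates the comparator and attenuates the marginal
ROR below the conditional odds ratio that generated the data; a drug whose
true conditional OR sits exactly at 3 will hover around the magnitude
threshold no matter how large the database. Parameter-recovery claims in
the test-suite are therefore stated against the candidate rule (which is
also the rule that feeds the LASSO), while the magnitude rule is tested on
its own fixed examples.

`volcano_table()` emits the plot-ready screening summary: `log2(ROR)`
against `-log10(p_adj)` (adjusted p floored at `1e-300` so exact zeros map
to 300), coloured by `log10(n_cases)`. The logarithm bases are arguments
and are written into the column names.

## Risk modelling

Candidates from the univariate screen enter a report-level design matrix:
one 0/1 primary-suspect indicator per drug plus unstandardized
`age_years`, `weight_kg` and `sex_female`. Rows are canonically ordered by
report id, which makes the seeded, outcome-stratified cross-validation
folds — and hence every reported statistic — invariant to input row order.

**Selection.** `fit_lasso_logistic()` runs L1-penalized logistic
regression (coordinate descent via glmnet) over a log-spaced grid of 100
penalties spanning four decades down from a data-derived
\(\lambda_{max}\): the smallest penalty with all drug coefficients zero,
obtained from the Karush–Kuhn–Tucker condition using the standardized
score of each drug column against the residual of the unpenalized
demographic-only fit. Demographics and the intercept are never penalized —
they are adjustment variables, not selection candidates. The selected
penalty minimizes mean cross-validated binomial deviance over 10
stratified folds ("lambda.min"); we prefer it to the sparser
one-standard-error rule because the stage is a *screen*, where a false
exclusion is costlier than a false inclusion (the multivariate Wald test
downstream re-examines every survivor).

**Estimation.** `fit_logistic()` fits the multivariate model by
iteratively reweighted least squares, with convergence declared on the
score max-norm (tolerance `1e-8`, at most 100 iterations) and verified
against the deviance-based stopping of the underlying solver. Standard
errors come from the inverse observed information; Wald 95% intervals are
`exp(coef ± 1.96·SE)`. Bonferroni adjustment spans the drug terms only.
Complete separation (|coef| > 15 with an exploding SE) is flagged per
column rather than failing the fit. Collinear columns are dropped with a
warning. A drug term with adjusted p below 0.01 is flagged as an
independent risk factor.

**Discrimination.** `roc_auc()` computes the area under the ROC curve in
its Mann–Whitney form from midranks, so tied scores contribute one half;
this equals pairwise concordance exactly, which the tests verify against
an \(O(n^2)\) oracle.

## Time to onset

For each event report the lag is `event_date` minus the *earliest*
primary-suspect `therapy_start`; records with a missing date or a
non-positive lag are excluded and counted by reason (no imputation — in
particular the report receipt date is never used as an event-date proxy).
Quantiles use type-7 linear interpolation between order statistics (R's
default). One consequence worth knowing: an interpolated quantile sits
strictly between two order statistics, so the empirical CDF evaluated at
the computed quantile can undershoot the target probability by up to one
observation's mass, `1/n` — the property tests state the bound that way.
The cumulative-incidence curve is the plain ECDF over distinct day values,
ending exactly at 1.

## The synthetic generator

`simulate_reports()` draws reports from the generative model the screening
statistics assume: exactly one primary-suspect drug per report, sampled by
exposure probability, and an event indicator
\[
  Y \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}\big(\alpha +
  \beta_{\mathrm{drug}} + \beta_a (a - \bar a) + \beta_w (w - \bar w) +
  \beta_s (s - \bar s)\big)\right),
\]
with demographic effects centred at their configured means so that
\(\alpha\) stays the population-average baseline logit. Defaults are the
cataract case-study conditions: a 30-drug panel at 1% exposure each with
injected odds ratios \{3, 4, 6, 10, 14\} on the first five drugs;
age 66.92 ± 11.95 years, 71.16% female, weight 72.44 ± 22.53 kg (the
reference cataract case-series demographics); modest demographic effects (log-odds
0.02 per year, 0.002 per kg, 0.1 for female sex); a 5% baseline event
rate, chosen so that a desk-scale run of 2×10⁵ reports yields roughly ten
thousand events — enough for every downstream stage to be estimated —
rather than the databases' far lower per-event reporting fraction, which
no fixed-size simulation could carry. Event reports get an onset lag drawn
log-normal with median 449 days and \(\sigma = \ln(901/150)/(2 z_{0.75})
\approx 1.33\), the value implied by the reference interquartile range
(which is not exactly log-symmetric; the IQR *ratio* pins the dispersion).

The exposure mass not claimed by the named panel goes to a pool of 20
null background drugs. This is deliberate: if the named drugs exhausted
the database, the case/non-case comparator would consist only of other
panel drugs and the injected odds ratios would be unrecoverable by
construction. With 70% background mass, comparator contamination by the
injected signals is a few percent — visible (the recovered marginal RORs
run slightly below the conditional truths) but small against the
estimators' standard errors.

Contamination injected last, with full bookkeeping in the truth ledger:

* *duplicates* — a configurable fraction of cases re-emitted as an extra
  **earlier-dated** version, so the keep-latest deduplication rule
  provably restores the truth copy;
* *missingness* — one demographic field blanked per selected report;
* *implausible values* — ages drawn above 120 or weights above 400,
  exercising the plausibility filters.

What the generator does **not** emulate: polypharmacy (one suspect drug
per report keeps the 2×2 mapping exact), misspelled or brand-variant drug
names, secular reporting trends beyond uniform year sampling, event-term
families beyond a single PT, and correlated demographics. Passing
recovery tests therefore demonstrate the statistical machinery under the
stated model, not robustness to the full messiness of real spontaneous
data.

## Problem sizes and numerical choices

The recovery suites run at the scale a single desk machine handles
comfortably: 2×10⁵ reports per replicate (20 replicates for screen and
coefficient recovery, 100 smaller null replicates for calibration), with
cleaning and screening taking roughly a second per replicate and the
multivariate fit a few seconds. The LASSO-to-ML consistency check uses a
500 × 8 fixture with moderate effects (odds ratios 1.2–1.35, exposure
25%) — a deliberately well-conditioned likelihood, since the demonstration
that the penalized path reaches the maximum-likelihood fit at
\(\lambda_{max}\cdot 10^{-4}\) requires the residual penalty shift to be
below the comparison tolerance, which is a property of the likelihood's
curvature, not of the solver. Fisher p-values carry the customary
\(1+10^{-7}\) relative slack when comparing hypergeometric masses for
two-sided accumulation; interval arithmetic uses the conventional 1.96 at
the 95% level, as the formula is written in the field.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  simulate = sim_config(n_reports = 2e5, seed = 1),
  criteria = signal_criteria()
)
res <- run_pipeline(cfg, "run1")
res$signals |> filter(flagged)
res$onset_summary
```

Every stage output lands in `run1/` as TSV/JSON, along with a manifest
(configuration echo, seed, provenance counters, package version). Re-runs
of the same configuration are byte-identical apart from the manifest
timestamp.

## Known limitations

Disproportionality is reporting-ratio inference, not risk estimation: no
denominators, no causality. The comparator-contamination attenuation
described above is inherent to the case/non-case design and grows with
the exposure share and effect size of co-screened signals. Bonferroni is
conservative for thousands of correlated drug tests. The multivariate
model conditions only on three demographics; indication bias and
comorbidity confounding, which the source data cannot resolve, are out of
scope. Time-to-onset uses reported dates at day precision and excludes,
rather than imputes, incomplete records — exclusion counters quantify the
information loss per run.
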