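---
title: "Disproportionality signal detection for FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect safety reports without a denominator:
we observe how often a drug–event pair is *reported*, never how often it
*occurs* among exposed patients. Signal detection therefore works by
disproportionality: a drug–event pair is interesting when the pair is
reported more often than the drug's overall reporting volume and the
event's overall reporting volume would jointly predict.

`faersignal` implements this workflow for combination-exposure questions —
its motivating use case is immune checkpoint inhibitors (durvalumab,
pembrolizumab, ipilimumab, atezolizumab, nivolumab) given together with
platinum agents (cisplatin, carboplatin, oxaliplatin) — from raw FAERS
quarterly ASCII files through deduplication, cohort construction,
four-algorithm disproportionality analysis, time-to-onset and subgroup
summaries. A synthetic FAERS generator with known ground truth makes every
stage testable without the multi-gigabyte public download.

## Ingestion and case cleaning

FAERS quarters are "$"-delimited text tables (DEMO, DRUG, REAC, THER,
OUTC) with no quoting convention. The reader treats any line whose field
count disagrees with the header as malformed — including lines with an
embedded "$" — and counts rather than repairs them. Child rows whose
`primaryid` has no DEMO parent are quarantined, not analysed. Only the
post-2012Q4 column layout is supported; the synthetic generator emits the
same layout.

Date fields are classified by completeness: `YYYYMMDD` strings that form a
real calendar date have day precision, `YYYYMM` month precision, `YYYY`
year precision, and everything else (including impossible dates such as
`20230230`) is invalid. Classification is total — no date ever raises an
error — because downstream stages treat exclusions as values with reasons.

FAERS carries multiple versions of the same case. Deduplication follows
the FDA-recommended rule: group rows by `CASEID`, keep the entry with the
latest `FDA_DT`, and break `FDA_DT` ties by the highest `PRIMARYID`
(numeric comparison, falling back to ranked string comparison when ids are
non-numeric). Rows with a missing `CASEID` cannot be grouped and are
retained unconditionally but tallied, so the screening funnel stays
conservative.

## Cohorts

Exposure is determined from normalised ingredient names (upper-casing,
trailing punctuation and dose-token stripping, then a packaged editable
synonym dictionary covering brands such as KEYTRUDA or ELOXATIN). A report
is assigned exactly one label:

* **combination** — at least one checkpoint inhibitor *and* one platinum
  agent, each at a suspect role;
* **ici_mono** / **platinum_mono** — the one class as primary suspect and
  no drug of the other class in any suspect (PS/SS) role;
* **background** — everything else.

The suspect role defining combination co-exposure defaults to primary
suspect (`PS`) only. This is the strictest reading of primary-suspect
screening; because reasonable analysts also count secondary suspects, the
rule is a configuration switch (`suspect_roles = "PS+SS"`). Drugs listed
only as concomitant or interacting never confer exposure: concomitant
listings are not suspect attributions.

## The 2×2 table and its counting convention

For an event term $t$ and a target cohort, the table is

|            | term $t$ | other terms |
|------------|----------|-------------|
| cohort     | $a$      | $b$         |
| background | $c$      | $d$         |

with report-level presence: a report contributes at most one count to a
term even if the term repeats among its reactions, and the margins $a+b$
and $c+d$ are the cohort's and background's *report–term pairs*. The
background comparator is all deduplicated reports outside the target
cohort over the same period — the usual full-database convention. The
expected count under independence is $E = (a+b)(a+c)/N$, $N = a+b+c+d$.
System Organ Class tables use the same convention after mapping each PT to
one SOC (primary SOC only) via a packaged stub map, since the licensed
MedDRA dictionary cannot be shipped.

## The four algorithms

All four estimators act on the same table; a term is a **signal** only
when all four criteria hold simultaneously.

**Reporting odds ratio.** $ROR = ad/bc$ with the Woolf interval
$\exp(\ln ROR \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$.
Criterion: $a \ge 3$ and lower bound $> 1$ (strict).

**Proportional reporting ratio.**
$PRR = \frac{a/(a+b)}{c/(c+d)}$ with Pearson's
$\chi^2 = N(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]$, by default without the
Yates correction (a corrected variant is a flag). Criterion: $a \ge 3$,
$PRR \ge 2$, $\chi^2 \ge 4$.

**BCPNN information component.** The default is the shrinkage
observed-to-expected form
$IC = \log_2 \frac{a + 0.5}{E + 0.5}$, with the credibility lower bound
$IC_{025} = IC - 3.3\,(a+0.5)^{-1/2} - 2.0\,(a+0.5)^{-3/2}$.
An alternative full-Bayes variant computes the posterior mean and variance
of the information component under independent Beta/Dirichlet priors with
a normal approximation for the bound; the two agree to first order and
coincide at large counts. Criterion: $IC_{025} > 0$ (strict).

**MGPS / EBGM.** The Multi-item Gamma Poisson Shrinker models the
reporting-rate ratio $\lambda$ of each cell as
$N_{obs} \sim \mathrm{Poisson}(\lambda E)$ with
$\lambda \sim p\,\Gamma(\alpha_1, \beta_1) + (1-p)\,\Gamma(\alpha_2, \beta_2)$
(shape/rate). The five hyperparameters are estimated by maximising the
marginal likelihood — a two-component negative-binomial mixture — over the
whole count grid. The posterior for a cell is again a Gamma mixture;
$EBGM = \exp E[\ln\lambda \mid N_{obs}]$ (the posterior geometric mean,
evaluated with digamma terms) and $EBGM_{05}$ is the posterior 5th
percentile by root-finding on the mixture CDF. Criterion:
$EBGM_{05} > 2$.

Published analyses rarely state which IC or EBGM variant they used, and
variants differ in the second decimal; every variant choice here is
therefore explicit, defaulted to the forms above, and switchable.

### Numerical choices

* **MGPS optimisation** runs quasi-Newton (BFGS) on
  $(\log\alpha_1, \log\beta_1, \log\alpha_2, \log\beta_2,
  \mathrm{logit}\,p)$ from five starts including DuMouchel's classic
  $(0.2, 0.1, 2.0, 4.0, 1/3)$, keeping the best converged optimum
  (relative tolerance $10^{-8}$ or better). Non-convergence from every
  start is an error carrying the last iterate. Components are reported
  with the larger prior mean first, which makes fits comparable across
  runs; a grid of fewer than 100 cells is refused.
* **Mixture likelihoods** are evaluated on the log scale with
  max-stabilised mixing so extreme cells cannot underflow.
* **$EBGM_{05}$ root-finding** brackets the mixture quantile by the
  component quantiles, widened slightly, because with near-degenerate
  fitted components (as on null data) the CDF equals 0.05 to rounding at
  an endpoint.
* **Zero cells** leave ROR/PRR undefined (`NA`, which fails the signal
  gate) by default; the Haldane–Anscombe +0.5 correction is available by
  flag. Boundary comparisons in the gate are strict: a lower bound of
  exactly 1, or $IC_{025}$ of exactly 0, is not a signal.

## Time to onset and descriptive summaries

Onset is `EVENT_DT − START_DT` in days, computed only when both dates
have day precision; events dated before therapy start are excluded as
pre-treatment, anything else as incomplete, and the accounting identity
`n_input = n_valid + n_pre_treatment + n_incomplete` is asserted in the
funnel. When a report has several therapy rows the earliest valid
`START_DT` is used — onset is measured from initiation of the regimen.
Summaries report the median and quartiles by linear interpolation
(type 7 by default; type 6 is a flag because published interquartile
ranges can depend on the convention) and counts in 0–30, 31–60, 61–90,
91–180, 181–360 and >360-day bins, with one month equal to exactly
30 days.

Subgroup tables stratify by sex and by age bins <18, 18–65 and >65 years
after unit conversion (decades ×10, months ÷12, days ÷365.25); unknown
strata are tallied, never silently dropped. Cohort comparisons merge two
cohorts' per-term counts over the union of terms and sort by absolute
difference.

## The synthetic reporting system

The generator exists so that every pipeline stage — parsing, dedup, cohort
logic, all four estimators, onset analysis — can be validated against
known ground truth. Each simulated case draws an exposure label, then
samples every catalogue term independently with probability
`base_p × RR(exposure, term)` capped at 0.99. The reporting-rate ratio is
multiplicative on the per-report reporting probability — deliberately a
*reporting-rate* model rather than an incidence model, because that is the
quantity disproportionality statistics estimate, making calibration
checks (such as confidence-interval coverage of an injected RR) exact in
their own terms.

Default parameters describe a desk-scale oncology combination-therapy
reporting system:

* demographic mixes follow the reporting pattern of such cohorts —
  sex 40% F / 52.6% M / 7.4% unknown; age 2.5% under 18, 36.9% 18–65,
  42.1% over 65, remainder unknown; physicians reporting 62.8% of cases;
  hospitalisation (36.6%) and death (16.3%) the commonest outcomes;
* onset is log-normal with median 38 days; the log-sd 1.54 places the
  quartiles near 13 and 108 days, the skew typical of early-onset
  haematological plus delayed immune-mediated toxicity;
* exposure prevalences (5% combination, 10% each monotherapy) are far
  higher than in the real database, where combination reports are roughly
  one report in a thousand — a deliberate scale-up so that desk-scale runs
  produce usable cohort sizes; the estimators are invariant to this choice
  because both cohort and background scale together;
* 10% of cases also emit an earlier report version (always an earlier
  `FDA_DT`, so the latest-wins dedup branch is exercised), a quarter of
  which share the original's `FDA_DT` to exercise the `PRIMARYID`
  tie-break; 10% of event dates are truncated to month or year precision
  or corrupted; 2% of events are dated before therapy start;
* the event catalogue holds 15 real preferred terms from this safety
  domain plus 240 synthetic filler terms with log-spaced baselines —
  kept above 200 terms so null-calibration studies have a meaningful
  denominator; the default injected association is a reporting-rate ratio
  of 8 for febrile neutropenia under combination exposure.

Reports are split one quarter per 25,000 cases to exercise multi-quarter
concatenation, and a fixed seed makes the written files byte-identical.
A `ground_truth.json` manifest records every construction count;
`manifest_check()` re-reads the files through the package's own reader and
verifies all of them.

What the generator does **not** emulate: the breadth of the MedDRA
vocabulary, correlated event co-reporting within a report (terms are
conditionally independent given exposure), drug–drug interaction
structure, reporting-volume trends over calendar time, and country- or
reporter-specific reporting styles. Passing tests on synthetic data
therefore demonstrate the correctness and calibration of the estimators
under the stated model, not the epidemiological validity of any signal in
real FAERS data.

## Validation design and problem sizes

The test suite checks, among others:

* hand-evaluated worked examples for every estimator, and published
  table rows reproduced by reconstructing each row's 2×2 table from its
  printed statistics (root-finding on the defining equations) and
  verifying the package's Woolf bounds against the printed intervals;
* `ebgm_scores()` against an independent adaptive-quadrature posterior
  oracle to $10^{-4}$ relative accuracy, and onset quantiles against a
  sort-based interpolation oracle;
* MGPS hyperparameter recovery within 25% on 5,000 cells simulated from
  the classic prior; an injected RR = 8 recovered through the full
  file-backed pipeline at 200,000 reports with a covering 95% interval,
  and interval coverage of 88–100% across 50 replicates;
* a null system (all RR = 1, 255 terms, 100,000 reports) flagging at most
  1% of terms across all four criteria jointly;
* byte-identical pipeline reruns and funnel conservation
  (`rows_in = rows_out + rows_excluded` at every stage).

These sizes keep the whole suite within a few minutes on one CPU while
leaving Monte-Carlo tolerances comfortable.

## Known limitations

* The stub PT→SOC map covers only the packaged vocabulary; real analyses
  should supply a licensed MedDRA map via `meddra_map_path`.
* SOC-level signals use each PT's primary SOC only; MedDRA multi-axiality
  is out of scope.
* The MGPS implementation is unstratified; covariate-adjusted
  (Mantel–Haenszel) expected counts are not computed.
* Monotherapy comparator cohorts exclude reports carrying the other drug
  class in any suspect role, one of several defensible readings of
  published cohort definitions.
* Disproportionality quantifies reporting, not risk: no denominator, no
  causality.
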