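# faersignal

Pharmacovigilance signal detection for FAERS spontaneous adverse-event
reports, built around the combination-exposure question: which adverse
events are disproportionately reported when immune checkpoint inhibitors
(durvalumab, pembrolizumab, ipilimumab, atezolizumab, nivolumab) are given
together with platinum agents (cisplatin, carboplatin, oxaliplatin)?

The package is for pharmacoepidemiologists and drug-safety analysts who
work with the public FAERS quarterly ASCII releases. It covers the full
workflow:

* **Ingestion** of the "$"-delimited DEMO/DRUG/REAC/THER/OUTC tables with
  malformed-line accounting and orphan-row quarantine.
* **Deduplication** by the FDA-recommended rule: one report per `CASEID`,
  latest `FDA_DT` wins, ties broken by highest `PRIMARYID`.
* **Cohort construction** from normalised drug names at suspect roles:
  combination, ICI monotherapy, platinum monotherapy, background.
* **Four-algorithm disproportionality analysis** on per-term 2×2 tables
  (a = cohort reports with the term, margins = report–term pairs):
  - ROR `= ad/bc` with Woolf 95% CI
    `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; signal if `a ≥ 3` and
    lower bound `> 1`;
  - PRR `= [a/(a+b)]/[c/(c+d)]` with Pearson `χ²` (no continuity
    correction); signal if `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`;
  - BCPNN information component
    `IC = log2[(a+0.5)/(E+0.5)]`, `E = (a+b)(a+c)/N`, with shrinkage
    lower bound `IC025`; signal if `IC025 > 0`;
  - MGPS empirical Bayes: `N_obs ~ Poisson(λE)` with a two-component
    Gamma-mixture prior on λ fitted by marginal maximum likelihood;
    `EBGM = exp(E[ln λ | N_obs])`, `EBGM05` the posterior 5th percentile;
    signal if `EBGM05 > 2`.

  A term is **significant** only when all four criteria hold.
* **Time-to-onset** (`EVENT_DT − START_DT`, day-precision dates only,
  pre-treatment events excluded), demographic summaries, age/sex subgroup
  tables, and combination-vs-monotherapy comparisons.
* **A synthetic FAERS generator** with configurable reporting-rate ratios,
  duplicate report versions, partial dates and demographic mixes, plus a
  ground-truth manifest — so the whole pipeline is testable without the
  20-million-report public download.

## Worked example

Simulate a 50,000-report system whose only planted signal is a
reporting-rate ratio of 8 for febrile neutropenia under combination
exposure, write it as FAERS quarterly files, and run the full pipeline:

```r
library(faersignal)

cfg <- synthetic_config(n_reports = 50000, seed = 42)
dir <- file.path(tempdir(), "faers_demo")
manifest <- generate_faers(cfg, dir)

res <- run_full(run_config(
  input_dirs = file.path(dir, manifest$quarter_dirs),
  output_dir = file.path(tempdir(), "faers_demo_out"),
  meddra_map_path = file.path(dir, "pt_soc_map.csv")))
```

The run log shows the screening funnel and result sizes:

```
ingest: 55000 DEMO rows, 0 malformed lines, 0 orphan child rows
dedup: 55000 -> 50000 reports; cohorts: background=37366, combination=2593,
       ici_mono=5009, platinum_mono=5032
signals: 255 PTs, 1 significant
signals: 31 SOCs, 0 significant
tto: n=2323, median 39 days (IQR 13-104), 44.1% in month 1
```

The 5,000 duplicate report versions were removed, and of 255 candidate
terms exactly one passes all four criteria — the planted one:

```r
res$pt_signals[res$pt_signals$significant == TRUE,
               c("term", "a", "ror", "ror_lo", "ror_hi", "prr", "chi2",
                 "ic", "ic025", "ebgm", "ebgm05")]
#>                   term  a   ror ror_lo ror_hi   prr  chi2    ic ic025  ebgm ebgm05
#> 1: Febrile neutropenia 85 8.819  6.781  11.47 8.541 382.4 2.559 2.199 6.063  6.053
```

85 combination reports mention the term; the ROR interval (6.78, 11.47)
covers the true ratio 8, and the empirical-Bayes estimate 6.06 is shrunk
toward 1, as it should be for a moderate count. The onset summary for the
combination cohort reflects the generator's log-normal onset model
(median 38 days):

```
Time to onset: n = 2323, median 39.0 days (IQR 13.0-104.0)
  within first month: 44.1%
```

All tables are also written as CSV (`pt_signals.csv`, `soc_signals.csv`,
`tto_summary.csv`, `subgroup_sex.csv`, `cohort_comparison_ici_mono.csv`,
`demographics.csv`, `annual_counts.csv`, `funnel.csv`) together with a
`provenance.json` recording every variant flag and dictionary hash.

A command-line wrapper with `generate`, `run`, `signals`, `tto` and
`subgroups` subcommands is installed at `inst/cli/faersignal.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/faersignal.R", package="faersignal"))')" \
  generate --seed 1 --n-reports 10000 --out /tmp/synth
```

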