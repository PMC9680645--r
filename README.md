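# finpheno — financial digital phenotyping of mood-episode spending

Objective financial records are a promising behavioral signal in bipolar
disorder: hypomanic episodes are associated with impulsive spending and a
shift toward credit, visible in everyday transaction streams long before a
clinical encounter. `finpheno` implements an N-of-1 analysis workflow for
exactly this setting — from messy bank-statement exports and a
retrospective monthly mood life chart to privacy-preserving transaction
features, burstiness statistics, phase-stratified inference, and
unsupervised anomaly flags — together with a mood-modulated synthetic
ledger generator, so every stage is fully testable without anyone's real
financial data.

## What it computes

- **Ingest.** Delimited statement exports with PDF-extraction artifacts
  (one transaction across several physical rows, several account sections
  per file, one account across many files) are parsed with an explicit
  dialect into a clean, date-sorted, account-labeled ledger.
- **Privacy transform.** Income transactions are dropped, free-text
  descriptions removed, and amounts min-max normalized *per account*:
  `x' = (x − min)/(max − min)`, so no identifying text or raw monetary
  value survives.
- **Labels.** Each transaction inherits the mania severity
  (none/mild/moderate/severe) of its calendar month from an NIMH
  Life-Chart-style monthly rating series, plus a merged binary label
  (none vs symptomatic).
- **Features.** Per-period transaction *frequency* (count) and *volume*
  (sum of normalized amounts) at daily/weekly/monthly grains, with
  zero-transaction periods retained, and the monthly percentage of
  purchases made on credit.
- **Burstiness.** `B = (r − 1)/(r + 1)` with `r = σ/τ`, the coefficient
  of variation of inter-event intervals, under two schemes: D (day gaps
  between successive transactions) and C (lengths of zero-expenditure day
  runs); −1 = perfectly regular, 0 = memoryless, → 1 = extreme spikes.
  Computed overall and per symptomatic phase.
- **Inference.** Welch's heteroscedasticity-robust one-way ANOVA with
  Games-Howell post-hoc contrasts (own studentized-range quadrature)
  comparing per-period frequency and volume across phases.
- **Anomalies.** An isolation forest (implemented in the package, scored
  as `s(x) = 2^(−E[h(x)]/c(ψ))`) over the weekly frequency series, with a
  contamination parameter fixing the flagged fraction.

## Worked example

The `analysis/` directory holds the numbered workflow scripts
(`01_simulate.R` … `06_anomaly.R`); each is a thin driver over package
functions and writes its tables under `results/`. Running them in order
on the default synthetic case study (24 months, two accounts, bursty
counting mode, seed 2017) prints, among other things:

```
Simulated 3726 transactions (3678 expenditures, 48 income) over 24 months
Episode structure: mild 2 episodes / 5 months; moderate 5 episodes / 9 months
...
Parsed 3726 transactions from 24 monthly statements; round-trip exact
...
Burstiness by phase (merged two-phase layout):
 scheme       phase    n      B
      D        none 1529  0.432
      D symptomatic 2134  0.410
      D     overall 3677  0.416
      C        none   49 -0.507
      C symptomatic   54 -0.581
      C     overall  102 -0.528

frequency (three phases): Welch F(2, 393) = 0.02, p = 0.977
...
Flagged 5 of 104 complete weeks (contamination 0.05, threshold score 0.578)
```

Read: transaction timing is bursty (positive B under scheme D) while the
zero-spend-run scheme sits on the regular side (negative B); daily
frequency does not differ significantly between phases at the default
near-null effect sizes, matching the study conditions the generator
encodes; and 5% of weeks are flagged as anomalous spending periods
without using the mood labels. The same ledger can equally be produced
via `run_pipeline()`, which executes every stage in one call and writes a
reproducibility manifest.

```r
library(finpheno)
chart <- case_study_lifechart()          # packaged 24-month fixture
episode_summary(chart)
cfg <- synthetic_config(interval_law = "heavy_tailed", seed = 2017)
sim <- generate_ledger(chart, cfg)
labeled <- preprocess_ledger(sim$ledger, chart)
burstiness_by_phase(labeled, chart, scheme = "D", merge = TRUE)
```

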