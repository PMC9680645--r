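---
title: "Methods: financial phenotyping of mood-episode spending"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: financial phenotyping of mood-episode spending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finpheno)
```

## The setting

`finpheno` analyzes a single person's transaction stream against a
retrospective monthly mood record. The subject is an individual with
bipolar disorder whose hypomanic episodes were charted month-by-month
(none/mild/moderate/severe mania, plus a depression channel that stays at
none in the reference case). The analysis asks three questions of the
spending record: does the *level* of spending (frequency, volume) differ
between symptomatic phases; does the *timing* of spending differ
(burstiness); and can unusual spending periods be found *without* the mood
labels at all (anomaly detection).

Because real statements are private, the package ships a synthetic
generator that emulates the study conditions; every claim the test suite
makes is a claim about this synthetic world, and the section on the
generator below is explicit about what that does and does not show.

## Ingest and its assumptions

Statement exports produced by PDF table extraction are not
row-per-transaction. The parser assumes:

- a **continuation row** is a row whose date cell and amount cell are both
  empty; its description cell is appended (space-separated) to the
  preceding transaction. Any other malformed row (amount present, date
  unparseable; zero amount) is a *record-level problem*: collected,
  reported via a warning and an attribute, and skipped — never silently
  dropped. The accounting identity `parsed + skipped = logical records` is
  tested.
- an **account marker row** (configurable regex, default
  `# ACCOUNT: <name>`) switches the account context for subsequent rows.
  A transaction row before any context, with no dialect default, is a
  fatal format error — guessing accounts would corrupt the whole series.
- dates carry **day-level resolution only** and are parsed with an
  explicit format string; there is no locale guessing.
- expenditure vs income is a dialect choice (`expenditure_sign`), default
  the common convention that debits print negative. Amounts are
  cent-quantized throughout; the statement writer and parser round-trip
  them exactly through fixed two-decimal formatting, so no cent-level
  drift can accumulate.

Joining monthly files deduplicates rows repeated *across* files (the
overlapping-statement-period artifact) on the full field tuple; rows
within one file are never collapsed against each other.

## Privacy transform

Descriptions are removed entirely, and amounts are min-max normalized per
account over the full analysis span: `x' = (x − min)/(max − min)`.
"Normalized between 0 and 1" is read as min-max rather than
divide-by-maximum because only min-max actually attains the lower
anchor 0 for strictly positive spending amounts; divide-by-max is kept as
a `method = "divmax"` sensitivity option. An account with a single
distinct amount maps to 0 with a warning (in-range, degenerate, visible).
Normalization happens after income exclusion; since income rows are
excluded either way, the order does not change the result. The
privacy-mode serialization writes only date, account, normalized amount
and severity; the test suite asserts that no description fragment and no
raw monetary value appears in the output file.

## Features

Frequency is the transaction count per period; volume is the sum of
normalized amounts per period. Series are zero-filled — every calendar
period of the span is present — because the zero-run interval scheme and
any honest "quiet week" reasoning require the empty periods. Choices that
the data do not force, made once and exposed as parameters:

- weekly bins are ISO weeks (Monday start), `week_start` configurable;
- a period's severity label is the label of the month containing the
  majority of its days, ties to the earlier month (daily periods simply
  inherit their month);
- partial edge periods are kept in the series but marked `partial`;
  consumers that would misread a truncated count (the anomaly detector)
  exclude them by default;
- the monthly credit ratio is count-based: per-account normalization
  makes cross-account *volume* ratios meaningless, so "percentage of
  purchases made on credit" counts purchases. A volume variant exists but
  is off by default.

## Burstiness

For inter-event intervals with mean τ and standard deviation σ, the
burstiness parameter is

\[ B = \frac{r - 1}{r + 1}, \qquad r = \sigma / \tau . \]

B is −1 exactly when σ = 0 (perfect regularity), near 0 for a memoryless
process (the exponential's coefficient of variation is 1), and approaches
1 only as r → ∞. Two interval schemes are computed: **D**, day
differences between successive transactions (several purchases on one day
give zero-length intervals), and **C**, lengths of maximal runs of
zero-expenditure days in the zero-filled daily series.

Numerical and definitional choices:

- σ is the **population** (n-denominator) standard deviation; a
  `sd_type = "sample"` switch exists for sensitivity. All documented
  example values use the population form.
- timestamps are unavailable in statements, so everything is day-grain;
  a consequence worth knowing is that at several transactions per day the
  day quantization alone pushes scheme-D burstiness well above 0 (most
  intervals are 0, a minority are 1), so "Poisson daily counts" and
  "B ≈ 0" only coincide in the sparse-rate regime. The test suite checks
  the memoryless null with continuous exponential intervals and with a
  sparse Poisson ledger.
- per-phase values group the stream by symptomatic intensity: intervals
  (scheme D) or zero-runs (scheme C) are collected within each contiguous
  same-phase stretch and pooled per phase, so a gap that spans another
  phase is attributed to neither side. Phases with fewer than two
  intervals yield NA rather than an error; τ = 0 (all-zero intervals) is
  an undefined statistic and raises a typed error.
- leading/trailing zero-runs are included in scheme C by default
  (`include_edges = FALSE` to drop them).

## Phase inference

Welch's one-way ANOVA is used because phase groups are unbalanced by
construction and need not share variances. With weights
\(w_i = n_i/s_i^2\), \(W = \sum w_i\), and
\(\Lambda = \sum (1 - w_i/W)^2/(n_i - 1)\):

\[ F = \frac{\sum_i w_i (\bar x_i - \bar x_w)^2 / (k - 1)}
          {1 + \frac{2(k-2)}{k^2-1}\Lambda},
   \quad df_1 = k - 1,\quad df_2 = \frac{k^2 - 1}{3\Lambda}. \]

Games-Howell post-hoc contrasts use per-pair standard errors
\(\sqrt{s_i^2/n_i + s_j^2/n_j}\), Welch–Satterthwaite degrees of freedom,
and the studentized-range distribution with k groups. The
studentized-range CDF and quantiles are computed inside the package by
Gauss–Legendre quadrature of the defining double integral
(`ptukey_num()`, 256 inner × 160 outer nodes), with absolute accuracy
below 1e-9 across the relevant k/df range — verified in the tests against
an independently computed reference table and against the k = 2 closed
form, where the studentized range reduces to the two-sided t tail. Note
that the "balanced, equal-variance" agreement between Welch and classic
ANOVA F is exact only at k = 2; for k ≥ 3 the Welch denominator differs
at finite n and the two statistics only converge as groups grow.

Frequency and volume are tested separately with no multiplicity
correction across the two endpoints; this mirrors the reporting
convention of the underlying case study and is a documented limitation.
Zero-variance groups are rejected with an error naming the group.

## Anomaly detection

The isolation forest is implemented in the package (so its internals are
assertable): `n_trees = 100` trees, per-tree subsamples of
`min(256, n)` points drawn without replacement, uniform split points
between the node's min and max, height limit `ceil(log2(ψ))`. Scores are
`s(x) = 2^(−E[h(x)]/c(ψ))` with the standard average-path-length
normalizer `c(·)` added at unexpanded leaves; constant training data
yields a degenerate model scoring everything 0.5. Flagging is
deterministic: exactly `floor(contamination · n)` top-scoring periods,
ties broken toward the earlier period, with the `1 − contamination`
score quantile reported as the threshold. The default contamination 0.05
is the value used in the reference analysis; it is a user judgment, not
estimated from data. Scoring is transductive (the fitted series is the
scored series), the usual usage for a retrospective N-of-1 record.
Partial edge weeks are excluded by default before fitting — a truncated
week has an artificially low count and would otherwise consume a flag as
a trivial extreme.

## The synthetic generator: what it emulates, and what passing tests mean

The generator encodes the study conditions: 24 months (2017–2018), two
accounts, a none-phase mean of 5.23 expenditures/day, mild/moderate rate
multipliers 1.05/1.02 taken from the observed phase-mean ratios — i.e.
*near-null effect sizes by default*, so the default world reproduces the
case study's non-significant phase differences; tests that need a
detectable effect inflate the moderate multiplier to 1.3 explicitly. The
episode layout reproduces the documented aggregates (two mild episodes
totaling 5 months, five moderate episodes totaling 9 months); the exact
placement of runs within the two years is not documented anywhere, so the
packaged fixture fixes an arbitrary placement and all aggregate-level
tests depend only on counts and totals.

Daily expenditure counts come from one of two counting processes:
`poisson` (counts Poisson at the phase rate) or `heavy_tailed`
(gamma-mixed Poisson, i.e. negative-binomial counts, dispersion shape
defaulting to 1). The heavy-tailed mode is the bursty regime: with the
default dispersion the day-grain scheme-D burstiness of generated ledgers
falls in the 0.3–0.5 band that the statistic is meant to flag, while the
sparse Poisson regime sits at B ≈ 0. The gamma-mixing construction was
chosen over a literal heavy-tailed renewal chain because it preserves the
per-phase mean-rate calibration exactly while still controlling
dispersion. Amounts are log-normal (meanlog log 20, sdlog 1; right-skewed
positive spending — a standard minimal choice, not an empirical claim
about the case study); the credit-account probability rises with severity
(0.30/0.40/0.45) to emulate the credit shift during symptomatic periods;
two monthly income events land on the checking account. Everything is
reproducible from one seed, and a ground-truth record (per-transaction
phase, per-day true rate, episode windows, bookkeeping counts) is
returned for recovery tests.

What the generator does *not* model: merchant structure, recurring bills
and paydays, depressive-phase spending changes (the reference case
observed none), sub-daily timing, and any dependence between amount and
timing beyond the shared phase. Passing tests therefore demonstrate that
the pipeline's statistics behave correctly on a stream with the *assumed*
structure — calibrated rates, episodic modulation, bursty or memoryless
timing — not that real bank data satisfies those assumptions.

## Problem sizes and test design

The test suite runs the inference oracle on 100 seed-fixed small datasets
(2–4 groups, 3–30 observations each) against frozen reference values and
a live `oneway.test()` comparison; the null level of the Welch test is
estimated from 5,000 replicates; generator recovery uses 200 seeds for
power/level at multiplier 1.3/1.0 and 20 seeds for anomaly-flag
enrichment in moderate-episode weeks. These sizes were chosen so the
whole suite exercises every stochastic claim at meaningful resolution
while remaining comfortable to run locally.

## Known limitations

- One subject, retrospective monthly labels: phase contrasts inherit all
  the label noise of recall; nothing here is a clinical instrument.
- Day-grain timing truncates burstiness information; the statistic's
  value depends visibly on the grain (see the quantization note above).
- The scheme-C "overall vs per-phase" relationship is not an identity:
  pooled zero-runs and phase-restricted zero-runs answer different
  questions, and both are reported rather than reconciled.
- No autocorrelation correction in the phase ANOVA: daily observations
  are treated as exchangeable within phase, as in the reference analysis.
- The credit ratio is a count share; with per-account normalization a
  faithful monetary share is unrecoverable by design (privacy first).
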