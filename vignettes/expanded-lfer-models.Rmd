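---
title: "Expanded LFER models for MCF partition coefficients: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expanded LFER models for MCF partition coefficients: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcflfer)
```

## The measurement and its models

A membrane-coated fiber (MCF) exposed to a solute-spiked formulation
takes up an amount `n0` of solute; the partition coefficient is the
ratio of equilibrium concentrations in the membrane and in the
formulation,

$$K = \frac{n_0 V_d}{V_m\,(C_0 V_d - n_0)},$$

with units fixed to µg and mL (`partition_coefficient()`). The membrane
volume $V_m$ is fiber-geometry dependent and is a required input — no
default is assumed. A zero extraction ($n_0 = 0$) gives $K = 0$ and no
finite $\log_{10} K$; such rows are dropped from modelling with a
warning rather than mapped to $-\infty$.

`log10 K` is regressed on the five Abraham descriptors. Three variants
share one fitting engine (`fit_ols()`):

* **single** — one block of six coefficients;
* **crossed** — one six-coefficient block per populated treatment cell
  (MWF × MWF concentration × solute concentration), cell-means coding:
  each block is complete and independent, there is no reference level
  and no shared intercept, so an observation activates exactly one
  block;
* **nested** — one seven-coefficient block per (MWF, MWF concentration)
  cell, solute concentration entering numerically as
  $t = \log_{10}(\text{conc})$, base 10.

Cell-means coding was chosen over contrast coding deliberately: the
scientific quantities of interest are the per-cell coefficients
themselves (e.g. "the `E` slope in mineral oil at 0.05 percent"), not
offsets from a reference cell.

## Numerical choices

Because the cross-product matrix of a cell-means design is
block-diagonal, the engine fits each block by its own rank-revealing QR
decomposition (relative pivot tolerance `1e-10`). Point estimates are
identical to a full-matrix least-squares fit — the unit tests verify
this against independent `lm()` fits cell by cell — while making the
hundreds of leave-one-solute-out refits of the 540-column crossed design
cheap. Columns that are collinear within their block are dropped and
reported; the expected cause is degenerate cells, e.g. every observed
solute in a cell sharing $A = 0$. For each dropped column the engine
retains its exact representation in the kept columns, so predictions for
new rows that replicate the training collinearity pattern (estimable
functions) remain defined; rows outside the training design's row space
are flagged unpredictable rather than extrapolated.

The residual variance of a pooled fit is a single $\hat\sigma^2$ across
all cells with `df = n - rank`, as befits one model fitted once; the
per-cell fits of `fit_per_cell()` instead use each cell's own residual
variance, because there each cell is its own model. Confidence intervals
use Student-t quantiles (per-cell sample sizes are small). A cell needs
at least 7 rows (6 parameters + 1 residual df) to be fitted on its own;
smaller cells are skipped with a reason.

## Cross-validation

$Q^2_{LOO} = 1 - \sum_l (y_l - \hat y_{l,-l})^2 / \sum_l (y_l - \bar
y)^2$ uses the closed-form deleted residual $e_l/(1-h_l)$ from the
leverages of the block fits; an explicit-refit path exists both as an
independent cross-check (the two agree to `1e-8` in the tests) and as
the conceptual fallback. $Q^2_{LOSO}$ removes *all* rows of each solute
per fold and refits genuinely — group deletion has no leverage shortcut.
$\bar y$ is the mean over the used rows of the full dataset, not
fold-specific means. Rows a training fold cannot predict are excluded
from numerator and denominator and counted in `n_unpredictable`, keeping
the statistic well-defined and the exclusion visible.

The distinction matters because of replicates: leave-one-row-out keeps a
held-out replicate's siblings in training, so $Q^2_{LOO}$ converges
toward $r^2$ as replication grows — duplicating every row of a noisy set
demonstrably inflates $Q^2_{LOO}$ while leaving $Q^2_{LOSO}$ unchanged
(numerator and denominator both double). $Q^2_{LOSO}$ is therefore the
headline statistic for predicting unseen solutes.

## The partition-theory battery

If extraction is proportional to the starting concentration,
$n_0 = p\,C_0$, then $C_0$ cancels in $K$:
$K = p V_d / (V_m (V_d - p))$ — the partition theory. In the nested
model this is exactly $H_0: \beta_{t,ij} = 0$ for all 15 cells. The
global test is the extra sum-of-squares F test of the full nested design
against the same design with every $t$ column removed; its numerator df
is the number of $t$ slopes the data can estimate, and it errors rather
than degenerates when no cell has two distinct concentrations. The 15
individual tests are t tests from the pooled fit — consistent with the
hypothesis being stated on the single nested model — at threshold
$\alpha/15$; the Bonferroni divisor stays at the design's 15 cells even
when some are unestimable (an option divides by the number actually
tested instead). The battery is repeated over nested subsets of the
concentration grid, each subset rebuilding its design from scratch; a
subset must retain at least two distinct concentrations.

Whether the per-cell tests should instead be partial F tests within
subset refits is an open design point; the pooled-t choice is recorded
in the output metadata and held fixed throughout.

## The generator: what it emulates and what it does not

`generator_config()` reproduces the study geometry — 37 solutes with
their published descriptor values, the 5 × 3 × 6 cell grid, up to 3
replicates — and draws responses from the nested model with Gaussian
noise on the log scale. Defaults are fixed once:

* `dropout = 0.535`: independent Bernoulli removal of replicates,
  calibrated so the expected retention (9990 × 0.465 ≈ 4646 rows)
  matches the study's realised sample;
* `noise_sd = 0.25`: the study reports no residual SD for its nested
  fit, so this is a calibration choice, picked to put the simulated
  $r^2$ near the reported fit quality and held fixed thereafter;
* `default_truth_coefficients()`: per-cell values encoding the
  qualitative structure the expanded models expose — positive `V`
  slopes, negative `A`, `B` and (mostly) `S` slopes, `E` slopes that
  fall with MWF concentration and change sign within mineral oil, and
  concentration slopes `bt` negative in 12 cells and exactly zero in
  `MO/0.05`, `PEG/5` and `SYN/0.05`, so the theory-test machinery has
  known ground truth for both rejection and non-rejection.

The generator does **not** model the laboratory causes of missingness
(detection limits, calibration range) — dropout is completely at random;
it does not generate raw extraction quantities (synthesis is at the
`log K` level; the partition formula is tested on analytic cases); and
solute concentrations sit exactly on the design grid. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under the assumed model, not that the model describes any
particular laboratory's data.

## Problem sizes and calibration checks

The test suite and the acceptance script run the pipeline at the study
scale (≈4.6k rows, 105-column nested and 540-column crossed designs),
with 200 generate/fit cycles for confidence-interval coverage, 500 null
datasets for the global test's type-I error, and 11 seeds for the
nested-vs-crossed $Q^2_{LOSO}$ comparison; brute-force oracles
(enumerated leave-one-out refits, per-cell `lm()` fits) run on reduced
sets of 50–150 rows. With 105 coefficients each tracked over 200
cycles, individual empirical coverages fluctuate binomially by a few
percent around 0.95 even under perfect calibration; the pooled coverage
is the stable summary.

## Known limitations

* The per-cell standard errors of a pooled fit assume homoscedasticity
  across cells; no robust or per-cell variance option exists for the
  pooled path.
* No regularised, robust or stepwise regression; the descriptor set is
  taken as given.
* `Q²` denominators exclude rows that were unpredictable in any fold;
  with heavily depleted cells this can differ from conventions that
  impute or drop folds wholesale. The `n_unpredictable` count makes the
  rule auditable.
* The YAML configuration covers the generator; model fitting is
  configured in code.
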