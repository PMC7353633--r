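---
title: "Screening UHT milk for adulteration from routine FTIR composition data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening UHT milk for adulteration from routine FTIR composition data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkscreen)
```

## The screening problem

Fluid-milk fraud — dilution with water, nitrogen-rich compounds added to fake
protein readings, carbohydrates or dairy powders added to restore solids,
preservatives used to conceal spoilage — leaves a signature in the seven
compositional parameters that FTIR milk analysers report routinely: protein,
fat, total solids (TS), solids-non-fat (SNF) and lactose (% w/w), density
(g/L) and freezing-point depression (FPD, °C, stored here as a positive
magnitude). `milkscreen` turns those seven numbers per sample into an
anomaly-screening decision, calibrated on a small set of genuine control
samples, and relates the resulting per-area prevalence of suspect samples to
fraud-vulnerability factor ranks.

The package works with two kinds of inputs: the bundled summaries of a
published Chinese UHT-milk market survey (three control pool profiles,
per-variable control statistics and percentile boundaries, 43 printed survey
records with their detection annotations, per-area survey totals, and 13
fraud-factor rank profiles for four production areas), and synthetic data the
package generates itself (control samples around the pool profiles, and the
full 339-sample adulteration design via mass balance).

## Univariate boundaries and the variance adjustment

Boundaries are the empirical 0.5th and 99.5th percentiles of each variable
over the control set (`compute_boundaries()`, linear interpolation between
order statistics — the conventional default; the percentile definition was a
free choice and is configurable). A sample is flagged when any variable falls
strictly outside its interval; values printed exactly on a boundary are
*within*. Strict comparison matters because the bundled survey records carry
the printed two-decimal precision: the protein lower-violation count of 32 is
reproduced only under strict comparison, while the fat and lactose counts each
land one or two below the narrative counts because single samples print
exactly on the 3.60 and 4.80 boundaries. We deliberately do not force
agreement with narrative counts where the printed table itself cannot yield
them.

A 15-sample control set understates the dispersion seen in large raw-milk
monitoring programmes (roughly double per variable). The variance adjustment
`variance_adjust()` maps each variable x to

    x_new = mu + f * (x - mu),  default f = 2,

which preserves the per-variable mean and multiplies the SD by exactly `f`.
Boundaries on the adjusted controls are therefore wider around the same
centres; the adjusted interval always encloses the measured one, so measured
boundaries flag at least as many samples.

## One-class classification

Three one-class classifiers are trained on genuine controls only, in
autoscaled space (per-variable centring/scaling with training statistics;
test data are never re-centred):

* **KNN** — score = mean Euclidean distance to the k nearest training
  vectors (k from 1–10; the mean is our aggregation choice, the distance-to-k
  -neighbours description leaves the aggregate open).
* **SIMCA** — a principal-component subspace of the controls (1–7 factors);
  score = sqrt of the sum of the squared orthogonal residual distance and the
  squared Mahalanobis score-space distance, each normalised by its training
  mean. This symmetric combination is a standard SIMCA variant and is
  testable against an explicit eigendecomposition.
* **One-class SVM** — RBF kernel, gamma from {1e-9, …, 1e-1, 1}, built on
  `e1071::svm(type = "one-classification")` with nu set to the significance
  level (0.01), mirroring the 1 % outlier budget. Scores are negated decision
  values so that, as for the other two, larger = more anomalous.

Thresholds come from repeated leave-30 %-out cross-validation
(`calibrate_threshold()`, 100 repetitions by default): each repetition holds
out round-half-up(0.30 n) samples (5 of 15), refits autoscaling and the model
on the remainder, and scores the held-out genuine samples; the threshold is
the empirical (1 − alpha) quantile of the pooled held-out scores. At
alpha = 0.01 at least 99 % of pooled scores sit inside by construction; the
"significance level of 1 %" is thus interpreted as an empirical quantile
calibration, the common OCC reading. All randomness flows through one seed;
sub-seeds are derived deterministically, so every threshold is reproducible.

Hyperparameters are selected by the mean of the cross-validation accuracy and
the percentage of adulterated samples correctly flagged (`occ_grid()` +
`select_model()`), ties going to the simpler model. The published
cross-validation percentages (92/88/90 etc.) depend on the unpublished raw
control samples and are *not* reproduction targets; on synthetic controls the
package asserts property bands instead: every selected classifier flags
> 80 % of level-4 water dilutions and carbohydrate additions while retaining
≥ 90 % of fresh genuine samples.

## The adulteration simulator

`enumerate_design()` spans the published design exactly: 24 adulterants in 5
categories × 4 single levels × 3 pools = 288 single recipes, plus
(5 protein-rich + 5 nitrogen + 7 carbohydrate) × 3 pools = 51 combined
recipes in which 100 g milk is diluted with 40 g water and the adulterant is
dosed to raise apparent protein (or, for carbohydrates, apparent TS) by 40 %
of the milk's own content. The per-level doses of the single adulterations
are configuration, not published measurements: water 10/20/30/40 g, powder
solids 0.5/1/2/4 g, preservatives 0.05/0.1/0.2/0.4 g per 100 g milk, all
overridable through `default_dose_levels()`.

`apply_recipe()` predicts the apparent composition by two-component mass
balance: every % w/w channel is component mass over total mass. Three
readout effects are modelled on top of plain mixing:

* apparent protein gains 6.38 × the adulterant's non-protein nitrogen
  (the Kjeldahl dairy factor), which is how melamine or urea inflate an
  FTIR protein reading;
* the lactose (carbohydrate) channel gains the solids of carbohydrate-class
  adulterants;
* density scales its excess over 1000 g/L with the milk concentration factor
  and rises 3.7 g/L per 1 % w/w added solids (a linear solids–density
  coefficient; configuration, not measurement);
* FPD scales with the milk water fraction — dilution moves it toward zero —
  and gains 1.86 °C·kg/mol × molality × dissociation count for dissolved
  low-molar-mass adulterants. Polymers (starch, maltodextrin, arrowroot,
  proteins) contribute negligibly and carry a dissociation count of 0.

Formaldehyde and hydrogen peroxide are dissolved liquids with essentially no
dry matter, so their solids fraction is 0 and a TS *decrease* of order
0.01 % w/w occurs at their doses; the TS-monotonicity property is therefore
asserted for adulterants that actually add solids.

## Consensus flagging and prevalence

Four criteria per survey sample — measured-boundary violation,
variance-adjusted-boundary violation, and the two KNN flags (measured /
variance-adjusted training data) — form a vote (`build_criteria()`); a
sample is a consensus suspect at ≥ 3 of 4 votes (`consensus()`). On the
bundled survey the rule yields exactly twelve suspects
(1, 2, 4, 5, 6, 12, 13, 14, 18, 19, 21, 26). When reproducing the published
survey the KNN votes come from the bundled annotations, because the fitted
models behind them depend on unpublished control data; in a fresh screening
the same function takes live `occ_model`s. Per-area prevalence
(`prevalence_by_area()`) keeps exact fractions for computation and
round-half-up integers for display (3/8 → 37.5 % → 38 %).

## Vulnerability regression

`regress_vulnerability()` relates the per-area suspect percentages (E, N,
NW, NE) to the 13 fraud-factor mean ranks by principal component regression:
predictors autoscaled, response centred only (the response treatment was
unstated; centring-only is our documented choice), coefficients reported in
autoscaled space. With four observations at most three components are
identifiable; the default count is the arg-min of the leave-one-out PRESS
over 1–3, computed by explicit refits with autoscaling redone inside every
fold. Inside a fold only three areas remain, so the centred rank is 2 and
candidate counts are capped at the fold rank. With 13 predictors and 4
observations the coefficient *magnitudes* are highly sensitive to these
choices; only qualitative signs are meaningful, and the package asserts only
the positive sign of factor 4 (supply-chain relationships), the direction
highlighted in the source study. On the bundled data the PRESS-selected
count is 2 and 11 of the 13 signs match the published regression vector.

## The synthetic control generator

`generate_controls()` emulates the 15-sample control set whose raw values
were never published: records cycle through pools A/B/C and draw each
variable independently from a normal around the pool mean. The within-pool
SD is the pooled SD minus the between-pool-mean variance (floored at 20 % of
the pooled SD), so a generated n = 15 set reproduces the published pooled
SDs; TS is generated by closure (pool TS mean plus the fat and SNF
deviations) to keep fat + SNF ≈ TS within each record. Two published
features are *not* emulated: between-variable covariance beyond the TS
closure (no covariance was published), and the density SD — printed as 1 g/L
after integer rounding, which is smaller than the spread of the printed pool
means alone, so generated density SDs land near 1.3 g/L. Property tests
passing on this generator show the machinery behaves correctly under the
stated dispersion model; they do not certify performance on real milk, whose
variables are strongly correlated.

## Numerical conventions and problem sizes

Quantiles are type-7 (linear interpolation); boundary comparisons are strict;
display percentages round half-up; degenerate inputs (zero SD columns,
constant responses, empty tables, empty grids) raise errors or return empty
summaries as documented on each function. Default analysis sizes — 15
synthetic controls, the 339-recipe adulterant set, 100 cross-validation
repetitions, full hyperparameter grids (10 + 7 + 10 points) — run in a few
seconds on one core and are the package's standard working set.

## Worked example

```{r example, eval = FALSE}
t3 <- load_table3_fixture()
report <- screen_survey(t3$records, annotations = t3$annotations)
report
pcr <- regress_vulnerability(prevalence = report$prevalence)
coefficient_signs(pcr)
```

## Known limitations

* No covariance model in the control generator; real compositional
  covariance would tighten multivariate models relative to the simulation.
* Dose levels and the solids–density coefficient are configurable defaults,
  not published constants.
* Published cross-validation accuracies and specificities are out of reach
  by design (unpublished raw controls); only property bands are checked.
* The PCR rests on 4 observations; it is a descriptive direction-of-
  association summary, not an inferential model.
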