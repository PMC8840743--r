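---
title: "Structure-free quantification of non-targeted LC/ESI/HRMS features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-free quantification of non-targeted LC/ESI/HRMS features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esiquant)
```

## The quantification problem

Electrospray response factors — the slope of peak area against molar
concentration — differ between small organic molecules by five to six
orders of magnitude. In non-targeted screening, where most detected
features have no standard and often no confirmed structure, this makes peak
areas incomparable across compounds. `esiquant` predicts the response
factor of a feature from its own chromatographic and mass spectrometric
behaviour, with no structural input, and converts areas to concentration
estimates.

The core assumptions are:

* **Linearity.** Within the working range, area = RF × concentration with a
  negligible intercept. Quantification therefore divides the area by the
  predicted RF and ignores the fitted intercept.
* **Shared physics of ionization.** How readily a compound ionizes in
  positive versus negative mode, and how its retention and response change
  with mobile-phase pH, reflect the same acid–base and polarity properties
  that drive ionization efficiency. Descriptors constructed from these
  observables therefore carry information about the response factor.
* **Same instrument, same method.** Retention times and area ratios are
  method-specific; models trained on one instrument/method are not expected
  to transfer without retraining.

## The twelve descriptors

For each compound (after split-peak merging) we compute, in fixed order:
three log₁₀ positive/negative area ratios (one per pH), three retention
times (one per pH, in minutes), the retention-time differences pH 8.0 −
pH 2.7 and pH 8.0 − pH 10.0, the detected-ion *m/z* (Da), a sodium-adduct
flag (pH 2.7), a negative-mode detectability flag, and the parity of the
nominal mass.

Decisions that the data formats leave open were fixed as follows:

* **Which dilution feeds the area ratio.** The ratio is the mean of
  per-dilution log₁₀(pos/neg) over dilutions detected in both modes. This
  cancels the (shared) concentration exactly and is robust to LOD censoring
  at the tails of the series. If the two modes were detected but never at a
  common dilution, the fallback is the difference of dilution-normalized
  mean log areas, which coincides with the per-dilution rule on common
  dilutions.
* **Sentinels.** −999 encodes "not detected in positive mode", +999 "not
  detected in negative mode". These values are consistent and far outside
  the genuine ratio range (the generator's configurations keep real ratios
  within ±20), which is exactly what tree-based learners need to route
  non-detections; they are deliberately not imputed or scaled. Missing
  retention times, retention-time differences involving a missing time, and
  the (rare) case of a pH with no detection in either mode also use −999.
* **Retention time source.** Positive-mode retention times are preferred,
  falling back to negative mode — positive mode detects the majority of
  compounds, keeping the descriptor consistent across the set.
* **m/z and parity.** The descriptor m/z is the positive-mode ion
  ([M + H]⁺) when available, else the negative-mode ion m/z + 2 proton
  masses; parity is computed on the nominal (half-away-from-zero rounded)
  mass of that ion.

## Calibration and the linear range

Response factors for standards are fitted by unweighted OLS of area on
concentration with a free intercept. "Linear range" needs an operational
definition; ours is: starting from all detected points sorted by
concentration, drop the highest-concentration point while more than three
points remain and the current fit fails an acceptance criterion. The
criterion is R² ≥ 0.99 **and** every point's back-calculated concentration
(area − intercept)/slope within ±30 % of nominal.

The back-calculation clause matters. A saturated top point has high
leverage: it can drag the fit toward itself and keep R² above 0.99 while
the low-concentration points are mis-predicted by a factor of two or more.
R² alone therefore fails to flag exactly the nonlinearity (electrospray
saturation at the top of the range) that linear-range trimming exists to
remove; back-calculation accuracy — the working criterion of routine
calibration practice — catches it. Trimming is top-down only because
saturation is the dominant nonlinearity in ESI; the low end is already
guarded by LOD censoring. Fits need ≥ 3 points and a positive slope,
otherwise the compound–condition is skipped with a message.

## The model set and baselines

One random-forest regressor (500 trees) per polarity × pH condition
predicts log₁₀ RF from the descriptor vector. Hyperparameters — features
per split (3, 6, 9) and minimum leaf size (2, 5) — are chosen by 5-fold
cross-validation with a fixed seed; ties go to the first grid entry, so
training is fully deterministic. A plain random forest is used rather than
a regularized variant: with twelve descriptors the sparsification such
regularization buys is marginal, and determinism and simplicity improve.
Conditions with fewer than 10 training compounds are skipped loudly; the
threshold exists to fail fast on degenerate inputs, not as a statistical
claim.

Because forest predictions are averages of training responses, predicted
log RF can never leave the training range — predictions regress toward the
mean, and the largest errors are expected for compounds with extreme
response factors. This is a property of the method, verified in the test
suite, not an implementation accident.

Two baselines calibrate expectations:

* **Equal RF**: 10^(mean log₁₀ RF) of the training standards — the
  geometric mean response factor — assigned to every compound.
* **Closest-eluting standard**: the RF of the training standard with the
  nearest mean retention time; ties break toward the earlier-eluting
  standard (a deterministic, arbitrary choice). The package implements this
  per condition; in practice it is most meaningful in positive mode at
  pH 2.7, and the pipeline reports it per condition so that restriction can
  be applied downstream.

The simplified linear model regresses log₁₀ RF⁺(pH 8.0) on the pH 8.0 area
ratio for compounds detected in both modes (sentinels excluded, minimum 3
compounds). Permutation importance is the mean increase in training MSE
when one descriptor column is permuted (10 repeats by default, seeded).
Interpretive trees are depth-limited CART fits meant for inspection;
`max_depth = 0` degenerates to the training mean.

## Uncertainty propagation

Fold uncertainties combine as
`1 + sqrt(sum((f - 1)^2))`: each factor is converted to a relative
uncertainty u = f − 1, combined in quadrature per the law of propagation of
error for a product, and converted back. This formula is a reconstruction:
it was fixed by requiring it to reproduce two published worked values
(10 ⊕ 10 → ≈ 13.7, printed as "a factor of 14"; 10 ⊕ 1.2 → ≈ 10), and the
package's tests pin both. Its consequence — the larger uncertainty always
dominates — is why concentration predictions with order-of-magnitude errors
remain useful next to toxicity predictions of comparable uncertainty.

Note the convention: u = f − 1 treats a factor of 10 as 900 % relative
uncertainty on the multiplicative scale's natural parameterization. For
small factors (f ≲ 1.5) it agrees with the familiar percent reading.

## The synthetic-data generator

The generator exists so the full chain — calibration, featurization,
training, prediction, evaluation — can be exercised against known ground
truth. Per compound it draws three latent traits (lipophilicity, basicity,
acidity) and builds:

* **Response factors.** log₁₀ RF⁺ ~ Normal(15.5, 1.0); log₁₀ RF⁻ ~
  Normal(15.0, 0.7) with correlation 0.4 to the positive draw. With ~5
  standard deviations of spread at n = 200, positive-mode RFs span ≥ 4–6
  orders of magnitude, matching the span such experiments report
  (~10¹²–10¹⁷ M⁻¹). Basicity adds +0.3 log units per SD in positive mode,
  acidity likewise in negative mode. Response factors decline with pH
  (default 0.5 log units over the pH 2.7 → 10.0 span in positive mode),
  scaled per compound by a unit-mean log-normal multiplier (σ = 0.6):
  how strongly ionization responds to pH is compound-specific, which also
  keeps the three per-pH ratios from being perfectly collinear. The
  magnitude of the pH trend is a configuration knob, not a claim — no
  quantitative value is established for it.
* **The ratio–RF correlation.** Because the negative-mode draw is only
  partially coupled to the positive one, the pos/neg gap (equal to the
  noiseless pH 8.0 area-ratio descriptor) correlates with log RF⁺ with
  R² ≈ 0.5–0.7 under defaults — the empirical regime in which the
  simplified linear model is useful.
* **Retention.** RT = affine map of the lipophilicity quantile into
  1–19 min of a 20-min gradient, plus a pH-dependent shift of
  (basicity − acidity) × 1 min at pH 10: bases elute later once
  deprotonation stops at high pH, and such compounds carry higher
  positive-mode RFs via the basicity effect. Setting both RF trait effects
  to 0 decorrelates retention from response factor entirely (the regime
  where the closest-eluting baseline collapses).
* **Acquisition.** 40 % of compounds ionize in negative mode; stock
  concentrations are log-uniform in 1.7 × 10⁻⁶–2.4 × 10⁻⁵ M; dilution
  series default to 1, 2, 4, 20, 40 (training) and 1, 2, 10, 20, 100
  (test); areas are concentration × 10^log RF times log-normal noise
  (CV 10 %); realized areas below 10⁵ counts are censored to
  "not detected" (standing in for S/N- and intensity-based detection
  filters); retention times get 0.02 min jitter; 30 % of compounds show a
  sodium adduct at pH 2.7.

What the generator does **not** emulate: chromatographic peak shapes and
integration error, isotope patterns, matrix effects (suppression or
enhancement), adduct chemistry beyond a flag, correlated censoring between
modes, or inter-instrument variation. Passing tests on synthetic data
therefore demonstrate the correctness and internal consistency of the
pipeline and the qualitative method ordering — not field accuracy on real
extracts, which is bounded by peak integration quality and matrix effects.

## Numerical and evaluation conventions

* All logarithms are base 10; response factors live on the log₁₀ scale
  throughout ("orders of magnitude" is the working unit of this field).
* Fold error = max(c_pred/c_actual, c_actual/c_pred); summaries report the
  arithmetic mean, median, maximum, and the fraction strictly below a
  factor of 10, at the granularity of compound × concentration ×
  condition datapoints.
* Concentration ranges across conditions report min/median/max; the median
  of an even count is the arithmetic midpoint of the central pair (the
  standard order-statistic convention).
* Split-peak merging sums areas and averages retention times; groups of
  any size k ≥ 2 use the same rule, which conserves total area and is
  idempotent.
* CSV is the single interchange dialect: comma-separated, UTF-8, "."
  decimal mark, empty cell = not detected, numerics at 15 significant
  digits (round-trip stable), deterministic row and column order.
* Every random stage (simulation, fold assignment, forest fits,
  permutations) is seeded; pipelines with equal configuration and seed
  produce byte-identical outputs.

The test suite runs the end-to-end comparisons at 150 training and 50 test
compounds — large enough for stable method ordering, small enough to keep
the whole suite fast — and the brute-force oracle comparisons at ≤ 20
compounds over 1000 randomized trials.

## Limitations

Sodium-adduct behaviour is recorded per record but used per compound
("any at pH 2.7"); the per-dilution ratio rule discards dilutions detected
in only one mode; the closest-eluting baseline's retention-time comparison
uses each condition's own retention times rather than a reference
condition. Models are not transferable across instruments without
retraining, and concentration estimates inherit every upstream integration
error — on real data the area ratios, being the dominant descriptors, make
peak-integration quality the practical accuracy ceiling.
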