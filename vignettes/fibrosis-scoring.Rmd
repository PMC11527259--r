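---
title: "Quantifying dermal fibrosis in SSc biopsies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dermal fibrosis in SSc biopsies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroscore)
```

## The problem

Skin involvement in systemic sclerosis (SSc) is conventionally measured
with the modified Rodnan skin score (mRSS): a clinician palpates 17 body
sites, grades each 0 (normal) to 3 (hidebound), and sums them to a total
in 0–51. The mRSS is semi-quantitative, assesses only dermal thickness,
and is insensitive to the inflammation and vasculopathy that also
characterize SSc skin. An image-based alternative scores the biopsy
itself: patches sampled from the dermis of a trichrome-stained section are
converted to fixed-length quantitative image features (QIFs), a penalized
linear model maps patch features to mRSS, and the patch-mean prediction is
the biopsy's **Fibrosis Score**. This package implements that pipeline
end to end, together with a 16-parameter dermatopathology scoring schema,
rater-agreement statistics, mixed-effects change-per-week estimates, and
the ordinal-logistic association analyses that relate histology to both
scores.

Because no public imaging dataset accompanies this design, the package
ships a first-class synthetic-data module. A single latent fibrosis
severity in $[0, 1]$ drives, jointly, the mRSS, the dermal image texture
and the histology sheets — exactly the dependence structure the downstream
association analyses assume — so every stage of the pipeline can be
exercised, and its parameter recovery quantified, at desk scale.

## The model

For biopsy $b$ with patches $i = 1, \dots, n_b$ and QIF vectors
$x_{bi} \in \mathbb{R}^p$ (default $p = 4096$), the patch-level model is
penalized least squares with an L1 (lasso) penalty:

$$
\min_{\beta_0, \beta}\; \frac{1}{2N} \sum_{b,i}
  \left(y_b - \beta_0 - x_{bi}^\top \beta\right)^2
  + \lambda \lVert \beta \rVert_1,
$$

where $y_b$ is the biopsy's total mRSS (patch-level supervision: every
patch inherits its biopsy's label). The Fibrosis Score of a biopsy is the
arithmetic mean of its per-patch predictions; it is not clipped, its range
only approximates the 0–51 mRSS range. The penalty $\lambda$ is selected
from a fixed grid of 16 values logarithmically spaced between $10^{-5}$
(weak) and $10^{3}$ (strong). At the strong extreme every coefficient is
exactly zero and the model predicts the training-mean mRSS — the
intercept-only model.

Three choices in the fitting procedure are deliberate and worth stating:

* **Patient-grouped cross-validation.** Folds never split a subject, so
  within-patient correlation cannot leak between training and validation.
  With at most 15 subjects the scheme is leave-one-subject-out; beyond
  that, 5 seeded subject-grouped folds.
* **Biopsy-level selection loss.** Held-out patch predictions are averaged
  per biopsy *before* computing squared error, because the deliverable is
  the biopsy score, not the patch prediction. Ties on the CV curve break
  toward the stronger penalty (the sparser model).
* **Fold-internal standardization.** Features are standardized with
  training-fold means and standard deviations only; an L1 penalty is not
  scale-equivariant, and the 4,096 features are heterogeneous.

The solver is cyclic coordinate descent with warm starts along the
decreasing penalty path and active-set iteration, written in C++. Its
convergence criterion is the maximum absolute coefficient change per
sweep; model fitting defaults to `tol = 1e-4` (mRSS units), while unit
tests run the solver at `1e-12`, where it agrees with an independent
reference implementation to better than $10^{-6}$ on a small dense
problem.

## Feature backends

The pipeline's contract with the extractor is only "one fixed-length
finite vector per patch". Two backends realize it:

* `texture_backend()` — the default, fully offline and deterministic. A
  bank of 33 multiscale texture statistics per patch (channel moments,
  luminance quantiles and dark fractions, gradient statistics with an
  8-bin orientation histogram, isotropic and oriented band-pass energies
  at scales 2/4/8 px) is expanded to the target width by a fixed, seeded
  random linear projection with entries
  $\mathcal{N}(0, 1)/\sqrt{n_\text{base}}$. The projection preserves the
  $100 \times 4096$ QIF-matrix geometry of a CNN extractor so every
  downstream code path is identical, while keeping tests free of any
  downloaded weights. Band-pass and gradient statistics are computed on
  mean-centred luminance, so all contrast-type features are exactly zero
  on a constant patch.
* `onnx_cnn_backend()` — the interface to the original extractor, an
  AlexNet pretrained on ImageNet whose named fully-connected layer (4,096
  units) supplies the QIF vector. The model file must be provisioned
  locally; the function never attempts network access, and inference is
  delegated to a user-supplied runner so the package itself carries no
  runtime dependency. Which fully-connected layer to read is a required
  configuration field, not a guess — both have 4,096 outputs.

## The synthetic cohort

`simulate_cohort()` draws, per subject, a baseline severity uniform on
0.3–0.8 (the diffuse-cutaneous range, mRSS roughly 15–40) and a linear
trajectory whose slope is the configured mean drift per week plus a
subject-level random effect (SD 0.0015/week). Site scores are generated
by thresholding: site $s$ becomes involved as severity crosses
$[(s-1)/17,\; s/17]$, and its latent value plus Gaussian noise
(`noise_sd_mrss`, default 0.25) is rounded and clamped into 0–3. Because
the 17 windows tile $[0,1]$, the noise-free total is exactly
$\mathrm{round}(51 \cdot \text{severity})$, monotone in severity, 0 at
severity 0 and 51 at severity 1.

`render_biopsy()` produces a layered trichrome-like raster: background
margin, dark epidermal band, collagen-rich dermis (58 % of the raster;
about two-thirds of the tissue), pale subcutis. Fibrosis appears as
near-horizontal wavy collagen streaks. The full streak geometry is drawn
up front from the seed; severity selects how many streaks are inked
(25–320) and how darkly (blend weight 0.25–0.9), so a higher severity
strictly adds ink at fixed seed. The companion statistic
`dermal_texture_stat()` — mean darkening of dermis pixels below the
renderer's ground luminance 0.77 — is therefore strictly increasing in
severity, which the tests verify by rank correlation over 50 renders.
Pixels are quantized to 8-bit levels so TIFF round trips are lossless.
The default geometry is 2048×2048 px at 1 µm/px, which holds well over
one hundred disjoint 0.16 mm² patches; tests and the acceptance script
render 1024 px at 2 µm/px (patch area unchanged: 200 px side) to keep
runs fast — a scale choice of this package, stated here once.

What the generator does **not** emulate: stain chemistry and
deconvolution, nuclei and cellular detail, scanner artefacts, staining
batch effects, oblique sectioning, and any non-trichrome stain. Passing
tests therefore demonstrate that the pipeline recovers a signal that is
present and monotone in the dermal texture; they cannot certify
performance on real slides.

`simulate_score_sheets()` draws a generative "truth" sheet at the
subject's severity — binary parameter probabilities interpolate 0.08 to
0.92 on the logit scale; ordinal scores threshold severity; epidermal
thickness falls with severity (75 to 50 µm, atrophy); perivascular CD3+
counts are Poisson with severity-increasing mean, CD8+ binomial within
them. The distributional detail of every histologic parameter is a
convention of this module: no such detail is published, and these choices
are tuned only for plausibility and monotonicity. Each of two raters then
copies each truth value with probability `rater_agreement`, else redraws
the parameter from its severity-free population marginal (the value the
generator would produce at a fresh uniform severity). The severity-free
redraw matters: it makes fully disagreeing raters statistically
independent, so empirical kappa converges to 0 at `rater_agreement = 0`,
while a severity-conditional redraw would leave raters correlated through
the biopsy. The truth sheet is fixed per biopsy, and only the rater draws
vary across assessment rounds, so intra-rater repeats re-score the same
slide. The realized copy indicators are recorded on each sheet pair, which
is how the tests verify the realized agreement rate against the parameter.

## Histology statistics

The 16-parameter schema has eight yes/no parameters, four ordinal
parameters scored against a standard image set (range 0–3 by default;
standard image sets are constructed per study by pathologist consensus,
so the bound is a configurable convention), mean epidermal thickness (mean of exactly
five site measurements, in µm), and three perivascular lymphocyte
parameters. Inter- and intra-rater agreement uses unweighted Cohen's
kappa for binary and ordinal parameters (weighted kappa would be a
defensible alternative for the ordinal ones; plain kappa is what the
interpretation bands below are defined for). Continuous parameters are
excluded from kappa and summarized by mean absolute difference between
raters. Kappa bands: ≤ 0 no agreement, 0.01–0.20 none-to-slight,
0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–1.00
almost perfect; since the bands are defined on two-decimal values, kappa
is rounded half-up to two decimals before banding so the mapping is total
(0.205 → 0.21 → fair).

Change per week fits `value ~ week` with independent (diagonal) random
intercept and slope per participant, by maximum likelihood via lme4; the
reported quantity is the fixed-effect week coefficient with a Wald
p-value. Zero-variance inputs short-circuit to slope 0, and designs too
sparse for the random slope fall back to an OLS slope, flagged in the
result's `method` field.

Associations enter each histologic parameter as the *outcome* of a
proportional-odds (ordinal logistic) model with one continuous exposure —
total mRSS or Fibrosis Score — and report the odds ratio per 1-unit
exposure change with a Wald 95 % CI. A two-level outcome reduces exactly
to ordinary logistic regression, which the tests pin to the 2×2
cross-product ratio and to an independent Newton-oracle MLE. Count and
percent parameters with more than 12 distinct values are binned into
decile categories before the ordinal fit — many-level ordered factors
make the cutpoint likelihood unstable at these sample sizes. Rater
consensus is explicit and configurable: binary "yes" iff both raters said
yes (default), ordinal and continuous values averaged. Complete
separation yields a flagged infinite-OR sentinel with a warning rather
than an error; single-level parameters are skipped and listed. No
multiple-testing correction is applied, and the output annotates this
together with the 0.05 threshold — the analysis is exploratory by design.

One design note: "change per 1-unit exposure" could be modelled on
visit-level observations or on within-subject 0–52-week deltas. This
package models visit-level observations, the reading consistent with
entering the exposure as a continuous covariate.

## Reproducibility machinery

Every stochastic component draws from a sub-stream derived from one
master seed by a platform-independent 31-bit polynomial hash of
`(seed, subject, week, purpose)` labels — inserting or removing a subject
never shifts another subject's draws, and biopsy rendering, patch
sampling, sheet simulation and CV fold assignment are all independently
replayable. `run_pipeline()` executes all stages from one validated
`run_config()`, stamps every artifact set with the MD5 of the serialized
configuration (output paths excluded — the run directory is ambient, not
scientific), and writes a manifest of per-artifact hashes; reruns at a
fixed seed are byte-identical, which both the tests and the acceptance
script verify by hashing two independent runs.

Degenerate inputs are handled explicitly rather than accidentally:
constant mRSS aborts the fit; a dermis-free mask aborts sampling; fewer
eligible patch positions than requested falls back to sampling with
replacement under a warning; kappa with expected agreement 1 is an error
(undefined), while a missing rater or single-level parameter is marked
not assessable; Spearman correlation on a constant vector is an error.

## Problem sizes used by tests and acceptance

Structural checks run on one 1024 px biopsy at 2 µm/px (100 patches,
4,096 features). End-to-end recovery uses 30 subjects, one biopsy each,
100 patches per biopsy, and a 128-wide texture projection; with noise-free
mRSS the held-out (patient-grouped) Spearman correlation between Fibrosis
Score and mRSS is ≈ 0.99 against an acceptance floor of 0.7. Mixed-model
recovery uses 50 subjects at weeks 0/24/52 with a true slope of −0.05.
Calibration uses a single n = 1000 null ordinal fit plus 1,000 null
replicates at n = 200 for the empirical type-I error. These sizes are the
package's chosen desk scale; all defaults remain at the full geometry.

## Known limitations

* The texture backend is a linear projection of 33 base statistics: its
  4,096 features have rank 33. That is sufficient for the geometry and
  for severity recovery, but it does not emulate the feature diversity of
  a CNN, and the lasso's selected support among projected features is not
  interpretable the way CNN channels might be.
* The synthetic severity signal is strong by construction; the ≈ 0.99
  held-out correlation says the plumbing is correct, not that real
  biopsies would score this well.
* Proportional odds is assumed, not tested, for ordinal outcomes, and
  Wald intervals are used throughout (no profile likelihood).
* The intra-rater design supports exactly two assessment rounds, matching
  the two-time-point re-scoring design it models.
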