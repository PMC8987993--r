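---
title: "Brain-age modeling and normative deviance profiling with brainpad"
author: "brainpad maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age modeling and normative deviance profiling with brainpad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis in one paragraph

brainpad implements a multimodal brain-age analysis for parkinsonian
disorders. Two regional MRI feature panels — 124 gray-matter features (56
regional volumes, 68 cortical thicknesses) and 90 white-matter features
(generalized fractional anisotropy and mean diffusivity averaged over 45
fiber tracts) — each feed a modality-specific brain-age model. The model's
prediction error on an individual, the predicted age difference
(PAD = predicted − chronological age), is corrected for its spurious
age trend and compared across groups (healthy controls, Parkinson's
disease, multiple system atrophy) by ANCOVA with age, sex and education
as covariates. In parallel, per-feature Gaussian-process normative models
convert each regional feature into a standardized deviance Z-score, and a
robust MM-regression of PAD on each feature's Z-score scores how strongly
that region contributes to the brain-age gap in each group. Features whose
contribution differs between groups by more than a medium effect size
(|ΔES| > 0.3) are flagged as markedly different.

Because clinical MRI cohorts of this kind are not publicly deposited, the
package ships a first-class synthetic cohort generator with known ground
truth. Every stage of the pipeline is validated against that ground truth
or against independent brute-force oracles.

# The synthetic cohort generator

The generator is the package's study bench: its defaults define the
conditions under which all end-to-end claims are tested.

Each feature $f$ follows a trajectory

$$\mu_f(a, s) = \beta_{0f} + \beta_{1f}(a - 45) + \beta_{2f}(a - 45)^2
  + \beta_{sf}\, s,$$

with $a$ age in years, $s$ sex (female = 0, male = 1), and additive
Gaussian noise of SD $\sigma_f$. Default signs follow biology: volumes,
thicknesses and GFA decline with age; MD rises. Baselines vary
deterministically across regions within physiological ranges (volumes
6–22 mL for cortical gyri with larger values for cerebellum and
brainstem; thickness 2.2–2.9 mm declining 4 µm/year; GFA 0.35–0.55; MD
0.70–0.85 ×10⁻³ mm²/s). Noise SDs (5% of baseline for volumes, 0.08 mm,
0.015, 0.025 respectively) were chosen once so that the pooled
feature panel carries an age signal resolvable to roughly ±2 years —
the performance regime a practitioner expects of regional-feature brain
age models. The reference population draws ages from a truncated normal
(mean 36.9, SD 19.1, range 14–92) with 46.9% males, matching the
demographics typical of lifespan training sets.

A clinical cohort adds three ground-truth mechanisms:

* **Brain-age offset.** Every feature is evaluated at the *effective age*
  $a_i + \delta_i$ with $\delta_i = \text{pad\_shift} + N(0,
  \text{jitter}^2)$ (jitter SD 2 years by default). This makes "true PAD"
  well defined: a perfect pipeline recovers the injected shift. Default
  shifts are 0 (HC-like), 1.5 (PD-like) and 9 years (MSA-like), the
  qualitative pattern reported for these diseases.
* **Focal deviance.** Named features can be shifted by a stated number of
  their own noise SDs, giving known targets for the normative models.
* **Clinical-score coupling.** Severity scores (UPDRS, UMSARS, H&Y) load
  linearly on the realized offset with correlation 0.4 by default;
  cognitive scores (MMSE, MoCA) couple negatively at −0.3. Group-level
  score means and SDs follow typical clinic cohorts.

What the generator does *not* emulate: spatial covariance between regions
(residuals are independent), non-Gaussian feature noise, scanner or site
effects, and disease-specific *patterns* of regional atrophy beyond the
explicitly injected deviances. Passing tests therefore demonstrate that
the estimators recover what they claim to estimate under a well-specified
generative model — not that the pipeline is robust to every pathology of
real imaging data.

# The cascade brain-age network

The regressor is a 12-layer cascade feed-forward network: hidden layer
$k$ receives the raw standardized inputs concatenated with all previous
layers' outputs, and the single linear output unit again receives the raw
inputs. Width 16 and tanh activations by default; sex enters as an
additional input. Because of the input-to-output skip path the network
contains an exact linear model as a special case — trained on noiseless
linear data it reaches held-out MAE below half a year, which is the
capacity sanity check in the test suite.

Training minimizes mean squared error by full-batch Adam (base learning
rate 0.01, cosine-decayed), with early stopping on a 10% validation split
(patience 200 epochs, cap 1500) and an L2 penalty (10⁻³) on the hidden
weights and the hidden part of the output weights. The skip connections,
biases and output bias are never penalized, so the penalty biases the
optimizer toward the linear solution rather than shrinking the prediction
itself; empirically this closes the train/held-out gap on near-linear
problems and slightly improves held-out MAE on the default generator.
Inputs are standardized to training mean/SD (stored in the model); the
age target is standardized internally and predictions are returned in
years. The weight-initialization seed and validation split are governed
by one explicit seed, so training is bit-reproducible.

Performance is quantified by 10-fold cross-validation (seeded random
permutation, fold sizes within one of each other) reporting pooled
Pearson r and MAE over the concatenated out-of-fold predictions.

# PAD and the age-bias correction

Uncorrected PAD shows a spurious negative trend on age
(regression-to-the-mean of the prediction). Following the standard linear
correction, PAD is regressed on age in a designated reference sample and
the fitted line subtracted:

$$\text{PAD}^{c}_i = \text{PAD}_i - (\hat a\, \text{age}_i + \hat b).$$

The package fits the correction on the healthy-control group of the
application cohort (configurable). On the reference sample itself the
corrected scores are exactly orthogonal to age; on an independent sample
from the same population the residual slope is zero within sampling
error. The reference group's mean corrected PAD is exactly zero by
construction, which is why group contrasts are read as differences from
the control group.

# Gaussian-process normative models

One GP regression per feature is fitted on the reference population with
inputs (age, sex) and kernel

$$k = \sigma_f^2 \exp\!\Big({-\tfrac12\big[(\Delta a/\ell_a)^2 +
(\Delta s/\ell_s)^2\big]}\Big) + \sigma_l^2\, a\, a' + \sigma_n^2
\delta_{ij},$$

on standardized age and target scales: a smooth nonlinear age term (with
its own length-scale for the binary sex dimension), a linear age term
carrying the dominant trend, and white noise. Sex as an input dimension
was preferred over separate per-sex models because it shares the age
trend across sexes where the data support it; with the generator's
additive sex offsets both parameterizations are equivalent and the input
encoding halves the number of models.

Hyperparameters maximize the exact log marginal likelihood
(analytic gradients, L-BFGS-B, box constraints on the log scale) from 3
seeded restarts. Three restarts rather than a larger number: with
gradients and a 5-parameter space, restarts beyond the first jittered
pair never changed the selected optimum on the generator's feature
families. To cap the cubic cost, hyperparameters are optimized on a
seeded subsample of at most 300 reference points while the exact
posterior conditions on the full reference sample — the predictive
equations are unchanged; only the hyperparameter search is subsampled.
Because the subsampled fit estimates the noise scale with a few percent
of error, the predictive SD is then recalibrated so that the full
reference sample's leave-one-out standardized residuals have unit SD
(computed from the GP LOO identities
$\mu_{-i} = y_i - \alpha_i / [K^{-1}]_{ii}$,
$\sigma^2_{-i} = 1/[K^{-1}]_{ii}$) — the ex-post variance calibration
step common in normative modeling. Recalibration is skipped when
hyperparameters are supplied by hand, so closed-form posterior
comparisons remain exact.

The deviance score is $Z = (y - \mu_*)/\sigma_*$ where $\sigma_*$
**includes the noise variance** — the norm for a *new observation*. This
is what makes held-out reference Z-scores approximately standard normal;
omitting the noise term would inflate |Z| by the noise-to-signal ratio.
Degenerate (zero-variance) targets are flagged rather than fitted;
queries outside the training age range are answered but flagged as
extrapolations.

Calibration is verified at study sizes chosen so the check's own
sampling noise sits well inside the acceptance bands (fit n = 2000,
held-out n = 4000 for the per-feature mean ∈ [−0.1, 0.1] and
SD ∈ [0.9, 1.1] bands; with these sizes the per-feature sampling SD of
the mean is ≈ 0.027). Focal-deviance recovery (+2σ injected, mean Z in
[1.6, 2.4] at n = 200) runs against the same fitted set.

# Robust contribution profiles

The contribution of a feature to brain age in a group is the association
between its Z-score and the corrected PAD, estimated robustly: both
variables are standardized by median/MAD, and the effect size is the
slope of an MM-regression (50%-breakdown S-estimate of scale, then a
redescending bisquare M-step with tuning constant 3.44, ≈85% efficiency
at the normal) of standardized PAD on standardized Z, clipped to [−1, 1].
The slope convention was chosen over a robust correlation coefficient
because it is the direct MM analogue of the standardized regression
coefficient; on exactly linear data it saturates at ±1, and under 10%
gross contamination it moves by less than 0.15 where plain Pearson moves
by more than 0.3 (verified over 20 seeds). Exactly collinear inputs are
detected first (the robust scale is zero there and iterative
reweighting is undefined) and scored ±1 directly; zero-MAD inputs are
flagged degenerate. The S-stage subsampling is seeded, making profiles
reproducible.

Features are ranked by |ES| (ties broken lexicographically, documented
and deterministic), the top 20 reported per group, and the between-group
difference ΔES = ES_A − ES_B flagged when |ΔES| > 0.3 — the conventional
medium effect-size difference. Regional aggregation reports
100·Σ|ES| per lobe (or fiber system, or hemisphere) normalized within
each feature type, summing to 100 by construction.

# Group statistics

* **ANCOVA**: omnibus F for the group factor from nested linear models
  (group dummies + covariates vs covariates only); with 3 groups, n
  participants and k covariates, df = (2, n − 3 − k). Post-hoc contrasts
  are pairwise two-group ANCOVAs with the same covariates,
  Benjamini–Hochberg-adjusted across the three pairs. When the covariates
  already explain the response exactly, the group F is defined as 0
  rather than 0/0.
* **Partial correlation** between GM-PAD and WM-PAD per group: Pearson
  correlation of OLS residuals on the covariates, p from t with
  n − 2 − k df.
* **Comparison of correlations**: independent-sample Fisher r-to-z with
  SE = √(1/(n₁−3) + 1/(n₂−3)). This choice is validated against
  published worked examples: (ρ=0.409, n=33) vs (ρ=−0.013, n=34) gives
  p = 0.081 and (0.074, 23) vs (0.409, 33) gives p = 0.212.
* **Clinical associations**: partial correlations of PAD with each
  clinical score, pairwise deletion of missing values with the retained
  n reported, entirely-missing scores flagged rather than dropped.
* **Outlier re-analysis**: per-group exclusion of the stated number of
  lowest values (stable first-occurrence tie-breaks), then the ANCOVA is
  rerun on the mask; excluding 2+3+2 of 90 leaves df = (2, 77).

# Numerical choices and degenerate inputs

* Constant features carry no information: their standardization scale is
  set to 1 (not 0) in the brain-age model, and normative fits flag them
  degenerate instead of inverting a singular kernel.
* GP kernels are built with a noise floor (σ² ≥ 10⁻⁵ on the standardized
  scale) and Cholesky failures during hyperparameter search score as +∞
  rather than aborting the fit.
* Predictive variances are clamped at 10⁻¹² before square roots.
* All "identical seed ⇒ identical output" guarantees use isolated RNG
  state (`withr::with_seed`), so library calls never perturb the caller's
  RNG.
* File round-trips write full-precision doubles; readers name the exact
  row and column of the first malformed cell.

# Problem sizes used by the validation suite

Unit tests run on reduced panels and small cohorts; the end-to-end
claims use a 500-participant training population (the default study
condition), clinical groups of 200 for recovery checks, a 2000/4000
fit/held-out split for normative calibration, and 20 contamination seeds
for the robustness property. The acceptance script runs the full default
pipeline (train 500; HC/PD/MSA of 34/33/23; 10-fold CV) and reports its
computed quantities as JSON.

# Known limitations

* The generator's independence across regional residuals understates the
  collinearity of real morphometry; contribution profiles on real data
  would show more shared variance across neighboring regions.
* The cascade architecture's layer widths, activation and optimizer are
  package choices; the original architecture family is reported only at
  the level of "12-layer cascade feed-forward", so no claim is made of
  weight-level equivalence.
* The MM effect size is one of several defensible operationalizations of
  "robust correlation"; the slope-on-standardized-variables convention is
  documented and configurable (tuning constant, iteration caps, seed).
* Whether normative models should be stratified by sex rather than take
  sex as an input is not settled; the package exposes the input-encoding
  variant only.
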