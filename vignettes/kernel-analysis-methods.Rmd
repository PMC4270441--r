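---
title: "Methods: kernel analysis and noise-matched representation comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel analysis and noise-matched representation comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelrep)
```

This vignette is the package's account of its methods: the estimators, the
assumptions behind them, the numerical conventions, and the design choices
that were genuinely open. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The problem

A population of recording sites in high-level visual cortex and a layer of
an artificial network both assign each image a feature vector. Asking which
representation "solves the task better" is confounded twice. First, any
decoder applied to the two representations has a complexity knob, and two
representations can trade places as that knob moves. Second, the neural
measurement is degraded by trial-to-trial noise and by finite sampling of
sites and repetitions, so a raw comparison is biased against it. The package
measures decoding performance *as a function of* decoder complexity, and
moves the noise handicap onto the model side instead of pretending to remove
it from the neural side.

## Kernel analysis

For a representation $X \in \mathbb{R}^{n \times d}$ over $n$ images and a
Gaussian kernel $K_{ij} = \exp(-\lVert x_i - x_j\rVert^2 / 2\sigma^2)$,
kernel ridge regression of a label vector $y$ solves
$\alpha = (K + \lambda I)^{-1} y$. The leave-one-out residual at example $i$
— the error a model refit without $i$ makes at $i$ — is available in closed
form,
$$ r_i = \frac{\alpha_i}{[(K+\lambda I)^{-1}]_{ii}}, $$
so one eigendecomposition $K = Q \Lambda Q^\top$ yields exact leave-one-out
errors for *every* $\lambda$ on the grid at negligible marginal cost:
$(K+\lambda I)^{-1}$ has eigenvalues $1/(\lambda_k + \lambda)$ on the same
eigenvectors. The test suite verifies the closed form against explicit
refit-without-$i$ training to $10^{-8}$ on random problems.

**Multiclass extension and label normalization.** Categories enter
one-vs-all: for each of the $C$ categories an indicator vector is regressed
on the kernel, its mean-squared leave-one-out error is divided by the mean
square of that label vector, and the normalized errors are averaged over
categories; *precision* is one minus the average. The indicators are
**centered** (indicator minus its mean). This was a genuinely open choice:
with raw $\{0,1\}$ indicators the ridge shrinks predictions toward zero
while an uninformative representation's best achievable prediction is the
base rate $1/C$, so representations with *no* category information would
plateau at precision $\approx 1/C$ rather than $0$. With centered labels
the zero predictor and the base-rate predictor coincide, so precision is
exactly $0$ for the zero predictor, exactly $1$ for perfect prediction, and
$\approx 0$ for any representation carrying no category signal — the
behavior the method is meant to have. Precision can go below zero when a
(low-$\lambda$) fit generalizes worse than predicting the mean; it can never
exceed 1.

**Complexity, bandwidth scan, and AUC.** Complexity is $1/\lambda$.
Defaults: 56 penalties log-spaced on $[10^{-6}, 10^{3}]$ and 32 bandwidths
$\sigma = f\,\sigma_{\mathrm{med}}$ with $f$ log-spaced on $[1/8, 8]$,
where $\sigma_{\mathrm{med}}$ is the median pairwise distance of the
evaluated subset (the median heuristic). At each $\lambda$ the bandwidth
minimizing the leave-one-out error is chosen; because a large $\sigma$ is
itself a regularizer, curves plateau at high complexity instead of
collapsing. The KA-AUC is the trapezoidal area of precision over
$\log_{10}$ complexity divided by the span of that axis, so a constant
curve at precision $p$ has AUC exactly $p$ and the AUC reads as a mean
precision. Both grids are configurable; the normalized quadrature is a
package convention.

**Image resampling.** Curves are recomputed over image subsets drawn once
per seed and shared across all representations: $\lfloor 0.8\,n/C \rfloor$
images per category, *without* replacement. Sampling with replacement is
available (`replace = TRUE`) but is not the default, deliberately: a
duplicated image makes its own leave-one-out prediction trivial (its twin
stays in the training set), and with 80% resampling roughly a third of
examples are duplicates — enough to push a pure-noise representation from
precision $\approx 0$ to a substantially positive AUC. Balanced
subsampling preserves the intent (spread due to image-set sampling, equal
category counts) without corrupting the leave-one-out statistic.

## The experimental noise model

Trial-structured responses (sites × images × trials) are first reduced the
way multi-electrode recordings usually are: spike counts in a fixed window,
background (blank-screen) rate subtracted, each site divided by the standard
deviation of its responses, then averaged over repetitions
(`preprocess_trials()`). The per-site scale is computed over all images and
trials unless a block structure is supplied — block boundaries are an
acquisition detail the package cannot reconstruct, and the global scale
preserves the intent of equalizing site variances.

The noise model itself assumes spike-count-like variability: across-trial
variance linear in the across-trial mean, $\mathrm{var} = a\,\mu + b$
(Poisson gives $a = 1, b = 0$). After centering the whole tensor by its
grand mean and scaling it to unit population variance, the package fits the
variance-on-mean line per site and averages coefficients over sites with
equal weight. Two estimator details matter:

* **Attenuation correction.** The regressor is the *estimated* trial mean,
  whose sampling variance is $\mathrm{var}/T$. Plain least squares is
  therefore attenuated — slope biased toward zero and intercept inflated by
  $a\,\bar\mu\,(1-\kappa)$, an effect large enough to matter at realistic
  $T$. Since the error variance of the mean is known ($\overline{v}/T$),
  the standard errors-in-variables moment correction applies: the
  denominator $\widehat{\mathrm{var}}(m)$ is debiased by
  $\overline{v}/T$. For Gaussian trial noise the corrected estimator is
  unbiased; `correct_attenuation = FALSE` restores plain least squares.
* **Sites with constant mean response** across images leave the slope
  unidentified and are excluded with a warning.

**Signal/noise decomposition.** The observed variance of the *trial-averaged*
responses decomposes as signal plus the standard error of the mean:
$\sigma^2_{\mathrm{total}} = \sigma^2_{\mathrm{signal}} +
\sigma^2_{\mathrm{noise}}$ with $\sigma^2_{\mathrm{noise}} =
\overline{\max(0, a\mu + b)}/T$. The package computes
$\sigma^2_{\mathrm{total}}$ from the averaged responses — not from the
single-trial tensor, whose variance is 1 by construction after
normalization. This distinction is load-bearing: crediting the
representation with the single-trial variance would inflate
$\sigma^2_{\mathrm{signal}}$ exactly when trial noise dominates, making the
injected noise too weak at small $T$ and breaking the conservativeness
property below. The signal share is always computed at the tensor's own
trial count; the injected noise is scaled by the target $T$, so a smaller
$T$ emulates a stingier recording of the same signal.

**Noise matching a model.** A model representation is subsampled to the
neural site count (80 for multi-unit-matched, 40 for single-unit-matched
comparisons), centered and globally rescaled to $\sigma^2_{\mathrm{signal}}$
(a single multiplier, so all pairwise distance ratios are preserved), and
each entry receives independent Gaussian noise of variance
$\max(0, a\,\mathrm{value} + b)/T$. Negative predicted variances — possible
at strongly negative normalized responses, about which the mean-variance
line says nothing reliable — are clipped to zero. The noise draw is
repeated (default 10×) with the feature subsample held fixed, so the spread
over repeats isolates the injected noise; `resample_features = TRUE` also
redraws the subsample. The post-injection total variance matches
$\sigma^2_{\mathrm{total}}$ of the averaged neural sample (the test suite
checks within 5%).

**Conservativeness.** Injected noise rides on top of the trial-averaged
responses, which still carry their own residual averaging noise
($\propto 1/T_{\mathrm{own}}$), so injection at trial count $T$ degrades a
representation at least as much as actually averaging only $T$ real trials.
The acceptance suite verifies this paired comparison across
$T \in \{2, 6, 12, 47\}$ on synthetic data.

## Decoding, encoding, and representational similarity

**Linear-SVM decoding** is the confirmatory analysis: stratified 80/20
train/test splits (stratification keeps chance exactly $1/C$), shared
across representations, with the SVM cost chosen per split by internal
k-fold cross-validation on the training rows only. The multiclass scheme
is one-vs-all by default (classify by the largest decision value), with the
libsvm native one-vs-one available; the choice was open, and one-vs-all
mirrors the regression-side convention.

**Ridge encoding models** predict each site's trial-averaged response from
a model representation. All sites and all candidate penalties share one
SVD of the centered training matrix; each site's penalty minimizes
generalized cross-validation on the training rows. Prediction quality on
held-out images is normalized by the site's own reliability:
$100\, r_{\mathrm{pred}}^2 / r_{\mathrm{ceiling}}^2$ percent of explained
*explainable* variance, with the ceiling the Spearman-Brown corrected
($2r/(1+r)$) split-half consistency over trials. Whether the raw metric
should be $r$ or $r^2$ was open; the ratio-of-$r^2$ convention is used
because the quantity reported is a percentage of variance, and both $r$
values are exposed for anyone preferring the other convention. Values can
exceed 100 by sampling error and are flagged, not clipped. Sites with a
non-positive ceiling are excluded with a warning.

**RDMs.** Object-level representational dissimilarity matrices average each
object's images and take $1 - $ Pearson correlation between object vectors
(49 × 49 for the default task). Two RDMs are compared by Spearman rank
correlation of the 1176 strictly-upper-triangle entries, making the
comparison invariant to monotone transforms. Correlation distance is
exactly invariant to global scalings, to per-object additive shifts, and to
rotations that preserve row means (e.g. any orthogonal map fixing the
all-ones direction); under fully general rotations it is invariant only up
to the row-centering term, which is small in high dimension — the tests
assert exact invariance for the structure-preserving class and near
invariance for general rotations. Split-half site consistency (random
disjoint halves of the sites, RDMs on held-out images, default 50 groupings
× 10 image splits) provides the noise ceiling. "+IT-fit" representations
rebuild the geometry from cross-validated encoding predictions: per
object-stratified split, encoding models fitted on 80% of images predict
all sites on the held-out 20%, and the RDM is computed from those held-out
predictions only — fit images never enter the RDM, and the same held-out
image sets are used for every representation.

## The synthetic generator

The generator emulates the statistical structure the analyses assume, not
images: a stimulus table of 7 categories × 7 object exemplars × 40
variation draws (1960 images; position, two octaves of scale, full-sphere
pose, unique background seed); latent image vectors composed of category
centroid + object offset + image-level nuisance with configurable
variances; site responses as fixed nonnegative mixtures of the latent
dimensions around a baseline rate; and Gaussian trial noise with variance
$a\,\mu + b$, clipped at zero, plus a positive blank rate so background
subtraction is exercised. Gaussian noise with a linear mean-variance law —
rather than true Poisson counts — makes the estimation pipeline exactly
well-specified; a `poisson = TRUE` option exists for robustness checks.
Multi-unit pooling sums disjoint random groups of single-unit sites per
trial, which raises reliability because signals add coherently while noise
adds in quadrature.

Default signal variances are category 1, object 1, nuisance 2: image-level
variation dominates, as it must for an invariant-recognition task to be
hard, while category structure remains recoverable. Defaults for the
recording side are 168 sites, 47 trials, Poisson-like noise ($a=1$, $b=0$),
baseline 5 and blank 0.5 counts per window, evoked standard deviation 2.
Because object exemplars are nested inside categories, a representation
with zero *category* variance but positive *object* variance still supports
categorization; the fully null control sets both to zero.

What passing tests on these data do **not** show: robustness to correlated
(site × site) noise, to non-Poisson-like variance laws, to temporal
structure within the response window, or to the contextual statistics of
natural images — none of which the generator models (correlated noise and
non-Gaussian families are explicit non-goals).

## Numerical conventions and degenerate inputs

* Kernel eigenvalues are clipped at zero before inversion; $K$ must be
  symmetric and $\lambda > 0$.
* The median heuristic errors on a representation whose rows all coincide
  (zero median distance); `kernel_analysis()` rejects such degenerate
  inputs up front.
* Consistency of a site with constant responses is reported as `NA`, never
  silently 0; top-k site selection ignores `NA` sites and breaks ties
  toward the lower site index, making selection deterministic.
* All stochastic steps (subsets, splits, noise draws, subsampling) take
  explicit seeds, restore the caller's RNG state, and reproduce bit-for-bit
  under the same seed. Shared subsets/splits are generated once and passed
  to every representation.
* Variances used in scaling are population (1/n) moments, so round-trip
  identities hold exactly.
* Single units are screened for consistency on a separate image set when
  one is supplied; by default the evaluation set is used, which mildly
  favors the selected sites — a flag worth remembering when comparing
  absolute single-unit numbers.

## Problem sizes

Structural checks (stimulus table, RDM dimensions) run at the full
1960-image scale, where they are cheap. The simulation-based suites run at
deliberately reduced scale — 7-category tasks with 2–3 exemplars and 6–10
images per object, 30–80 sites, 8–12 bandwidths and 12–20 penalties —
chosen so each property is measured well away from its decision boundary
while the whole suite stays fast; noise-model recovery uses 500 images,
50 trials and 400 sites, the site count providing the averaging needed for
tight (±10%) coefficient recovery. The defaults of every exported function
remain at the full study scale.

## Known limitations

* The noise model is independent across sites and entries; correlated
  variability, which can matter for population decoding, is out of scope.
* The mean-variance line is extrapolated to model feature values where the
  neural data provide no support; clipping at zero variance is a pragmatic
  guard, not a model.
* Kernel analysis at $n$ images costs one $n \times n$ eigendecomposition
  per bandwidth per subset; beyond a few thousand images the cost grows
  cubically.
* The SVM cost grid and the ridge GCV grid are finite log grids; pathological
  scalings outside them require widening the grids explicitly.
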