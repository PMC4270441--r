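# kernelrep

Comparing the object-recognition performance of a neural population to that
of a model feature space is harder than it looks: the neural side is
penalized by trial-to-trial noise, a finite number of recording sites, and a
finite number of stimulus repetitions, while the model side hides an extra
free parameter — the complexity of the decoder used to read categories out
of it. `kernelrep` implements a comparison methodology that addresses both
problems, for anyone benchmarking representations (cortical recordings,
deep-network layers, hand-crafted features) on invariant object
categorization tasks.

## What it computes

**Kernel analysis.** A representation `X` (images × features) is evaluated
by Gaussian-kernel ridge regression of category labels. For the kernel
`K_ij = exp(-||x_i - x_j||² / 2σ²)` and penalty λ, the fitted coefficients
are `α = (K + λI)⁻¹ y`, and the leave-one-out residual at example *i* has
the closed form

```
r_i = α_i / [(K + λI)⁻¹]_ii
```

so the full leave-one-out error costs one eigendecomposition per kernel
instead of *n* refits. Categories are handled one-vs-all with centered
indicator labels; the mean-squared leave-one-out error is normalized so the
zero predictor scores exactly 0 and perfect prediction exactly 1
(**precision**). Sweeping λ over a log grid — with σ re-optimized at every λ
around the median pairwise distance — traces precision against **complexity**
`1/λ`; the normalized area under that curve (**KA-AUC**) summarizes the
representation. Curves are resampled over category-balanced image subsets
shared across representations.

**Noise matching.** From trial-structured recordings (sites × images ×
trials) the package estimates a Poisson-like noise model, `var = a·mean + b`
per site (coefficients averaged over sites, with an errors-in-variables
correction for the sampling noise of the trial mean). Model features are
subsampled to the neural site count, rescaled to the estimated signal
variance, and corrupted with zero-mean Gaussian noise of variance
`max(0, a·value + b)/T` — the standard error of a T-trial average — so the
model is measured under the neural recording's handicap. Neural
representations are never injected with noise.

**Confirmatory and encoding analyses.** Cross-validated linear-SVM decoding
(chance = 1/7 ≈ 14.3% for the default 7-way task); ridge encoding models
predicting each site's response with per-site penalties chosen by GCV on
training images only, scored as percent explained *explainable* variance
(prediction r² over the Spearman-Brown-corrected split-half ceiling);
object-level representational dissimilarity matrices (1 − Pearson r between
object-averaged features, 49 × 49 for the default task) compared by Spearman
correlation of their upper triangles, with split-half noise ceilings and
"+IT-fit" representations built from held-out encoding-model predictions.

**Synthetic data.** A generator reproduces the study structure end to end —
7 categories × 7 object exemplars × 40 images (1960 stimuli), latent
category/object/nuisance components, trial noise with variance linear in
the mean, background rates, and multi-unit pooling — so every stage of the
pipeline is testable without any recordings.

## Worked example

```r
library(kernelrep)

# synthetic study: 7 categories x 3 exemplars x 8 images, 30 recording sites
cfg <- generator_config(n_objects_per_category = 3, n_images_per_object = 8,
                        n_sites = 30, n_trials = 12, seed = 1)
stim   <- make_stimulus_set(cfg)
latent <- make_latent_representation(stim, cfg)   # ground-truth representation
tensor <- simulate_trials(latent, cfg)            # trial-structured recordings
neural <- preprocess_trials(tensor)               # images x sites features

noise <- fit_noise_model(tensor)
print(noise)
#> Rate-dependent additive noise model (variance = a * mean + b)
#>   a = 0.3289, b = 0.5830, trials T = 12
#>   variance decomposition: total 0.4656 = signal 0.4171 + noise 0.0486 (SEM level)

# kernel analysis of the neural sample and of a noise-matched "model"
model_rep <- latent %*% matrix(rnorm(ncol(latent) * 120), ncol(latent))
matched <- noise_match(model_rep, noise, n_features = 30, n_repeats = 5, seed = 2)

subsets <- ka_subsets(stim$category, n_subsets = 5, seed = 3)
ka_neural <- kernel_analysis(neural, stim$category,
                             lambdas = ka_lambda_grid(20),
                             sigma_factors = ka_sigma_factors(12),
                             subsets = subsets)
print(ka_neural)
#> Kernel analysis curve
#>   images: 168, categories: 7, subsets: 5
#>   lambda grid: 20 values in [1e-06, 1e+03]
#>   KA-AUC: 0.3542 (sd 0.0218 over subsets)

mean(sapply(matched, function(m)
  kernel_analysis(m, stim$category, lambdas = ka_lambda_grid(20),
                  sigma_factors = ka_sigma_factors(12), subsets = subsets)$auc))
#> noise-matched model KA-AUC: 0.530

svm_decoding(neural, stim$category, n_splits = 5, seed = 4)
#> Linear-SVM decoding
#>   accuracy: 76.0% (sd 8.5%) over 5 splits; chance 14.3%

rdm_similarity(compute_rdm(object_average(model_rep, stim)),
               compute_rdm(object_average(neural, stim)))
#> model-to-neural RDM similarity (Spearman): 0.552
```

Reading the numbers: the noise model says roughly 10% of the averaged
neural sample's variance is trial noise at T = 12. The 30-site neural sample
reaches KA-AUC 0.354, while this (deliberately strong, linearly mixed) model
representation still scores 0.530 after being subsampled to 30 features and
noise-matched — on these synthetic data the model out-represents the
recorded sample. The SVM confirms the neural sample decodes far above the
14.3% chance level, and the model's object-level geometry correlates with
the neural geometry at ρ ≈ 0.55.

A command-line interface wrapping the same functions ships at
`inst/cli/kernelrep` (subcommands `simulate`, `ka-curve`, `noise-match`,
`svm-eval`, `rdm`, `compare`), reading CSV/JSON/YAML and writing JSON
reports.

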