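# Shared helpers: reduced grids and small synthetic tasks keep individual
# tests fast while exercising the full pipeline.

small_lambdas <- ka_lambda_grid(12)
small_sigmas <- ka_sigma_factors(8)

# single-curve KA-AUC (no bootstrap) on reduced grids
quick_auc <- function(x, labels, subsets = NULL) {
  if (is.null(subsets)) {
    kernel_analysis(x, labels, lambdas = small_lambdas,
                    sigma_factors = small_sigmas,
                    n_subsets = 1, frac = 1, replace = FALSE)$auc
  } else {
    kernel_analysis(x, labels, lambdas = small_lambdas,
                    sigma_factors = small_sigmas, subsets = subsets)$auc
  }
}

# a small 7-category task with its latent representation
small_task <- function(n_obj = 2, n_img = 8, seed = 1, ...) {
  cfg <- generator_config(n_objects_per_category = n_obj,
                          n_images_per_object = n_img, seed = seed, ...)
  stim <- make_stimulus_set(cfg)
  list(cfg = cfg, stim = stim,
       latent = make_latent_representation(stim, cfg))
}

# trial means of a tensor as an images x sites matrix (independent of
# preprocess_trials, used as its oracle and for empirical-noise baselines)
trial_means <- function(tensor, trials = NULL) {
  tn <- unclass(tensor)
  if (!is.null(trials)) tn <- tn[, , trials, drop = FALSE]
  t(apply(tn, c(1, 2), mean))
}

# orthogonal matrix fixing the all-ones direction, so Pearson-correlation
# structure is preserved exactly under rotation
rotation_fixing_ones <- function(d, seed = 1) {
  set.seed(seed)
  ones <- rep(1, d) / sqrt(d)
  U <- qr.Q(qr(cbind(ones, matrix(rnorm(d * (d - 1)), d))))[, -1]
  R <- qr.Q(qr(matrix(rnorm((d - 1)^2), d - 1)))
  U %*% R %*% t(U) + tcrossprod(rep(1, d)) / d
}
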