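#' Configuration for the synthetic data generator
#'
#' Collects the parameters of the synthetic stimulus/representation/trial
#' generator. The defaults reproduce the structure of the study conditions
#' the package targets: 7 categories x 7 object exemplars x 40 images
#' (1960 stimuli), 168 recording sites, 47 trials per image, Poisson-like
#' trial noise (variance equal to the mean rate), and a positive background
#' rate so background subtraction is exercised.
#'
#' Signal structure: every image's latent vector is a category centroid
#' plus an object-exemplar offset plus an image-level nuisance draw, with
#' the three variance components set by `category_signal`, `object_signal`
#' and `nuisance_signal`. The defaults make image-level variation dominate
#' (nuisance twice the category variance), mirroring a high-variation task
#' on which category information is present but not trivially linear.
#'
#' @param n_categories,n_objects_per_category,n_images_per_object task
#'   layout (defaults 7 / 7 / 40).
#' @param latent_dims dimensionality of the ground-truth latent space.
#' @param category_signal,object_signal,nuisance_signal variances of the
#'   category, object and image-level latent components.
#' @param noise_a,noise_b linear mean-variance coefficients of the trial
#'   noise (`var = noise_a * mean + noise_b`); the default `(1, 0)` is
#'   Poisson-like.
#' @param n_trials trials (repetitions) per image.
#' @param n_sites number of single-unit-like recording sites.
#' @param multiunit_pool_size single units summed per multi-unit site.
#' @param base_rate mean evoked rate added on top of the background rate
#'   (spike counts per window).
#' @param response_sd standard deviation of evoked rates across images.
#' @param blank_rate per-site background rate.
#' @param poisson use true Poisson counts instead of Gaussian noise with
#'   linear mean-variance (robustness option; the estimation pipeline is
#'   exactly well-specified only for the Gaussian default).
#' @param seed RNG seed for all generator draws.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(n_categories = 7L,
                             n_objects_per_category = 7L,
                             n_images_per_object = 40L,
                             latent_dims = 50L,
                             category_signal = 1,
                             object_signal = 1,
                             nuisance_signal = 2,
                             noise_a = 1,
                             noise_b = 0,
                             n_trials = 47L,
                             n_sites = 168L,
                             multiunit_pool_size = 5L,
                             base_rate = 5,
                             response_sd = 2,
                             blank_rate = 0.5,
                             poisson = FALSE,
                             seed = 1L) {
  cfg <- list(n_categories = as.integer(n_categories),
              n_objects_per_category = as.integer(n_objects_per_category),
              n_images_per_object = as.integer(n_images_per_object),
              latent_dims = as.integer(latent_dims),
              category_signal = category_signal,
              object_signal = object_signal,
              nuisance_signal = nuisance_signal,
              noise_a = noise_a, noise_b = noise_b,
              n_trials = as.integer(n_trials),
              n_sites = as.integer(n_sites),
              multiunit_pool_size = as.integer(multiunit_pool_size),
              base_rate = base_rate, response_sd = response_sd,
              blank_rate = blank_rate, poisson = isTRUE(poisson),
              seed = as.integer(seed))
  stopifnot(cfg$n_categories >= 1, cfg$n_objects_per_category >= 1,
            cfg$n_images_per_object >= 1, cfg$latent_dims >= 1,
            cfg$category_signal >= 0, cfg$object_signal >= 0,
            cfg$nuisance_signal >= 0, cfg$n_trials >= 1, cfg$n_sites >= 1,
            cfg$multiunit_pool_size >= 1, cfg$response_sd >= 0)
  class(cfg) <- "generator_config"
  cfg
}

#' Stimulus set for a generator configuration
#'
#' @param config a [generator_config()].
#' @return a [stimulus_set()] with the configured layout (1960 images by
#'   default), deterministic given the config.
#' @export
make_stimulus_set <- function(config = generator_config()) {
  stimulus_set(config$n_categories, config$n_objects_per_category,
               config$n_images_per_object, seed = config$seed)
}

#' Ground-truth latent representation for a stimulus set
#'
#' Draws, per image, `latent_dims`-dimensional vectors composed of a
#' category centroid, an object-exemplar offset and an image-level nuisance
#' draw (i.i.d. Gaussian components with the configured variances). This is
#' the synthetic stand-in for a high-level neural representation: category
#' structure is present at variance `category_signal` against nuisance
#' variation of variance `nuisance_signal`.
#'
#' @param stimuli a [stimulus_set()].
#' @param config a [generator_config()].
#' @return feature matrix (images x latent_dims), `feature_kind = "model"`.
#' @export
make_latent_representation <- function(stimuli, config = generator_config()) {
  validate_stimulus_set(stimuli)
  if (config$latent_dims < config$n_categories)
    warning("latent_dims < n_categories: category separability is limited")
  d <- config$latent_dims
  rng <- local_rng(config$seed + 1L)
  on.exit(rng(), add = TRUE)
  cats <- levels(stimuli$category)
  objs <- levels(stimuli$object_id)
  cat_centroid <- matrix(stats::rnorm(length(cats) * d,
                                      sd = sqrt(config$category_signal)),
                         length(cats), d, dimnames = list(cats, NULL))
  obj_offset <- matrix(stats::rnorm(length(objs) * d,
                                    sd = sqrt(config$object_signal)),
                       length(objs), d, dimnames = list(objs, NULL))
  n <- nrow(stimuli)
  nuisance <- matrix(stats::rnorm(n * d, sd = sqrt(config$nuisance_signal)),
                     n, d)
  x <- cat_centroid[as.character(stimuli$category), , drop = FALSE] +
    obj_offset[as.character(stimuli$object_id), , drop = FALSE] +
    nuisance
  dimnames(x) <- list(NULL, sprintf("latent%03d", seq_len(d)))
  attr(x, "feature_kind") <- "model"
  x
}

#' Simulate trial-structured responses from a latent representation
#'
#' Each site responds with a fixed nonnegative random mixture of the latent
#' dimensions, rescaled so evoked rates have standard deviation
#' `response_sd` around `base_rate`, plus the background rate. Trial noise
#' is zero-mean Gaussian with variance `noise_a * mean + noise_b` (clipped
#' at 0), i.e. the linear mean-variance family the noise-model estimator
#' assumes; with `poisson = TRUE`, counts are true Poisson draws instead.
#'
#' @param latent feature matrix (images x latent_dims) from
#'   [make_latent_representation()].
#' @param config a [generator_config()].
#' @return a [trial_tensor()] (n_sites x n_images x n_trials) with the
#'   configured blank rate.
#' @export
simulate_trials <- function(latent, config = generator_config()) {
  latent <- as.matrix(latent)
  rng <- local_rng(config$seed + 2L)
  on.exit(rng(), add = TRUE)
  ns <- config$n_sites
  d <- ncol(latent)
  W <- matrix(abs(stats::rnorm(ns * d)), ns, d)  # nonnegative mixing
  evoked <- W %*% t(latent)                       # sites x images
  evoked <- evoked - rowMeans(evoked)
  row_sd <- apply(evoked, 1, stats::sd)
  row_sd[row_sd == 0] <- 1
  mu <- config$blank_rate + config$base_rate +
    evoked * (config$response_sd / row_sd)
  mu <- pmax(mu, 0.01)                            # rates stay positive
  n_img <- ncol(mu)
  Tt <- config$n_trials
  counts <- array(NA_real_, c(ns, n_img, Tt))
  if (config$poisson) {
    counts[] <- stats::rpois(ns * n_img * Tt, lambda = rep(mu, Tt))
  } else {
    sds <- sqrt(pmax(0, config$noise_a * mu + config$noise_b))
    counts[] <- rep(mu, Tt) + stats::rnorm(ns * n_img * Tt, sd = rep(sds, Tt))
  }
  trial_tensor(counts, blank_rate = rep(config$blank_rate, ns))
}

#' Pool single-unit sites into multi-unit sites
#'
#' Randomly partitions the sites into disjoint groups of `pool_size` and
#' sums the spike counts within each group per image and trial, emulating
#' the aggregation of spatially local single units at a multi-unit
#' electrode. Blank rates add. Sites left over when `pool_size` does not
#' divide the site count are dropped with a warning.
#'
#' @param tensor a [trial_tensor()] of single-unit-like responses.
#' @param pool_size single units per multi-unit site.
#' @param seed RNG seed for the grouping.
#' @return a [trial_tensor()] with `floor(n_sites / pool_size)` sites.
#' @export
pool_multiunit <- function(tensor, pool_size, seed = 1) {
  stopifnot(length(dim(tensor)) == 3L, pool_size >= 1)
  ns <- n_sites(tensor)
  if (pool_size > ns) stop("pool_size exceeds the number of sites")
  n_groups <- ns %/% pool_size
  if (n_groups * pool_size < ns)
    warning(ns - n_groups * pool_size,
            " site(s) dropped: pool_size does not divide the site count")
  if (pool_size == 1L) return(tensor)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  perm <- sample.int(ns)
  blank <- attr(tensor, "blank_rate")
  tn <- unclass(tensor)
  out <- array(0, c(n_groups, dim(tn)[2], dim(tn)[3]))
  blank_out <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    members <- perm[((g - 1L) * pool_size + 1L):(g * pool_size)]
    out[g, , ] <- apply(tn[members, , , drop = FALSE], c(2, 3), sum)
    blank_out[g] <- sum(blank[members])
  }
  trial_tensor(out, blank_rate = blank_out, window = attr(tensor, "window"))
}
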