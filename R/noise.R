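#' Normalize a trial tensor to unit population variance
#'
#' Centers the responses by the grand mean (over sites, images and trials)
#' and scales them so the total variance over sites, images and trials is 1.
#' This is the first step of noise-model estimation; all noise-model
#' coefficients are expressed on this normalized scale.
#'
#' @param tensor a [trial_tensor()].
#' @return the normalized trial tensor (blank rate transformed consistently).
#' @export
normalize_population <- function(tensor) {
  stopifnot(length(dim(tensor)) == 3L)
  v <- stats::var(as.vector(tensor)) * (length(tensor) - 1) / length(tensor)
  if (v <= 0) stop("zero population variance: cannot normalize")
  mu <- mean(tensor)
  out <- (unclass(tensor) - mu) / sqrt(v)
  blank <- attr(tensor, "blank_rate")
  if (is.null(blank)) blank <- rep(0, dim(tensor)[1])
  trial_tensor(out, blank_rate = (blank - mu) / sqrt(v),
               window = attr(tensor, "window") %||% c(70, 170))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the linear mean-variance (Poisson-like) noise relation
#'
#' For each site, the across-trial variance of the response to each image
#' is regressed linearly on the across-trial mean of that response; the
#' slope/intercept pairs are then averaged over sites with equal weight. A
#' slope of 1 and intercept 0 corresponds to Poisson-like variability.
#'
#' The regressor is the estimated trial mean, whose sampling variance
#' (`variance / T`) attenuates a plain least-squares slope and inflates the
#' intercept. Since that error variance is known, the fit applies the
#' standard errors-in-variables moment correction — the denominator
#' `var(mean)` is debiased by `mean(variance) / T` — giving (for Gaussian
#' trial noise) unbiased coefficients. Set `correct_attenuation = FALSE`
#' for the uncorrected ordinary least-squares fit. Sites whose mean
#' response is constant across images are excluded with a warning.
#'
#' @param tensor a [trial_tensor()] with at least 2 trials; normally the
#'   output of [normalize_population()].
#' @param correct_attenuation apply the errors-in-variables moment
#'   correction for the sampling error of the trial mean (default TRUE).
#' @return object of class `"noise_model"` with elements `a` (slope),
#'   `b` (intercept), `n_trials`, and per-site coefficients `per_site`.
#' @export
fit_mean_variance <- function(tensor, correct_attenuation = TRUE) {
  stopifnot(length(dim(tensor)) == 3L)
  Tt <- n_trials(tensor)
  if (Tt < 2) stop("at least 2 trials are required")
  tn <- unclass(tensor)
  ns <- dim(tn)[1]
  coefs <- matrix(NA_real_, ns, 2, dimnames = list(NULL, c("a", "b")))
  for (s in seq_len(ns)) {
    resp <- matrix(tn[s, , ], nrow = dim(tn)[2])  # images x trials
    m <- rowMeans(resp)
    v <- apply(resp, 1, stats::var)
    if (stats::sd(m) == 0) next  # constant mean: slope unidentifiable
    denom <- stats::var(m)
    if (correct_attenuation) {
      adj <- denom - mean(v) / Tt
      if (adj > denom / 10) denom <- adj  # guard against near-zero denominators
    }
    a <- stats::cov(m, v) / denom
    coefs[s, ] <- c(a, mean(v) - a * mean(m))
  }
  ok <- stats::complete.cases(coefs)
  if (!any(ok)) stop("all sites have constant mean responses; cannot fit")
  if (!all(ok))
    warning(sum(!ok), " site(s) with constant mean excluded from the fit")
  structure(list(a = mean(coefs[ok, "a"]),
                 b = mean(coefs[ok, "b"]),
                 n_trials = n_trials(tensor),
                 per_site = coefs),
            class = "noise_model")
}

#' Decompose population variance into signal and trial-noise shares
#'
#' Completes a noise model with the signal/noise variance decomposition.
#' The noise share is taken at the level of the standard error of the mean
#' (the matched neural features are T-trial averages): the mean over sites
#' and images of the model-predicted variance `max(0, a * mu + b)` divided
#' by the trial count. The total is the variance of the trial-averaged
#' responses — the quantity actually observed in a neural feature matrix —
#' and the signal share is that total minus the noise share, floored at a
#' small positive value. A representation scaled to the signal share and
#' then noise-injected at trial count T reproduces the variance of the
#' T-trial-averaged neural sample.
#'
#' @param tensor the (normalized) trial tensor the model was fitted on.
#' @param model a `"noise_model"` from [fit_mean_variance()].
#' @param n_trials target trial count T for the SEM scaling of injected
#'   noise; defaults to the tensor's own trial count. The signal share is
#'   always computed against the tensor's own trial count, so injecting at
#'   a smaller T emulates a recording with fewer repetitions.
#' @return the noise model with `sigma2_total` (variance of the tensor's
#'   trial-averaged responses), `sigma2_noise` (SEM-level noise at the
#'   target T), `sigma2_signal` filled in.
#' @export
estimate_signal_noise <- function(tensor, model, n_trials = NULL) {
  stopifnot(inherits(model, "noise_model"))
  tn <- unclass(tensor)
  t_own <- dim(tn)[3]
  if (is.null(n_trials)) n_trials <- t_own
  mu <- apply(tn, c(1, 2), mean)
  total <- stats::var(as.vector(mu)) * (length(mu) - 1) / length(mu)
  pred <- mean(pmax(0, model$a * mu + model$b))
  if (pred / t_own >= total)
    stop(sprintf(paste0("degenerate decomposition: estimated noise variance ",
                        "(%.4g) is not below the variance of the averaged ",
                        "responses (%.4g); the recording carries no ",
                        "resolvable signal"), pred / t_own, total))
  model$n_trials <- as.integer(n_trials)
  model$sigma2_total <- total
  model$sigma2_noise <- pred / n_trials
  model$sigma2_signal <- max(total - pred / t_own, 1e-12)
  model
}

#' Fit a complete experimental noise model from a trial tensor
#'
#' Convenience wrapper running [normalize_population()],
#' [fit_mean_variance()] and [estimate_signal_noise()] in sequence, the
#' standard route from a raw trial tensor to a noise model usable by
#' [noise_match()].
#'
#' @param tensor a raw [trial_tensor()].
#' @param n_trials trial count for the SEM scaling (defaults to the
#'   tensor's trial count; use 47 for multi-unit-matched and 6 for
#'   single-unit-matched analyses when injecting at a different trial
#'   budget than the recording).
#' @return a complete `"noise_model"`.
#' @export
fit_noise_model <- function(tensor, n_trials = NULL) {
  norm <- normalize_population(tensor)
  model <- fit_mean_variance(norm)
  estimate_signal_noise(norm, model, n_trials = n_trials)
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Rate-dependent additive noise model (variance = a * mean + b)\n")
  cat(sprintf("  a = %.4f, b = %.4f, trials T = %d\n", x$a, x$b, x$n_trials))
  if (!is.null(x$sigma2_signal))
    cat(sprintf("  variance decomposition: total %.4f = signal %.4f + noise %.4f (SEM level)\n",
                x$sigma2_total, x$sigma2_signal, x$sigma2_noise))
  invisible(x)
}

#' @export
coef.noise_model <- function(object, ...) c(a = object$a, b = object$b)

#' Predicted trial-noise variance at given mean responses
#'
#' @param object a `"noise_model"`.
#' @param mu mean responses (any numeric shape).
#' @param sem divide by the trial count (variance of a T-trial average)
#'   rather than returning single-trial variance.
#' @param ... unused.
#' @return predicted variances `max(0, a * mu + b)`, optionally `/ T`.
#' @export
predict.noise_model <- function(object, mu, sem = TRUE, ...) {
  v <- pmax(0, object$a * mu + object$b)
  if (sem) v / object$n_trials else v
}

#' Scale model features to the estimated signal variance
#'
#' Centers a model representation by its grand mean and rescales it by a
#' single global multiplier so its total variance equals the noise model's
#' signal variance. After the subsequent noise injection the total variance
#' then matches the variance of the trial-averaged neural sample at the
#' model's trial count. A global rescaling preserves all pairwise distance
#' ratios, so kernel analysis of the scaled representation differs from the
#' original only through the added noise.
#'
#' @param x feature matrix (images x features) with nonzero variance.
#' @param model a complete `"noise_model"` (with `sigma2_signal`).
#' @return the centered, rescaled matrix.
#' @export
scale_model_features <- function(x, model) {
  stopifnot(inherits(model, "noise_model"))
  if (is.null(model$sigma2_signal))
    stop("noise model lacks the signal/noise decomposition; run estimate_signal_noise()")
  x <- as.matrix(x)
  v <- stats::var(as.vector(x)) * (length(x) - 1) / length(x)
  if (v <= 0) stop("zero-variance representation cannot be scaled")
  (x - mean(x)) * sqrt(model$sigma2_signal / v)
}

#' Inject rate-dependent Gaussian noise into a scaled representation
#'
#' Adds to every entry an independent zero-mean Gaussian draw whose
#' variance is the noise model's prediction at that entry, at the SEM
#' level: `max(0, a * value + b) / T`. Entries whose predicted variance is
#' negative before clipping are left noiseless (clip at 0).
#'
#' @param x feature matrix already passed through [scale_model_features()].
#' @param model a `"noise_model"`.
#' @param seed RNG seed; the same seed reproduces the draw bit for bit.
#' @return the noise-corrupted matrix.
#' @export
inject_noise <- function(x, model, seed = 1) {
  stopifnot(inherits(model, "noise_model"))
  x <- as.matrix(x)
  v <- predict(model, x, sem = TRUE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  x + stats::rnorm(length(x), sd = sqrt(as.vector(v)))
}

#' Sample- and noise-match a model representation to a neural recording
#'
#' The full correction pipeline: the representation is subsampled to
#' `n_features` columns (matching the neural sample size), globally
#' rescaled to the estimated signal variance, and corrupted with
#' rate-dependent Gaussian noise at the SEM level. The noise draw is
#' repeated `n_repeats` times so downstream metrics can be reported as a
#' mean and spread over draws; the feature subsample is fixed across
#' repeats (set `resample_features = TRUE` to redraw it each repeat).
#'
#' @param x model feature matrix (images x features).
#' @param model a complete `"noise_model"`.
#' @param n_features number of columns to keep (e.g. 80 multi-unit-matched,
#'   40 single-unit-matched).
#' @param n_repeats number of independent noise draws.
#' @param seed RNG seed.
#' @param resample_features redraw the feature subsample per repeat.
#' @return list of `n_repeats` noise-matched matrices
#'   (images x n_features).
#' @export
noise_match <- function(x, model, n_features, n_repeats = 10, seed = 1,
                        resample_features = FALSE) {
  stopifnot(inherits(model, "noise_model"))
  x <- as.matrix(x)
  sub <- subsample_features(x, n_features, seed = seed)
  scaled <- scale_model_features(sub, model)
  lapply(seq_len(n_repeats), function(k) {
    if (resample_features && k > 1) {
      sub_k <- subsample_features(x, n_features, seed = seed + k)
      scaled_k <- scale_model_features(sub_k, model)
      inject_noise(scaled_k, model, seed = seed + 1000L * k)
    } else {
      inject_noise(scaled, model, seed = seed + 1000L * k)
    }
  })
}

#' Read / write noise models as JSON
#'
#' @param model a `"noise_model"`; `path` a file path.
#' @return `read_noise_model()` returns the model; `write_noise_model()`
#'   the path, invisibly.
#' @export
write_noise_model <- function(model, path) {
  stopifnot(inherits(model, "noise_model"))
  keep <- model[intersect(c("a", "b", "n_trials", "sigma2_total",
                            "sigma2_signal", "sigma2_noise"), names(model))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_noise_model
#' @export
read_noise_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "noise_model")
}
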