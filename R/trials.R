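#' Trial tensor container
#'
#' A trial tensor holds spike-count (or rate) responses as a 3-dimensional
#' array of sites x images x trials, together with each site's background
#' (blank-screen) firing rate and the spike-count window in milliseconds.
#'
#' @param counts numeric array, dim = c(n_sites, n_images, n_trials).
#' @param blank_rate per-site background rate (recycled to n_sites).
#' @param window spike-count window `c(start_ms, end_ms)`, start < end.
#' @return the array with class `"trial_tensor"` and attributes
#'   `blank_rate` and `window`.
#' @export
trial_tensor <- function(counts, blank_rate = 0, window = c(70, 170)) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3L)
    stop("counts must be a 3-d array (sites x images x trials)")
  if (!all(is.finite(counts)))
    stop("counts contains non-finite values")
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(start_ms, end_ms) with start < end")
  n_sites <- dim(counts)[1]
  blank_rate <- rep_len(as.numeric(blank_rate), n_sites)
  structure(counts, class = "trial_tensor",
            blank_rate = blank_rate, window = as.numeric(window))
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Trial tensor: %d sites x %d images x %d trials, window %g-%g ms\n",
              d[1], d[2], d[3], attr(x, "window")[1], attr(x, "window")[2]))
  invisible(x)
}

n_sites <- function(tensor) dim(tensor)[1]
n_images <- function(tensor) dim(tensor)[2]
n_trials <- function(tensor) dim(tensor)[3]

#' Preprocess a trial tensor into a feature matrix
#'
#' Converts trial-structured responses to the trial-averaged representation
#' used throughout: per site, the background rate is subtracted from every
#' count, the result is divided by a per-site scale (the standard deviation
#' of the site's responses across images and trials unless supplied), and
#' finally responses are averaged over trials. The result is transposed to
#' images x sites so that rows index stimuli, as for model feature matrices.
#'
#' @param tensor a [trial_tensor()].
#' @param block_std optional strictly positive per-site scale; when `NULL`
#'   it is the per-site standard deviation over all images and trials.
#' @return numeric matrix (n_images x n_sites), `feature_kind`
#'   attribute set to `"neural"`.
#' @examples
#' counts <- array(rpois(2 * 4 * 3, 10), c(2, 4, 3))
#' x <- preprocess_trials(trial_tensor(counts, blank_rate = 5))
#' dim(x)  # 4 images x 2 sites
#' @export
preprocess_trials <- function(tensor, block_std = NULL) {
  stopifnot(inherits(tensor, "trial_tensor") || length(dim(tensor)) == 3L)
  if (!all(is.finite(tensor))) stop("tensor contains non-finite values")
  blank <- attr(tensor, "blank_rate")
  if (is.null(blank)) blank <- rep(0, n_sites(tensor))
  ns <- n_sites(tensor)
  if (is.null(block_std)) {
    block_std <- apply(tensor, 1, stats::sd)
  } else {
    block_std <- rep_len(as.numeric(block_std), ns)
  }
  if (any(!is.finite(block_std)) || any(block_std <= 0))
    stop("degenerate scale: block_std must be strictly positive for every site")
  centred <- sweep(unclass(tensor), 1, blank, "-")
  scaled <- sweep(centred, 1, block_std, "/")
  out <- t(apply(scaled, c(1, 2), mean))  # images x sites
  dimnames(out) <- list(NULL, sprintf("site%03d", seq_len(ns)))
  attr(out, "feature_kind") <- "neural"
  out
}

#' Split-half response consistency per site
#'
#' For each site, trials are randomly partitioned into two halves, each half
#' is averaged across trials, and the Pearson correlation between the two
#' half-averaged image-response vectors is recorded; the mean over
#' `n_repeats` random partitions is the site's split-half consistency.
#' The Spearman-Brown prophecy formula (factor 2) gives the corrected value.
#' Sites whose half-averaged responses are constant across images have
#' undefined consistency and are reported as `NA` (never silently zero).
#'
#' @param tensor a [trial_tensor()] with at least 2 trials.
#' @param n_repeats number of random even splits to average over.
#' @param seed RNG seed.
#' @return data.frame with columns `site`, `split_half_r`, `corrected_r`.
#' @export
split_half_consistency <- function(tensor, n_repeats = 20, seed = 1) {
  stopifnot(length(dim(tensor)) == 3L)
  Tt <- n_trials(tensor)
  if (Tt < 2) stop("at least 2 trials are required for split-half consistency")
  ns <- n_sites(tensor)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  half <- Tt %/% 2L
  rsum <- matrix(0, ns, n_repeats)
  defined <- matrix(TRUE, ns, n_repeats)
  tn <- unclass(tensor)
  for (k in seq_len(n_repeats)) {
    idx <- sample.int(Tt)
    g1 <- idx[seq_len(half)]
    g2 <- idx[(half + 1L):Tt]
    m1 <- apply(tn[, , g1, drop = FALSE], c(1, 2), mean)
    m2 <- apply(tn[, , g2, drop = FALSE], c(1, 2), mean)
    for (s in seq_len(ns)) {
      if (stats::sd(m1[s, ]) == 0 || stats::sd(m2[s, ]) == 0) {
        defined[s, k] <- FALSE
      } else {
        rsum[s, k] <- stats::cor(m1[s, ], m2[s, ])
      }
    }
  }
  r <- vapply(seq_len(ns), function(s) {
    ok <- defined[s, ]
    if (!any(ok)) NA_real_ else mean(rsum[s, ok])
  }, numeric(1))
  if (anyNA(r))
    warning(sum(is.na(r)), " site(s) had constant responses; consistency undefined (NA)")
  data.frame(site = seq_len(ns),
             split_half_r = r,
             corrected_r = ifelse(is.na(r), NA_real_, spearman_brown_safe(r)))
}

# vectorized Spearman-Brown that maps r = -1 to NA instead of erroring
spearman_brown_safe <- function(r) ifelse(r <= -1, NA_real_, 2 * r / (1 + r))

#' Select the most consistent sites
#'
#' Returns the indices of the `k` sites with the highest split-half
#' consistency. Ties are broken toward the lower site index so the
#' selection is deterministic. Sites with undefined (`NA`) consistency are
#' never selected.
#'
#' @param consistency data.frame from [split_half_consistency()].
#' @param k number of sites to keep.
#' @return integer vector of site indices, length `k`.
#' @export
select_top_consistent_sites <- function(consistency, k) {
  stopifnot(is.data.frame(consistency),
            all(c("site", "split_half_r") %in% names(consistency)))
  ok <- which(!is.na(consistency$split_half_r))
  if (k > length(ok))
    stop("k exceeds the number of sites with defined consistency")
  ord <- ok[order(-consistency$split_half_r[ok], consistency$site[ok])]
  sort(consistency$site[ord[seq_len(k)]])
}

#' Subsample feature columns without replacement
#'
#' Uniform random choice of `n` feature columns, reproducible from `seed`.
#' Used to equalize the number of model features and neural samples before
#' any comparison (e.g. 80 for multi-unit-matched, 40 for
#' single-unit-matched analyses).
#'
#' @param x feature matrix (images x features).
#' @param n number of columns to keep, `n <= ncol(x)`.
#' @param seed RNG seed.
#' @return matrix (images x n); attributes of `x` are preserved.
#' @export
subsample_features <- function(x, n, seed = 1) {
  x <- as.matrix(x)
  if (n > ncol(x)) stop("n exceeds the number of available features")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  keep <- sample.int(ncol(x), n)
  out <- x[, keep, drop = FALSE]
  attr(out, "feature_kind") <- attr(x, "feature_kind")
  out
}

#' Spearman-Brown prophecy correction
#'
#' Corrects a split-half reliability for test length:
#' `factor * r / (1 + (factor - 1) * r)`. With the default factor 2 this is
#' the standard `2r / (1 + r)` used to turn a half-data self-consistency
#' into a full-data noise ceiling.
#'
#' @param r correlation in (-1, 1].
#' @param factor lengthening factor (2 for split halves).
#' @return corrected correlation.
#' @examples
#' spearman_brown(0.5)  # 2/3
#' @export
spearman_brown <- function(r, factor = 2) {
  if (any(r <= -1)) stop("Spearman-Brown correction undefined for r <= -1")
  factor * r / (1 + (factor - 1) * r)
}
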