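#' Gaussian kernel matrix
#'
#' Computes the kernel matrix `K[i, j] = exp(-||x_i - x_j||^2 / (2 sigma^2))`
#' over the rows of a feature matrix. The kernel depends only on pairwise
#' Euclidean distances, so it is invariant to rotations and translations of
#' the feature space and to permutations of the feature columns.
#'
#' @param x feature matrix (images x features).
#' @param sigma bandwidth, strictly positive.
#' @return symmetric positive semi-definite n x n matrix with unit diagonal.
#' @examples
#' gaussian_kernel(rbind(c(0, 0), c(1, 0)), sigma = 1)[1, 2]  # exp(-1/2)
#' @export
gaussian_kernel <- function(x, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("x contains non-finite values")
  d2 <- squared_distances(x)
  K <- exp(-d2 / (2 * sigma^2))
  diag(K) <- 1
  K
}

# pairwise squared Euclidean distances between rows, clipped at 0
squared_distances <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

#' Median-heuristic kernel bandwidth
#'
#' The median of the pairwise Euclidean distances between the rows of `x`
#' (pairs i < j). The bandwidth scan in [kernel_analysis()] is centered on
#' this value.
#'
#' @param x feature matrix.
#' @return positive scalar; error if all rows coincide (zero median).
#' @export
median_heuristic_sigma <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least 2 rows are required")
  d2 <- squared_distances(x)
  med <- stats::median(sqrt(d2[upper.tri(d2)]))
  if (med <= 0) stop("median pairwise distance is zero: all rows identical")
  med
}

#' Closed-form leave-one-out residuals of kernel ridge regression
#'
#' For the model `alpha = (K + lambda I)^{-1} y`, the leave-one-out residual
#' at example i (the error a model refit without example i makes at i) is
#' `alpha_i / G_ii` where `G = (K + lambda I)^{-1}`. The whole vector is
#' obtained from one eigendecomposition of `K`, which is reused across
#' regularization values in [kernel_analysis()].
#'
#' @param K symmetric PSD kernel matrix.
#' @param y numeric response vector.
#' @param lambda positive ridge penalty.
#' @return numeric vector of per-example leave-one-out residuals.
#' @export
loo_errors <- function(K, y, lambda) {
  K <- as.matrix(K)
  if (!isSymmetric(K, tol = 1e-8)) stop("K must be symmetric")
  if (lambda <= 0) stop("lambda must be positive")
  if (length(y) != nrow(K)) stop("length(y) must equal nrow(K)")
  eig <- kernel_eigen(K)
  drop(loo_residuals_eig(eig, cbind(y), lambda))
}

kernel_eigen <- function(K) {
  eig <- eigen(K, symmetric = TRUE)
  eig$values[eig$values < 0] <- 0  # clip numerical negatives
  eig$Q2 <- eig$vectors^2
  eig
}

# LOO residuals for a response matrix Y (n x C) at one lambda, given an
# eigendecomposition with precomputed Q2 = Q^2 (n x n).
loo_residuals_eig <- function(eig, Y, lambda, QtY = NULL) {
  w <- 1 / (eig$values + lambda)
  if (is.null(QtY)) QtY <- crossprod(eig$vectors, Y)
  alpha <- eig$vectors %*% (w * QtY)       # (K + lambda I)^{-1} Y
  g <- drop(eig$Q2 %*% w)                   # diag((K + lambda I)^{-1})
  alpha / g
}

#' Regularization and bandwidth grids for kernel analysis
#'
#' The regularization grid is log-spaced and returned in decreasing order so
#' that complexity `1/lambda` is increasing. The bandwidth grid is expressed
#' as multiplicative factors of the median pairwise distance, log-spaced and
#' symmetric about 1.
#'
#' @param n_lambda,lambda_range number and range of ridge penalties.
#' @param n_sigma,sigma_factor_range number and range of bandwidth factors.
#' @return numeric vector of penalties / factors.
#' @export
ka_lambda_grid <- function(n_lambda = 56, lambda_range = c(1e-6, 1e3)) {
  sort(10^seq(log10(lambda_range[1]), log10(lambda_range[2]),
              length.out = n_lambda), decreasing = TRUE)
}

#' @rdname ka_lambda_grid
#' @export
ka_sigma_factors <- function(n_sigma = 32, sigma_factor_range = c(1 / 8, 8)) {
  10^seq(log10(sigma_factor_range[1]), log10(sigma_factor_range[2]),
         length.out = n_sigma)
}

# One-vs-all centered indicator matrix (n x C). Centering makes the zero
# predictor coincide with predicting every category at its base rate, so a
# representation carrying no category information scores precision ~0 (not
# the base-rate floor), while perfect indicator prediction still scores 1.
label_indicators <- function(labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("at least 2 categories are required")
  if (any(table(labels) < 2)) stop("every category needs at least 2 examples")
  Y <- 1 * outer(labels, levels(labels), "==")
  Y <- sweep(Y, 2, colMeans(Y))
  colnames(Y) <- levels(labels)
  Y
}

# Mean over categories of the normalized per-class LOO error for every
# (lambda, sigma) combination. Returns a n_lambda x n_sigma matrix.
ka_error_surface <- function(x, labels, lambdas, sigma_factors,
                             sigma_med = NULL) {
  x <- as.matrix(x)
  Y <- label_indicators(labels)
  norm2 <- colMeans(Y^2)  # zero predictor has normalized error exactly 1
  if (is.null(sigma_med)) sigma_med <- median_heuristic_sigma(x)
  d2 <- squared_distances(x)
  errs <- matrix(NA_real_, length(lambdas), length(sigma_factors))
  for (j in seq_along(sigma_factors)) {
    sigma <- sigma_factors[j] * sigma_med
    K <- exp(-d2 / (2 * sigma^2))
    eig <- kernel_eigen(K)
    QtY <- crossprod(eig$vectors, Y)
    for (i in seq_along(lambdas)) {
      res <- loo_residuals_eig(eig, Y, lambdas[i], QtY = QtY)
      errs[i, j] <- mean(colMeans(res^2) / norm2)
    }
  }
  attr(errs, "sigma_med") <- sigma_med
  errs
}

#' Multiclass kernel-analysis precision at a single grid point
#'
#' One-vs-all extension of the leave-one-out error: for each category an
#' indicator response is regressed on the Gaussian kernel, its mean squared
#' leave-one-out error is normalized so that the zero predictor scores
#' exactly 1, the normalized errors are averaged over categories, and
#' precision is 1 minus that average. Predicting 0 everywhere therefore
#' yields precision exactly 0 and perfect prediction yields 1.
#'
#' @param x feature matrix (images x features).
#' @param labels category labels (factor or coercible).
#' @param lambda ridge penalty.
#' @param sigma kernel bandwidth; default is the median heuristic.
#' @return precision scalar in (-Inf, 1].
#' @export
multiclass_precision <- function(x, labels, lambda,
                                 sigma = median_heuristic_sigma(x)) {
  errs <- ka_error_surface(x, labels, lambdas = lambda, sigma_factors = 1,
                           sigma_med = sigma)
  1 - errs[1, 1]
}

#' Category-balanced bootstrap image subsets
#'
#' Draws `n_subsets` image subsets of the evaluation set, each obtained by
#' sampling `floor(frac * n / C)` images per category (so categories stay
#' equalized). The subsets are generated once from `seed` and are meant to
#' be shared across all representations being compared.
#'
#' Sampling is without replacement by default: with replacement, duplicated
#' images make the leave-one-out problem degenerate (each duplicate's twin
#' remains in the training set), inflating precision even for
#' representations carrying no category information.
#'
#' @param labels per-image category labels.
#' @param n_subsets number of bootstrap subsets.
#' @param frac fraction of images (per category) per subset.
#' @param replace sample with replacement instead (duplicates kept; the
#'   leave-one-out error then treats them as distinct examples).
#' @param seed RNG seed.
#' @return list of integer index vectors into the image rows.
#' @export
ka_subsets <- function(labels, n_subsets = 10, frac = 0.8, replace = FALSE,
                       seed = 1) {
  labels <- droplevels(as.factor(labels))
  per_cat <- floor(frac * length(labels) / nlevels(labels))
  counts <- table(labels)
  if (per_cat < 2)
    stop("category imbalance or frac too small: fewer than 2 images per category")
  if (!replace && any(counts < per_cat))
    stop("cannot equalize categories without replacement: a category is too small")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  lapply(seq_len(n_subsets), function(b) {
    unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, per_cat, replace = replace)
    }), use.names = FALSE)
  })
}

#' Kernel analysis: precision-complexity curves for a representation
#'
#' Fits Gaussian-kernel ridge regression of one-vs-all category indicators
#' over a grid of ridge penalties, computing the closed-form leave-one-out
#' error at every penalty and maximizing precision over a bandwidth scan
#' centered on the median pairwise distance. Complexity is the inverse
#' penalty `1/lambda`; precision is 1 minus the normalized mean-squared
#' leave-one-out error (0 for the zero predictor, 1 for perfect
#' prediction). The curve is bootstrapped over category-balanced image
#' subsets; the area under the mean curve on the log-complexity axis
#' (normalized by its span, see [ka_auc()]) summarizes the representation.
#'
#' @param x feature matrix (images x features).
#' @param labels per-image category labels.
#' @param lambdas decreasing vector of ridge penalties ([ka_lambda_grid()]).
#' @param sigma_factors bandwidth factors relative to the median pairwise
#'   distance ([ka_sigma_factors()]).
#' @param n_subsets,frac,replace resampling settings (see [ka_subsets()]).
#'   `n_subsets = 1, frac = 1` evaluates the plain curve.
#' @param subsets optionally, precomputed subsets from [ka_subsets()] to
#'   share bootstrap membership across representations.
#' @param seed RNG seed for subset generation.
#' @return object of class `"ka_curve"`: a list with elements `lambda`,
#'   `complexity`, `precision` (mean over subsets), `precision_sd`,
#'   `best_sigma` (bandwidth minimizing the LOO error per penalty, from the
#'   mean error surface), `per_subset` (subset x penalty precision matrix),
#'   `auc`, `auc_per_subset`, `auc_sd`, and bookkeeping fields.
#' @seealso [ka_auc()], [plot.ka_curve()]
#' @export
kernel_analysis <- function(x, labels,
                            lambdas = ka_lambda_grid(),
                            sigma_factors = ka_sigma_factors(),
                            n_subsets = 10, frac = 0.8, replace = FALSE,
                            subsets = NULL, seed = 1) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nrow(x) != length(labels)) stop("nrow(x) must match length(labels)")
  if (any(diff(lambdas) >= 0)) stop("lambdas must be strictly decreasing")
  if (nrow(unique(x)) < 2) stop("degenerate representation: all rows identical")
  if (is.null(subsets)) {
    subsets <- if (n_subsets == 1 && frac == 1 && !replace)
      list(seq_len(nrow(x)))
    else
      ka_subsets(labels, n_subsets, frac, replace, seed)
  }
  nb <- length(subsets)
  err_sum <- matrix(0, length(lambdas), length(sigma_factors))
  per_subset <- matrix(NA_real_, nb, length(lambdas))
  sigma_meds <- numeric(nb)
  for (b in seq_len(nb)) {
    idx <- subsets[[b]]
    errs <- ka_error_surface(x[idx, , drop = FALSE], labels[idx],
                             lambdas, sigma_factors)
    sigma_meds[b] <- attr(errs, "sigma_med")
    err_sum <- err_sum + errs
    per_subset[b, ] <- 1 - apply(errs, 1, min)
  }
  err_mean <- err_sum / nb
  best_j <- apply(err_mean, 1, which.min)
  precision <- colMeans(per_subset)
  out <- list(
    lambda = lambdas,
    complexity = 1 / lambdas,
    precision = precision,
    precision_sd = apply(per_subset, 2, stats::sd),
    best_sigma = sigma_factors[best_j] * mean(sigma_meds),
    best_sigma_factor = sigma_factors[best_j],
    per_subset = per_subset,
    sigma_factors = sigma_factors,
    sigma_med = mean(sigma_meds),
    subsets = subsets,
    n_images = nrow(x),
    labels = labels
  )
  out$auc_per_subset <- apply(per_subset, 1, function(p)
    trapezoid_auc(log10(out$complexity), p))
  out$auc <- mean(out$auc_per_subset)
  out$auc_sd <- stats::sd(out$auc_per_subset)
  class(out) <- "ka_curve"
  out
}

trapezoid_auc <- function(xs, ys) {
  if (length(xs) < 2) stop("at least 2 grid points are required for the AUC")
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  area <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  area / (max(xs) - min(xs))
}

#' Area under a precision-complexity curve (KA-AUC)
#'
#' Trapezoidal area of precision over `log10(complexity)`, normalized by the
#' span of the log-complexity axis, so a constant curve at precision p has
#' AUC exactly p and the AUC reads as a mean precision.
#'
#' @param curve a `"ka_curve"` object (or a list with `complexity` and
#'   `precision`).
#' @return scalar AUC.
#' @export
ka_auc <- function(curve) {
  trapezoid_auc(log10(curve$complexity), curve$precision)
}

#' @export
print.ka_curve <- function(x, ...) {
  cat("Kernel analysis curve\n")
  cat(sprintf("  images: %d, categories: %d, subsets: %d\n",
              x$n_images, nlevels(x$labels), nrow(x$per_subset)))
  cat(sprintf("  lambda grid: %d values in [%.3g, %.3g]\n",
              length(x$lambda), min(x$lambda), max(x$lambda)))
  cat(sprintf("  KA-AUC: %.4f (sd %.4f over subsets)\n", x$auc, x$auc_sd))
  invisible(x)
}

#' @export
summary.ka_curve <- function(object, ...) {
  df <- data.frame(lambda = object$lambda,
                   complexity = object$complexity,
                   precision = object$precision,
                   precision_sd = object$precision_sd,
                   best_sigma = object$best_sigma)
  structure(list(table = df, auc = object$auc, auc_sd = object$auc_sd),
            class = "summary.ka_curve")
}

#' @export
print.summary.ka_curve <- function(x, ...) {
  cat(sprintf("KA-AUC: %.4f (sd %.4f)\n", x$auc, x$auc_sd))
  n <- nrow(x$table)
  show <- unique(round(seq(1, n, length.out = min(10, n))))
  print(x$table[show, ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a precision-complexity curve
#'
#' @param x a `"ka_curve"` object.
#' @param add add to an existing plot.
#' @param col line color.
#' @param shade draw the +/- 1 sd band over bootstrap subsets.
#' @param ... passed to [graphics::lines()].
#' @export
plot.ka_curve <- function(x, add = FALSE, col = "steelblue", shade = TRUE,
                          ...) {
  lx <- log10(x$complexity)
  if (!add) {
    graphics::plot(lx, x$precision, type = "n", ylim = c(0, 1),
                   xlab = expression(log[10] * " complexity (1/" * lambda * ")"),
                   ylab = "precision (1 - normalized LOO error)")
  }
  if (shade && all(is.finite(x$precision_sd))) {
    graphics::polygon(c(lx, rev(lx)),
                      c(x$precision - x$precision_sd,
                        rev(x$precision + x$precision_sd)),
                      border = NA,
                      col = grDevices::adjustcolor(col, alpha.f = 0.25))
  }
  graphics::lines(lx, x$precision, col = col, lwd = 2, ...)
  invisible(x)
}
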