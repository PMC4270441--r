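# --- ridge regression path via one SVD, shared across sites and penalties ---

# Fit ridge regressions of every column of Y on X (both centered internally,
# intercept implicit) with a per-column penalty chosen by generalized
# cross-validation over a log-spaced grid, then predict at newx.
ridge_path_predict <- function(X, Y, newx, lambdas = 10^seq(-4, 4, length.out = 25)) {
  X <- as.matrix(X); Y <- as.matrix(Y); newx <- as.matrix(newx)
  n <- nrow(X)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm)
  Yc <- sweep(Y, 2, ym)
  sv <- svd(Xc, nu = min(n, ncol(X)), nv = min(n, ncol(X)))
  d <- sv$d
  UtY <- crossprod(sv$u, Yc)                     # r x q
  y2 <- colSums(Yc^2)
  u2 <- colSums(UtY^2)
  best_lambda <- numeric(ncol(Y))
  best_gcv <- rep(Inf, ncol(Y))
  for (lam in lambdas) {
    s <- d^2 / (d^2 + lam)
    df <- sum(s) + 1                              # +1 for the intercept
    rss <- y2 - u2 + colSums(((1 - s) * UtY)^2)
    gcv <- n * rss / (n - df)^2
    upd <- gcv < best_gcv
    best_gcv[upd] <- gcv[upd]
    best_lambda[upd] <- lam
  }
  newc <- sweep(newx, 2, xm)
  NV <- newc %*% sv$v                             # m x r
  pred <- matrix(NA_real_, nrow(newx), ncol(Y))
  for (lam in unique(best_lambda)) {
    cols <- which(best_lambda == lam)
    shrink <- d / (d^2 + lam)
    pred[, cols] <- NV %*% (shrink * UtY[, cols, drop = FALSE])
  }
  pred <- sweep(pred, 2, ym, "+")
  list(pred = pred, lambda = best_lambda)
}

#' Ridge encoding models of site responses
#'
#' Fits, per neural site, a ridge regression predicting the trial-averaged
#' site response from the model representation, on a training fraction of
#' the images, and evaluates the predictions on the held-out images. The
#' ridge penalty is selected per site by generalized cross-validation on
#' the training rows only. Repeated over `n_splits` random splits; splits
#' can be stratified (e.g. by object) and shared across representations.
#'
#' @param model_rep model feature matrix (images x features).
#' @param neural_rep neural feature matrix (images x sites), rows matched
#'   to `model_rep`.
#' @param n_splits,train_frac split settings.
#' @param lambdas candidate ridge penalties for the GCV selection.
#' @param stratify optional per-image labels (e.g. object ids) used to
#'   stratify the splits; default unstratified.
#' @param splits optional precomputed splits from [make_cv_splits()].
#' @param seed RNG seed.
#' @return object of class `"encoding_fit"`: `pred_r` (splits x sites
#'   test-set Pearson correlations), `predictions` (per split: test indices
#'   and predicted site responses, reused by [it_fit_representation()]),
#'   `lambda` (splits x sites selected penalties), `splits`.
#' @export
ridge_encode <- function(model_rep, neural_rep, n_splits = 10,
                         train_frac = 0.8,
                         lambdas = 10^seq(-4, 4, length.out = 25),
                         stratify = NULL, splits = NULL, seed = 1) {
  model_rep <- as.matrix(model_rep); neural_rep <- as.matrix(neural_rep)
  stopifnot(nrow(model_rep) == nrow(neural_rep))
  if (is.null(splits)) {
    strat <- if (is.null(stratify)) rep("all", nrow(model_rep)) else stratify
    splits <- make_cv_splits(strat, n_splits, train_frac, seed)
  }
  ns <- ncol(neural_rep)
  zero_var <- apply(neural_rep, 2, stats::sd) == 0
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance site(s): predictions undefined (NA)")
  pred_r <- lam <- matrix(NA_real_, length(splits), ns)
  predictions <- vector("list", length(splits))
  for (b in seq_along(splits)) {
    train <- splits[[b]]$train; test <- splits[[b]]$test
    fit <- ridge_path_predict(model_rep[train, , drop = FALSE],
                              neural_rep[train, , drop = FALSE],
                              model_rep[test, , drop = FALSE], lambdas)
    lam[b, ] <- fit$lambda
    for (s in seq_len(ns)) {
      if (zero_var[s] || stats::sd(fit$pred[, s]) == 0 ||
          stats::sd(neural_rep[test, s]) == 0) next
      pred_r[b, s] <- stats::cor(fit$pred[, s], neural_rep[test, s])
    }
    predictions[[b]] <- list(test = test, pred = fit$pred)
  }
  structure(list(pred_r = pred_r, lambda = lam, predictions = predictions,
                 splits = splits, n_sites = ns),
            class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat("Ridge encoding models\n")
  cat(sprintf("  %d sites, %d splits; median test r = %.3f\n",
              x$n_sites, length(x$predictions),
              stats::median(colMeans(x$pred_r), na.rm = TRUE)))
  invisible(x)
}

#' Explained explainable variance
#'
#' Normalizes a site's prediction accuracy by its own reliability ceiling:
#' `100 * pred_r^2 / ceiling_r^2`, where the ceiling is the Spearman-Brown
#' corrected split-half self-consistency of the site over trials. Sites
#' with a non-positive ceiling are excluded (NA) with a warning. Values can
#' exceed 100 by sampling error; overshoot is reported, not clipped.
#'
#' @param pred_r per-site test-set prediction correlations.
#' @param ceiling_r per-site Spearman-Brown corrected split-half
#'   consistencies.
#' @return per-site percentages; summarize as the median over sites (and
#'   mean over splits).
#' @export
explained_explainable <- function(pred_r, ceiling_r) {
  stopifnot(length(pred_r) == length(ceiling_r))
  bad <- !is.na(ceiling_r) & ceiling_r <= 0
  if (any(bad)) {
    warning(sum(bad), " site(s) with non-positive ceiling excluded")
    ceiling_r[bad] <- NA_real_
  }
  100 * pred_r^2 / ceiling_r^2
}

#' Average a representation over each object's image variations
#'
#' @param x feature matrix (images x features).
#' @param stimuli the matching [stimulus_set()].
#' @return matrix (objects x features), rows named and ordered by
#'   `levels(stimuli$object_id)` (49 for the default task).
#' @export
object_average <- function(x, stimuli) {
  x <- as.matrix(x)
  validate_stimulus_set(stimuli)
  stopifnot(nrow(x) == nrow(stimuli))
  objs <- levels(stimuli$object_id)
  present <- objs %in% as.character(unique(stimuli$object_id))
  if (!all(present))
    stop("object(s) without images: ", paste(objs[!present], collapse = ", "))
  out <- t(vapply(objs, function(o) {
    colMeans(x[stimuli$object_id == o, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(out) <- objs
  out
}

#' Representational dissimilarity matrix over objects
#'
#' Entries are `1 - r` where `r` is the Pearson correlation between the
#' object-averaged feature vectors of the two objects, so identical
#' profiles score 0, uncorrelated ones 1 and anti-correlated ones 2. The
#' RDM is invariant to global scalings and rotations of the feature space.
#'
#' @param object_matrix objects x features matrix from [object_average()].
#' @return symmetric matrix of class `"rdm"` with zero diagonal.
#' @export
compute_rdm <- function(object_matrix) {
  object_matrix <- as.matrix(object_matrix)
  if (nrow(object_matrix) < 3) stop("at least 3 objects are required")
  sds <- apply(object_matrix, 1, stats::sd)
  if (any(sds == 0)) {
    nm <- rownames(object_matrix) %||% as.character(seq_along(sds))
    stop("constant object vector(s), correlation undefined: ",
         paste(nm[sds == 0], collapse = ", "))
  }
  rdm <- 1 - stats::cor(t(object_matrix))
  rdm[rdm < 0] <- 0  # numerical guard; entries live in [0, 2]
  diag(rdm) <- 0
  rdm <- (rdm + t(rdm)) / 2
  class(rdm) <- c("rdm", "matrix")
  rdm
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d x %d objects, entries in [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x[upper.tri(x)])))
  invisible(x)
}

#' Spearman similarity between two RDMs
#'
#' Spearman rank correlation over the strictly-upper-triangular entries of
#' the two matrices (1176 values for 49 objects). Rank correlation makes
#' the comparison invariant to any monotone transform of either RDM's
#' entries.
#'
#' @param a,b square dissimilarity matrices with identical object ordering.
#' @return Spearman rho.
#' @export
rdm_similarity <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!all(dim(a) == dim(b))) stop("RDM size mismatch")
  ut <- upper.tri(a)
  stats::cor(a[ut], b[ut], method = "spearman")
}

#' Split-half RDM consistency of a neural representation
#'
#' Noise ceiling for RDM comparisons: the sites are split into two random
#' disjoint halves, an object-level RDM is computed from each half on a
#' held-out test fraction of the images, and the Spearman similarity of the
#' two half-RDMs is recorded, over `n_repeats` random site groupings
#' crossed with `n_splits` image splits.
#'
#' @param neural_rep neural feature matrix (images x sites), >= 2 sites.
#' @param stimuli the matching [stimulus_set()].
#' @param n_repeats random site groupings.
#' @param n_splits image splits; test fraction `1 - train_frac`.
#' @param train_frac fraction of images excluded from the RDM (kept to
#'   mirror the encoding-model splits).
#' @param splits optional precomputed object-stratified splits.
#' @param seed RNG seed.
#' @return list with `rho` (n_repeats x n_splits), `mean`, `sd`.
#' @export
split_half_rdm_consistency <- function(neural_rep, stimuli, n_repeats = 50,
                                       n_splits = 10, train_frac = 0.8,
                                       splits = NULL, seed = 1) {
  neural_rep <- as.matrix(neural_rep)
  if (ncol(neural_rep) < 2) stop("at least 2 sites are required")
  validate_stimulus_set(stimuli)
  if (is.null(splits))
    splits <- make_cv_splits(stimuli$object_id, n_splits, train_frac, seed)
  rng <- local_rng(seed + 13L)
  on.exit(rng(), add = TRUE)
  ns <- ncol(neural_rep)
  half <- ns %/% 2L
  rho <- matrix(NA_real_, n_repeats, length(splits))
  for (k in seq_len(n_repeats)) {
    idx <- sample.int(ns)
    g1 <- idx[seq_len(half)]
    g2 <- idx[(half + 1L):(2L * half)]
    for (b in seq_along(splits)) {
      test <- splits[[b]]$test
      sub_stim <- stimuli[test, , drop = FALSE]
      r1 <- compute_rdm(object_average(neural_rep[test, g1, drop = FALSE], sub_stim))
      r2 <- compute_rdm(object_average(neural_rep[test, g2, drop = FALSE], sub_stim))
      rho[k, b] <- rdm_similarity(r1, r2)
    }
  }
  list(rho = rho, mean = mean(rho), sd = stats::sd(as.vector(rho)))
}

#' "+IT-fit" representation: RDMs from cross-validated site predictions
#'
#' For each object-stratified image split, ridge encoding models of every
#' site are estimated on the training images and their predictions on the
#' held-out test images form a new representation; the object-level RDM is
#' computed from those held-out predictions only, so the images used to fit
#' the encoding models never enter the RDM.
#'
#' @param model_rep model feature matrix (images x features).
#' @param neural_rep neural feature matrix (images x sites) being
#'   predicted.
#' @param stimuli the matching [stimulus_set()].
#' @param n_splits,train_frac,lambdas,seed see [ridge_encode()].
#' @param splits optional precomputed object-stratified splits (shared so
#'   the test images are identical for all RDM calculations).
#' @return list with `rdms` (one `"rdm"` per split), `splits`, and the
#'   underlying `"encoding_fit"`.
#' @export
it_fit_representation <- function(model_rep, neural_rep, stimuli,
                                  n_splits = 10, train_frac = 0.8,
                                  lambdas = 10^seq(-4, 4, length.out = 25),
                                  splits = NULL, seed = 1) {
  validate_stimulus_set(stimuli)
  if (is.null(splits))
    splits <- make_cv_splits(stimuli$object_id, n_splits, train_frac, seed)
  for (sp in splits) {
    miss <- setdiff(levels(stimuli$object_id),
                    as.character(stimuli$object_id[sp$test]))
    if (length(miss))
      stop("object(s) absent from a test split (splits must be object-stratified): ",
           paste(miss, collapse = ", "))
  }
  fit <- ridge_encode(model_rep, neural_rep, splits = splits,
                      lambdas = lambdas, seed = seed)
  rdms <- lapply(fit$predictions, function(p) {
    compute_rdm(object_average(p$pred, stimuli[p$test, , drop = FALSE]))
  })
  list(rdms = rdms, splits = splits, encoding = fit)
}

#' Read / write RDMs as square CSV with object-id headers
#'
#' @param rdm an `"rdm"` matrix; `path` a file path.
#' @export
write_rdm <- function(rdm, path) {
  utils::write.csv(as.data.frame(unclass(rdm)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  class(m) <- c("rdm", "matrix")
  m
}
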