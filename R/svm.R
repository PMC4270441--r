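#' Stratified train/test splits shared across representations
#'
#' Draws `n_splits` category-stratified splits of the images into a
#' training fraction and a held-out test fraction. Generated once from the
#' seed, the splits can be passed to [svm_decoding()] (and reused for every
#' representation) so all representations are evaluated on identical image
#' partitions.
#'
#' @param labels per-image category (or stratification) labels.
#' @param n_splits number of random splits.
#' @param train_frac fraction of images (per stratum) used for training.
#' @param seed RNG seed.
#' @return list of lists with integer elements `train` and `test`.
#' @export
make_cv_splits <- function(labels, n_splits = 10, train_frac = 0.8, seed = 1) {
  labels <- droplevels(as.factor(labels))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  lapply(seq_len(n_splits), function(b) {
    train <- unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      n_tr <- round(train_frac * length(idx))
      if (n_tr < 1 || n_tr >= length(idx))
        stop("train_frac leaves an empty train or test stratum")
      sample(idx, n_tr)
    }), use.names = FALSE)
    list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
  })
}

# one-vs-all linear SVM: fit one binary machine per class, classify by the
# largest decision value for the positive class
fit_ova_svm <- function(x, labels, cost) {
  lapply(levels(labels), function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  })
}

predict_ova_svm <- function(fits, labels_levels, newx) {
  scores <- vapply(fits, function(fit) {
    dv <- attr(stats::predict(fit, newx, decision.values = TRUE),
               "decision.values")
    # orient so larger means more "pos"
    if (grepl("^pos/", colnames(dv)[1])) drop(dv) else -drop(dv)
  }, numeric(nrow(newx)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  factor(labels_levels[max.col(scores, ties.method = "first")],
         levels = labels_levels)
}

# accuracy of a one-vs-all (or one-vs-one) linear SVM with the given cost,
# trained on train rows, evaluated on test rows
svm_split_accuracy <- function(x, labels, train, test, cost, scheme) {
  if (scheme == "ova") {
    fits <- fit_ova_svm(x[train, , drop = FALSE], droplevels(labels[train]),
                        cost)
    pred <- predict_ova_svm(fits, levels(droplevels(labels[train])),
                            x[test, , drop = FALSE])
  } else {
    fit <- e1071::svm(x[train, , drop = FALSE], droplevels(labels[train]),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- stats::predict(fit, x[test, , drop = FALSE])
  }
  mean(as.character(pred) == as.character(labels[test]))
}

#' Cross-validated linear-SVM decoding accuracy
#'
#' Confirmatory decoding analysis: a linear support-vector classifier is
#' trained on a stratified 80% of the images and tested on the held-out
#' 20%, repeated over `n_splits` random splits. The regularization cost is
#' chosen per split by internal k-fold cross-validation on the training
#' rows only (no test-set leakage). Chance level for a balanced C-way task
#' is 1/C (~14.3% for 7 categories).
#'
#' @param x feature matrix (images x features).
#' @param labels per-image category labels; every category must appear in
#'   every training split.
#' @param n_splits number of train/test randomizations.
#' @param train_frac training fraction per category.
#' @param costs candidate SVM cost values (log-spaced grid).
#' @param n_folds folds of the internal cost selection.
#' @param scheme multiclass scheme: `"ova"` (one-vs-all, default) or
#'   `"ovo"` (one-vs-one, the libsvm native scheme).
#' @param splits optional precomputed splits from [make_cv_splits()],
#'   shared across representations.
#' @param seed RNG seed for split generation.
#' @return object of class `"svm_decoding"`: list with `accuracy` (per
#'   split), `mean`, `sd`, `chance`, `best_cost` per split, `splits`.
#' @export
svm_decoding <- function(x, labels, n_splits = 10, train_frac = 0.8,
                         costs = 10^seq(-4, 2, length.out = 7),
                         n_folds = 5, scheme = c("ova", "ovo"),
                         splits = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  stopifnot(nrow(x) == length(labels))
  if (is.null(splits))
    splits <- make_cv_splits(labels, n_splits, train_frac, seed)
  rng <- local_rng(seed + 7L)
  on.exit(rng(), add = TRUE)
  acc <- best_cost <- numeric(length(splits))
  for (b in seq_along(splits)) {
    train <- splits[[b]]$train
    test <- splits[[b]]$test
    if (nlevels(droplevels(labels[train])) < nlevels(labels))
      stop("a category is absent from a training split")
    # internal CV over costs on the training rows only
    fold_id <- make_fold_ids(labels[train], n_folds)
    cv_acc <- vapply(costs, function(cost) {
      mean(vapply(seq_len(n_folds), function(f) {
        tr <- train[fold_id != f]
        te <- train[fold_id == f]
        svm_split_accuracy(x, labels, tr, te, cost, scheme)
      }, numeric(1)))
    }, numeric(1))
    best_cost[b] <- costs[which.max(cv_acc)]
    acc[b] <- svm_split_accuracy(x, labels, train, test, best_cost[b], scheme)
  }
  structure(list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
                 chance = 1 / nlevels(labels), n_splits = length(splits),
                 train_fraction = train_frac, best_cost = best_cost,
                 scheme = scheme, splits = splits),
            class = "svm_decoding")
}

# stratified fold assignment within a label vector
make_fold_ids <- function(labels, n_folds) {
  fold_id <- integer(length(labels))
  for (cl in levels(droplevels(labels))) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold_id
}

#' @export
print.svm_decoding <- function(x, ...) {
  cat("Linear-SVM decoding\n")
  cat(sprintf("  accuracy: %.1f%% (sd %.1f%%) over %d splits; chance %.1f%%\n",
              100 * x$mean, 100 * x$sd, x$n_splits, 100 * x$chance))
  invisible(x)
}
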