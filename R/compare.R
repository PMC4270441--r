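#' Read / write feature matrices as CSV
#'
#' Images as rows, one column per feature, header row of feature ids.
#'
#' @param x feature matrix; `path` a file path; `kind` feature kind tag
#'   (`"model"`, `"neural_multiunit"`, `"neural_singleunit"`).
#' @export
write_feature_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(as.matrix(x)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, kind = "model") {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (!all(is.finite(m))) stop("feature matrix contains non-finite values")
  attr(m, "feature_kind") <- kind
  m
}

#' Read / write trial tensors as long-format CSV
#'
#' Plain-text round trip for trial tensors: columns `site`, `image`,
#' `trial`, `count`, plus per-site `blank_rate` repeated on each row and
#' the window bounds stored on the first row.
#'
#' @param tensor a [trial_tensor()]; `path` a file path.
#' @export
write_trial_tensor <- function(tensor, path) {
  d <- dim(tensor)
  grid <- expand.grid(site = seq_len(d[1]), image = seq_len(d[2]),
                      trial = seq_len(d[3]))
  grid$count <- as.vector(unclass(tensor))
  grid$blank_rate <- attr(tensor, "blank_rate")[grid$site]
  win <- attr(tensor, "window")
  grid$window_start <- c(win[1], rep(NA, nrow(grid) - 1))
  grid$window_end <- c(win[2], rep(NA, nrow(grid) - 1))
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_tensor
#' @export
read_trial_tensor <- function(path) {
  df <- utils::read.csv(path)
  ns <- max(df$site); ni <- max(df$image); nt <- max(df$trial)
  counts <- array(NA_real_, c(ns, ni, nt))
  counts[cbind(df$site, df$image, df$trial)] <- df$count
  blank <- vapply(seq_len(ns), function(s) df$blank_rate[df$site == s][1],
                  numeric(1))
  trial_tensor(counts, blank_rate = blank,
               window = c(df$window_start[1], df$window_end[1]))
}

#' Run the full representation-comparison workflow
#'
#' For each representation: model representations are subsampled to
#' `n_features` columns and noise-matched to the neural noise model
#' (neural representations are subsampled only; no noise is added to
#' them), then evaluated by kernel analysis (precision-complexity curve
#' and KA-AUC), cross-validated linear-SVM decoding, and object-level RDM
#' similarity to a reference representation. Bootstrap subsets, SVM splits
#' and RDM image splits are generated once from `seed` and shared across
#' all representations.
#'
#' @param representations named list of feature matrices (images x
#'   features). Attribute `feature_kind` starting with `"neural"` marks a
#'   representation as neural (exempt from noise injection); anything else
#'   is treated as a model.
#' @param stimuli the common [stimulus_set()].
#' @param noise_model optional `"noise_model"`; when supplied, model
#'   representations are noise-matched before evaluation.
#' @param reference optional name of the representation whose RDM is the
#'   similarity reference (default: the first neural one, else none).
#' @param n_features sample size to equalize to (`NULL` keeps all
#'   features).
#' @param n_noise_repeats noise draws per model representation.
#' @param lambdas,sigma_factors kernel-analysis grids.
#' @param n_subsets bootstrap subsets for kernel analysis.
#' @param n_svm_splits SVM train/test randomizations.
#' @param seed master seed for all shared randomization.
#' @return list of class `"rep_comparison"`: per-representation results
#'   (`ka_auc`, `ka_auc_sd`, `svm_accuracy`, `svm_sd`, `rdm_similarity`),
#'   the full `ka` and `svm` objects, and the shared split bookkeeping.
#' @export
run_comparison <- function(representations, stimuli, noise_model = NULL,
                           reference = NULL, n_features = NULL,
                           n_noise_repeats = 10,
                           lambdas = ka_lambda_grid(),
                           sigma_factors = ka_sigma_factors(),
                           n_subsets = 10, n_svm_splits = 10, seed = 1) {
  stopifnot(is.list(representations), length(representations) >= 1,
            !is.null(names(representations)))
  validate_stimulus_set(stimuli)
  labels <- stimuli$category
  for (nm in names(representations)) {
    if (nrow(as.matrix(representations[[nm]])) != nrow(stimuli))
      stop("representation '", nm, "' does not match the stimulus set size")
  }
  subsets <- ka_subsets(labels, n_subsets, seed = seed)
  svm_splits <- make_cv_splits(labels, n_svm_splits, seed = seed + 1L)

  is_neural <- vapply(representations, function(x) {
    kind <- attr(x, "feature_kind") %||% "model"
    startsWith(kind, "neural")
  }, logical(1))
  if (is.null(reference) && any(is_neural))
    reference <- names(representations)[which(is_neural)[1]]

  prepared <- lapply(names(representations), function(nm) {
    x <- as.matrix(representations[[nm]])
    if (!is.null(n_features) && n_features < ncol(x))
      x <- subsample_features(x, n_features, seed = seed + 2L)
    if (!is_neural[[nm]] && !is.null(noise_model)) {
      noise_match(x, noise_model, n_features = ncol(x),
                  n_repeats = n_noise_repeats, seed = seed + 3L)
    } else {
      list(x)
    }
  })
  names(prepared) <- names(representations)

  ref_rdm <- if (!is.null(reference)) {
    compute_rdm(object_average(as.matrix(representations[[reference]]), stimuli))
  } else NULL

  results <- lapply(names(prepared), function(nm) {
    draws <- prepared[[nm]]
    kas <- lapply(draws, function(x)
      kernel_analysis(x, labels, lambdas = lambdas,
                      sigma_factors = sigma_factors, subsets = subsets))
    svms <- lapply(draws, function(x)
      svm_decoding(x, labels, splits = svm_splits, seed = seed + 4L))
    rdm_sim <- if (!is.null(ref_rdm) && nm != reference) {
      mean(vapply(draws, function(x)
        rdm_similarity(compute_rdm(object_average(x, stimuli)), ref_rdm),
        numeric(1)))
    } else NA_real_
    list(name = nm,
         neural = is_neural[[nm]],
         n_noise_draws = length(draws),
         ka_auc = mean(vapply(kas, function(k) k$auc, numeric(1))),
         ka_auc_sd = stats::sd(vapply(kas, function(k) k$auc, numeric(1))),
         svm_accuracy = mean(vapply(svms, function(s) s$mean, numeric(1))),
         svm_sd = stats::sd(vapply(svms, function(s) s$mean, numeric(1))),
         rdm_similarity = rdm_sim,
         ka = kas[[1]], svm = svms[[1]])
  })
  names(results) <- names(prepared)
  structure(list(results = results, reference = reference, seed = seed,
                 n_features = n_features,
                 noise_model = noise_model),
            class = "rep_comparison")
}

#' @export
print.rep_comparison <- function(x, ...) {
  cat("Representation comparison\n")
  df <- summary(x)
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.rep_comparison <- function(object, ...) {
  do.call(rbind, lapply(object$results, function(r)
    data.frame(representation = r$name, neural = r$neural,
               ka_auc = r$ka_auc, svm_accuracy = r$svm_accuracy,
               rdm_similarity = r$rdm_similarity)))
}

#' Write a comparison report as JSON
#'
#' Serializes the per-representation summary metrics, the seed, and the
#' noise model (if any) so a run is fully reproducible from the report.
#'
#' @param comparison a `"rep_comparison"`; `path` output file.
#' @export
write_comparison <- function(comparison, path) {
  out <- list(
    seed = comparison$seed,
    n_features = comparison$n_features,
    reference = comparison$reference,
    noise_model = if (!is.null(comparison$noise_model))
      comparison$noise_model[c("a", "b", "n_trials", "sigma2_signal",
                               "sigma2_noise")] else NULL,
    representations = lapply(comparison$results, function(r)
      r[c("name", "neural", "n_noise_draws", "ka_auc", "ka_auc_sd",
          "svm_accuracy", "svm_sd", "rdm_similarity")])
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
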