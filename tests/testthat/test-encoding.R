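test_that("ridge encoding recovers a planted linear map and scores nulls at zero", {
  set.seed(1)
  n <- 210
  stim <- stimulus_set(3, 2, 35, seed = 1)
  model_rep <- matrix(rnorm(n * 20), n)
  planted <- model_rep %*% matrix(rnorm(20 * 12), 20) +
    matrix(rnorm(n * 12, sd = 0.01), n)
  fit <- ridge_encode(model_rep, planted, n_splits = 3,
                      stratify = stim$object_id, seed = 2)
  expect_true(all(colMeans(fit$pred_r) > 0.99))
  # self-prediction is perfect
  self_fit <- ridge_encode(model_rep, model_rep, n_splits = 2, seed = 2)
  expect_true(all(self_fit$pred_r > 0.999))
  # independent predictor: median prediction ~ 0
  null_fit <- ridge_encode(matrix(rnorm(n * 20), n), planted, n_splits = 3, seed = 2)
  expect_lt(abs(median(colMeans(null_fit$pred_r))), 0.15)
})

test_that("penalty selection happens on training rows only", {
  set.seed(2)
  n <- 120
  x <- matrix(rnorm(n * 10), n)
  y <- cbind(x %*% rnorm(10) + rnorm(n, sd = 0.5))
  splits <- make_cv_splits(rep("all", n), 2, 0.8, seed = 3)
  fit <- ridge_encode(x, y, splits = splits, seed = 3)
  # predictions exist exactly for held-out rows
  for (b in seq_along(splits)) {
    expect_identical(fit$predictions[[b]]$test, splits[[b]]$test)
    expect_equal(nrow(fit$predictions[[b]]$pred), length(splits[[b]]$test))
  }
  # refitting on train rows alone reproduces the stored predictions
  b <- 1
  ref <- kernelrep:::ridge_path_predict(x[splits[[b]]$train, ], y[splits[[b]]$train, , drop = FALSE],
                                        x[splits[[b]]$test, ])
  expect_equal(fit$predictions[[b]]$pred, ref$pred, tolerance = 1e-10)
})

test_that("explained explainable variance normalizes by the reliability ceiling", {
  expect_equal(explained_explainable(0.6, 0.6), 100)
  expect_equal(explained_explainable(0, 0.7), 0)
  expect_equal(explained_explainable(0.3, 0.6), 25)
  expect_warning(out <- explained_explainable(c(0.5, 0.5), c(0.8, -0.1)),
                 "non-positive ceiling")
  expect_true(is.na(out[2]))

  # planted shared-variance recovery: prediction explains ~50% of the
  # explainable variance when the predictor carries half the signal
  set.seed(3)
  n_img <- 400; Tt <- 20
  shared <- rnorm(n_img); private <- rnorm(n_img)
  signal <- sqrt(0.5) * shared + sqrt(0.5) * private
  counts <- array(rep(signal, Tt), c(1, n_img, Tt)) +
    array(rnorm(n_img * Tt, sd = 0.7), c(1, n_img, Tt))
  tens <- trial_tensor(counts)
  neural <- preprocess_trials(tens)
  cons <- split_half_consistency(tens, n_repeats = 10, seed = 4)
  fit <- ridge_encode(cbind(shared, rnorm(n_img)), neural, n_splits = 4, seed = 4)
  eev <- explained_explainable(mean(fit$pred_r), cons$corrected_r)
  expect_gt(eev, 35)
  expect_lt(eev, 65)
})

test_that("object averaging produces one row per object and respects permutations", {
  stim <- stimulus_set(7, 7, 4, seed = 5)
  x <- matrix(rnorm(nrow(stim) * 6), nrow(stim))
  oa <- object_average(x, stim)
  expect_equal(dim(oa), c(49L, 6L))
  # permuting an object's images leaves its average unchanged
  perm <- order(stim$object_id, sample(nrow(stim)))
  oa2 <- object_average(x[perm, ], stim[perm, ])
  expect_equal(oa, oa2[rownames(oa), ], tolerance = 1e-12)
  # single image per object: identity selection
  stim1 <- stimulus_set(3, 2, 1, seed = 5)
  x1 <- matrix(rnorm(6 * 4), 6)
  expect_equal(unname(object_average(x1, stim1)), x1)
})

test_that("RDM entries follow the correlation-distance closed forms", {
  base <- matrix(rnorm(5 * 30), 5, 30)
  m <- rbind(base[1, ], base[1, ], -base[1, ], base[2, ], base[3, ])
  rdm <- compute_rdm(m)
  expect_equal(unname(rdm[1, 2]), 0, tolerance = 1e-12)
  expect_equal(unname(rdm[1, 3]), 2, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(rdm)))
  expect_equal(diag(rdm), rep(0, 5))
  expect_true(all(rdm >= 0 & rdm <= 2))
  bad <- rbind(rep(1, 10), rnorm(10), rnorm(10))
  rownames(bad) <- c("objA", "objB", "objC")
  expect_error(compute_rdm(bad), "objA")
  # independent high-dimensional vectors are ~ uncorrelated: entries ~ 1
  set.seed(6)
  big <- matrix(rnorm(20 * 1000), 20)
  ut <- upper.tri(diag(20))
  expect_lt(abs(mean(compute_rdm(big)[ut]) - 1), 0.05)
})

test_that("RDM similarity is a rank correlation over the upper triangle", {
  set.seed(7)
  A <- compute_rdm(matrix(rnorm(10 * 50), 10))
  expect_equal(rdm_similarity(A, A), 1)
  # monotone transforms leave the similarity at 1
  B <- unclass(A)^1.7
  expect_equal(rdm_similarity(A, B), 1)
  # independent RDMs: similarity near zero
  rhos <- vapply(1:10, function(k) {
    rdm_similarity(A, compute_rdm(matrix(rnorm(10 * 50), 10)))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 3 / sqrt(45))
  expect_error(rdm_similarity(A, compute_rdm(matrix(rnorm(8 * 50), 8))),
               "mismatch")
})

test_that("RDMs are invariant to scaling, correlation-preserving rotations and shifts", {
  set.seed(8)
  stim <- stimulus_set(7, 7, 2, seed = 8)
  x <- matrix(rnorm(nrow(stim) * 24), nrow(stim))
  oa <- object_average(x, stim)
  Q <- rotation_fixing_ones(24, seed = 9)
  shifted <- 3.1 * oa %*% Q + matrix(rnorm(49), 49, 24)[, rep(1, 24)]
  expect_equal(rdm_similarity(compute_rdm(oa), compute_rdm(shifted)), 1,
               tolerance = 1e-10)
  # a fully general rotation still leaves the RDM nearly unchanged
  Qg <- qr.Q(qr(matrix(rnorm(24^2), 24)))
  expect_gt(rdm_similarity(compute_rdm(oa), compute_rdm(oa %*% Qg)), 0.9)
})

test_that("split-half RDM consistency tracks signal content and site count", {
  # nearly noise-free, many-site recording with mild image variation: the
  # two site halves estimate the same object geometry
  cfg <- generator_config(n_objects_per_category = 7, n_images_per_object = 10,
                          n_sites = 80, n_trials = 4, noise_a = 0,
                          noise_b = 0.01, nuisance_signal = 0.3, seed = 10)
  stim <- make_stimulus_set(cfg)
  neural <- preprocess_trials(simulate_trials(make_latent_representation(stim, cfg), cfg))
  high <- split_half_rdm_consistency(neural, stim, n_repeats = 4, n_splits = 2,
                                     seed = 11)
  expect_gt(high$mean, 0.5)
  # pure-noise sites carry no shared RDM structure
  noise_rep <- matrix(rnorm(length(neural)), nrow(neural))
  null <- split_half_rdm_consistency(noise_rep, stim, n_repeats = 4,
                                     n_splits = 2, seed = 11)
  expect_lt(abs(null$mean), 0.2)
  # halving the population lowers the expected consistency
  low <- split_half_rdm_consistency(neural[, 1:10], stim, n_repeats = 4,
                                    n_splits = 2, seed = 11)
  expect_gt(high$mean, low$mean)
  expect_error(split_half_rdm_consistency(neural[, 1, drop = FALSE], stim),
               "at least 2 sites")
})

test_that("IT-fit representations are built from held-out predictions only", {
  set.seed(12)
  stim <- stimulus_set(7, 7, 5, seed = 12)
  n <- nrow(stim)
  model_rep <- make_latent_representation(stim, generator_config(
    n_objects_per_category = 7, n_images_per_object = 5, latent_dims = 30,
    seed = 12))
  # neural responses exactly linear in the model + small noise
  neural <- model_rep %*% matrix(rnorm(30 * 25), 30) +
    matrix(rnorm(n * 25, sd = 0.05), n)
  out <- it_fit_representation(model_rep, neural, stim, n_splits = 3, seed = 13)
  expect_length(out$rdms, 3)
  # reference: the neural RDM computed on the identical held-out images, so
  # the planted linear map should reproduce it almost exactly
  ref_rdm <- function(sp) compute_rdm(object_average(neural[sp$test, ],
                                                     stim[sp$test, ]))
  sims <- vapply(seq_along(out$rdms), function(b)
    rdm_similarity(out$rdms[[b]], ref_rdm(out$splits[[b]])), numeric(1))
  expect_gt(mean(sims), 0.9)
  # pure-noise model representations produce unrelated RDMs
  null_out <- it_fit_representation(matrix(rnorm(n * 30), n), neural, stim,
                                    splits = out$splits, seed = 13)
  null_sims <- vapply(seq_along(null_out$rdms), function(b)
    rdm_similarity(null_out$rdms[[b]], ref_rdm(null_out$splits[[b]])),
    numeric(1))
  expect_lt(abs(mean(null_sims)), 0.25)
  # non-stratified splits that drop an object are rejected
  bad <- make_cv_splits(rep("all", n), 1, 0.995, seed = 14)
  expect_error(it_fit_representation(model_rep, neural, stim, splits = bad),
               "absent from a test split")
})

test_that("RDMs round-trip through CSV", {
  set.seed(15)
  rdm <- compute_rdm(matrix(rnorm(6 * 20), 6,
                            dimnames = list(paste0("o", 1:6), NULL)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rdm(rdm, path)
  back <- read_rdm(path)
  expect_equal(unclass(back), unclass(rdm), tolerance = 1e-12)
})
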