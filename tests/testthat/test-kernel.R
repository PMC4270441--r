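test_that("gaussian kernel matches its closed form and is PSD", {
  x <- rbind(c(0, 0), c(1, 0))
  K <- gaussian_kernel(x, sigma = 1)
  expect_equal(K[1, 2], exp(-1 / 2))
  expect_equal(diag(K), c(1, 1))

  same <- matrix(1, 4, 3)
  expect_equal(unname(gaussian_kernel(same, 2)), matrix(1, 4, 4))

  set.seed(1)
  K <- gaussian_kernel(matrix(rnorm(100), 20, 5), 1.7)
  expect_true(isSymmetric(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(gaussian_kernel(x, 0), "positive")
})

test_that("median heuristic returns the median pairwise distance", {
  expect_equal(median_heuristic_sigma(rbind(0, 2)), 2)
  expect_equal(median_heuristic_sigma(rbind(0, 1, 3)), 2)  # distances 1,2,3
  expect_error(median_heuristic_sigma(matrix(1, 3, 2)), "identical")
  # standard-normal cloud in d dims: median distance ~ sqrt(2 d)
  set.seed(2)
  d <- 10
  sig <- median_heuristic_sigma(matrix(rnorm(100 * d), 100, d))
  expect_equal(sig, sqrt(2 * d), tolerance = 0.1)
})

test_that("closed-form LOO residuals equal explicit refit-without-i residuals", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    X <- matrix(rnorm(n * 3), n)
    y <- rnorm(n)
    K <- gaussian_kernel(X, runif(1, 0.5, 3))
    lam <- 10^runif(1, -4, 1)
    got <- loo_errors(K, y, lam)
    brute <- vapply(seq_len(n), function(i) {
      alpha <- solve(K[-i, -i] + lam * diag(n - 1), y[-i])
      y[i] - drop(K[i, -i] %*% alpha)
    }, numeric(1))
    expect_equal(got, brute, tolerance = 1e-8)
  }
})

test_that("LOO residuals approach y under heavy regularization", {
  set.seed(4)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8)
  K <- gaussian_kernel(X, 1)
  expect_equal(loo_errors(K, y, 1e12), y, tolerance = 1e-8)
  expect_error(loo_errors(K[, c(2, 1, 3:8)], y, 1), "symmetric")
})

test_that("duplicated examples with identical labels have near-zero residuals at small lambda", {
  set.seed(5)
  X <- matrix(rnorm(6 * 2), 6)
  X <- rbind(X, X)
  y <- rep(rnorm(6), 2)
  K <- gaussian_kernel(X, 1.5)
  res <- loo_errors(K, y, 1e-8)
  expect_lt(max(abs(res)), 1e-4)
})

test_that("precision conventions: zero predictor 0, perfect 1, bounded above by 1", {
  lab <- rep(letters[1:7], each = 6)
  one_hot <- 1 * outer(lab, letters[1:7], "==")
  # heavy regularization forces the zero predictor: precision exactly 0
  expect_equal(multiclass_precision(one_hot, lab, 1e12), 0, tolerance = 1e-6)
  # trivially solvable task at small lambda
  expect_gt(multiclass_precision(one_hot, lab, 1e-6), 0.95)
  # constant features carry no category information
  expect_lt(abs(multiclass_precision(matrix(1, 42, 3), lab, 1e-3, sigma = 1)), 0.1)
  # shuffled features: precision ~ 0 once sigma is optimized over its grid
  set.seed(6)
  errs <- kernelrep:::ka_error_surface(matrix(rnorm(42 * 5), 42), lab,
                                       lambdas = small_lambdas,
                                       sigma_factors = small_sigmas)
  best <- 1 - apply(errs, 1, min)
  expect_true(all(abs(best) < 0.15))
  # precision never exceeds 1
  for (k in 1:25) {
    Xr <- matrix(rnorm(28 * 4), 28)
    p <- multiclass_precision(Xr, rep(letters[1:7], each = 4), 10^runif(1, -6, 3))
    expect_lte(p, 1)
  }
})

test_that("multiclass precision validates degenerate inputs", {
  expect_error(multiclass_precision(matrix(rnorm(10), 5), c("a", "a", "a", "b", "c"), 1),
               "at least 2 examples")
  expect_error(multiclass_precision(matrix(rnorm(8), 4), rep("a", 4), 1),
               "at least 2 categories")
})

test_that("ka_curve bookkeeping: ascending complexity, feature-order invariance, plateau", {
  task <- small_task(seed = 8)
  curve <- kernel_analysis(task$latent, task$stim$category,
                           lambdas = small_lambdas, sigma_factors = small_sigmas,
                           n_subsets = 1, frac = 1, replace = FALSE)
  expect_true(all(diff(curve$complexity) > 0))
  expect_true(all(curve$precision <= 1))
  # permuting feature columns leaves the kernel, hence the curve, unchanged
  perm <- task$latent[, sample(ncol(task$latent))]
  curve2 <- kernel_analysis(perm, task$stim$category,
                            lambdas = small_lambdas, sigma_factors = small_sigmas,
                            n_subsets = 1, frac = 1, replace = FALSE)
  expect_equal(curve$precision, curve2$precision, tolerance = 1e-10)
  # sigma re-optimization keeps the high-complexity end from collapsing
  high <- tail(curve$precision, 3)
  expect_gt(min(high), max(curve$precision) - 0.35)
  expect_error(kernel_analysis(matrix(1, 20, 3), rep(letters[1:2], 10),
                               lambdas = small_lambdas), "degenerate")
})

test_that("ka_curve is invariant to rotation and translation of the feature space", {
  task <- small_task(n_obj = 2, n_img = 6, seed = 9, latent_dims = 20)
  Q <- qr.Q(qr(matrix(rnorm(400), 20)))
  moved <- task$latent %*% Q + matrix(5, nrow(task$latent), 20)
  c1 <- kernel_analysis(task$latent, task$stim$category, lambdas = small_lambdas,
                        sigma_factors = small_sigmas, n_subsets = 1, frac = 1,
                        replace = FALSE)
  c2 <- kernel_analysis(moved, task$stim$category, lambdas = small_lambdas,
                        sigma_factors = small_sigmas, n_subsets = 1, frac = 1,
                        replace = FALSE)
  expect_equal(c1$precision, c2$precision, tolerance = 1e-8)
})

test_that("high-signal representations dominate low-signal ones at every penalty", {
  stim <- small_task(seed = 10)$stim
  strong <- make_latent_representation(stim, generator_config(
    n_objects_per_category = 2, n_images_per_object = 8,
    category_signal = 5, seed = 10))
  weak <- make_latent_representation(stim, generator_config(
    n_objects_per_category = 2, n_images_per_object = 8,
    category_signal = 0.1, seed = 10))
  subsets <- ka_subsets(stim$category, 3, seed = 11)
  cs <- kernel_analysis(strong, stim$category, lambdas = small_lambdas,
                        sigma_factors = small_sigmas, subsets = subsets)
  cw <- kernel_analysis(weak, stim$category, lambdas = small_lambdas,
                        sigma_factors = small_sigmas, subsets = subsets)
  expect_true(all(cs$precision > cw$precision))
  expect_gt(cs$auc, cw$auc)
})

test_that("KA-AUC quadrature is the normalized trapezoid on log-complexity", {
  flat0 <- list(complexity = 10^seq(0, 3, length.out = 7), precision = rep(0, 7))
  expect_equal(ka_auc(flat0), 0)
  flat5 <- list(complexity = 10^seq(-2, 4, length.out = 9), precision = rep(0.5, 9))
  expect_equal(ka_auc(flat5), 0.5)
  # hand-computed piecewise-linear toy curve on log10 grid {0,1,3}
  toy <- list(complexity = c(1, 10, 1000), precision = c(0, 1, 0.5))
  expect_equal(ka_auc(toy), (0.5 * 1 + 2 * 0.75) / 3)
  expect_error(ka_auc(list(complexity = 1, precision = 0.2)), "2 grid points")
})

test_that("bootstrap subsets are category-balanced, shared and seed-stable", {
  labels <- rep(letters[1:7], each = 20)
  s1 <- ka_subsets(labels, 4, seed = 12)
  s2 <- ka_subsets(labels, 4, seed = 12)
  expect_identical(s1, s2)
  for (idx in s1) {
    tab <- table(labels[idx])
    expect_true(all(tab == tab[1]))          # equalized categories
    expect_equal(sum(tab), 7 * floor(0.8 * 20))
  }
  # degenerate bootstrap reduces to the plain curve
  task <- small_task(n_obj = 2, n_img = 6, seed = 13)
  plain <- kernel_analysis(task$latent, task$stim$category,
                           lambdas = small_lambdas, sigma_factors = small_sigmas,
                           n_subsets = 1, frac = 1, replace = FALSE)
  degenerate <- kernel_analysis(task$latent, task$stim$category,
                                lambdas = small_lambdas,
                                sigma_factors = small_sigmas,
                                subsets = list(seq_len(nrow(task$latent))))
  expect_equal(plain$precision, degenerate$precision, tolerance = 1e-12)
})

test_that("noise dimensions that dominate the signal do not raise the AUC", {
  task <- small_task(n_obj = 2, n_img = 6, seed = 14, latent_dims = 20)
  set.seed(14)
  swamped <- cbind(task$latent,
                   matrix(rnorm(nrow(task$latent) * 60, sd = 25), ncol = 60))
  subsets <- ka_subsets(task$stim$category, 3, seed = 15)
  expect_lte(quick_auc(swamped, task$stim$category, subsets),
             quick_auc(task$latent, task$stim$category, subsets) + 0.02)
})
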