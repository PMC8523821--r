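test_that("FWHM to sigma conversion follows the Gaussian definition", {
  expect_equal(fwhm_to_sigma(2 * sqrt(2 * log(2)), 1), 1.0)
  expect_equal(fwhm_to_sigma(0, 3), 0)
  expect_equal(fwhm_to_sigma(4, 4), 1 / (2 * sqrt(2 * log(2))))
  expect_error(fwhm_to_sigma(4, 0), "positive")
})

test_that("volume preprocessing smooths and block-averages correctly", {
  # constants are invariant under smoothing and averaging
  vc <- volume(array(7, c(8, 8, 8)), 2)
  out <- preprocess_volume(vc, fwhm = 4, target_res = 4)
  expect_equal(dim(out$data), c(4, 4, 4))
  expect_true(all(abs(out$data - 7) < 1e-12))
  expect_equal(out$voxel_size, c(4, 4, 4))

  # shape arithmetic: 64^3 at 2 mm -> 32^3 at 4 mm
  v <- volume(array(rnorm(16^3), c(16, 16, 16)), 2)
  expect_equal(dim(preprocess_volume(v, 4, 4)$data), c(8, 8, 8))

  # a unit impulse smooths to a symmetric kernel peaked at the impulse
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 1
  sm <- preprocess_volume(volume(a, 4), fwhm = 4, target_res = 4)$data
  expect_identical(which.max(sm), (5L - 1L) * 81L + (5L - 1L) * 9L + 5L)
  expect_equal(sm[4, 5, 5], sm[6, 5, 5])
  expect_equal(sm[5, 3, 5], sm[5, 7, 5])
  expect_equal(sum(sm), 1)  # renormalized convolution preserves mass here

  expect_error(preprocess_volume(volume(a, 3), 4, 4), "integer multiple")
  expect_error(preprocess_volume(volume(a, 4), 4, 2), "at least")
})

test_that("scanner orthogonalization removes batch structure and is idempotent", {
  fm <- age_signal_features(n_subjects = 10, noise = 0.3, seed = 2)
  fm$x <- fm$x + 3 * (fm$scanner == "B")
  orth <- orthogonalize_scanner(fm)
  dummy <- as.numeric(orth$scanner == "B")
  cors <- apply(orth$x, 2, function(col)
    if (sd(col) == 0) 0 else cor(col, dummy))
  expect_true(all(abs(cors) < 1e-10))
  twice <- orthogonalize_scanner(orth)
  expect_equal(twice$x, orth$x, tolerance = 1e-12)

  # single scanner: features are mean-centered only
  fm1 <- fm; fm1$scanner <- rep("A", length(fm1$scanner))
  out1 <- orthogonalize_scanner(fm1)
  expect_equal(out1$x, scale(fm1$x, center = TRUE, scale = FALSE),
               ignore_attr = TRUE)
})

test_that("scanner orthogonalization commutes with feature-wise scaling", {
  fm <- age_signal_features(n_subjects = 8, noise = 0.5, seed = 3)
  scale_vec <- runif(ncol(fm$x), 0.5, 2)
  fm_scaled <- fm; fm_scaled$x <- sweep(fm$x, 2, scale_vec, `*`)
  a <- orthogonalize_scanner(fm_scaled)$x
  b <- sweep(orthogonalize_scanner(fm)$x, 2, scale_vec, `*`)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("PCA basis matches an eigendecomposition oracle and handles edge cases", {
  set.seed(10)
  x <- matrix(rnorm(50), 10, 5)
  basis <- fit_pca_basis(x, k = 5)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(basis$var_explained, ev / sum(ev), tolerance = 1e-10)
  expect_equal(crossprod(basis$rotation), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(basis$var_explained) <= 1e-12))

  # full basis reconstructs exactly
  scores <- predict(basis, x)
  recon <- scores %*% t(basis$rotation) +
    matrix(basis$center, 10, 5, byrow = TRUE)
  expect_equal(recon, x, tolerance = 1e-10, ignore_attr = TRUE)

  # collinear data on a line has one informative component
  line <- outer(seq(1, 10), c(1, 2, 3))
  b1 <- fit_pca_basis(line)
  expect_equal(b1$k, 1L)
  expect_equal(b1$var_explained[1], 1, tolerance = 1e-12)

  expect_warning(bk <- fit_pca_basis(x, k = 50), "clipped")
  expect_equal(bk$k, 5L)
})

test_that("RVR interpolates a noiseless linear signal", {
  set.seed(4)
  x <- matrix(seq(-2, 2, length.out = 20), ncol = 1)
  y <- 2 * drop(x)
  fit <- rvr_fit(x, y, kernel = "linear")
  expect_lt(max(abs(predict(fit, x) - y)), 1e-6)
  # predictions at relevance vectors in particular
  rv <- fit$relevance_vectors
  if (nrow(rv) > 0)
    expect_lt(max(abs(predict(fit, rv) - 2 * drop(rv))), 1e-6)
  # duplicated input rows get identical predictions
  pr <- predict(fit, rbind(x[3, , drop = FALSE], x[3, , drop = FALSE]))
  expect_equal(pr[1], pr[2])
})

test_that("RVR posterior mean equals the ridge closed form under shared alpha", {
  set.seed(6)
  n <- 30; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(n, 0, 0.3)
  alpha <- 2.7; beta <- 4.1
  post <- rvr_posterior(X, y, alpha, beta)
  lambda <- alpha / beta
  ridge <- solve(crossprod(X) + lambda * diag(p), crossprod(X, y))
  expect_equal(post$mean, drop(ridge), tolerance = 1e-8)
})

test_that("RVR on constant response reduces to a bias-only prediction", {
  set.seed(8)
  x <- matrix(rnorm(15), ncol = 1)
  fit <- suppressWarnings(rvr_fit(x, rep(5, 15), kernel = "linear"))
  expect_equal(unname(predict(fit, x)), rep(5, 15), tolerance = 1e-4)
})

test_that("RVR marginal likelihood is non-decreasing over updates", {
  set.seed(12)
  x <- matrix(rnorm(40), ncol = 2)
  y <- x[, 1] - 0.5 * x[, 2] + rnorm(20, 0, 0.2)
  fit <- rvr_fit(x, y, kernel = "linear")
  ml <- fit$log_marginal
  expect_true(all(diff(ml) > -1e-4 * (1 + abs(ml[-length(ml)]))))
})

test_that("pruned RVR predictions agree with the unpruned model", {
  set.seed(13)
  x <- matrix(rnorm(60), ncol = 2)
  y <- 50 + 2 * x[, 1] + rnorm(30, 0, 0.5)
  pruned <- rvr_fit(x, y, kernel = "linear")
  unpruned <- rvr_fit(x, y, kernel = "linear", alpha_cap = Inf)
  expect_lt(length(pruned$relevance_index), unpruned$n_train + 1)
  expect_equal(predict(pruned, x), predict(unpruned, x), tolerance = 0.05)
})

test_that("RVR agrees with an independent relevance-vector implementation", {
  skip_if_not_installed("kernlab")
  set.seed(14)
  x <- matrix(runif(40, 40, 80), ncol = 1)
  y <- 0.5 * drop(x) + rnorm(40, 0, 0.5)
  ours <- rvr_fit(x, y, kernel = "rbf", kernel_par = 10)
  ref <- kernlab::rvm(x, y, kernel = "rbfdot",
                      kpar = list(sigma = 1 / (2 * 10^2)))
  ours_pred <- predict(ours, x)
  ref_pred <- kernlab::predict(ref, x)
  expect_gt(cor(ours_pred, ref_pred), 0.99)
  expect_lt(mean(abs(ours_pred - ref_pred)), 1)
})

test_that("RVR input validation catches malformed problems", {
  expect_error(rvr_fit(matrix(c(1, NA), 2, 1), c(1, 2)), "non-finite")
  expect_error(rvr_fit(matrix(1, 1, 1), 1), "at least 2")
  fit <- rvr_fit(matrix(rnorm(10), ncol = 1), rnorm(10))
  expect_error(predict(fit, matrix(1, 1, 3)), "dimension mismatch")
})

test_that("leave-one-subject-out folds never include the held-out subject", {
  fm <- age_signal_features(n_subjects = 8, scans_each = 3, noise = 0.5)
  est <- estimate_brainage_loso(fm, k = 3)
  expect_identical(attr(est, "leakage"), 0L)
  expect_identical(est$fold, est$subject_id)
  expect_true(all(is.finite(est$estimated_age)))
})

test_that("three-subject LOSO with age as the only feature is exact", {
  fm <- feature_matrix(matrix(c(50, 60, 70), ncol = 1),
                       scan_id = c("a", "b", "c"),
                       subject_id = c("s1", "s2", "s3"),
                       age = c(50, 60, 70), scanner = rep("A", 3))
  est <- estimate_brainage_loso(fm, k = 1)
  expect_lt(max(abs(est$estimated_age - est$age)), 1e-6)
})

test_that("LOSO recovers a strong age signal from simulated features", {
  cfg <- tiny_config(feature_dim = 30L, n_latent = 3L, feature_noise_sd = 0.1,
                     scanner_effect_size = 0.5, feature_bp_effect = 0,
                     feature_sex_effect = 0)
  d <- simulate_cohort(cfg, seed = 20)
  fm <- simulate_features(d$visits, d$subjects, cfg, seed = 20)
  fm <- orthogonalize_scanner(fm)
  est <- estimate_brainage_loso(fm, var_target = 0.95)
  expect_gt(cor(est$estimated_age, est$age), 0.9)
})

test_that("bias correction leaves BrainAGE uncorrelated with age", {
  set.seed(16)
  age <- runif(100, 45, 75)
  # perfect estimates give identically zero BrainAGE
  expect_equal(bias_correct(age, age), rep(0, 100), tolerance = 1e-12)
  # any affine distortion of age is absorbed by the correction
  expect_equal(bias_correct(3 + 0.8 * age, age), rep(0, 100),
               tolerance = 1e-10)
  est <- age + rnorm(100, 0, 2) + 0.1 * (age - 60)
  ba <- bias_correct(est, age)
  expect_lt(abs(cor(ba, age)), 1e-10)
  expect_error(bias_correct(c(1, 2, 3), rep(50, 3)), "zero variance")
})

test_that("diagnostics report MAD and post-correction age correlation", {
  age <- seq(50, 70, length.out = 21)
  expect_equal(brainage_diagnostics(age, age)$mad, 0)
  expect_equal(brainage_diagnostics(age + 1.26, age)$mad, 1.26)
  # correlation cross-checked against the covariance formula on a toy sample
  est <- c(51, 53, 50, 57, 60)
  a5 <- c(50, 52, 54, 56, 58)
  ba <- bias_correct(est, a5)
  r_oracle <- sum((ba - mean(ba)) * (a5 - mean(a5))) /
    sqrt(sum((ba - mean(ba))^2) * sum((a5 - mean(a5))^2))
  expect_equal(brainage_diagnostics(est, a5)$cor_age, r_oracle,
               tolerance = 1e-10)
})
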