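#' Construct a 3-D volume
#'
#' Minimal container for a gray-matter intensity grid with isotropic or
#' anisotropic voxel sizes in mm.
#'
#' @param data 3-D numeric array of finite intensities.
#' @param voxel_size voxel edge length(s) in mm, length 1 or 3.
#' @return object of class `"volume"`.
#' @export
volume <- function(data, voxel_size = 1) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3-D array")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  structure(list(data = data, voxel_size = voxel_size), class = "volume")
}

#' @exportS3Method base::print
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s voxels at %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' Convert a Gaussian FWHM to a kernel SD in voxel units
#'
#' `sigma = fwhm / (2 sqrt(2 ln 2) * voxel)`.
#'
#' @param fwhm full width at half maximum, mm (>= 0).
#' @param voxel voxel size, mm (> 0).
#' @return kernel standard deviation in voxels.
#' @export
fwhm_to_sigma <- function(fwhm, voxel = 1) {
  if (any(voxel <= 0)) stop("voxel size must be positive")
  if (any(fwhm < 0)) stop("fwhm must be non-negative")
  fwhm / (2 * sqrt(2 * log(2)) * voxel)
}

# 1-D Gaussian convolution along the first dimension of a matrix, with
# edge renormalization so constants are preserved exactly.
smooth_matrix_cols <- function(mat, sigma) {
  n <- nrow(mat)
  if (sigma <= 0 || n == 1L) return(mat)
  r <- max(1L, ceiling(4 * sigma))
  offs <- (-r):r
  g <- dnorm(offs, sd = sigma)
  K <- matrix(0, n, n)
  for (j in seq_along(offs)) {
    o <- offs[j]
    idx <- seq_len(n)
    tgt <- idx + o
    ok <- tgt >= 1 & tgt <= n
    K[cbind(idx[ok], tgt[ok])] <- K[cbind(idx[ok], tgt[ok])] + g[j]
  }
  K <- K / rowSums(K)
  K %*% mat
}

smooth_along_dim <- function(arr, sigma, dim_index) {
  d <- dim(arr)
  perm <- c(dim_index, setdiff(1:3, dim_index))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[dim_index])
  m <- smooth_matrix_cols(m, sigma)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

#' Smooth and resample a volume
#'
#' Applies separable Gaussian smoothing at the given FWHM (kernel SD derived
#' per axis from the voxel size) followed by block-mean downsampling to the
#' target resolution.  The target must be an integer multiple of the source
#' voxel size on every axis so that resampling is an exact block average.
#'
#' @param vol a [volume()].
#' @param fwhm smoothing kernel FWHM, mm (default 4).
#' @param target_res target voxel size, mm (default 4).
#' @return smoothed, downsampled [volume()] with voxel size `target_res`.
#' @export
preprocess_volume <- function(vol, fwhm = 4, target_res = 4) {
  stopifnot(inherits(vol, "volume"))
  if (any(target_res < vol$voxel_size))
    stop("target resolution must be at least the source voxel size")
  factor <- target_res / vol$voxel_size
  if (any(abs(factor - round(factor)) > 1e-8))
    stop("target resolution must be an integer multiple of the voxel size")
  factor <- as.integer(round(factor))
  a <- vol$data
  for (ax in 1:3) {
    sig <- fwhm_to_sigma(fwhm, vol$voxel_size[ax])
    a <- smooth_along_dim(a, sig, ax)
  }
  d <- dim(a)
  if (any(d %% factor != 0))
    stop("grid dimensions must be divisible by the resampling factor")
  nd <- d %/% factor
  # block mean via successive dimension folding
  out <- a
  for (ax in 1:3) {
    f <- factor[ax]
    if (f == 1L) next
    dd <- dim(out)
    perm <- c(ax, setdiff(1:3, ax))
    b <- aperm(out, perm)
    m <- matrix(b, nrow = dd[ax])
    m <- rowsum(m, group = rep(seq_len(dd[ax] %/% f), each = f)) / f
    b <- array(m, dim = c(dd[ax] %/% f, dd[perm][-1]))
    out <- aperm(b, order(perm))
  }
  volume(out, rep_len(target_res, 3L))
}

#' Read a NIfTI volume (optional helper)
#'
#' Thin wrapper over `RNifti::readNifti()` returning a [volume()].
#'
#' @param path path to a NIfTI file.
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package")
  img <- RNifti::readNifti(path)
  volume(array(as.numeric(img), dim = dim(img)[1:3]),
         RNifti::pixdim(img)[1:3])
}

#' Orthogonalize features with respect to scanner
#'
#' Replaces every feature by its residual from a regression on scanner
#' indicators plus intercept, removing additive scanner/protocol batch
#' effects.  Residual features are exactly uncorrelated with every scanner
#' dummy, and the operation is idempotent.
#'
#' @param fm a [feature_matrix()].
#' @return a [feature_matrix()] with residualized features.
#' @export
orthogonalize_scanner <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  scanner <- factor(fm$scanner)
  if (any(table(scanner) == 0))
    stop("scanner label set contains an empty group")
  X <- if (nlevels(scanner) == 1L) matrix(1, nrow(fm$x), 1) else
    model.matrix(~scanner)
  qrX <- qr(X)
  res <- fm$x - X %*% qr.coef(qrX, fm$x)
  rownames(res) <- fm$scan_id
  fm$x <- res
  fm
}

#' Fit a PCA basis on training scans
#'
#' Principal-component reduction of the feature matrix (centered, unscaled).
#' The number of retained components is either fixed via `k` or chosen as
#' the smallest number explaining `var_target` of the training variance,
#' capped at `n - 2`.
#'
#' @param x numeric matrix (scans x features) or a [feature_matrix()].
#' @param k number of components; overrides `var_target` when given.  Values
#'   above `min(n - 1, p)` are clipped with a warning.
#' @param var_target fraction of variance to retain when `k` is `NULL`
#'   (default 0.95).
#' @return object of class `"pca_basis"`: `center`, `rotation`, `k`,
#'   `var_explained` (all components' fractions).
#' @export
fit_pca_basis <- function(x, k = NULL, var_target = 0.95) {
  if (inherits(x, "feature_matrix")) x <- x$x
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("need at least 2 scans to fit a PCA basis")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  kmax <- min(n - 1L, p)
  if (is.null(k)) {
    k <- which(cumsum(frac) >= var_target - 1e-12)[1]
    if (is.na(k)) k <- kmax
    k <- min(k, max(1L, n - 2L))
  } else {
    if (k > kmax) {
      warning("k = ", k, " exceeds min(n-1, p) = ", kmax, "; clipped")
      k <- kmax
    }
  }
  k <- max(1L, as.integer(k))
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 k = k, var_explained = frac),
            class = "pca_basis")
}

#' Project scans onto a fitted PCA basis
#'
#' @param object a `"pca_basis"` from [fit_pca_basis()].
#' @param newdata matrix of scans (rows) in the original feature space.
#' @param ... unused.
#' @return score matrix (scans x k).
#' @export
predict.pca_basis <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, object$center) %*% object$rotation
}

## ---- relevance vector regression -------------------------------------

rvr_kernel <- function(A, B, kernel, kernel_par) {
  switch(kernel,
         linear = A %*% t(B),
         rbf = {
           width <- kernel_par %||% 1
           d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
           exp(-pmax(d2, 0) / (2 * width^2))
         },
         poly = {
           degree <- kernel_par %||% 2
           (1 + A %*% t(B))^degree
         },
         stop("unknown kernel: ", kernel))
}

#' Posterior of the relevance-vector-regression weight vector
#'
#' For a fixed design `Phi`, per-weight precisions `alpha` and noise
#' precision `beta`, the Gaussian weight posterior has covariance
#' `Sigma = (diag(alpha) + beta Phi'Phi)^-1` and mean
#' `mu = beta Sigma Phi' y`.  With a single shared `alpha` this mean is the
#' ridge-regression solution with penalty `lambda = alpha / beta`.
#'
#' @param Phi design matrix (n x m basis functions).
#' @param y numeric response.
#' @param alpha per-weight precision(s), recycled to `ncol(Phi)`.
#' @param beta noise precision.
#' @return list with `mean`, `cov`, `gamma` (per-weight well-determinedness).
#' @export
rvr_posterior <- function(Phi, y, alpha, beta) {
  m <- ncol(Phi)
  alpha <- rep_len(alpha, m)
  A <- diag(alpha, m, m)
  H <- A + beta * crossprod(Phi)
  ch <- tryCatch(chol(H), error = function(e) chol(H + diag(1e-10 * max(diag(H)), m)))
  Sigma <- chol2inv(ch)
  mu <- beta * Sigma %*% crossprod(Phi, y)
  gamma <- 1 - alpha * diag(Sigma)
  list(mean = drop(mu), cov = Sigma, gamma = gamma,
       logdetH = 2 * sum(log(diag(ch))))
}

#' Fit a relevance vector regression model
#'
#' Sparse Bayesian kernel regression: basis functions are a bias column plus
#' one kernel function per training point, weights get independent zero-mean
#' Gaussian priors with precisions `alpha_i`, and the hyperparameters are
#' optimized by type-II maximum likelihood with the fixed-point updates
#' `alpha_i <- gamma_i / mu_i^2` and
#' `beta <- (n - sum(gamma)) / ||y - Phi mu||^2`, where
#' `gamma_i = 1 - alpha_i Sigma_ii`.  Basis functions whose `alpha` exceeds
#' `alpha_cap` are pruned (the bias column is never pruned); training points
#' whose kernel function survives are the relevance vectors.
#'
#' @param X numeric matrix of training inputs (rows = scans).
#' @param y numeric response (ages, years).
#' @param kernel `"linear"`, `"rbf"` or `"poly"`.
#' @param kernel_par RBF width or polynomial degree.
#' @param tol convergence tolerance on `max |delta log alpha|`.
#' @param max_iter maximum update iterations.
#' @param alpha_cap pruning threshold on `alpha`.
#' @param beta_cap upper bound on the noise precision (guards the noiseless
#'   limit).
#' @return object of class `"rvr_model"`.
#' @export
rvr_fit <- function(X, y, kernel = c("linear", "rbf", "poly"),
                    kernel_par = NULL, tol = 1e-6, max_iter = 1000L,
                    alpha_cap = 1e12, beta_cap = 1e14) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training points")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in training inputs")
  if (length(y) != n) stop("length(y) must equal nrow(X)")

  K <- rvr_kernel(X, X, kernel, kernel_par)
  Phi_full <- cbind(bias = 1, K)
  active <- seq_len(n + 1L)             # column 1 is the bias
  vy <- var(y)
  beta <- if (vy > 0) 10 / vy else 1
  alpha <- rep(1e-4, n + 1L)
  logml <- numeric(0)
  converged <- FALSE
  it <- 0L

  for (it in seq_len(max_iter)) {
    Phi <- Phi_full[, active, drop = FALSE]
    post <- rvr_posterior(Phi, y, alpha[active], beta)
    mu <- post$mean
    gamma <- post$gamma
    rss <- sum((y - Phi %*% mu)^2)

    # marginal log-likelihood (Woodbury form)
    logdetC <- -n * log(beta) + post$logdetH - sum(log(alpha[active]))
    # stable form of y' C^-1 y (avoids cancellation at large beta)
    quad <- beta * rss + sum(alpha[active] * mu^2)
    logml <- c(logml, -0.5 * (n * log(2 * pi) + logdetC + quad))

    alpha_new <- alpha
    alpha_new[active] <- pmax(gamma, 1e-12) / pmax(mu^2, 1e-300)
    ng <- n - sum(gamma)
    beta_new <- if (ng > 1e-8) min(ng / max(rss, 1e-300), beta_cap) else
      min(beta * 10, beta_cap)  # fully determined fit: drive noise to zero

    keep <- alpha_new[active] < alpha_cap
    keep[1] <- TRUE                      # bias never pruned (active[1] == 1)
    delta <- max(abs(log(pmax(alpha_new[active][keep], 1e-300)) -
                       log(pmax(alpha[active][keep], 1e-300))))
    alpha <- alpha_new
    beta <- beta_new
    active <- active[keep]
    if (delta < tol) { converged <- TRUE; break }
  }

  # The marginal likelihood can be flat in beta when the surviving basis can
  # interpolate y (small n, noiseless signal); the fixed-point update then
  # stalls at an arbitrary noise level.  Tie-break along the flat ridge by
  # escalating beta while the marginal likelihood does not decrease.
  eval_logml <- function(alpha_act, beta, Phi) {
    post <- rvr_posterior(Phi, y, alpha_act, beta)
    rss <- sum((y - Phi %*% post$mean)^2)
    logdetC <- -n * log(beta) + post$logdetH - sum(log(alpha_act))
    quad <- beta * rss + sum(alpha_act * post$mean^2)
    list(logml = -0.5 * (n * log(2 * pi) + logdetC + quad), post = post,
         rss = rss)
  }
  Phi <- Phi_full[, active, drop = FALSE]
  cur <- eval_logml(alpha[active], beta, Phi)
  while (beta < beta_cap && cur$rss > 0) {
    beta_try <- min(beta * 10, beta_cap)
    alpha_try <- alpha[active]
    for (j in seq_len(100)) {
      p_try <- rvr_posterior(Phi, y, alpha_try, beta_try)
      alpha_new <- pmax(p_try$gamma, 1e-12) / pmax(p_try$mean^2, 1e-300)
      moved <- max(abs(log(alpha_new) - log(pmax(alpha_try, 1e-300))))
      alpha_try <- alpha_new
      if (moved < tol) break
    }
    try_fit <- eval_logml(alpha_try, beta_try, Phi)
    # accept only while the likelihood holds and the fit keeps improving;
    # a real noise level rejects immediately, numerical breakdown too
    if (try_fit$logml >= cur$logml - 1e-4 * (1 + abs(cur$logml)) &&
        try_fit$rss < cur$rss) {
      beta <- beta_try
      alpha[active] <- alpha_try
      cur <- try_fit
    } else break
  }
  post <- cur$post
  rel_idx <- active[active > 1L] - 1L    # training-point indices
  if (length(rel_idx) == 0L && length(active) == 1L)
    warning("no kernel basis functions survived pruning; bias-only model")
  structure(list(kernel = kernel, kernel_par = kernel_par,
                 relevance_index = rel_idx,
                 relevance_vectors = X[rel_idx, , drop = FALSE],
                 weights = post$mean[-1],
                 bias = post$mean[1],
                 alpha = alpha[active], beta = beta,
                 n_train = n, n_iter = it, converged = converged,
                 log_marginal = logml),
            class = "rvr_model")
}

#' @exportS3Method base::print
print.rvr_model <- function(x, ...) {
  cat(sprintf("<rvr_model> kernel %s, %d/%d relevance vectors, beta %.3g, %s in %d iterations\n",
              x$kernel, length(x$relevance_index), x$n_train, x$beta,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Predict ages from a fitted RVR model
#'
#' Kernel expansion over the relevance vectors plus the bias term.
#'
#' @param object an `"rvr_model"`.
#' @param newdata matrix of inputs with the training feature dimension.
#' @param ... unused.
#' @return numeric vector of predictions (years).
#' @export
predict.rvr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (length(object$relevance_index) == 0L)
    return(rep(object$bias, nrow(newdata)))
  if (ncol(newdata) != ncol(object$relevance_vectors))
    stop("feature dimension mismatch: model expects ",
         ncol(object$relevance_vectors), " features")
  K <- rvr_kernel(newdata, object$relevance_vectors, object$kernel,
                  object$kernel_par)
  drop(K %*% object$weights) + object$bias
}

#' Leave-one-subject-out brain-age estimation
#'
#' For every subject, a PCA basis and RVR model are refit on all other
#' subjects' scans and the held-out subject's scans are predicted by that
#' model, so no scan ever contributes to its own training fold.  All scans
#' of a subject are held out together, which avoids leaking within-subject
#' information across repeated scans.
#'
#' @param fm a [feature_matrix()] (typically scanner-orthogonalized first).
#' @param k,var_target PCA dimension controls, see [fit_pca_basis()].
#' @param kernel,kernel_par,tol,max_iter RVR controls, see [rvr_fit()].
#' @return object of class `"brainage_estimates"`: a data frame with
#'   `scan_id`, `subject_id`, `age`, `estimated_age`, `fold`; attribute
#'   `leakage` counts self-inclusions across folds (always 0).
#' @export
estimate_brainage_loso <- function(fm, k = NULL, var_target = 0.95,
                                   kernel = "linear", kernel_par = NULL,
                                   tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(fm, "feature_matrix"))
  subjects <- unique(fm$subject_id)
  if (length(subjects) < 3L) stop("need at least 3 subjects for LOSO")
  counts <- table(fm$subject_id)
  if (any(counts == 0)) stop("subject with zero scans")
  est <- rep(NA_real_, nrow(fm$x))
  leakage <- 0L
  for (s in subjects) {
    test <- fm$subject_id == s
    train <- !test
    leakage <- leakage + sum(test & train)
    basis <- fit_pca_basis(fm$x[train, , drop = FALSE], k = k,
                           var_target = var_target)
    scores_train <- predict(basis, fm$x[train, , drop = FALSE])
    scores_test <- predict(basis, fm$x[test, , drop = FALSE])
    model <- rvr_fit(scores_train, fm$age[train], kernel = kernel,
                     kernel_par = kernel_par, tol = tol, max_iter = max_iter)
    est[test] <- predict(model, scores_test)
  }
  out <- data.frame(scan_id = fm$scan_id, subject_id = fm$subject_id,
                    age = fm$age, estimated_age = est,
                    fold = fm$subject_id, stringsAsFactors = FALSE)
  structure(out, class = c("brainage_estimates", "data.frame"),
            leakage = leakage)
}

#' Age-bias correction of brain-age estimates
#'
#' The raw gap (estimated minus chronological age) is regressed on
#' chronological age over the full estimation sample and the residual is the
#' final BrainAGE score, which is uncorrelated with age by construction.
#' A positive BrainAGE means an older-appearing brain.
#'
#' @param estimated numeric vector of estimated ages, or a
#'   `"brainage_estimates"` data frame (then `age` may be omitted).
#' @param age chronological ages, years.
#' @return if given a data frame, the same frame with a `brainage` column;
#'   otherwise the numeric BrainAGE vector.
#' @export
bias_correct <- function(estimated, age = NULL) {
  if (is.data.frame(estimated)) {
    df <- estimated
    ba <- bias_correct(df$estimated_age, df$age)
    df$brainage <- ba
    return(df)
  }
  if (length(estimated) < 3L) stop("need at least 3 estimates")
  if (sd(age) == 0) stop("zero variance in age; bias correction undefined")
  gap <- estimated - age
  unname(resid(lm(gap ~ age)))
}

#' Brain-age estimation diagnostics
#'
#' Reports the mean absolute deviation between estimated and chronological
#' age (before bias correction) and the correlation of the bias-corrected
#' BrainAGE with age (zero to numerical tolerance by construction).
#'
#' @param estimated estimated ages (or a `"brainage_estimates"` frame).
#' @param age chronological ages.
#' @param brainage optional bias-corrected scores; computed if missing.
#' @return list with `mad` (years) and `cor_age`.
#' @export
brainage_diagnostics <- function(estimated, age = NULL, brainage = NULL) {
  if (is.data.frame(estimated)) {
    age <- estimated$age
    brainage <- estimated$brainage
    estimated <- estimated$estimated_age
  }
  if (!length(estimated)) stop("no estimates supplied")
  if (is.null(brainage)) brainage <- bias_correct(estimated, age)
  list(mad = mean(abs(estimated - age)),
       cor_age = if (sd(brainage) == 0) 0 else cor(brainage, age))
}
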