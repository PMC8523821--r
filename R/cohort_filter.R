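#' Apply the study eligibility flow
#'
#' Reproduces the inclusion flowchart, in order: (1) fewer than `min_scans`
#' usable scans; (2) neurological exclusion (neuro flag at any visit or MMSE
#' below `mmse_cutoff` at any visit); (3) baseline blood pressure beyond
#' `k_sd` standard deviations from the mean (MAP, computed within age cohort
#' by default since the cohorts differ in mean BP); (4) missing key baseline
#' covariates.
#'
#' @param subjects subject table (`subject_id`, `cohort`, covariates).
#' @param visits visit table carrying `scan_available`, `mmse`, `neuro_flag`
#'   and either `map` or the raw reading columns.
#' @param min_scans minimum number of scans for inclusion (default 2).
#' @param mmse_cutoff exclusion below this MMSE (strict `<`, default 25).
#' @param k_sd SD multiplier for the BP outlier rule (default 3).
#' @param pooled_sd if `TRUE`, compute the outlier mean/SD over the pooled
#'   sample instead of within cohort.
#' @param key_covariates baseline covariate columns that must be non-missing.
#' @return list: filtered `subjects`, filtered `visits`, and `report`
#'   (an `eligibility_report` with per-stage counts).
#' @export
apply_eligibility <- function(subjects, visits, min_scans = 2L,
                              mmse_cutoff = 25, k_sd = 3, pooled_sd = FALSE,
                              key_covariates = c("education", "diabetes",
                                                 "bmi", "smoker",
                                                 "depression_score",
                                                 "physical_activity",
                                                 "alcohol_intake", "apoe4")) {
  need <- c("scan_available", "mmse", "neuro_flag")
  miss <- setdiff(need, names(visits))
  if (length(miss)) stop("visits is missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(visits$map)) {
    if (all(c("sbp_reading_1", "sbp_reading_2", "dbp_reading_1",
              "dbp_reading_2") %in% names(visits))) {
      visits <- add_bp_measures(visits)
    } else stop("visits is missing required column(s): map (or the raw reading columns)")
  }
  key_covariates <- intersect(key_covariates, names(subjects))

  stages <- data.frame(stage = character(0), n_entering = integer(0),
                       n_excluded = integer(0))
  keep <- subjects$subject_id
  note <- function(stage, excluded) {
    stages <<- rbind(stages, data.frame(stage = stage,
                                        n_entering = length(keep),
                                        n_excluded = length(excluded)))
    keep <<- setdiff(keep, excluded)
  }

  # stage 1: < min_scans usable scans
  scans <- tapply(visits$scan_available[visits$subject_id %in% keep] > 0,
                  visits$subject_id[visits$subject_id %in% keep], sum)
  too_few <- names(scans)[scans < min_scans]
  too_few <- union(too_few, setdiff(keep, visits$subject_id))
  note("fewer than minimum scans", too_few)

  # stage 2: neurological condition or low MMSE at any visit
  vk <- visits[visits$subject_id %in% keep, ]
  bad <- unique(vk$subject_id[vk$neuro_flag > 0 | vk$mmse < mmse_cutoff])
  note("neurological condition or MMSE below cutoff", bad)

  # stage 3: baseline MAP outliers (per cohort unless pooled_sd)
  vk <- visits[visits$subject_id %in% keep, ]
  base <- vk[order(vk$subject_id, vk$wave), ]
  base <- base[!duplicated(base$subject_id), ]
  cohort <- subjects$cohort[match(base$subject_id, subjects$subject_id)]
  flag <- logical(nrow(base))
  groups <- if (pooled_sd) list(seq_len(nrow(base))) else
    split(seq_len(nrow(base)), cohort)
  for (idx in groups) flag[idx] <- flag_bp_outliers(base$map[idx], k = k_sd)
  note("baseline BP outlier", base$subject_id[flag])

  # stage 4: missing key baseline covariates
  sk <- subjects[subjects$subject_id %in% keep, , drop = FALSE]
  if (length(key_covariates)) {
    incomplete <- !complete.cases(sk[, key_covariates, drop = FALSE])
    note("missing key baseline covariates", sk$subject_id[incomplete])
  } else note("missing key baseline covariates", character(0))

  subjects_out <- subjects[subjects$subject_id %in% keep, , drop = FALSE]
  visits_out <- visits[visits$subject_id %in% keep, , drop = FALSE]
  rownames(subjects_out) <- rownames(visits_out) <- NULL
  final <- table(factor(subjects_out$cohort))
  report <- structure(list(stages = stages,
                           n_final = nrow(subjects_out),
                           n_final_by_cohort = as.list(final)),
                      class = "eligibility_report")
  list(subjects = subjects_out, visits = visits_out, report = report)
}

#' @exportS3Method base::print
print.eligibility_report <- function(x, ...) {
  cat("Eligibility flow:\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-42s entering %4d, excluded %3d\n",
                x$stages$stage[i], x$stages$n_entering[i],
                x$stages$n_excluded[i]))
  cat(sprintf("  final n = %d (%s)\n", x$n_final,
              paste(names(x$n_final_by_cohort), unlist(x$n_final_by_cohort),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' EM imputation of missing covariates under a multivariate-normal model
#'
#' Fits a multivariate-normal working model to the numeric covariate table
#' by expectation-maximization over the missing entries and replaces each
#' missing cell by its conditional mean given the row's observed cells.
#' Observed entries are never altered.  Columns whose observed values are all
#' 0/1 are treated as binary and thresholded at 0.5 after imputation.
#'
#' @param x data frame or matrix of numeric covariates with `NA`s.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the relative change of the MVN
#'   parameters between iterations.
#' @param missing_cap error if any column's missingness fraction exceeds this.
#' @return completed data frame; attributes `iterations`, `converged` and
#'   `loglik` (per-iteration observed-data log-likelihood trace).
#' @export
em_impute <- function(x, max_iter = 100L, tol = 1e-6, missing_cap = 0.1) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) stop("all columns must be numeric")
  X <- as.matrix(df)
  n <- nrow(X); p <- ncol(X)
  fmiss <- colMeans(is.na(X))
  if (any(fmiss >= 1)) stop("column(s) entirely missing: ",
                            paste(colnames(X)[fmiss >= 1], collapse = ", "))
  if (any(fmiss > missing_cap))
    stop("missingness exceeds cap (", missing_cap, ") in: ",
         paste(colnames(X)[fmiss > missing_cap], collapse = ", "))
  binary <- vapply(seq_len(p), function(j) {
    v <- X[, j]; all(v[!is.na(v)] %in% c(0, 1))
  }, logical(1))
  if (!anyNA(X)) {
    attr(df, "iterations") <- 0L; attr(df, "converged") <- TRUE
    attr(df, "loglik") <- numeric(0)
    return(df)
  }

  M <- is.na(X)
  mu <- colMeans(X, na.rm = TRUE)
  Sigma <- stats::cov(X, use = "pairwise.complete.obs")
  Sigma[!is.finite(Sigma)] <- 0
  diag(Sigma) <- pmax(diag(Sigma), 1e-6)
  # guard positive definiteness of the start
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) Sigma <- Sigma + diag(1e-6 - min(ev, 0), p)

  obs_loglik <- function(mu, Sigma) {
    # best-effort: NA when the working covariance is (near) singular, as
    # happens with exactly collinear columns
    tryCatch({
      ll <- 0
      for (i in seq_len(n)) {
        o <- !M[i, ]
        if (!any(o)) next
        S <- Sigma[o, o, drop = FALSE]
        d <- X[i, o] - mu[o]
        ll <- ll - 0.5 * (sum(o) * log(2 * pi) +
                            determinant(S, logarithm = TRUE)$modulus +
                            sum(d * solve(S, d)))
      }
      as.numeric(ll)
    }, error = function(e) NA_real_)
  }

  patterns <- apply(M, 1, paste, collapse = "")
  ll_trace <- numeric(0)
  converged <- FALSE
  Ximp <- X
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E step: fill conditional means; accumulate conditional covariance
    Cadd <- matrix(0, p, p)
    for (pat in unique(patterns)) {
      rows <- which(patterns == pat)
      m <- M[rows[1], ]
      if (!any(m)) { Ximp[rows, ] <- X[rows, ]; next }
      o <- !m
      if (!any(o)) {
        Ximp[rows, ] <- matrix(mu, length(rows), p, byrow = TRUE)
        Cadd[m, m] <- Cadd[m, m] + length(rows) * Sigma[m, m]
        next
      }
      Soo <- Sigma[o, o, drop = FALSE]
      Smo <- Sigma[m, o, drop = FALSE]
      B <- Smo %*% solve(Soo)
      cond_cov <- Sigma[m, m, drop = FALSE] - B %*% t(Smo)
      D <- X[rows, o, drop = FALSE] -
        matrix(mu[o], length(rows), sum(o), byrow = TRUE)
      Ximp[rows, m] <- matrix(mu[m], length(rows), sum(m), byrow = TRUE) +
        D %*% t(B)
      Ximp[rows, o] <- X[rows, o]
      Cadd[m, m] <- Cadd[m, m] + length(rows) * cond_cov
    }
    # M step
    mu_new <- colMeans(Ximp)
    Xc <- sweep(Ximp, 2, mu_new)
    Sigma_new <- (crossprod(Xc) + Cadd) / n
    diag(Sigma_new) <- pmax(diag(Sigma_new), 1e-10)
    delta <- max(abs(mu_new - mu), abs(Sigma_new - Sigma)) /
      (1 + max(abs(mu_new), abs(Sigma_new)))
    mu <- mu_new; Sigma <- Sigma_new
    ll_trace <- c(ll_trace, obs_loglik(mu, Sigma))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    message("em_impute: reached max_iter (", max_iter, ") without convergence")

  out <- as.data.frame(Ximp)
  names(out) <- colnames(df)
  for (j in which(binary)) {
    v <- out[[j]]
    v[M[, j]] <- as.numeric(v[M[, j]] >= 0.5)
    out[[j]] <- v
  }
  # observed entries are authoritative
  for (j in seq_len(p)) out[[j]][!M[, j]] <- df[[j]][!M[, j]]
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  attr(out, "loglik") <- ll_trace
  out
}
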