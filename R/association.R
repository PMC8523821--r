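#' Specify a longitudinal mixed-effects model
#'
#' Describes a random-intercept model for the brain-age gap with a centered
#' blood-pressure measure as exposure.  The base model controls for age —
#' decomposed into time in study (within-person change, years from baseline)
#' and cohort (between-cohort difference) — and sex; the adjusted model adds
#' education, diabetes, BMI, smoking, depression, physical activity, alcohol
#' intake, APOE e4 and the time-varying medication/hypertension terms.
#'
#' @param bp one of `"map"`, `"sbp"`, `"dbp"`; the centered column
#'   (`map_c` etc.) is used as the fixed-effect exposure.
#' @param model `"base"` or `"adjusted"`.
#' @param outcome outcome column name (default `"brainage"`).
#' @param interactions optional character vector of terms to interact with
#'   the BP exposure (e.g. `"time_in_study"`, `"hypertensive"`).
#' @param random_bp_slope if `TRUE`, adds a per-subject random slope on the
#'   centered BP exposure.
#' @param method `"ML"` (default; valid nested-model likelihood comparisons)
#'   or `"REML"`.
#' @param subset optional expression (as one-sided formula or character) used
#'   to filter rows before fitting, for stratified analyses.
#' @param extra_terms additional fixed-effect terms appended verbatim.
#' @return object of class `"lmm_spec"`.
#' @export
lmm_spec <- function(bp = c("map", "sbp", "dbp"),
                     model = c("base", "adjusted"),
                     outcome = "brainage",
                     interactions = NULL,
                     random_bp_slope = FALSE,
                     method = c("ML", "REML"),
                     subset = NULL,
                     extra_terms = NULL) {
  bp <- match.arg(bp)
  model <- match.arg(model)
  method <- match.arg(method)
  bp_term <- paste0(bp, "_c")
  fixed <- c(bp_term, "time_in_study", "cohort", "sex")
  if (model == "adjusted")
    fixed <- c(fixed, "education", "diabetes", "bmi", "smoker",
               "depression_score", "physical_activity", "alcohol_intake",
               "apoe4", "on_bp_med")
  fixed <- c(fixed, extra_terms)
  structure(list(bp = bp, bp_term = bp_term, model = model,
                 outcome = outcome, fixed = fixed,
                 interactions = interactions,
                 random_bp_slope = random_bp_slope,
                 method = method, subset = subset),
            class = "lmm_spec")
}

lmm_formula <- function(spec) {
  rhs <- spec$fixed
  if (!is.null(spec$interactions))
    rhs <- c(rhs, paste(spec$bp_term, spec$interactions, sep = ":"))
  rand <- if (spec$random_bp_slope)
    sprintf("(1 + %s | subject_id)", spec$bp_term) else "(1 | subject_id)"
  as.formula(paste(spec$outcome, "~", paste(c(rhs, rand), collapse = " + ")))
}

#' Fit a longitudinal mixed-effects model
#'
#' Fits the random-intercept model described by an [lmm_spec()] with
#' `lme4::lmer`, by maximum likelihood by default.  Returns the coefficient
#' table with Wald 95% confidence intervals and p-values, the
#' random-intercept and residual SDs, and fit statistics.  Non-convergence
#' and singular random-effect fits are flagged, never silent.
#'
#' @param spec an [lmm_spec()].
#' @param data long-format analysis table (one row per visit) carrying the
#'   outcome, the centered BP columns, `time_in_study`, `cohort`, `sex`,
#'   `subject_id`, and the adjusted covariates when requested.
#' @return object of class `"lmm_fit"`: list with `coefficients` (data frame
#'   `term`, `estimate`, `ci_lower`, `ci_upper`, `p`), `sd_intercept`,
#'   `sd_resid`, `n_obs`, `n_subjects`, `logLik`, `AIC`, `BIC`,
#'   `converged`, `singular`, `spec`, and the underlying `model`.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "lmm_spec"))
  if (!spec$outcome %in% names(data))
    stop("outcome column '", spec$outcome, "' not present in data")
  if (!is.null(spec$subset)) {
    expr <- if (inherits(spec$subset, "formula")) spec$subset[[2]] else
      parse(text = spec$subset)[[1]]
    data <- data[eval(expr, data, parent.frame()), , drop = FALSE]
  }
  vars <- unique(c(spec$outcome, spec$fixed, "subject_id",
                   if (!is.null(spec$interactions)) spec$interactions))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("data is missing column(s): ",
                         paste(miss, collapse = ", "))
  data <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  # stratified analyses: a term constant within the stratum (e.g. the
  # grouping variable itself) carries no information and would break the
  # design matrix, so it is dropped from the fixed effects
  constant <- vapply(spec$fixed, function(v)
    length(unique(data[[v]])) < 2L, logical(1))
  if (any(constant)) {
    message("dropping constant fixed-effect term(s): ",
            paste(spec$fixed[constant], collapse = ", "))
    spec$fixed <- spec$fixed[!constant]
  }
  fml <- lmm_formula(spec)

  warn_conv <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = data, REML = spec$method == "REML"),
    warning = function(w) {
      warn_conv <<- c(warn_conv, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  singular <- lme4::isSingular(fit)
  conv_ok <- length(fit@optinfo$conv$lme4) == 0 &&
    !any(grepl("converge", warn_conv, ignore.case = TRUE))
  if (!conv_ok) warning("mixed-model fit did not converge cleanly: ",
                        paste(warn_conv, collapse = "; "))
  if (singular) warning("singular random-effects fit")

  # Wald t tests with Satterthwaite denominator df (near-nominal size in
  # longitudinal designs); CIs are Wald 95% intervals
  ct <- tryCatch(summary(fit)$coefficients,
                 error = function(e) NULL)
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- qnorm(0.975)
  pvals <- if (!is.null(ct) && "Pr(>|t|)" %in% colnames(ct))
    ct[names(b), "Pr(>|t|)"] else 2 * pnorm(-abs(b / se))
  dfs <- if (!is.null(ct) && "df" %in% colnames(ct))
    ct[names(b), "df"] else rep(NA_real_, length(b))
  coefs <- data.frame(term = names(b), estimate = unname(b),
                      se = unname(se), df = unname(dfs),
                      ci_lower = unname(b - z * se),
                      ci_upper = unname(b + z * se),
                      p = unname(pvals),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_int <- vc$sdcor[vc$grp == "subject_id" & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)]
  structure(list(coefficients = coefs,
                 sd_intercept = sd_int,
                 sd_resid = sigma(fit),
                 n_obs = nobs(fit),
                 n_subjects = as.integer(lme4::ngrps(fit)[["subject_id"]]),
                 logLik = as.numeric(logLik(fit)),
                 AIC = AIC(fit), BIC = BIC(fit),
                 converged = conv_ok, singular = singular,
                 spec = spec, model = fit),
            class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed-effects fit: %s, %s model (%s), n_obs = %d, n_subjects = %d\n",
              toupper(x$spec$bp), x$spec$model, x$spec$method, x$n_obs,
              x$n_subjects))
  cf <- x$coefficients
  cf$estimate <- signif(cf$estimate, digits)
  cf$ci <- sprintf("(%.3f, %.3f)", cf$ci_lower, cf$ci_upper)
  print(cf[, c("term", "estimate", "ci", "p")], row.names = FALSE)
  cat(sprintf("Random effects: intercept SD %.3f, residual SD %.3f\n",
              x$sd_intercept, x$sd_resid))
  cat(sprintf("logLik %.3f, AIC %.3f, BIC %.3f%s\n", x$logLik, x$AIC, x$BIC,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Refits both models by ML on the rows common to both and returns the
#' chi-square likelihood-ratio test.
#'
#' @param fit_null,fit_full `"lmm_fit"` objects with nested fixed effects.
#' @return list with `lr`, `df`, `p`.
#' @export
lrt_lmm <- function(fit_null, fit_full) {
  a <- stats::anova(fit_full$model, fit_null$model)
  list(lr = a$Chisq[2], df = a$Df[2], p = a$`Pr(>Chisq)`[2])
}

#' Convert a model coefficient to days of brain ageing
#'
#' A coefficient in years of BrainAGE per mmHg, multiplied by a pressure
#' difference and by the length of a year, gives the expected extra brain
#' ageing in days: `coef * delta * days_per_year`.  Conventionally reported
#' at 3 significant figures.
#'
#' @param coef years per mmHg.
#' @param delta pressure difference, mmHg.
#' @param days_per_year days in a year (default 365.25).
#' @return days (full precision; round with `signif(x, 3)` for reporting).
#' @export
coef_to_days <- function(coef, delta = 1, days_per_year = 365.25) {
  stopifnot(is.finite(coef), is.finite(delta))
  coef * delta * days_per_year
}

#' Group summary (n, mean, SD)
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group SD (>= 0).
#' @return list of class `"group_summary"`.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop("group size must be at least 2")
  if (sd < 0) stop("SD must be non-negative")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed from group means, SDs and sizes:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch--Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param g1,g2 [group_summary()] objects (or lists with `n`, `mean`, `sd`).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_from_summary <- function(g1, g2) {
  for (g in list(g1, g2)) {
    if (g$n < 2) stop("group size must be at least 2")
    if (g$sd <= 0) stop("group SD must be positive")
  }
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  t <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test from a contingency table
#'
#' Pearson chi-square without continuity correction,
#' df = (rows - 1)(cols - 1).
#'
#' @param counts matrix of contingency counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chisq_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero marginal")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("all expected counts must be positive")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
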