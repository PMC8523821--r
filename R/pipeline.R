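#' Pipeline configuration
#'
#' Bundles the simulation, brain-age and association settings together with
#' the output directory and the single top-level seed from which every
#' stage's RNG stream is derived.
#'
#' @param sim a [sim_config()].
#' @param brainage list of brain-age engine settings: `kernel`, `k`,
#'   `var_target`, `tol`.
#' @param association list with `measures` (subset of map/sbp/dbp) and
#'   `models` (subset of base/adjusted).
#' @param seed integer seed stamped into every output.
#' @param out_dir output directory for the report bundle.
#' @param run_brainage if `TRUE`, simulate features and run the LOSO
#'   brain-age engine (the slow stage); otherwise the generated outcome is
#'   analysed directly.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            brainage = list(kernel = "linear", k = NULL,
                                            var_target = 0.95, tol = 1e-6),
                            association = list(measures = c("map", "sbp", "dbp"),
                                               models = c("base", "adjusted")),
                            seed = 1L, out_dir = "results",
                            run_brainage = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, brainage = brainage, association = association,
                 seed = as.integer(seed), out_dir = out_dir,
                 run_brainage = isTRUE(run_brainage)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]  # paths don't identify the run
  s <- jsonlite::toJSON(unclass(rapply(config, unclass, how = "replace")),
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  codes <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(codes * (seq_along(codes) %% 97 + 1)) %% 4294967296)
}

write_stamped_tsv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", seed, hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full simulation-to-report pipeline
#'
#' Executes simulate -> BP measures -> eligibility filter -> (optionally)
#' feature simulation + scanner orthogonalization + LOSO brain-age
#' estimation + bias correction -> mixed-effects association models ->
#' table rendering.  Every artifact written to `config$out_dir` is stamped
#' with the seed and a hash of the configuration, so the bundle is
#' regenerable bit-identically from `(config, seed)`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the tables, fits and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$out_dir) || !nzchar(config$out_dir))
    stop("pipeline config must name an output directory")
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  stage <- function(name, code) {
    tryCatch(force(code),
             error = function(e) stop("pipeline stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  sim <- stage("simulate", simulate_cohort(config$sim, seed = seed))
  filt <- stage("filter", apply_eligibility(sim$subjects, sim$visits))
  data <- merge(filt$visits, filt$subjects, by = "subject_id", sort = FALSE)
  data <- data[order(data$subject_id, data$wave), ]

  estimates <- NULL
  if (config$run_brainage) {
    estimates <- stage("brainage", {
      fm <- simulate_features(filt$visits, filt$subjects, config$sim, seed)
      fm <- orthogonalize_scanner(fm)
      est <- estimate_brainage_loso(fm, k = config$brainage$k,
                                    var_target = config$brainage$var_target %||% 0.95,
                                    kernel = config$brainage$kernel %||% "linear",
                                    tol = config$brainage$tol %||% 1e-6)
      bias_correct(est)
    })
    sid <- sprintf("%s_w%d", data$subject_id, data$wave)
    data$brainage_estimated <- estimates$brainage[match(sid, estimates$scan_id)]
  }

  fits <- stage("associate", {
    out <- list()
    for (m in config$association$measures)
      for (mod in config$association$models)
        out[[paste(m, mod, sep = "_")]] <-
          fit_lmm(lmm_spec(bp = m, model = mod), data)
    out
  })

  t1 <- render_table1(data)
  t2 <- render_table2(fits)

  paths <- c(subjects = file.path(config$out_dir, "subjects.tsv"),
             visits = file.path(config$out_dir, "visits.tsv"),
             table1 = file.path(config$out_dir, "table1.tsv"),
             table2 = file.path(config$out_dir, "table2.tsv"),
             report = file.path(config$out_dir, "report.json"))
  write_stamped_tsv(filt$subjects, paths["subjects"], seed, hash)
  write_stamped_tsv(filt$visits, paths["visits"], seed, hash)
  write_stamped_tsv(t1, paths["table1"], seed, hash)
  write_stamped_tsv(t2, paths["table2"], seed, hash)
  if (!is.null(estimates)) {
    paths["estimates"] <- file.path(config$out_dir, "brainage_estimates.tsv")
    write_stamped_tsv(as.data.frame(estimates), paths["estimates"], seed, hash)
  }
  report <- list(seed = seed, config_hash = hash,
                 eligibility = list(stages = filt$report$stages,
                                    n_final = filt$report$n_final),
                 fits = lapply(fits, function(f)
                   list(coefficients = f$coefficients,
                        sd_intercept = f$sd_intercept, sd_resid = f$sd_resid,
                        n_obs = f$n_obs, logLik = f$logLik, AIC = f$AIC,
                        BIC = f$BIC, converged = f$converged)),
                 elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(list(data = data, subjects = filt$subjects, visits = filt$visits,
                 eligibility = filt$report, estimates = estimates,
                 fits = fits, table1 = t1, table2 = t2, paths = paths))
}

#' Render a demographics summary table
#'
#' Baseline characteristics as mean (SD) for continuous measures and n (%)
#' for categorical ones, by whole sample, age cohort and sex, with Welch t
#' or Pearson chi-square comparison columns.
#'
#' @param data merged long-format analysis table (visit rows with subject
#'   covariates); baseline rows (wave 0) are used.
#' @return data frame, one row per measure.
#' @export
render_table1 <- function(data) {
  base <- data[data$wave == 0, , drop = FALSE]
  cont <- c(Age = "age_at_visit", Education = "education", SBP = "sbp",
            DBP = "dbp", MAP = "map", BMI = "bmi",
            `Physical activity` = "physical_activity")
  cat_ <- c(Smoker = "smoker", Hypertension = "hypertensive",
            `BP medication` = "on_bp_med", Diabetes = "diabetes",
            `APOE e4` = "apoe4")
  cont <- cont[cont %in% names(base)]
  cat_ <- cat_[cat_ %in% names(base)]
  fmt_ms <- function(v) sprintf("%.2f (%.2f)", mean(v, na.rm = TRUE),
                                sd(v, na.rm = TRUE))
  fmt_np <- function(v) {
    v <- v[!is.na(v)]
    sprintf("%d (%.2f%%)", sum(v), 100 * mean(v))
  }
  gs <- function(v) group_summary(sum(!is.na(v)), mean(v, na.rm = TRUE),
                                  sd(v, na.rm = TRUE))
  rows <- list()
  for (i in seq_along(cont)) {
    v <- base[[cont[i]]]
    tc <- welch_t_from_summary(gs(v[base$cohort == "MA"]),
                               gs(v[base$cohort == "OA"]))
    ts <- welch_t_from_summary(gs(v[base$sex == "male"]),
                               gs(v[base$sex == "female"]))
    rows[[length(rows) + 1]] <- data.frame(
      measure = names(cont)[i], type = "continuous",
      whole = fmt_ms(v),
      ma = fmt_ms(v[base$cohort == "MA"]), oa = fmt_ms(v[base$cohort == "OA"]),
      test_cohort = sprintf("%.2f (%.3g)", tc$t, tc$p),
      male = fmt_ms(v[base$sex == "male"]),
      female = fmt_ms(v[base$sex == "female"]),
      test_sex = sprintf("%.2f (%.3g)", ts$t, ts$p),
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(cat_)) {
    v <- base[[cat_[i]]]
    ct <- chisq_from_counts(table(base$cohort, v))
    cs <- chisq_from_counts(table(base$sex, v))
    rows[[length(rows) + 1]] <- data.frame(
      measure = names(cat_)[i], type = "categorical",
      whole = fmt_np(v),
      ma = fmt_np(v[base$cohort == "MA"]), oa = fmt_np(v[base$cohort == "OA"]),
      test_cohort = sprintf("%.2f (%.3g)", ct$statistic, ct$p),
      male = fmt_np(v[base$sex == "male"]),
      female = fmt_np(v[base$sex == "female"]),
      test_sex = sprintf("%.2f (%.3g)", cs$statistic, cs$p),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Render a mixed-model coefficient table
#'
#' One column per fitted model, rows: coefficient (95% CI) per term, then
#' random-effect SDs, observations, log-likelihood, AIC, BIC.
#'
#' @param fits named list of `"lmm_fit"` objects.
#' @return data frame in the conventional stacked layout.
#' @export
render_table2 <- function(fits) {
  stopifnot(length(fits) > 0)
  terms <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  rows <- lapply(terms, function(tm) {
    vals <- vapply(fits, function(f) {
      cf <- f$coefficients
      i <- match(tm, cf$term)
      if (is.na(i)) "" else sprintf("%.3f (%.3f, %.3f)", cf$estimate[i],
                                    cf$ci_lower[i], cf$ci_upper[i])
    }, character(1))
    c(term = tm, vals)
  })
  extras <- list(
    c(term = "Random effects intercept SD",
      vapply(fits, function(f) sprintf("%.3f", f$sd_intercept), character(1))),
    c(term = "Random effects residual SD",
      vapply(fits, function(f) sprintf("%.3f", f$sd_resid), character(1))),
    c(term = "Observations",
      vapply(fits, function(f) sprintf("%d", f$n_obs), character(1))),
    c(term = "Log likelihood",
      vapply(fits, function(f) sprintf("%.3f", f$logLik), character(1))),
    c(term = "AIC",
      vapply(fits, function(f) sprintf("%.3f", f$AIC), character(1))),
    c(term = "BIC",
      vapply(fits, function(f) sprintf("%.3f", f$BIC), character(1))))
  out <- as.data.frame(do.call(rbind, c(rows, extras)),
                       stringsAsFactors = FALSE)
  names(out) <- c("term", names(fits))
  out
}
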