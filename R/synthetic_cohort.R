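#' Simulation configuration for a synthetic longitudinal BP/brain-age cohort
#'
#' Builds the configuration object consumed by [build_design()],
#' [simulate_bp()], [simulate_features()] and [simulate_brainage_outcome()].
#' Defaults emulate a two-cohort community study: a middle-aged (MA) cohort
#' aged 44--46 at baseline and an older (OA) cohort aged 60--64, followed for
#' up to four assessment waves roughly four years apart (about 12 years).
#'
#' Blood pressure is generated on the (MAP, pulse-pressure) scale: each
#' subject gets a baseline mean arterial pressure (MAP) and pulse pressure
#' (PP = 3/2 x (SBP - MAP)) plus subject-specific annual slopes, and
#' SBP = MAP + (2/3) PP, DBP = MAP - (1/3) PP, so the identity
#' MAP = (SBP + 2 DBP)/3 holds exactly at every visit.  Default annual slope
#' means are 0.8 mmHg/yr for MAP (SD 0.92) and 0.915 mmHg/yr for PP, which
#' imply a mean SBP slope of 1.41 mmHg/yr.
#'
#' The default outcome model generates a brain-age gap (years) per visit as
#' `beta_map*(MAP-90) + beta_time*t + beta_cohort*I(OA) + beta_sex*I(female)
#' + intercept + u_i + e_ij` with a subject random intercept
#' (`u_i ~ N(0, sd_intercept^2)`) and residual noise.
#'
#' @param n_ma,n_oa number of subjects in the middle-aged / older cohort.
#' @param baseline_age_range_ma,baseline_age_range_oa baseline age ranges in
#'   years (uniform within range).
#' @param n_waves number of assessment waves (2--4).
#' @param wave_interval planned years between waves.
#' @param wave_jitter_sd SD (years) of visit-timing jitter around the planned
#'   schedule.
#' @param attrition per-wave dropout hazards, length `n_waves - 1`:
#'   element `w` is the probability that a subject seen at wave `w-1` (0-based)
#'   is never seen again.  The default `(0, 0.26, 0.5676)` yields
#'   2/3/4-visit proportions of roughly 26/42/32%.
#' @param prop_female_ma,prop_female_oa proportion of female subjects.
#' @param bp_baseline nested list of baseline MAP and PP means per cohort and
#'   sex (mmHg) and their SDs; see the default for the structure.
#' @param bp_slopes list of annual slope distributions (mmHg/yr): `map` and
#'   `pp`, each `c(mean, sd)`.
#' @param reading_noise_sd SD (mmHg) of the independent within-visit noise on
#'   each of the two SBP and two DBP readings.
#' @param outcome_model named list of generating fixed effects (years or
#'   years/mmHg), random-intercept SD and residual SD for the brain-age gap.
#' @param covariates named list of covariate generating parameters:
#'   prevalences for smoker/diabetes/APOE e4 and per-cohort anti-hypertensive
#'   medication probabilities, plus mean/SD for the continuous covariates.
#' @param mmse_mean,mmse_sd MMSE generating distribution (scores capped at 30).
#' @param neuro_rate_ma,neuro_rate_oa per-subject probability of a
#'   neurological exclusion flag (stroke/Parkinson's/dementia analogue).
#' @param covariate_missing_rate MCAR missingness rate applied to continuous
#'   baseline covariates when `apply_missingness = TRUE` in [build_design()].
#' @param feature_dim,n_latent dimensions of the simulated gray-matter-like
#'   feature vectors and of their latent space (`feature_dim >= n_latent`).
#' @param feature_age_scale multiplier applied to the latent brain-age axis
#'   before mixing, controlling the strength of the age signal.
#' @param feature_bp_effect years of latent brain-age deviation per mmHg of
#'   MAP above 90 encoded into the features.
#' @param feature_sex_effect latent brain-age offset (years) for female
#'   subjects encoded into the features.
#' @param scanner_effect_size additive offset applied to every feature for
#'   scans acquired after the scanner changepoint.
#' @param scanner_changepoint first 0-based wave using the second scanner.
#' @param feature_noise_sd SD of iid feature noise.
#' @param seed optional default seed; the generator functions also take an
#'   explicit `seed` argument which wins.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_ma = 335L, n_oa = 351L,
                       baseline_age_range_ma = c(44, 46),
                       baseline_age_range_oa = c(60, 64),
                       n_waves = 4L,
                       wave_interval = 4,
                       wave_jitter_sd = 0.35,
                       attrition = NULL,
                       prop_female_ma = 0.52,
                       prop_female_oa = 0.46,
                       bp_baseline = list(
                         map = list(ma = c(male = 98.83, female = 92.80),
                                    oa = c(male = 103.76, female = 97.73),
                                    sd = 11.3),
                         pp  = list(ma = c(male = 46.15, female = 43.14),
                                    oa = c(male = 56.75, female = 53.74),
                                    sd = 12)),
                       bp_slopes = list(map = c(mean = 0.8,  sd = 0.92),
                                        pp  = c(mean = 0.915, sd = 1.758)),
                       reading_noise_sd = 3,
                       outcome_model = list(beta_map = 0.019,
                                            beta_time = 0.035,
                                            beta_cohort = -0.402,
                                            beta_sex = -0.837,
                                            intercept = 0.073,
                                            sd_intercept = 3.633,
                                            sd_resid = 1.590),
                       covariates = list(
                         smoker = 0.4446, diabetes_ma = 0.0627,
                         diabetes_oa = 0.1852, apoe4 = 0.2974,
                         bp_med_ma = 0.0866, bp_med_oa = 0.2963,
                         bp_med_initiation = 0.05,
                         education_mean = 14.49, education_sd = 2.49,
                         bmi_mean = 26.91, bmi_sd = 4.43,
                         activity_mean = 39.15, activity_sd = 34.95,
                         depression_mean = 2.5, depression_sd = 2,
                         alcohol_mean = 1.2, alcohol_sd = 1),
                       mmse_mean = 28.6, mmse_sd = 1.1,
                       neuro_rate_ma = 0, neuro_rate_oa = 0.06,
                       covariate_missing_rate = 0,
                       feature_dim = 100L, n_latent = 5L,
                       feature_age_scale = 1,
                       feature_bp_effect = 0.019,
                       feature_sex_effect = -0.8,
                       scanner_effect_size = 0.5,
                       scanner_changepoint = 2L,
                       feature_noise_sd = 0.5,
                       seed = NULL) {
  if (is.null(attrition)) {
    attrition <- if (n_waves >= 2L) c(0, 0.26, 0.5676)[seq_len(n_waves - 1L)] else numeric(0)
  }
  cfg <- list(n_ma = as.integer(n_ma), n_oa = as.integer(n_oa),
              baseline_age_range_ma = baseline_age_range_ma,
              baseline_age_range_oa = baseline_age_range_oa,
              n_waves = as.integer(n_waves), wave_interval = wave_interval,
              wave_jitter_sd = wave_jitter_sd, attrition = attrition,
              prop_female_ma = prop_female_ma, prop_female_oa = prop_female_oa,
              bp_baseline = bp_baseline, bp_slopes = bp_slopes,
              reading_noise_sd = reading_noise_sd,
              outcome_model = outcome_model, covariates = covariates,
              mmse_mean = mmse_mean, mmse_sd = mmse_sd,
              neuro_rate_ma = neuro_rate_ma, neuro_rate_oa = neuro_rate_oa,
              covariate_missing_rate = covariate_missing_rate,
              feature_dim = as.integer(feature_dim),
              n_latent = as.integer(n_latent),
              feature_age_scale = feature_age_scale,
              feature_bp_effect = feature_bp_effect,
              feature_sex_effect = feature_sex_effect,
              scanner_effect_size = scanner_effect_size,
              scanner_changepoint = as.integer(scanner_changepoint),
              feature_noise_sd = feature_noise_sd,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  err <- function(field, why) stop("invalid sim_config field '", field, "': ",
                                   why, call. = FALSE)
  if (cfg$n_ma < 0 || cfg$n_oa < 0) err("n_ma/n_oa", "counts must be >= 0")
  if (cfg$n_ma + cfg$n_oa < 1) err("n_ma/n_oa", "need at least one subject")
  if (!cfg$n_waves %in% 2:4) err("n_waves", "must be 2, 3 or 4")
  for (f in c("baseline_age_range_ma", "baseline_age_range_oa")) {
    r <- cfg[[f]]
    if (length(r) != 2 || r[1] > r[2]) err(f, "must be an ordered range")
  }
  if (length(cfg$attrition) != cfg$n_waves - 1L)
    err("attrition", "needs one hazard per inter-wave gap")
  probs <- c(cfg$attrition, cfg$prop_female_ma, cfg$prop_female_oa,
             cfg$covariates$smoker, cfg$covariates$apoe4,
             cfg$covariates$diabetes_ma, cfg$covariates$diabetes_oa,
             cfg$covariates$bp_med_ma, cfg$covariates$bp_med_oa,
             cfg$covariate_missing_rate, cfg$neuro_rate_ma, cfg$neuro_rate_oa)
  if (any(probs < 0 | probs > 1))
    err("probabilities", "all rates/prevalences must lie in [0, 1]")
  sds <- c(cfg$wave_jitter_sd, cfg$bp_baseline$map$sd, cfg$bp_baseline$pp$sd,
           cfg$bp_slopes$map["sd"], cfg$bp_slopes$pp["sd"],
           cfg$reading_noise_sd, cfg$outcome_model$sd_intercept,
           cfg$outcome_model$sd_resid, cfg$feature_noise_sd)
  if (any(sds < 0)) err("sd", "all SDs must be >= 0")
  if (cfg$feature_dim < cfg$n_latent || cfg$n_latent < 1L)
    err("feature_dim", "need feature_dim >= n_latent >= 1")
  invisible(cfg)
}

#' Generate the longitudinal study design (subjects and visits)
#'
#' Draws subjects for both age cohorts with demographics and baseline
#' covariates, assigns each subject a monotone visit history under the
#' configured per-wave dropout hazards, and lays out visit times (planned
#' interval plus jitter).  Blood-pressure readings are left `NA`; fill them
#' with [simulate_bp()].
#'
#' @param config a [sim_config()].
#' @param seed integer seed; every generator stage derives its own named
#'   RNG stream from it.
#' @param apply_missingness if `TRUE`, knock out continuous baseline
#'   covariates MCAR at `config$covariate_missing_rate` (for exercising
#'   [em_impute()]).
#' @return list with `subjects` and `visits` data frames.
#' @export
build_design <- function(config, seed = config$seed %||% 1L,
                         apply_missingness = FALSE) {
  validate_sim_config(config)
  n <- config$n_ma + config$n_oa
  cohort <- rep(c("MA", "OA"), c(config$n_ma, config$n_oa))
  subjects <- with_stage_seed(seed, "design", {
    sex <- ifelse(runif(n) < ifelse(cohort == "MA", config$prop_female_ma,
                                    config$prop_female_oa),
                  "female", "male")
    rng_ma <- config$baseline_age_range_ma
    rng_oa <- config$baseline_age_range_oa
    baseline_age <- ifelse(cohort == "MA",
                           runif(n, rng_ma[1], rng_ma[2]),
                           runif(n, rng_oa[1], rng_oa[2]))
    cv <- config$covariates
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      cohort = cohort, sex = sex, baseline_age = baseline_age,
      education = pmax(6, rnorm(n, cv$education_mean, cv$education_sd)),
      apoe4 = as.integer(runif(n) < cv$apoe4),
      smoker = as.integer(runif(n) < cv$smoker),
      diabetes = as.integer(runif(n) < ifelse(cohort == "MA",
                                              cv$diabetes_ma, cv$diabetes_oa)),
      bmi = pmax(15, rnorm(n, cv$bmi_mean, cv$bmi_sd)),
      physical_activity = pmax(0, rnorm(n, cv$activity_mean, cv$activity_sd)),
      depression_score = pmax(0, rnorm(n, cv$depression_mean, cv$depression_sd)),
      alcohol_intake = pmax(0, rnorm(n, cv$alcohol_mean, cv$alcohol_sd)),
      neuro_flag_subject = as.integer(runif(n) < ifelse(cohort == "MA",
                                                        config$neuro_rate_ma,
                                                        config$neuro_rate_oa)),
      stringsAsFactors = FALSE)
  })

  visits <- with_stage_seed(seed, "visits", {
    # monotone dropout: subject seen at waves 0..k
    last_wave <- rep(config$n_waves - 1L, n)
    if (config$n_waves > 1L) {
      for (i in seq_len(n)) {
        for (w in seq_len(config$n_waves - 1L)) {
          if (runif(1) < config$attrition[w]) { last_wave[i] <- w - 1L; break }
        }
      }
    }
    rows <- lapply(seq_len(n), function(i) {
      waves <- 0:last_wave[i]
      gaps <- config$wave_interval +
        rnorm(length(waves), 0, config$wave_jitter_sd)
      t <- cumsum(c(0, pmax(0.5, gaps[-1])))
      mmse <- pmin(30, round(rnorm(length(waves), config$mmse_mean,
                                   config$mmse_sd)))
      data.frame(
        subject_id = subjects$subject_id[i],
        wave = waves,
        time_in_study = t,
        age_at_visit = subjects$baseline_age[i] + t,
        sbp_reading_1 = NA_real_, sbp_reading_2 = NA_real_,
        dbp_reading_1 = NA_real_, dbp_reading_2 = NA_real_,
        mmse = mmse,
        neuro_flag = subjects$neuro_flag_subject[i],
        scan_available = 1L,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  # time-varying anti-hypertensive medication: baseline status by cohort,
  # monotone (once on, stays on) with a small per-wave initiation hazard
  visits <- with_stage_seed(seed, "medication", {
    cv <- config$covariates
    on_med <- integer(nrow(visits))
    for (i in seq_len(n)) {
      idx <- which(visits$subject_id == subjects$subject_id[i])
      p0 <- if (subjects$cohort[i] == "MA") cv$bp_med_ma else cv$bp_med_oa
      status <- as.integer(runif(1) < p0)
      for (j in seq_along(idx)) {
        if (j > 1 && status == 0L)
          status <- as.integer(runif(1) < cv$bp_med_initiation)
        on_med[idx[j]] <- status
      }
    }
    visits$on_bp_med <- on_med
    visits
  })

  if (apply_missingness && config$covariate_missing_rate > 0) {
    subjects <- with_stage_seed(seed, "missingness", {
      for (col in c("education", "bmi", "physical_activity",
                    "depression_score", "alcohol_intake")) {
        drop <- runif(n) < config$covariate_missing_rate
        subjects[[col]][drop] <- NA_real_
      }
      subjects
    })
  }
  rownames(subjects) <- rownames(visits) <- NULL
  list(subjects = subjects, visits = visits)
}

#' Simulate blood-pressure trajectories and readings
#'
#' Each subject receives a baseline MAP and pulse pressure drawn from
#' cohort/sex-specific distributions and subject-specific annual slopes drawn
#' from the configured slope distributions.  The visit-level true SBP/DBP are
#' reconstructed from (MAP, PP) and observed as two independent readings per
#' measure (true value plus reading noise).
#'
#' @param subjects,visits tables from [build_design()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return `visits` with the four reading columns filled and hidden
#'   generating columns `true_map`, `true_sbp`, `true_dbp` appended.
#' @export
simulate_bp <- function(subjects, visits, config, seed = config$seed %||% 1L) {
  if (nrow(visits) == 0L) stop("no visits to simulate BP for")
  validate_sim_config(config)
  with_stage_seed(seed, "bp", {
    n <- nrow(subjects)
    key <- paste(tolower(subjects$cohort))
    bb <- config$bp_baseline
    base_map_mean <- ifelse(subjects$cohort == "MA",
                            bb$map$ma[subjects$sex], bb$map$oa[subjects$sex])
    base_pp_mean <- ifelse(subjects$cohort == "MA",
                           bb$pp$ma[subjects$sex], bb$pp$oa[subjects$sex])
    map0 <- rnorm(n, base_map_mean, bb$map$sd)
    pp0 <- pmax(20, rnorm(n, base_pp_mean, bb$pp$sd))
    slope_map <- rnorm(n, config$bp_slopes$map["mean"],
                       config$bp_slopes$map["sd"])
    slope_pp <- rnorm(n, config$bp_slopes$pp["mean"],
                      config$bp_slopes$pp["sd"])
    idx <- match(visits$subject_id, subjects$subject_id)
    t <- visits$time_in_study
    true_map <- map0[idx] + slope_map[idx] * t
    true_pp <- pp0[idx] + slope_pp[idx] * t
    true_sbp <- true_map + (2 / 3) * true_pp
    true_dbp <- true_map - (1 / 3) * true_pp
    m <- nrow(visits)
    s <- config$reading_noise_sd
    visits$sbp_reading_1 <- true_sbp + rnorm(m, 0, s)
    visits$sbp_reading_2 <- true_sbp + rnorm(m, 0, s)
    visits$dbp_reading_1 <- true_dbp + rnorm(m, 0, s)
    visits$dbp_reading_2 <- true_dbp + rnorm(m, 0, s)
    visits$true_map <- true_map
    visits$true_sbp <- true_sbp
    visits$true_dbp <- true_dbp
    visits
  })
}

#' Simulate gray-matter-like feature vectors for each scan
#'
#' Features are a linear mixing of a small latent space whose first axis is a
#' latent brain age (chronological age plus configured BP and sex
#' deviations), plus a scanner batch offset and iid noise.  Scanner labels
#' switch from `"A"` to `"B"` at the configured changepoint wave.
#'
#' @param visits visit table; must carry `map` (see [add_bp_measures()]) when
#'   `feature_bp_effect != 0`, and `sex` is looked up via `subjects`.
#' @param subjects subject table (for sex).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `"feature_matrix"`: list with the numeric matrix
#'   `x` (scans x features), `scan_id`, `subject_id`, `age`, `scanner`.
#' @export
simulate_features <- function(visits, subjects, config,
                              seed = config$seed %||% 1L) {
  validate_sim_config(config)
  if (config$feature_dim < config$n_latent)
    stop("invalid sim_config field 'feature_dim': need feature_dim >= n_latent")
  if (config$feature_bp_effect != 0 && is.null(visits$map))
    stop("visits must carry a 'map' column (run add_bp_measures) when ",
         "feature_bp_effect != 0")
  with_stage_seed(seed, "features", {
    nsc <- nrow(visits)
    p <- config$feature_dim; L <- config$n_latent
    sex <- subjects$sex[match(visits$subject_id, subjects$subject_id)]
    latent_age <- visits$age_at_visit +
      config$feature_bp_effect * ((visits$map %||% 90) - 90) +
      config$feature_sex_effect * (sex == "female")
    Z <- matrix(rnorm(nsc * L), nsc, L)
    Z[, 1] <- latent_age * config$feature_age_scale
    mix <- matrix(rnorm(p * L), L, p) / sqrt(L)
    scanner <- ifelse(visits$wave >= config$scanner_changepoint, "B", "A")
    x <- Z %*% mix +
      config$scanner_effect_size * (scanner == "B") +
      matrix(rnorm(nsc * p, 0, config$feature_noise_sd), nsc, p)
    scan_id <- sprintf("%s_w%d", visits$subject_id, visits$wave)
    rownames(x) <- scan_id
    feature_matrix(x, scan_id = scan_id, subject_id = visits$subject_id,
                   age = visits$age_at_visit, scanner = scanner)
  })
}

#' Simulate the brain-age-gap outcome from the generating mixed model
#'
#' Generates per-visit BrainAGE (years) as
#' `beta_map*(MAP - 90) + beta_time*time + beta_cohort*I(OA) +
#' beta_sex*I(female) + intercept + u_i + e_ij` with subject random
#' intercepts `u_i` and residuals `e_ij` from the configured SDs.
#'
#' @param visits visit table carrying a `map` column (mmHg).
#' @param subjects subject table.
#' @param config a [sim_config()]; coefficients under `outcome_model`.
#' @param seed integer seed.
#' @return `visits` with a `brainage` column appended.
#' @export
simulate_brainage_outcome <- function(visits, subjects, config,
                                      seed = config$seed %||% 1L) {
  if (is.null(visits$map))
    stop("visits must carry a 'map' column; run simulate_bp + add_bp_measures first")
  om <- config$outcome_model
  with_stage_seed(seed, "outcome", {
    idx <- match(visits$subject_id, subjects$subject_id)
    u <- rnorm(nrow(subjects), 0, om$sd_intercept)
    e <- rnorm(nrow(visits), 0, om$sd_resid)
    lp <- om$beta_map * (visits$map - 90) +
      om$beta_time * visits$time_in_study +
      om$beta_cohort * (subjects$cohort[idx] == "OA") +
      om$beta_sex * (subjects$sex[idx] == "female") +
      om$intercept
    visits$brainage <- lp + u[idx] + e
    visits
  })
}

#' Simulate a complete analysis-ready cohort
#'
#' Convenience wrapper: design, BP trajectories, derived BP measures and the
#' generated brain-age-gap outcome, merged with subject-level covariates into
#' one long-format analysis table.
#'
#' @inheritParams build_design
#' @param features if `TRUE`, also simulate a [feature_matrix].
#' @return list with `subjects`, `visits`, `data` (merged long table) and
#'   optionally `features`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed %||% 1L,
                            features = FALSE) {
  d <- build_design(config, seed)
  d$visits <- simulate_bp(d$subjects, d$visits, config, seed)
  d$visits <- add_bp_measures(d$visits)
  d$visits <- simulate_brainage_outcome(d$visits, d$subjects, config, seed)
  data <- merge(d$visits, d$subjects, by = "subject_id", sort = FALSE)
  data <- data[order(data$subject_id, data$wave), ]
  rownames(data) <- NULL
  out <- list(subjects = d$subjects, visits = d$visits, data = data)
  if (features)
    out$features <- simulate_features(d$visits, d$subjects, config, seed)
  out
}

#' Construct a feature matrix object
#'
#' Container for per-scan feature vectors with scan metadata, as consumed by
#' the brain-age estimation engine.
#'
#' @param x numeric matrix, scans in rows.
#' @param scan_id,subject_id,age,scanner per-scan metadata vectors.
#' @return object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(x, scan_id, subject_id, age, scanner) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(scan_id), length(scan_id) == length(subject_id),
            length(age) == length(scan_id), length(scanner) == length(scan_id))
  if (anyNA(x)) stop("feature matrix must not contain missing values")
  structure(list(x = x, scan_id = as.character(scan_id),
                 subject_id = as.character(subject_id),
                 age = as.numeric(age), scanner = as.character(scanner)),
            class = "feature_matrix")
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d scans x %d features, %d subjects, scanners: %s\n",
              nrow(x$x), ncol(x$x), length(unique(x$subject_id)),
              paste(sort(unique(x$scanner)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)
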