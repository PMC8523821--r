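# Small cohort configuration used across tests: quick to simulate but with
# the same structure as the default study conditions.
tiny_config <- function(...) {
  sim_config(n_ma = 30L, n_oa = 30L, ...)
}

# Feature matrix with a clean linear age signal in one latent dimension.
age_signal_features <- function(n_subjects = 12, scans_each = 2, p = 8,
                                noise = 0, seed = 42) {
  set.seed(seed)
  subject_id <- rep(sprintf("S%02d", seq_len(n_subjects)), each = scans_each)
  age <- runif(n_subjects * scans_each, 45, 75)
  load <- rnorm(p)
  x <- outer(age, load) + matrix(rnorm(length(age) * p, 0, noise),
                                 length(age), p)
  feature_matrix(x, scan_id = paste0(subject_id, "_", seq_along(age)),
                 subject_id = subject_id, age = age,
                 scanner = rep(c("A", "B"), length.out = length(age)))
}

# Analysis table generated from the configured outcome model, for mixed-model
# tests that need full control over the variance components.
outcome_cohort <- function(config = tiny_config(), seed = 1) {
  simulate_cohort(config, seed = seed)$data
}
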