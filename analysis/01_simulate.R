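#!/usr/bin/env Rscript
# Simulate the synthetic longitudinal cohort at the study scale:
# 335 middle-aged + 351 older adults, up to four waves ~4 years apart,
# blood-pressure trajectories, covariates and the generated brain-age-gap
# outcome.  Writes the long-format tables under results/.

library(brainageBP)

seed <- 1L
cfg <- sim_config()
dir.create("results", showWarnings = FALSE)

sim <- simulate_cohort(cfg, seed = seed)

cat(sprintf("subjects: %d (MA %d, OA %d); visits: %d\n",
            nrow(sim$subjects), sum(sim$subjects$cohort == "MA"),
            sum(sim$subjects$cohort == "OA"), nrow(sim$visits)))
scan_counts <- table(table(sim$visits$subject_id))
cat("visits per subject:",
    paste(names(scan_counts), as.numeric(scan_counts), sep = "x",
          collapse = ", "), "\n")

# per-subject OLS slopes of the three BP measures, for calibration eyeballing
slope_of <- function(col) {
  s <- vapply(split(sim$visits, sim$visits$subject_id), function(d)
    if (nrow(d) >= 2) unname(coef(lm(d[[col]] ~ d$time_in_study))[2])
    else NA_real_, numeric(1))
  mean(s, na.rm = TRUE)
}
cat(sprintf("mean annual change: MAP %.2f, SBP %.2f, DBP %.2f mmHg/yr\n",
            slope_of("map"), slope_of("sbp"), slope_of("dbp")))

write.table(sim$subjects, "results/subjects.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$visits, "results/visits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$data, "results/analysis_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/subjects.tsv, results/visits.tsv, results/analysis_table.tsv\n")
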