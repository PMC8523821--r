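#!/usr/bin/env Rscript
# Apply the eligibility flow to the simulated cohort: minimum two scans,
# no neurological flag or MMSE < 25, baseline MAP within 3 SD of the
# cohort mean, complete key baseline covariates.  Writes the filtered
# tables and the per-stage exclusion report.

library(brainageBP)

subjects <- read.delim("results/subjects.tsv")
visits <- read.delim("results/visits.tsv")

res <- apply_eligibility(subjects, visits)
print(res$report)

write.table(res$subjects, "results/subjects_eligible.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$visits, "results/visits_eligible.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(stages = res$report$stages, n_final = res$report$n_final,
       n_final_by_cohort = res$report$n_final_by_cohort),
  "results/eligibility_report.json", auto_unbox = TRUE, digits = NA,
  dataframe = "columns")
cat("wrote results/subjects_eligible.tsv, results/visits_eligible.tsv, results/eligibility_report.json\n")
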