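#!/usr/bin/env Rscript
# Individual-level replication arm on a simulated cohort.
#
# The cohort emulates a population biobank slice: 20,000 unrelated adults
# aged 40-69, 46% male, genotypes at the homocysteine instrument variants,
# eGFR median near 92.5 mL/min/1.73 m^2 computed from back-derived serum
# creatinine via the CKD-EPI equation, genotyping batches, 10 genetic PCs,
# comorbidity flags, and realistic missingness. The causal effect is set to
# -0.0095 log-eGFR per SD exposure. Both the main model (age, sex, batch,
# PCs) and the clinical sensitivity model (+hypertension, diabetes, obesity)
# are fitted per exposure.

suppressPackageStartupMessages(library(mrkit))

seed <- 1L
dir.create("results", showWarnings = FALSE)

sim <- simulate_cohort(cohort_sim_config(n_individuals = 20000L,
                                         theta = -0.0095,
                                         seed = derive_seed(seed, "cohort")))
cat("Simulated cohort: ")
print(sim$cohort)
cat(sprintf("median eGFR %.1f mL/min/1.73m^2\n",
            median(sim$cohort$phenotype$egfr, na.rm = TRUE)))

report <- run_cohort_arm(run_config(cohort = sim$cohort,
                                    out_dir = "results", seed = seed))

cat("\nAllele-score MR, eGFR change per 1 SD of allele score:\n")
print(report$score_results, digits = 3, row.names = FALSE)

cat("\nNote: with a homocysteine-calibrated data-generating effect, the",
    "\nfolate and cobalamin scores are expected to show attenuated or null",
    "\nassociations driven only by variants shared across instruments.\n")
cat("\nReport files under results/ (cohort_*.tsv, cohort_report.json)\n")
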