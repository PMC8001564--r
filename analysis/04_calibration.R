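#!/usr/bin/env Rscript
# Sampling calibration of the estimator suite (desk-scale companion of the
# heavier checks in tests/testthat/test-acceptance.R):
#   * no-pleiotropy recovery: IVW bias and IVW/penalized-weighted-median
#     coverage over 200 replicate summary datasets;
#   * directional pleiotropy (30% invalid instruments, InSIDE holding):
#     mean-bias comparison of IVW vs MR-Egger and contamination-mixture
#     behaviour.
# Writes results/method_calibration.tsv.

suppressPackageStartupMessages(library(mrkit))

seed <- 1L
theta <- -0.0095
n_rep <- 200L
dir.create("results", showWarnings = FALSE)

rec <- t(vapply(seq_len(n_rep), function(i) {
  sim <- simulate_summary(summary_sim_config(
    seed = derive_seed(seed, paste0("rec", i))))
  h <- harmonize(sim$instrument, sim$outcome)
  ivw <- ivw_fixed(h)
  pwm <- weighted_median(h, n_boot = 1000,
                         seed = derive_seed(seed, paste0("pwm", i)))
  c(ivw$beta, ivw$ci_low <= theta && theta <= ivw$ci_high,
    pwm$ci_low <= theta && theta <= pwm$ci_high)
}, numeric(3)))

ple <- t(vapply(seq_len(n_rep), function(i) {
  sim <- simulate_summary(summary_sim_config(
    prop_invalid = 0.3, pleiotropy_mean = 0.002, pleiotropy_sd = 0.001,
    seed = derive_seed(seed, paste0("ple", i))))
  h <- harmonize(sim$instrument, sim$outcome)
  c(ivw_fixed(h)$beta,
    egger(h, n_boot = 200, seed = derive_seed(seed, paste0("eg", i)))$beta,
    contamination_mixture(h)$beta)
}, numeric(3)))

tab <- data.frame(
  quantity = c("ivw_mean_bias_pct_of_theta", "ivw_coverage_pct",
               "pwm_coverage_pct", "ivw_abs_bias_pleiotropy",
               "egger_abs_bias_pleiotropy", "conmix_abs_bias_pleiotropy"),
  value = c(100 * abs(mean(rec[, 1]) - theta) / abs(theta),
            100 * mean(rec[, 2]), 100 * mean(rec[, 3]),
            abs(mean(ple[, 1]) - theta), abs(mean(ple[, 2]) - theta),
            abs(mean(ple[, 3]) - theta)),
  n_rep = n_rep)

cat("No pleiotropy: IVW mean bias is", sprintf("%.2f%%", tab$value[1]),
    "of |theta|; coverage IVW", sprintf("%.1f%%,", tab$value[2]),
    "penalized weighted median", sprintf("%.1f%%.\n", tab$value[3]))
cat("Directional pleiotropy (30% invalid): |mean bias| IVW",
    sprintf("%.2e,", tab$value[4]), "MR-Egger", sprintf("%.2e,", tab$value[5]),
    "contamination mixture", sprintf("%.2e.\n", tab$value[6]))
cat("The pleiotropy-robust estimators out-perform IVW exactly when invalid",
    "\ninstruments push a directional effect through the excluded path.\n")

write.table(tab, "results/method_calibration.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nWrote results/method_calibration.tsv\n")
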