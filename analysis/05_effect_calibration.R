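#!/usr/bin/env Rscript
# Calibrate the synthetic generator's disposition gap so that the planted
# effects match the target Cohen's d values for the two strongest reported
# effects, then re-estimate all seven effect sizes at the calibrated gap.

library(riskpool)

targets <- c(mean_amount_given = 0.65, repetitive_giving = 0.46)
cal <- calibrate_to_effect_sizes(targets, seed = 5L)
print(cal)
write.csv(cal$report, "results/calibration_grid.csv", row.names = FALSE)

d_mat <- sapply(1:10, function(r) {
  log <- generate_experiment(cal$spec, lab_game_config(), seed = 600L + r)
  rep <- reproduce_report(log)
  setNames(rep$cohens_d, rep$variable)
})
cat("\nmean Cohen's d over 10 replicate experiments at the calibrated gap:\n")
print(round(rowMeans(d_mat), 3))
write.csv(
  data.frame(variable = rownames(d_mat), mean_d = rowMeans(d_mat)),
  "results/calibrated_effect_sizes.csv", row.names = FALSE
)
cat("wrote results/calibration_grid.csv and results/calibrated_effect_sizes.csv\n")
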