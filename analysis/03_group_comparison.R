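#!/usr/bin/env Rscript
# Compare control vs (pooled) primed players on the seven behavioral
# variables: ANOVA + Scheffe pooling check across the primed
# sub-conditions, then independent-samples t tests with Cohen's d and the
# Bonferroni-adjusted alpha. Writes the comparison table and a bar figure
# of group means with standard errors.

library(riskpool)
library(dplyr)

metrics <- read_metrics_table("results/metrics_net.csv")

# pooling check across the four primed sub-conditions
chk <- condition_pooling_check(filter(metrics, condition != "control"))
cat("ANOVA across primed sub-conditions (pooling justified if nothing is significant):\n")
print(as.data.frame(chk$anova), digits = 3)
n_flagged <- sum(chk$scheffe$significant)
cat(sprintf("Scheffe contrasts flagged at 0.05: %d of %d\n\n",
            n_flagged, nrow(chk$scheffe)))
write.csv(chk$anova, "results/pooling_anova.csv", row.names = FALSE)

report <- compare_groups(metrics) # pools all non-control conditions
cat("control vs primed (Student's t, net accounting):\n")
print(as.data.frame(report[, c("variable", "mean_control", "mean_primed",
                               "t", "df", "p_two_tailed", "cohens_d",
                               "significant_at_alpha")]), digits = 3)
cat(sprintf("\nBonferroni-adjusted alpha: %.3f (0.05 / 7)\n",
            unique(report$alpha_used)))
write.csv(report, "results/group_comparison.csv", row.names = FALSE)

welch <- compare_groups(metrics, welch = TRUE)
write.csv(welch, "results/group_comparison_welch.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  plot_df <- metrics |>
    mutate(group = ifelse(condition == "control", "control", "primed")) |>
    tidyr::pivot_longer(all_of(behavioral_variables()),
                        names_to = "variable") |>
    group_by(group, variable) |>
    summarise(mean = mean(value), sem = sd(value) / sqrt(n()),
              .groups = "drop")
  fig <- ggplot(plot_df, aes(variable, mean, fill = group)) +
    geom_col(position = position_dodge(0.9)) +
    geom_errorbar(aes(ymin = mean - sem, ymax = mean + sem),
                  position = position_dodge(0.9), width = 0.25) +
    coord_flip() +
    labs(x = NULL, y = "group mean ± SEM", fill = NULL) +
    theme_minimal()
  ggsave("results/group_means.png", fig, width = 7, height = 4.5, dpi = 150)
  cat("wrote results/group_means.png\n")
}
cat("wrote results/group_comparison*.csv\n")
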