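#!/usr/bin/env Rscript
# Compute the seven behavioral variables per player from the session log,
# under both debt-accounting conventions (net ledger and gift-by-gift).

library(riskpool)
library(dplyr)

log <- read_session_log("results/session_log.csv")

metrics <- player_metrics(log, accounting = "net")
metrics_gift <- player_metrics(log, accounting = "gift")
write_metrics_table(metrics, "results/metrics_net.csv")
write_metrics_table(metrics_gift, "results/metrics_gift.csv")

pooled <- metrics |>
  mutate(group = ifelse(condition == "control", "control", "primed")) |>
  group_by(group) |>
  summarise(across(all_of(behavioral_variables()), mean), .groups = "drop")
cat("group means (net accounting):\n")
print(as.data.frame(pooled), digits = 3)

agree <- all(metrics$repetitive_giving == metrics_gift$repetitive_giving &
               metrics$repetitive_asking == metrics_gift$repetitive_asking)
cat(sprintf(
  "\naccounting conventions %s on this log (they differ only when gifts are over-repaid).\n",
  if (agree) "agree exactly" else "differ for some players"
))
cat("wrote results/metrics_net.csv and results/metrics_gift.csv\n")
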