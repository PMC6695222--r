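#!/usr/bin/env Rscript
# Survival under paired transfer strategies in a harsh high-volatility
# environment: the coordination (Stag Hunt) structure of risk-pooling
# norms. Mutual need-based transfers should top the survival ordering.

library(riskpool)

res <- stag_hunt_experiment(n_sessions = 500, seed = 4L)
cat("mean periods survived (of 80) by strategy pairing, 500 sessions each:\n")
print(as.data.frame(res$summary), digits = 3)
write.csv(res$summary, "results/stag_hunt_summary.csv", row.names = FALSE)

s <- res$summary
best <- s$pairing[which.max(s$mean_survival)]
cat(sprintf("\nhighest survival: %s\n", best))
cat("wrote results/stag_hunt_summary.csv\n")
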