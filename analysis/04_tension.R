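#!/usr/bin/env Rscript
# Ectoderm junctional tension from the energy gradient: time series,
# percent change at 40 min per scenario, and the endpoint contrast
# between control and division-inhibited tissues.

library(meboundary)

ex <- readRDS("results/experiment.rds")
reps <- ex$replicates

for (sc in c("control", "no_division")) {
  pc <- reps$tension_pct[reps$scenario == sc]
  cat(sprintf("%-12s: tension change over 40 min %+5.1f +/- %.1f %%\n",
              sc, mean(pc), sd(pc) / sqrt(length(pc))))
}
t_c <- mean(reps$tension_end[reps$scenario == "control"])
t_n <- mean(reps$tension_end[reps$scenario == "no_division"])
cat(sprintf("endpoint tension %.0f%% greater without divisions\n",
            100 * (t_n / t_c - 1)))
res <- group_compare(
  c(reps$tension_pct[reps$scenario == "control"],
    reps$tension_pct[reps$scenario == "no_division"]),
  rep(c("control", "no_division"), each = sum(reps$scenario == "control")))
cat(sprintf("Mann-Whitney p = %.2g\n", res$omnibus$p_value))
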