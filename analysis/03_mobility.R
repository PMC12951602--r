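#!/usr/bin/env Rscript
# Ectoderm cell mobility: self-overlap half-times (with the fraction of
# replicates whose overlap never decays below one half) and registered
# MSD with anterior-posterior / dorsal-ventral components.

library(meboundary)

ex <- readRDS("results/experiment.rds")
reps <- ex$replicates

for (sc in c("control", "no_division")) {
  ht <- reps$halftime[reps$scenario == sc]
  dec <- is.finite(ht)
  cat(sprintf("%-12s: Q half-time %.1f +/- %.1f min (%d/%d replicates decayed)\n",
              sc, mean(ht[dec]), sd(ht[dec]) / sqrt(max(sum(dec), 1)),
              sum(dec), length(ht)))
}

m_c <- reps$msd_end[reps$scenario == "control"]
m_n <- reps$msd_end[reps$scenario == "no_division"]
cat(sprintf("MSD at 40 min: control %.1f um^2, no-division %.1f um^2 (-%.0f%%)\n",
            mean(m_c), mean(m_n), 100 * (1 - mean(m_n) / mean(m_c))))
res <- group_compare(c(m_c, m_n),
                     rep(c("control", "no_division"), c(length(m_c),
                                                        length(m_n))))
cat(sprintf("Mann-Whitney p = %.2g\n", res$omnibus$p_value))

ap <- mean(reps$msd_ap_end[reps$scenario == "control"])
dv <- mean(reps$msd_dv_end[reps$scenario == "control"])
cat(sprintf("control axis components at 40 min: AP %.1f, DV %.1f um^2\n",
            ap, dv))
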