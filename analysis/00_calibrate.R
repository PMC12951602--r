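#!/usr/bin/env Rscript
# Calibration of the free model parameters.
#
# The published description fixes K_A = 1, T = 0.010, dt = 0.01 tau,
# tau = 0.1 min, q = 3.4, 400 cells, and the division block at 5 min, but
# the remaining values (gamma0, k_gamma, K_P, the bidisperse preferred
# areas, the mesectoderm constriction depth, the division rate) live in
# supplementary material that is not reproduced in the main text. They
# are fixed here by a small grid search anchored on the published
# in-silico outcomes, primarily:
#   (i)  control relative roughness decreasing ~7% by 40 min,
#   (ii) acute-tension-loss roughness rising ~36% by 10 min,
# with the division-driven tension release (-27.2% over 40 min in
# control, +5.1% without divisions), the self-overlap half-time (~31 min)
# and the published mean junction counts per simulation (~1439 control,
# ~1234 without divisions) as secondary anchors.
#
# The chosen values are FROZEN as the defaults of me_schedule() /
# scenario_config(); re-running this script explores the neighbourhood of
# those defaults and reports the anchor statistics per candidate. At the
# default desk scale (a handful of seeds per candidate) each line takes a
# few minutes.

library(meboundary)

args <- commandArgs(trailingOnly = TRUE)
nseed <- if (length(args) >= 1) as.integer(args[1]) else 3L

candidates <- expand.grid(
  gamma0 = c(0.7, 0.9),
  k_gamma = c(0.02),
  division_rate = c(8),
  inject = c(0.18),          # 2*A0_post - A0_pre at (A0_pre+A0_post)/2 = 1
  mesec_end_frac = c(0.6),
  equil_min = c(5, 7))

dir.create("results", showWarnings = FALSE)
rows <- list()
for (i in seq_len(nrow(candidates))) {
  cand <- candidates[i, ]
  post <- (2 + cand$inject) / 3
  pre <- 2 - post
  sch <- me_schedule(gamma0 = cand$gamma0, k_gamma = cand$k_gamma,
                     division_rate = cand$division_rate,
                     A0_ecto_pre = pre, A0_ecto_post = post,
                     A0_mesec_end_frac = cand$mesec_end_frac)
  base <- scenario_config(schedule = sch, equil_min = cand$equil_min)
  ex <- run_experiment(replicates = nseed, seeds = seq_len(nseed),
                       base_config = base)
  s <- summarize_experiment(ex)
  rownames(s) <- s$scenario
  row <- cbind(cand, data.frame(
    ctrl_rough_40 = 100 * (s["control", "rough_rel_end"] - 1),
    loss_rough_10 = 100 * (s["no_tension", "rough_rel_10"] - 1),
    loss_rough_40 = 100 * (s["no_tension", "rough_rel_end"] - 1),
    nodiv_rough_40 = 100 * (s["no_division", "rough_rel_end"] - 1),
    ctrl_tension_pct = s["control", "tension_pct"],
    nodiv_tension_pct = s["no_division", "tension_pct"],
    ctrl_halftime = s["control", "halftime"],
    msd_reduction = 100 * (1 - s["no_division", "msd_end"] /
                             s["control", "msd_end"])))
  rows[[i]] <- row
  print(row, digits = 3)
}
out <- do.call(rbind, rows)
write.csv(out, "results/calibration_grid.csv", row.names = FALSE)
cat("\nanchors: ctrl_rough_40 ~ -7, loss_rough_10 ~ +36,",
    "ctrl_tension_pct ~ -27.2, nodiv_tension_pct ~ +5.1,",
    "ctrl_halftime ~ 31 min\n")
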