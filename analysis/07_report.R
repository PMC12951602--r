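#!/usr/bin/env Rscript
# Renders ensemble figures (mean +/- sem curves, AUC boxplots, a
# tension-coloured tissue snapshot) from the stored experiment bundle.

library(meboundary)
ex <- readRDS("results/experiment.rds")
paths <- render_reports(ex, "results/figures")
cat("wrote:\n"); cat(paste(" ", paths), sep = "\n")
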