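#!/usr/bin/env Rscript

# Render summary figures from the tidy results written by the earlier steps.

library(synthrep)

res <- read.csv("results/sequential_metrics.csv")
if (nrow(res) == 0) stop("run analysis/04_sequential_replicability.R first")
res <- tibble::as_tibble(res)

report_results(res,
               metrics = c("decision_agreement", "estimate_agreement",
                           "standardized_difference", "ci_overlap"),
               file = "results/figures/comparison_metrics.png")
report_results(res,
               metrics = c("bias", "coverage", "power", "emp_se"),
               file = "results/figures/inference_metrics.png")
cat("figures written under results/figures/\n")
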