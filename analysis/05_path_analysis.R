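#!/usr/bin/env Rscript
# Stage 5: crown allometry by age stage.
#
# Wright path analysis of crown width and live crown ratio on DBH and tree
# height, one model per age stage: standardized direct coefficients,
# indirect effects through the other predictor, and t-test significance
# ("***" marks p < 0.001).

suppressMessages(library(standstruct))

inv <- read_inventory("results/synthetic/trees.csv",
                      "results/synthetic/plots.csv", quiet = TRUE)
out <- "results/paths"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (resp in c("crown_width", "live_crown_ratio")) {
  tab <- stage_path_table(inv$trees, inv$plots, response = resp)
  write_table(tab, file.path(out, paste0("path_", resp, ".csv")))
  message(sprintf("%s:", resp))
  message(paste(capture.output(
    print(tab[, c("stage", "n", "direct_dbh", "sig_dbh", "direct_height",
                  "sig_height", "indirect_dbh", "indirect_height")],
          digits = 2, row.names = FALSE)), collapse = "\n"))
}
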