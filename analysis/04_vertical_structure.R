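#!/usr/bin/env Rscript
# Stage 4: vertical structure.
#
# TSTRAT-stratifies every plot (founder cut-off 0.4*CL + HBLC) and pools
# the layer summary: how many plots are single- vs multi-layered, and the
# dominant layer's tree share and mean dimensions.

suppressMessages(library(standstruct))

inv <- read_inventory("results/synthetic/trees.csv",
                      "results/synthetic/plots.csv", quiet = TRUE)
out <- "results/vertical"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

strat <- stratify_inventory(inv$trees, inv$plots)
write_table(strat$per_tree, file.path(out, "strata_per_tree.csv"))
ls <- strat$layer_summary
write_table(data.frame(n_strata = as.integer(names(ls$plots_by_n_strata)),
                       n_plots = as.integer(ls$plots_by_n_strata)),
            file.path(out, "layer_counts.csv"))
write_table(data.frame(
  dominant_share_pct = ls$dominant_share_pct,
  dominant_mean_height_m = ls$dominant_mean_height_m,
  dominant_mean_dbh_cm = ls$dominant_mean_dbh_cm,
  dominant_mean_crown_length_m = ls$dominant_mean_crown_length_m,
  multilayer_mean_dominant_share_pct = ls$multilayer_mean_dominant_share_pct),
  file.path(out, "layer_summary.csv"))

message(sprintf("plots by layer count: %s",
                paste(names(ls$plots_by_n_strata), ls$plots_by_n_strata,
                      sep = " layer(s): ", collapse = ", ")))
message(sprintf(
  "dominant layer holds %.2f%% of trees (mean height %.2f m, DBH %.2f cm, crown length %.2f m)",
  ls$dominant_share_pct, ls$dominant_mean_height_m,
  ls$dominant_mean_dbh_cm, ls$dominant_mean_crown_length_m))
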