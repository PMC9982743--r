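#!/usr/bin/env Rscript
# Stage 1: build the synthetic study region.
#
# Generates the default nine-city inventory — 31 plots of 1,000 m2, 3,633
# trees, stage-dependent truncated-Weibull DBH, allometric heights and
# crowns, covariate-driven diversity — and writes the two inventory tables
# plus the generating ground truth.  Everything downstream reads these
# files.

suppressMessages(library(standstruct))

seed <- 1L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

inv <- generate_inventory(stand_params(), seed = seed)
write_table(inv$trees, file.path(out, "trees.csv"))
write_table(inv$plots, file.path(out, "plots.csv"))
jsonlite::write_json(inv$ground_truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf("inventory: %d trees in %d plots across %d cities",
                nrow(inv$trees), nrow(inv$plots),
                length(unique(inv$plots$city))))
message(sprintf("DBH %.1f-%.1f cm, height %.1f-%.1f m, crown-length clamp rate %.2g",
                min(inv$trees$dbh_cm), max(inv$trees$dbh_cm),
                min(inv$trees$height_m), max(inv$trees$height_m),
                inv$ground_truth$clamp_rate))
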