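# Shared fixtures, all built in code at test time.

# The default nine-city synthetic inventory (31 plots, 3,633 trees).
table1_inventory <- function(seed = 1L) {
  generate_inventory(stand_params(), seed = seed)
}

# Write an inventory to csv files in a fresh temp dir; returns the paths.
write_inventory_fixture <- function(inv, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tree_path <- file.path(dir, "trees.csv")
  plot_path <- file.path(dir, "plots.csv")
  write_table(inv$trees, tree_path)
  write_table(inv$plots, plot_path)
  list(tree_path = tree_path, plot_path = plot_path, dir = dir)
}

# A minimal valid plot row for hand-built stands.
minimal_plot <- function(plot_id = "P1", stand_age = 25L, altitude_m = 400,
                         slope_direction = "N", landform = "hill",
                         soil_type = "red", stand_density = 100,
                         temperature_c = 17, precipitation_mm = 1500,
                         n_trees = NA_integer_) {
  data.frame(plot_id = plot_id, city = "TestCity", stand_age = stand_age,
             altitude_m = altitude_m, slope_direction = slope_direction,
             landform = landform, soil_type = soil_type,
             stand_density = stand_density, temperature_c = temperature_c,
             precipitation_mm = precipitation_mm, n_trees = n_trees,
             stringsAsFactors = FALSE)
}

# Hand-built tree table satisfying all record invariants.
minimal_trees <- function(n = 5, plot_id = "P1") {
  h <- seq(6, 12, length.out = n)
  data.frame(plot_id = plot_id, dbh_cm = seq(8, 20, length.out = n),
             height_m = h, crown_width_m = rep(2.5, n),
             crown_length_m = 0.5 * h, stringsAsFactors = FALSE)
}
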