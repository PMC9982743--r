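#' Default configuration of the full analysis run
#'
#' One configuration object drives the whole pipeline.  With no input
#' paths, a synthetic inventory is generated from `params` (the default
#' 31-plot, nine-city layout); the fixed constants of the analysis — the
#' diameter-class edges, the age-stage bounds, the 0.4 crown coefficient of
#' the stratification cut-off — are built into the respective functions.
#'
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory for result tables and the run report.
#' @param tree_path,plot_path optional existing inventory tables; when
#'   `NULL` the synthetic generator supplies the data.
#' @param params a [stand_params()] object for the generator.
#' @param stages which stages to run.
#' @param ad_permutations permutations for the k-sample test.
#' @param gbm [driver_hyperparams()] for the driver model.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "results",
                       tree_path = NULL, plot_path = NULL,
                       params = stand_params(),
                       stages = c("horizontal", "drivers", "vertical", "paths"),
                       ad_permutations = 999,
                       gbm = driver_hyperparams()) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 tree_path = tree_path, plot_path = plot_path,
                 params = params, stages = stages,
                 ad_permutations = ad_permutations, gbm = gbm),
            class = "run_config")
}

#' Run the full stand-structure analysis
#'
#' Executes the requested stages in order — horizontal structure (per-city
#' distribution summary, k-sample test, stage comparisons, class-proportion
#' curves), diversity drivers (boosted model, influence, marginal
#' effects), vertical structure (stratification and layer summary), and
#' path analysis (both crown responses) — writing every result table as
#' delimited text under `config$out_dir` plus a machine-readable
#' `report.json` with seeds, input checksums and per-stage headline
#' numbers.  Runs are deterministic under a fixed config and seed.
#'
#' @param config a [run_config()] object.
#' @param quiet suppress progress messages.
#' @return the report, invisibly.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outfile <- function(name) file.path(config$out_dir, name)
  report <- list(seed = config$seed, stages = as.list(config$stages))

  if (is.null(config$tree_path)) {
    say("simulating synthetic inventory (seed %d)", config$seed)
    inv <- generate_inventory(config$params, seed = config$seed)
    write_table(inv$trees, outfile("trees.csv"))
    write_table(inv$plots, outfile("plots.csv"))
    jsonlite::write_json(inv$ground_truth, outfile("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tree_path <- outfile("trees.csv")
    plot_path <- outfile("plots.csv")
  } else {
    tree_path <- config$tree_path
    plot_path <- config$plot_path
  }
  inv <- read_inventory(tree_path, plot_path, quiet = quiet)
  trees <- inv$trees
  plots <- inv$plots
  report$input <- list(
    tree_path = tree_path, plot_path = plot_path,
    n_trees = nrow(trees), n_plots = nrow(plots),
    n_cities = length(unique(plots$city)),
    md5 = as.list(tools::md5sum(c(tree_path, plot_path)))
  )

  if ("horizontal" %in% config$stages) {
    say("horizontal structure")
    summ <- distribution_summary(trees, plots, group_by = "city")
    write_table(summ, outfile("distribution_summary.csv"))
    city_dbh <- split(trees$dbh_cm, plots$city[match(trees$plot_id, plots$plot_id)])
    ad <- ad_k_sample(city_dbh, n_permutations = config$ad_permutations,
                      seed = config$seed)
    jsonlite::write_json(unclass(ad), outfile("ad_test.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_tests <- do.call(rbind, lapply(
      c("dbh", "height", "crown_width", "crown_length"),
      function(v) pairwise_stage_tests(trees, plots, v)))
    write_table(stage_tests, outfile("stage_tests.csv"))
    curves <- do.call(rbind, lapply(names(city_dbh), function(city) {
      fc <- fit_class_proportion_curve(bin_dbh(city_dbh[[city]]))
      cbind(city = city, fc$curve)
    }))
    write_table(curves, outfile("class_curves.csv"))
    report$horizontal <- list(
      shannon_range = range(summ$shannon),
      ad_statistic = ad$statistic,
      ad_standardized = ad$standardized_statistic,
      ad_p_value = ad$p_value
    )
  }

  if ("drivers" %in% config$stages) {
    say("diversity drivers")
    design <- plot_diversity(trees, plots)
    model <- fit_driver_model(design, hyperparams = config$gbm,
                              seed = config$seed)
    infl <- relative_influence(model)
    write_table(infl, outfile("influence.csv"))
    for (v in c("stand_density", "altitude_m", "slope_direction")) {
      write_table(marginal_effect(model, v),
                  outfile(paste0("marginal_", v, ".csv")))
    }
    write_table(
      marginal_effect(model, c("stand_density", "altitude_m", "slope_direction"),
                      grid_size = 20),
      outfile("marginal3_density_altitude_slope.csv"))
    report$drivers <- list(
      top_predictor = infl$predictor[1],
      top_influence_pct = infl$influence_pct[1],
      influence_sum = sum(infl$influence_pct),
      n_trees_used = attr(infl, "n_trees_used"),
      cv_rmse = attr(infl, "cv_rmse")
    )
  }

  if ("vertical" %in% config$stages) {
    say("vertical structure (TSTRAT)")
    strat <- stratify_inventory(trees, plots)
    write_table(strat$per_tree, outfile("strata_per_tree.csv"))
    ls <- strat$layer_summary
    layer_df <- data.frame(
      n_strata = as.integer(names(ls$plots_by_n_strata)),
      n_plots = as.integer(ls$plots_by_n_strata))
    write_table(layer_df, outfile("layer_counts.csv"))
    write_table(data.frame(
      dominant_share_pct = ls$dominant_share_pct,
      dominant_mean_height_m = ls$dominant_mean_height_m,
      dominant_mean_dbh_cm = ls$dominant_mean_dbh_cm,
      dominant_mean_crown_length_m = ls$dominant_mean_crown_length_m,
      multilayer_mean_dominant_share_pct = ls$multilayer_mean_dominant_share_pct),
      outfile("layer_summary.csv"))
    report$vertical <- ls[c("dominant_share_pct", "dominant_mean_height_m",
                            "dominant_mean_dbh_cm", "dominant_mean_crown_length_m")]
    report$vertical$plots_by_n_strata <- as.list(
      stats::setNames(as.integer(ls$plots_by_n_strata),
                      names(ls$plots_by_n_strata)))
  }

  if ("paths" %in% config$stages) {
    say("path analysis")
    for (resp in c("crown_width", "live_crown_ratio")) {
      tab <- stage_path_table(trees, plots, response = resp)
      write_table(tab, outfile(paste0("path_", resp, ".csv")))
      report[[paste0("path_", resp)]] <- list(
        direct_dbh = as.list(stats::setNames(tab$direct_dbh, tab$stage)),
        direct_height = as.list(stats::setNames(tab$direct_height, tab$stage)))
    }
  }

  outputs <- setdiff(list.files(config$out_dir, full.names = TRUE),
                     outfile("report.json"))
  report$output_md5 <- as.list(tools::md5sum(sort(outputs)))
  jsonlite::write_json(report, outfile("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %d output files in %s", length(outputs) + 1, config$out_dir)
  invisible(report)
}
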