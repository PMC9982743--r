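#' The seven candidate drivers of diameter diversity
#' @export
driver_predictors <- function() {
  c("altitude_m", "stand_density", "landform", "slope_direction",
    "soil_type", "temperature_c", "precipitation_mm")
}

#' Per-plot diameter diversity with site covariates
#'
#' Computes the Shannon index of each plot's binned DBH distribution and
#' joins the plot covariates, giving the design table for the driver model.
#'
#' @param trees tree table.
#' @param plots plot table.
#' @return data frame with `plot_id`, `shannon` and the seven drivers.
#' @export
plot_diversity <- function(trees, plots) {
  groups <- split(trees$dbh_cm, factor(trees$plot_id, levels = plots$plot_id))
  H <- vapply(groups, function(d) {
    if (length(d) == 0) NA_real_ else shannon_index(bin_dbh(d))
  }, numeric(1))
  out <- data.frame(plot_id = plots$plot_id, shannon = unname(H),
                    stringsAsFactors = FALSE)
  cbind(out, plots[, driver_predictors(), drop = FALSE])
}

#' Boosting hyperparameters for the driver model
#'
#' Conventional small-data settings: slow learning on shallow trees with
#' bagging, the ensemble size chosen by seeded k-fold cross-validation up
#' to `n_trees` rounds.  The 2-row leaf minimum reflects the small-plot
#' regime this model targets (a few dozen plots, categorical drivers with
#' minority levels).
#'
#' @param n_trees maximum boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param max_depth tree depth.
#' @param min_samples minimum observations per leaf.
#' @param bag_fraction row subsample per round.
#' @param cv_folds folds for selecting the round count (0 disables CV and
#'   uses `n_trees` rounds).
#' @param early_stopping rounds without CV improvement before stopping.
#' @return named list.
#' @export
driver_hyperparams <- function(n_trees = 3000, learning_rate = 0.01,
                               max_depth = 3, min_samples = 2,
                               bag_fraction = 0.75, cv_folds = 5,
                               early_stopping = 100) {
  list(n_trees = n_trees, learning_rate = learning_rate,
       max_depth = max_depth, min_samples = min_samples,
       bag_fraction = bag_fraction, cv_folds = cv_folds,
       early_stopping = early_stopping)
}

# Predictor frame with fixed factor levels, suitable for a categorical
# xgb.DMatrix (level-subset splits) and reproducible across predict calls.
build_design <- function(data, predictors, levels_map = NULL) {
  df <- data[, predictors, drop = FALSE]
  levels_out <- list()
  for (v in predictors) {
    if (!is.numeric(df[[v]])) {
      levs <- if (!is.null(levels_map) && !is.null(levels_map[[v]])) {
        levels_map[[v]]
      } else sort(unique(as.character(df[[v]])))
      df[[v]] <- factor(as.character(df[[v]]), levels = levs)
      levels_out[[v]] <- levs
    }
  }
  list(frame = df, levels = levels_out)
}

xgb_param_list <- function(hp, seed) {
  xgboost::xgb.params(
    objective = "reg:squarederror",
    learning_rate = hp$learning_rate,
    max_depth = hp$max_depth,
    min_child_weight = hp$min_samples,
    subsample = hp$bag_fraction,
    nthread = 1,
    seed = seed
  )
}

#' Fit the gradient-boosted driver model
#'
#' Boosted ensemble of shallow regression trees under squared-error loss
#' for per-plot Shannon diversity on the seven drivers.  Categorical
#' predictors are handled natively through level-subset splits, so a
#' factor's split gain is attributed to the factor as a whole.  The number
#' of boosting rounds is chosen by seeded k-fold cross-validation with
#' early stopping; per-fold influence is retained so the report can show
#' across-fold instability.
#'
#' @param data a per-plot table from [plot_diversity()] (response column
#'   `shannon`).
#' @param hyperparams from [driver_hyperparams()].
#' @param seed integer seed (CV folds, bagging).
#' @param predictors predictor columns (default all seven drivers).
#' @return an object of class `driver_model`.
#' @export
fit_driver_model <- function(data, hyperparams = driver_hyperparams(), seed = 1L,
                             predictors = driver_predictors()) {
  data <- as.data.frame(data)
  stopifnot(all(c("shannon", predictors) %in% names(data)))
  if (anyNA(data$shannon)) stop("missing response values", call. = FALSE)
  if (nrow(data) < 10) stop("need at least 10 plots", call. = FALSE)
  if (stats::sd(data$shannon) == 0) {
    stop("constant response: the driver model is degenerate", call. = FALSE)
  }
  hp <- hyperparams
  des <- build_design(data, predictors)
  y <- data$shannon
  dm <- xgboost::xgb.DMatrix(des$frame, label = y, nthread = 1)
  params <- xgb_param_list(hp, seed)

  best_n <- hp$n_trees
  cv_rmse <- NA_real_
  fold_influence <- NULL
  if (hp$cv_folds >= 2) {
    set.seed(seed)
    cv <- xgboost::xgb.cv(params = params, data = dm, nrounds = hp$n_trees,
                          nfold = hp$cv_folds,
                          early_stopping_rounds = hp$early_stopping,
                          verbose = 0)
    best_n <- cv$early_stop$best_iteration
    cv_rmse <- unname(cv$early_stop$best_score)
    # across-fold influence dispersion: refit on each CV training split
    fold_imp <- lapply(cv$folds, function(test_idx) {
      tr <- setdiff(seq_len(nrow(data)), test_idx)
      set.seed(seed)
      bst_f <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(des$frame[tr, , drop = FALSE],
                                    label = y[tr], nthread = 1),
        nrounds = best_n, verbose = 0)
      imp <- try(aggregate_influence(bst_f, predictors), silent = TRUE)
      if (inherits(imp, "try-error")) NULL else imp$influence_pct
    })
    keep <- !vapply(fold_imp, is.null, logical(1))
    if (any(keep)) {
      fold_influence <- do.call(rbind, fold_imp[keep])
      colnames(fold_influence) <- predictors
    }
  }

  set.seed(seed)
  booster <- xgboost::xgb.train(params = params, data = dm,
                                nrounds = best_n, verbose = 0)
  structure(list(booster = booster, design = des, data = data,
                 predictors = predictors, hyperparams = hp, seed = seed,
                 n_trees_used = best_n, cv_rmse = cv_rmse,
                 fold_influence = fold_influence),
            class = "driver_model")
}

#' @export
predict.driver_model <- function(object, newdata = NULL, ...) {
  df <- if (is.null(newdata)) object$data else as.data.frame(newdata)
  des <- build_design(df, object$predictors, levels_map = object$design$levels)
  stats::predict(object$booster,
                 xgboost::xgb.DMatrix(des$frame, nthread = 1))
}

# Per-predictor share of split gain as percentages summing to 100, in the
# order of `predictors` (unused predictors get 0).  Gains are read from the
# model dump, which covers numeric and categorical (level-subset) splits
# alike.
aggregate_influence <- function(booster, predictors) {
  dump <- xgboost::xgb.dump(booster, dump_format = "json", with_stats = TRUE)
  trees <- jsonlite::fromJSON(paste(dump, collapse = "\n"),
                              simplifyVector = FALSE)
  gain <- stats::setNames(rep(0, length(predictors)), predictors)
  walk <- function(node) {
    if (!is.null(node$split)) {
      gain[[node$split]] <<- gain[[node$split]] + node$gain
      for (ch in node$children) walk(ch)
    }
  }
  for (tr in trees) walk(tr)
  if (sum(gain) == 0) stop("model contains no splits; influence undefined",
                           call. = FALSE)
  pct <- 100 * gain / sum(gain)
  data.frame(predictor = names(pct), influence_pct = unname(pct),
             stringsAsFactors = FALSE)
}

#' Relative influence of each driver
#'
#' Per-predictor share of the total squared-error split gain across all
#' trees of the ensemble, as percentages summing to 100.  When the model
#' was cross-validated the across-fold standard deviation of each
#' percentage is included as `cv_sd`.
#'
#' @param model a fitted `driver_model`.
#' @return an object of class `influence_report`: a data frame sorted by
#'   decreasing influence, with the hyperparameters and seed attached.
#' @export
relative_influence <- function(model) {
  stopifnot(inherits(model, "driver_model"))
  inf <- aggregate_influence(model$booster, model$predictors)
  if (!is.null(model$fold_influence)) {
    inf$cv_sd <- apply(model$fold_influence[, inf$predictor, drop = FALSE], 2,
                       stats::sd)
  }
  inf <- inf[order(-inf$influence_pct), ]
  rownames(inf) <- NULL
  structure(inf, class = c("influence_report", "data.frame"),
            hyperparams = model$hyperparams, seed = model$seed,
            n_trees_used = model$n_trees_used, cv_rmse = model$cv_rmse)
}

#' Marginal (partial-dependence) effect of one to three drivers
#'
#' Partial dependence: the mean model prediction over the training rows
#' with the chosen predictors clamped to each point of a grid covering
#' their observed range (50 equally spaced points for numeric predictors,
#' the observed levels for categorical ones).
#'
#' @param model a fitted `driver_model`.
#' @param variables 1 to 3 distinct predictor names.
#' @param grid_size grid points per numeric variable.
#' @return an object of class `marginal_curve`: a data frame with one
#'   column per variable plus `effect`.
#' @export
marginal_effect <- function(model, variables, grid_size = 50) {
  stopifnot(inherits(model, "driver_model"))
  variables <- unique(variables)
  if (length(variables) < 1 || length(variables) > 3) {
    stop("marginal effects support 1 to 3 variables", call. = FALSE)
  }
  if (!all(variables %in% model$predictors)) {
    stop("unknown predictor(s): ",
         paste(setdiff(variables, model$predictors), collapse = ", "),
         call. = FALSE)
  }
  axes <- lapply(variables, function(v) {
    x <- model$data[[v]]
    if (is.numeric(x)) seq(min(x), max(x), length.out = grid_size)
    else sort(unique(as.character(x)))
  })
  names(axes) <- variables
  grid <- expand.grid(axes, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$effect <- vapply(seq_len(nrow(grid)), function(i) {
    df <- model$data
    for (v in variables) df[[v]] <- grid[[v]][i]
    mean(stats::predict(model, df))
  }, numeric(1))
  class(grid) <- c("marginal_curve", "data.frame")
  grid
}
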