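#' Default city layout of the synthetic inventory
#'
#' Nine cities with the plot and tree counts of the study region's
#' inventory (31 plots, 3,633 trees in total).  `trees` is split as evenly
#' as possible across a city's plots; set it to `NA` to let tree counts be
#' driven by the drawn stand density instead.
#'
#' @return data frame with columns `city`, `plots`, `trees`.
#' @export
default_city_table <- function() {
  data.frame(
    city  = c("Chenzhou", "Hengyang", "Huaihua", "Loudi", "Shaoyang",
              "Xiangtan", "Xiangxi", "Yongzhou", "Yueyang"),
    plots = c(8L, 1L, 6L, 1L, 3L, 1L, 4L, 4L, 3L),
    trees = c(1123L, 80L, 729L, 28L, 218L, 73L, 434L, 467L, 481L),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the synthetic stand generator
#'
#' The generator emulates a two-table plot inventory of even-aged pure pine
#' stands.  Within a plot, DBH follows a Weibull distribution truncated to
#' (1, 40] cm; the scale is set per age stage so that the stage mean DBH
#' matches `stage_mean_dbh`, and the shape (which controls diameter-class
#' diversity: smaller shape, wider spread, higher Shannon index) is
#' `dbh_shape` plus additive covariate effects from `driver_effects`.
#' Height follows the allometry `H = 1.3 + a * DBH^b * exp(eps)` with
#' log-normal noise; crown width and crown length are linear in DBH and
#' height with Gaussian noise, so true standardized path coefficients are
#' computable from the generating covariance (see
#' [true_path_coefficients()]).  Crown length is clamped to `[0, height]`;
#' clamp events are counted and stay well below 1% at these defaults.
#'
#' @param ... named overrides of any default component.
#' @return a list of class `stand_params`.
#' @export
stand_params <- function(...) {
  p <- list(
    cities = default_city_table(),
    plot_area_m2 = 1000,
    density_range = c(80, 150),        # stems per 1,000 m^2
    age_range = c(8L, 51L),            # years
    altitude_range = c(105, 1250),     # m
    temperature_range = c(15.5, 18.5), # degrees C, mean annual
    precipitation_range = c(1200, 1800), # mm, mean annual
    dbh_shape = 2.6,                   # Weibull shape before driver effects
    dbh_shape_min = 1.2,               # floor after effects
    dbh_range = c(1, 40),              # truncation bounds, cm
    stage_mean_dbh = c(young = 8.73, middle = 12.19,
                       `near-mature` = 14.4, mature = 21.75), # cm
    height_allometry = list(a = 4.3, b = 0.28, sd_log = 0.04, site_sd = 0.13),
    crown_width = list(c0 = 0.5, c_dbh = 0.15, c_height = 0.05, sd = 0.35),
    crown_length = list(c0 = -0.5, c_dbh = 0.08, c_height = 0.45, sd = 0.5),
    driver_effects = default_driver_effects(),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) stop("unknown stand_params component(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  p[names(over)] <- over
  stopifnot(p$dbh_shape > 0, p$height_allometry$sd_log >= 0,
            p$crown_width$sd >= 0, p$crown_length$sd >= 0,
            p$dbh_range[1] > 0, p$dbh_range[2] > p$dbh_range[1])
  class(p) <- "stand_params"
  p
}

#' Default additive covariate effects on the Weibull shape
#'
#' Slope direction is the dominant driver (north-facing aspects get lower
#' shape, hence wider diameter spread and higher structural diversity);
#' stand density, landform, altitude, soil type, precipitation and
#' temperature carry progressively smaller effects.  Continuous covariates
#' contribute `coef * (value - center)`.
#'
#' @return a list with one element per driver.
#' @export
default_driver_effects <- function() {
  list(
    slope_direction = c(N = -0.55, NE = -0.45, NW = -0.40, E = -0.05,
                        W = 0.00, SE = 0.50, S = 0.40, SW = 0.25),
    stand_density = list(coef = 0.004, center = 115),
    landform = c(hill = 0.06, `low-mountain` = -0.03, `mid-mountain` = -0.03),
    altitude = list(coef = -1e-4, center = 500),
    precipitation = list(coef = -1e-4, center = 1500),
    soil_type = c(red = 0.04, `lateritic-red` = 0, yellow = -0.04),
    temperature = list(coef = -0.01, center = 17)
  )
}

#' Effects of all driver settings set to zero
#'
#' Convenience for null-model simulations: per-plot diversity then varies
#' only by sampling noise.
#' @export
null_driver_effects <- function() {
  list(
    slope_direction = c(N = 0, NE = 0, NW = 0, E = 0, W = 0, SE = 0, S = 0, SW = 0),
    stand_density = list(coef = 0, center = 115),
    landform = c(hill = 0, `low-mountain` = 0, `mid-mountain` = 0),
    altitude = list(coef = 0, center = 500),
    precipitation = list(coef = 0, center = 1500),
    soil_type = c(red = 0, `lateritic-red` = 0, yellow = 0),
    temperature = list(coef = 0, center = 17)
  )
}

#' Generator preset for driver-recovery studies
#'
#' Thirty-one single-stage plots (middle-aged, so the Weibull scale is
#' common) in which slope direction is the sole driver of diameter
#' diversity: all other covariate effects are zero and the slope-direction
#' deltas are scaled so that the between-aspect spread of expected per-plot
#' Shannon H is three times its within-plot sampling standard deviation
#' (effect:noise 3:1, measured by replicate simulation at these
#' densities).
#'
#' @param effect_scale multiplier on the default slope-direction deltas
#'   (1.7 gives the 3:1 regime).
#' @return a [stand_params()] object.
#' @export
driver_recovery_params <- function(effect_scale = 1.7) {
  de <- null_driver_effects()
  de$slope_direction <- default_driver_effects()$slope_direction * effect_scale
  stand_params(
    cities = data.frame(city = "Sim", plots = 31L, trees = NA_integer_,
                        stringsAsFactors = FALSE),
    age_range = c(25L, 25L),
    driver_effects = de
  )
}

#' Weibull shape of a plot's DBH distribution
#'
#' Base shape plus the additive driver effects evaluated at the plot's
#' covariates, floored at `dbh_shape_min`.
#'
#' @param plot a one-row plot data frame.
#' @param params a [stand_params()] object.
#' @return the positive Weibull shape.
#' @export
plot_dbh_shape <- function(plot, params) {
  de <- params$driver_effects
  eff <- de$slope_direction[[plot$slope_direction]] +
    de$landform[[plot$landform]] +
    de$soil_type[[plot$soil_type]] +
    de$stand_density$coef * (plot$stand_density - de$stand_density$center) +
    de$altitude$coef * (plot$altitude_m - de$altitude$center) +
    de$temperature$coef * (plot$temperature_c - de$temperature$center) +
    de$precipitation$coef * (plot$precipitation_mm - de$precipitation$center)
  max(params$dbh_shape + eff, params$dbh_shape_min)
}

#' Draw plot-level covariates
#'
#' Altitude, stand density, age, climate and the categorical site factors
#' are drawn uniformly from the documented ranges; landform is derived from
#' the drawn altitude band.  Randomness comes from R's global RNG: seed with
#' `set.seed()` for reproducibility.
#'
#' @param params a [stand_params()] object.
#' @param n number of plots.
#' @param city optional city label(s), recycled to length `n`.
#' @return data frame of plot records (without derived tree data).
#' @export
generate_plot_covariates <- function(params, n = 1, city = NA_character_) {
  stopifnot(inherits(params, "stand_params"), n >= 1)
  altitude <- stats::runif(n, params$altitude_range[1], params$altitude_range[2])
  data.frame(
    plot_id = paste0("P", seq_len(n)),
    city = rep_len(city, n),
    stand_age = sample(seq(params$age_range[1], params$age_range[2]), n, replace = TRUE),
    altitude_m = altitude,
    slope_direction = sample(SLOPE_DIRECTIONS, n, replace = TRUE),
    landform = landform_from_altitude(altitude),
    soil_type = sample(SOIL_TYPES, n, replace = TRUE),
    stand_density = stats::runif(n, params$density_range[1], params$density_range[2]),
    temperature_c = stats::runif(n, params$temperature_range[1], params$temperature_range[2]),
    precipitation_mm = stats::runif(n, params$precipitation_range[1], params$precipitation_range[2]),
    stringsAsFactors = FALSE
  )
}

# Inverse-CDF draw from a Weibull truncated to params$dbh_range.
rtrunc_weibull <- function(n, shape, scale, range) {
  lo <- stats::pweibull(range[1], shape, scale)
  hi <- stats::pweibull(range[2], shape, scale)
  stats::qweibull(lo + stats::runif(n) * (hi - lo), shape, scale)
}

# Weibull scale that puts the (untruncated) mean at the stage target.
stage_dbh_scale <- function(stage, shape, params) {
  target <- params$stage_mean_dbh[[as.character(stage)]]
  target / gamma(1 + 1 / shape)
}

#' Generate the trees of one plot
#'
#' Tree count is `round(stand_density * plot_area / 1000)`.  DBH is drawn
#' from the plot's truncated Weibull; height and crown dimensions follow the
#' allometries in `params`.  Crown length is clamped to `[0, height]`; the
#' number of clamp events is attached as attribute `n_clamped`.
#'
#' @param plot a one-row plot data frame (as from
#'   [generate_plot_covariates()]).
#' @param params a [stand_params()] object.
#' @return data frame of tree records with derived fields.
#' @export
generate_stand <- function(plot, params) {
  stopifnot(inherits(params, "stand_params"), nrow(plot) == 1)
  n <- if (!is.null(plot$n_trees) && !is.na(plot$n_trees)) {
    as.integer(plot$n_trees)
  } else {
    as.integer(round(plot$stand_density * params$plot_area_m2 / 1000))
  }
  shape <- plot_dbh_shape(plot, params)
  stage <- assign_age_stage(plot$stand_age)
  scale <- stage_dbh_scale(stage, shape, params)
  dbh <- rtrunc_weibull(n, shape, scale, params$dbh_range)

  ha <- params$height_allometry
  # plot-level site multiplier (site quality): heights vary across plots
  # much more than within an even-aged plot
  site_sd <- if (is.null(ha$site_sd)) 0 else ha$site_sd
  site <- exp(stats::rnorm(1, 0, site_sd))
  height <- 1.3 + site * ha$a * dbh^ha$b * exp(stats::rnorm(n, 0, ha$sd_log))
  cw <- params$crown_width
  crown_width <- pmax(cw$c0 + cw$c_dbh * dbh + cw$c_height * height +
                        stats::rnorm(n, 0, cw$sd), 0)
  cl <- params$crown_length
  crown_length_raw <- cl$c0 + cl$c_dbh * dbh + cl$c_height * height +
    stats::rnorm(n, 0, cl$sd)
  crown_length <- pmin(pmax(crown_length_raw, 0), height)

  trees <- data.frame(
    plot_id = plot$plot_id,
    dbh_cm = dbh,
    height_m = height,
    crown_width_m = crown_width,
    crown_length_m = crown_length,
    stringsAsFactors = FALSE
  )
  trees <- derive_tree_fields(trees)
  attr(trees, "n_clamped") <- sum(crown_length_raw != crown_length)
  attr(trees, "site_mult") <- site
  trees
}

#' Generate a full synthetic inventory with ground truth
#'
#' Draws covariates for every plot of `params$cities` (when a city's tree
#' total is given it is split as evenly as possible over its plots and the
#' plot densities are set accordingly), generates each stand, and returns
#' the two inventory tables together with a ground-truth record: the
#' generating allometric coefficients, the driver effects, and each plot's
#' true Weibull shape and scale.
#'
#' @param params a [stand_params()] object.
#' @param seed integer seed (defaults to `params$seed`).
#' @return list with `trees`, `plots`, `ground_truth`.
#' @export
generate_inventory <- function(params = stand_params(), seed = params$seed) {
  stopifnot(inherits(params, "stand_params"))
  set.seed(seed)
  ct <- params$cities
  plots_list <- vector("list", nrow(ct))
  for (i in seq_len(nrow(ct))) {
    p <- generate_plot_covariates(params, n = ct$plots[i], city = ct$city[i])
    if (!is.null(ct$trees) && !is.na(ct$trees[i])) {
      base <- ct$trees[i] %/% ct$plots[i]
      extra <- ct$trees[i] %% ct$plots[i]
      p$n_trees <- base + (seq_len(ct$plots[i]) <= extra)
      p$stand_density <- p$n_trees / (params$plot_area_m2 / 1000)
    } else {
      p$n_trees <- NA_integer_
    }
    plots_list[[i]] <- p
  }
  plots <- do.call(rbind, plots_list)
  plots$plot_id <- sprintf("P%02d", seq_len(nrow(plots)))

  trees_list <- vector("list", nrow(plots))
  truth_shape <- numeric(nrow(plots))
  truth_scale <- numeric(nrow(plots))
  n_clamped <- 0L
  for (i in seq_len(nrow(plots))) {
    stand <- generate_stand(plots[i, ], params)
    n_clamped <- n_clamped + attr(stand, "n_clamped")
    truth_shape[i] <- plot_dbh_shape(plots[i, ], params)
    truth_scale[i] <- stage_dbh_scale(assign_age_stage(plots$stand_age[i]),
                                      truth_shape[i], params)
    trees_list[[i]] <- stand
  }
  trees <- do.call(rbind, trees_list)
  rownames(trees) <- NULL
  plots$n_trees <- NULL

  ground_truth <- list(
    seed = seed,
    height_allometry = params$height_allometry,
    crown_width = params$crown_width,
    crown_length = params$crown_length,
    driver_effects = params$driver_effects,
    dbh_shape = data.frame(plot_id = plots$plot_id, shape = truth_shape,
                           scale = truth_scale, stringsAsFactors = FALSE),
    n_clamped = n_clamped,
    clamp_rate = n_clamped / nrow(trees)
  )
  list(trees = trees, plots = plots, ground_truth = ground_truth)
}

#' Closed-form standardized path coefficients of the generating crown model
#'
#' For a single plot with DBH ~ truncated Weibull(shape, scale) and the
#' generating allometries of `params`, the joint second moments of DBH,
#' height and a linear crown response `y = c0 + c1*DBH + c2*height + e` are
#' available in closed form (truncated Weibull moments by numerical
#' integration; the log-normal height noise analytically).  Returns the true
#' predictor correlation and standardized direct path coefficients the
#' estimators should recover.
#'
#' @param params a [stand_params()] object.
#' @param shape,scale Weibull parameters of the plot.
#' @param response `"crown_width"` or `"crown_length"`.
#' @param site the plot's site multiplier on the height allometry (1 for a
#'   plot of average site quality).
#' @return list with `r_dbh_height`, `P_dbh`, `P_height`, and the sds.
#' @export
true_path_coefficients <- function(params, shape, scale,
                                   response = c("crown_width", "crown_length"),
                                   site = 1) {
  response <- match.arg(response)
  rng <- params$dbh_range
  Z <- stats::pweibull(rng[2], shape, scale) - stats::pweibull(rng[1], shape, scale)
  mom <- function(m) {
    stats::integrate(function(d) d^m * stats::dweibull(d, shape, scale) / Z,
                     rng[1], rng[2], rel.tol = 1e-10)$value
  }
  ha <- params$height_allometry
  b <- ha$b
  a_eff <- ha$a * site
  m1 <- exp(ha$sd_log^2 / 2)          # E exp(eps)
  m2 <- exp(2 * ha$sd_log^2)          # E exp(2 eps)
  ED <- mom(1); ED2 <- mom(2)
  EDb <- mom(b); ED2b <- mom(2 * b); ED1b <- mom(1 + b)
  var_d <- ED2 - ED^2
  var_h <- a_eff^2 * (ED2b * m2 - EDb^2 * m1^2)
  cov_dh <- a_eff * m1 * (ED1b - ED * EDb)
  cc <- params[[response]]
  var_y <- cc$c_dbh^2 * var_d + cc$c_height^2 * var_h +
    2 * cc$c_dbh * cc$c_height * cov_dh + cc$sd^2
  list(
    r_dbh_height = cov_dh / sqrt(var_d * var_h),
    P_dbh = cc$c_dbh * sqrt(var_d) / sqrt(var_y),
    P_height = cc$c_height * sqrt(var_h) / sqrt(var_y),
    sd_dbh = sqrt(var_d), sd_height = sqrt(var_h), sd_y = sqrt(var_y)
  )
}

#' Simulate standardized crown data with known direct path coefficients
#'
#' Draws standardized bivariate-normal predictors (DBH, height) with
#' correlation `r` and a response `y = P[1]*dbh + P[2]*height + noise`,
#' scaled so the true standardized direct path coefficients are exactly
#' `P`.  Used for parameter-recovery checks of the path-analysis fit.
#'
#' @param n number of trees.
#' @param p_direct length-2 vector of true direct coefficients (dbh, height).
#' @param r predictor correlation, |r| < 1.
#' @param seed integer seed.
#' @return data frame with columns `dbh`, `height`, `y`.
#' @export
simulate_path_data <- function(n, p_direct = c(0.47, 0.27), r = 0.68, seed = 1L) {
  stopifnot(abs(r) < 1, length(p_direct) == 2)
  var_signal <- p_direct[1]^2 + p_direct[2]^2 + 2 * r * p_direct[1] * p_direct[2]
  if (var_signal >= 1) stop("direct coefficients imply signal variance >= 1",
                            call. = FALSE)
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  y <- p_direct[1] * z1 + p_direct[2] * z2 +
    stats::rnorm(n, 0, sqrt(1 - var_signal))
  data.frame(dbh = z1, height = z2, y = y)
}
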