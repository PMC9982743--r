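#' Wright path analysis of a crown response on DBH and tree height
#'
#' Ordinary least squares of the response on the two predictors, decomposed
#' into standardized direct and indirect path coefficients: the direct
#' coefficient of predictor i is `P_yi = b_i * s_i / s_y` (the standardized
#' partial regression coefficient), and its indirect coefficient is the
#' effect transmitted through the other predictor, `r_ij * P_yj`, so that
#' for each predictor `cor(x_i, y) = P_yi + r_ij * P_yj` holds exactly.
#' Direct-effect p-values are classical two-sided t-tests on the OLS
#' partial coefficients.
#'
#' @param data data frame with columns `dbh`, `height` and the response.
#' @param response name of the response column (default `"y"`).
#' @return an object of class `path_model`: `n`, `r_dbh_height`, and per
#'   predictor `direct`, `indirect`, `p_value`, `cor_with_y`.
#' @export
fit_path_model <- function(data, response = "y") {
  data <- as.data.frame(data)
  stopifnot(all(c("dbh", "height", response) %in% names(data)))
  data <- data[stats::complete.cases(data[, c("dbh", "height", response)]), ]
  n <- nrow(data)
  if (n < 10) stop("need at least 10 trees to fit a path model", call. = FALSE)
  s_d <- stats::sd(data$dbh)
  s_h <- stats::sd(data$height)
  s_y <- stats::sd(data[[response]])
  if (s_d == 0 || s_h == 0) stop("a predictor is constant", call. = FALSE)
  if (s_y == 0) stop("response is constant", call. = FALSE)
  r <- stats::cor(data$dbh, data$height)
  if (abs(r) > 0.999) stop("predictors are collinear (|r| > 0.999)", call. = FALSE)

  fml <- stats::reformulate(c("dbh", "height"), response = response)
  fit <- stats::lm(fml, data = data)
  b <- stats::coef(fit)[c("dbh", "height")]
  pvals <- stats::coef(summary(fit))[c("dbh", "height"), "Pr(>|t|)"]
  P_d <- unname(b["dbh"]) * s_d / s_y
  P_h <- unname(b["height"]) * s_h / s_y

  structure(list(
    response = response, n = n, r_dbh_height = r,
    direct = c(dbh = P_d, height = P_h),
    indirect = c(dbh = r * P_h, height = r * P_d),
    p_value = c(dbh = unname(pvals[1]), height = unname(pvals[2])),
    cor_with_y = c(dbh = stats::cor(data$dbh, data[[response]]),
                   height = stats::cor(data$height, data[[response]]))
  ), class = "path_model")
}

signif_stars <- function(p) ifelse(p < 0.001, "***", "")

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("Path model for %s (n = %d, r_dbh_height = %.3f)\n",
              x$response, x$n, x$r_dbh_height))
  for (v in c("dbh", "height")) {
    cat(sprintf("  %-7s direct %6.3f%-3s indirect %6.3f  (p = %.3g)\n",
                v, x$direct[[v]], signif_stars(x$p_value[[v]]),
                x$indirect[[v]], x$p_value[[v]]))
  }
  invisible(x)
}

#' Per-age-stage path-coefficient table
#'
#' Fits one path model per age stage (stage taken from each tree's plot
#' stand age) for the chosen crown response, pooling trees across plots
#' within a stage.  Stages absent from the data (or with fewer than 10
#' trees) produce a row of `NA`s with a warning.
#'
#' @param trees tree table.
#' @param plots plot table.
#' @param response `"crown_width"` or `"live_crown_ratio"`.
#' @return data frame with one row per stage: n, direct and indirect
#'   coefficients per predictor, p-values, and significance stars
#'   (`***` marks p < 0.001).
#' @export
stage_path_table <- function(trees, plots,
                             response = c("crown_width", "live_crown_ratio")) {
  response <- match.arg(response)
  stage <- assign_age_stage(plots$stand_age[match(trees$plot_id, plots$plot_id)])
  ycol <- switch(response, crown_width = "crown_width_m",
                 live_crown_ratio = "live_crown_ratio")
  out <- lapply(levels(stage), function(st) {
    idx <- which(stage == st)
    na_row <- data.frame(
      stage = st, n = length(idx),
      direct_dbh = NA_real_, direct_height = NA_real_,
      indirect_dbh = NA_real_, indirect_height = NA_real_,
      p_dbh = NA_real_, p_height = NA_real_,
      sig_dbh = "", sig_height = "", stringsAsFactors = FALSE)
    if (length(idx) < 10) {
      warning("age stage '", st, "' has fewer than 10 trees; row left empty",
              call. = FALSE)
      return(na_row)
    }
    d <- data.frame(dbh = trees$dbh_cm[idx], height = trees$height_m[idx],
                    y = trees[[ycol]][idx])
    pm <- fit_path_model(d, response = "y")
    data.frame(
      stage = st, n = pm$n,
      direct_dbh = pm$direct[["dbh"]], direct_height = pm$direct[["height"]],
      indirect_dbh = pm$indirect[["dbh"]], indirect_height = pm$indirect[["height"]],
      p_dbh = pm$p_value[["dbh"]], p_height = pm$p_value[["height"]],
      sig_dbh = signif_stars(pm$p_value[["dbh"]]),
      sig_height = signif_stars(pm$p_value[["height"]]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
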