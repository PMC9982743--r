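#' Fixed diameter-class edges
#'
#' The ten classes are (0,5], (5,8], (8,12], ..., (36,40] cm; intervals are
#' lower-open/upper-closed so that a tree of exactly 8.0 cm falls in the
#' 5--8 class and the first class is the "<= 5 cm" class.
#' @export
dbh_class_edges <- function() c(0, 5, 8, 12, 16, 20, 24, 28, 32, 36, 40)

#' Stand age stage
#'
#' Stages: young (<= 20 yr), middle (21--30), near-mature (31--40),
#' mature (41--60).  Ages outside 1--60 are rejected.
#'
#' @param stand_age integer vector of stand ages in years.
#' @return factor with levels `young`, `middle`, `near-mature`, `mature`.
#' @export
assign_age_stage <- function(stand_age) {
  stopifnot(is.numeric(stand_age))
  if (any(stand_age < 1 | stand_age > 60)) {
    stop("stand_age outside the supported 1-60 year range", call. = FALSE)
  }
  cut(stand_age, breaks = c(0, 20, 30, 40, 60),
      labels = c("young", "middle", "near-mature", "mature"), right = TRUE)
}

#' Bin DBH values into the fixed diameter classes
#'
#' @param dbh_values numeric vector of DBH in cm, all > 0.
#' @param allow_overflow fold values above 40 cm into the top class (with a
#'   warning) instead of erroring.
#' @return an object of class `diameter_distribution` with the class edges,
#'   counts, proportions, Shannon index (nats) and, when computable, the
#'   population skewness and excess kurtosis of the raw values.
#' @export
bin_dbh <- function(dbh_values, allow_overflow = FALSE) {
  stopifnot(is.numeric(dbh_values))
  if (any(!(dbh_values > 0))) stop("all DBH values must be > 0", call. = FALSE)
  edges <- dbh_class_edges()
  over <- dbh_values > edges[length(edges)]
  if (any(over)) {
    if (!allow_overflow) {
      stop(sum(over), " DBH value(s) exceed 40 cm; use allow_overflow = TRUE ",
           "to fold them into the top class", call. = FALSE)
    }
    warning(sum(over), " DBH value(s) above 40 cm folded into the top class",
            call. = FALSE)
    dbh_values[over] <- edges[length(edges)]
  }
  counts <- as.integer(table(cut(dbh_values, breaks = edges, right = TRUE)))
  n <- sum(counts)
  moments <- if (length(dbh_values) >= 3 && stats::sd(dbh_values) > 0) {
    distribution_moments(dbh_values)
  } else {
    list(skewness = NA_real_, kurtosis = NA_real_)
  }
  dist <- list(
    class_edges = edges,
    counts = counts,
    proportions = if (n > 0) counts / n else rep(NA_real_, length(counts)),
    n_classes = length(counts),
    n_trees = n,
    skewness = moments$skewness,
    kurtosis = moments$kurtosis
  )
  class(dist) <- "diameter_distribution"
  dist$shannon <- if (n > 0) shannon_index(dist) else NA_real_
  dist
}

#' @export
as.data.frame.diameter_distribution <- function(x, ...) {
  e <- x$class_edges
  data.frame(
    class = c("<=5", paste0(e[-c(1, length(e))], "-", e[-(1:2)])),
    lower_cm = e[-length(e)],
    upper_cm = e[-1],
    midpoint_cm = (e[-length(e)] + e[-1]) / 2,
    count = x$counts,
    proportion = x$proportions,
    stringsAsFactors = FALSE
  )
}

#' @export
print.diameter_distribution <- function(x, ...) {
  cat(sprintf("Diameter distribution: %d trees in %d classes\n",
              x$n_trees, x$n_classes))
  cat(sprintf("  Shannon H = %.4f nats  skewness = %.4f  excess kurtosis = %.4f\n",
              x$shannon, x$skewness, x$kurtosis))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Shannon-Wiener structural diversity index
#'
#' `H = -sum(p_i * log(p_i))` over the diameter classes, natural logarithm,
#' with empty classes contributing zero.  For the fixed ten-class scheme
#' `0 <= H <= log(10)`.
#'
#' @param dist a `diameter_distribution`, or a numeric vector of class
#'   counts or proportions.
#' @return H in nats.
#' @export
shannon_index <- function(dist) {
  counts <- if (inherits(dist, "diameter_distribution")) dist$counts else dist
  stopifnot(is.numeric(counts))
  if (any(counts < 0)) stop("negative class counts", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("Shannon index undefined for an empty distribution",
                       call. = FALSE)
  p <- counts / total
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Population skewness and excess kurtosis
#'
#' Population (biased) moment estimators: `m3 / m2^1.5` and
#' `m4 / m2^2 - 3`, so a normal sample has excess kurtosis near zero.
#'
#' @param values numeric vector, `n >= 3`, non-constant.
#' @return list with `skewness` and `kurtosis`.
#' @export
distribution_moments <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("moments undefined for constant sample",
                                   call. = FALSE)
  list(skewness = e1071::skewness(values, type = 1),
       kurtosis = e1071::kurtosis(values, type = 1))
}

#' Per-group diameter-distribution summary
#'
#' One row per group (city, plot or age stage) with tree count, population
#' skewness, excess kurtosis, and the Shannon index of the binned DBH
#' distribution.
#'
#' @param trees tree table (with `plot_id`, `dbh_cm`).
#' @param plots plot table.
#' @param group_by `"city"`, `"plot"` or `"stage"`.
#' @param allow_overflow passed to [bin_dbh()].
#' @return data frame in the per-city summary layout.
#' @export
distribution_summary <- function(trees, plots, group_by = c("city", "plot", "stage"),
                                 allow_overflow = FALSE) {
  group_by <- match.arg(group_by)
  key <- switch(group_by,
    city = plots$city[match(trees$plot_id, plots$plot_id)],
    plot = trees$plot_id,
    stage = as.character(assign_age_stage(
      plots$stand_age[match(trees$plot_id, plots$plot_id)]))
  )
  groups <- split(trees$dbh_cm, key)
  out <- lapply(names(groups), function(g) {
    d <- bin_dbh(groups[[g]], allow_overflow = allow_overflow)
    data.frame(group = g, n_trees = d$n_trees, skewness = d$skewness,
               kurtosis = d$kurtosis, shannon = d$shannon,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  names(res)[1] <- group_by
  res
}

#' Pairwise rank-sum tests between age stages
#'
#' Wilcoxon rank-sum test (normal approximation with tie correction, no
#' multiplicity adjustment) for every pair of age stages on one tree-level
#' variable.
#'
#' @param trees tree table.
#' @param plots plot table (stage comes from the plot's stand age).
#' @param variable one of `dbh`, `height`, `crown_width`, `crown_length`.
#' @return data frame with one row per stage pair: sample sizes, the
#'   rank-sum statistic `W`, and the unadjusted p-value.
#' @export
pairwise_stage_tests <- function(trees, plots,
                                 variable = c("dbh", "height", "crown_width",
                                              "crown_length")) {
  variable <- match.arg(variable)
  col <- paste0(variable, switch(variable, dbh = "_cm", "_m"))
  stage <- assign_age_stage(plots$stand_age[match(trees$plot_id, plots$plot_id)])
  values <- split(trees[[col]], stage)
  empty <- names(values)[vapply(values, length, integer(1)) == 0]
  if (length(empty) > 0) {
    warning("age stage(s) with no trees skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
    values <- values[vapply(values, length, integer(1)) > 0]
  }
  if (length(values) < 2) stop("need at least two non-empty age stages",
                               call. = FALSE)
  pairs <- utils::combn(names(values), 2)
  out <- apply(pairs, 2, function(pr) {
    wt <- stats::wilcox.test(values[[pr[1]]], values[[pr[2]]], exact = FALSE)
    data.frame(stage_a = pr[1], stage_b = pr[2],
               n_a = length(values[[pr[1]]]), n_b = length(values[[pr[2]]]),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$variable <- variable
  res
}

#' Quadratic fit of class proportions on class midpoints
#'
#' Degree-2 unweighted least squares of the class proportions on the class
#' midpoints (first class midpoint 2.5 cm), with a pointwise 95% confidence
#' band — the summary curve drawn over per-city diameter-class profiles.
#'
#' @param dist a `diameter_distribution` with at least 3 non-empty classes.
#' @return list with `coefficients` (intercept, linear, quadratic) and a
#'   data frame `curve` (`midpoint_cm`, `proportion`, `fit`, `lwr`, `upr`).
#' @export
fit_class_proportion_curve <- function(dist) {
  stopifnot(inherits(dist, "diameter_distribution"))
  if (sum(dist$counts > 0) < 3) {
    stop("need at least 3 non-empty classes to fit a quadratic", call. = FALSE)
  }
  df <- as.data.frame(dist)
  fit <- stats::lm(proportion ~ midpoint_cm + I(midpoint_cm^2), data = df)
  pred <- suppressWarnings(
    stats::predict(fit, newdata = df, interval = "confidence", level = 0.95))
  list(
    coefficients = stats::setNames(stats::coef(fit),
                                   c("intercept", "linear", "quadratic")),
    curve = data.frame(midpoint_cm = df$midpoint_cm,
                       proportion = df$proportion,
                       fit = pred[, "fit"], lwr = pred[, "lwr"],
                       upr = pred[, "upr"])
  )
}
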