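#' TSTRAT cut-off height of a tree
#'
#' `CPS = 0.4 * CL + HBLC`, i.e. `height - 0.6 * crown_length`: competition
#' for light is assumed strongest in the top 60% of the crown, so a tree
#' shares the stratum of a taller founder only if it reaches that height.
#'
#' @param height_m tree height(s), m.
#' @param crown_length_m crown length(s), m.
#' @return cut-off height(s), m.
#' @export
cutoff_height <- function(height_m, crown_length_m) {
  stopifnot(all(crown_length_m >= 0), all(crown_length_m <= height_m + 1e-9))
  0.4 * crown_length_m + (height_m - crown_length_m)
}

#' Live crown ratio
#'
#' Crown length divided by total height, in `[0, 1]`.
#'
#' @param height_m tree height(s), m, > 0.
#' @param crown_length_m crown length(s), m.
#' @return dimensionless ratio(s).
#' @export
live_crown_ratio <- function(height_m, crown_length_m) {
  stopifnot(all(height_m > 0))
  crown_length_m / height_m
}

#' TSTRAT vertical stratification of one plot
#'
#' Trees are sorted by descending height (ties broken by descending DBH,
#' then input order).  The tallest unassigned tree founds a stratum and
#' sets its cut-off height via [cutoff_height()]; every unassigned tree
#' whose height is at or above that cut-off joins the stratum; the first
#' shorter tree founds the next stratum, until all trees are assigned.
#' Stratum 1 is the dominant (tallest) layer.
#'
#' @param trees one plot's tree table (columns `height_m`, `crown_length_m`
#'   and optionally `dbh_cm`).
#' @return an object of class `stratification`: per-tree stratum indices in
#'   input order, the founder cut-off heights `cps_m`, and a per-stratum
#'   summary (tree share %, mean height, mean DBH, mean crown length).
#' @export
tstrat_assign <- function(trees) {
  trees <- as.data.frame(trees)
  n <- nrow(trees)
  if (n == 0) stop("cannot stratify an empty plot", call. = FALSE)
  dbh <- if ("dbh_cm" %in% names(trees)) trees$dbh_cm else rep(0, n)
  ord <- order(-trees$height_m, -dbh, seq_len(n))
  h <- trees$height_m[ord]
  cl <- trees$crown_length_m[ord]

  stratum_sorted <- integer(n)
  cps <- numeric(0)
  s <- 0L
  i <- 1L
  while (i <= n) {
    s <- s + 1L
    cut <- cutoff_height(h[i], cl[i])
    cps[s] <- cut
    members <- which(stratum_sorted == 0L & h >= cut)
    stratum_sorted[members] <- s
    i <- if (any(stratum_sorted == 0L)) min(which(stratum_sorted == 0L)) else n + 1L
  }
  stratum <- integer(n)
  stratum[ord] <- stratum_sorted

  summary <- do.call(rbind, lapply(seq_len(s), function(j) {
    idx <- stratum == j
    data.frame(
      stratum = j,
      n_trees = sum(idx),
      share_pct = 100 * sum(idx) / n,
      cps_m = cps[j],
      mean_height_m = mean(trees$height_m[idx]),
      mean_dbh_cm = if ("dbh_cm" %in% names(trees)) mean(trees$dbh_cm[idx]) else NA_real_,
      mean_crown_length_m = mean(trees$crown_length_m[idx])
    )
  }))
  structure(list(stratum = stratum, cps_m = cps, n_strata = s,
                 summary = summary, n_trees = n),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("TSTRAT stratification: %d trees in %d stratum(s)\n",
              x$n_trees, x$n_strata))
  print(x$summary, row.names = FALSE, ...)
  invisible(x)
}

#' Pooled vertical-layer summary across plots
#'
#' Counts plots by number of strata and pools (tree-weighted) the dominant
#' layer: its share of all trees and the mean height, DBH and crown length
#' of dominant-layer trees, plus the average dominant-layer share among
#' multi-layer plots.
#'
#' @param results a named list of `stratification` objects, one per plot.
#' @param trees_by_plot a list of the corresponding plot tree tables (same
#'   order).
#' @return list with `plots_by_n_strata`, `dominant_share_pct`,
#'   `dominant_mean_height_m`, `dominant_mean_dbh_cm`,
#'   `dominant_mean_crown_length_m`,
#'   `multilayer_mean_dominant_share_pct`.
#' @export
population_layer_summary <- function(results, trees_by_plot) {
  stopifnot(length(results) >= 1, length(results) == length(trees_by_plot))
  n_strata <- vapply(results, function(r) r$n_strata, integer(1))
  dom <- do.call(rbind, Map(function(r, tr) {
    tr <- as.data.frame(tr)
    tr[r$stratum == 1L, , drop = FALSE]
  }, results, trees_by_plot))
  total_trees <- sum(vapply(results, function(r) r$n_trees, integer(1)))
  multi <- n_strata > 1
  list(
    plots_by_n_strata = table(n_strata),
    dominant_share_pct = 100 * nrow(dom) / total_trees,
    dominant_mean_height_m = mean(dom$height_m),
    dominant_mean_dbh_cm = if ("dbh_cm" %in% names(dom)) mean(dom$dbh_cm) else NA_real_,
    dominant_mean_crown_length_m = mean(dom$crown_length_m),
    multilayer_mean_dominant_share_pct = if (any(multi)) {
      mean(vapply(results[multi], function(r) r$summary$share_pct[1], numeric(1)))
    } else NA_real_
  )
}

#' Stratify every plot of an inventory
#'
#' @param trees full tree table.
#' @param plots plot table (defines the plot set).
#' @return list with `results` (per-plot `stratification`), `per_tree`
#'   (tree table plus `stratum` column) and `layer_summary` (from
#'   [population_layer_summary()]).
#' @export
stratify_inventory <- function(trees, plots) {
  split_trees <- split(trees, factor(trees$plot_id, levels = plots$plot_id))
  split_trees <- split_trees[vapply(split_trees, nrow, integer(1)) > 0]
  results <- lapply(split_trees, tstrat_assign)
  per_tree <- do.call(rbind, Map(function(tr, r) {
    tr$stratum <- r$stratum
    tr
  }, split_trees, results))
  rownames(per_tree) <- NULL
  list(results = results, per_tree = per_tree,
       layer_summary = population_layer_summary(results, split_trees))
}
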