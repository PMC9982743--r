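#' @keywords internal
"_PACKAGE"

## Closed categorical vocabularies shared across the package.
SLOPE_DIRECTIONS <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
LANDFORMS <- c("hill", "low-mountain", "mid-mountain")
SOIL_TYPES <- c("red", "lateritic-red", "yellow")

TREE_COLUMNS <- c("plot_id", "dbh_cm", "height_m", "crown_width_m", "crown_length_m")
PLOT_COLUMNS <- c("plot_id", "city", "stand_age", "altitude_m", "slope_direction",
                  "landform", "soil_type", "stand_density")
CLIMATE_COLUMNS <- c("temperature_c", "precipitation_mm")

#' Landform class implied by an altitude
#'
#' Landform bands: hill 200--500 m, low-mountain 500--1,000 m, mid-mountain
#' 1,000--3,500 m.  Plots below 200 m exist in real inventories; they are
#' treated as hill (the consistency check elsewhere only warns).
#'
#' @param altitude_m numeric vector of altitudes in metres.
#' @return character vector of landform labels.
#' @export
landform_from_altitude <- function(altitude_m) {
  stopifnot(is.numeric(altitude_m))
  ifelse(altitude_m < 500, "hill",
         ifelse(altitude_m < 1000, "low-mountain", "mid-mountain"))
}

validate_trees <- function(trees) {
  missing <- setdiff(TREE_COLUMNS, names(trees))
  if (length(missing) > 0) {
    stop("tree table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(trees) == 0) return(trees)
  bad <- which(!(trees$dbh_cm > 0) | !(trees$height_m > 1.3))
  if (length(bad) > 0) {
    stop("tree rows with non-positive dbh or height <= 1.3 m: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad <- which(trees$crown_width_m < 0 | trees$crown_length_m < 0)
  if (length(bad) > 0) {
    stop("tree rows with negative crown dimensions: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad <- which(trees$crown_length_m > trees$height_m + 1e-9)
  if (length(bad) > 0) {
    stop("crown_length exceeds tree height in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  trees
}

validate_plots <- function(plots) {
  missing <- setdiff(PLOT_COLUMNS, names(plots))
  if (length(missing) > 0) {
    stop("plot table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in CLIMATE_COLUMNS) {
    if (!col %in% names(plots)) plots[[col]] <- NA_real_
  }
  if (nrow(plots) == 0) return(plots)
  if (anyDuplicated(plots$plot_id)) {
    stop("duplicate plot_id in plot table", call. = FALSE)
  }
  check_vocab <- function(values, vocab, what) {
    bad <- setdiff(unique(values), vocab)
    if (length(bad) > 0) {
      stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(vocab, collapse = ", "), ")", call. = FALSE)
    }
  }
  check_vocab(plots$slope_direction, SLOPE_DIRECTIONS, "slope_direction")
  check_vocab(plots$landform, LANDFORMS, "landform")
  check_vocab(plots$soil_type, SOIL_TYPES, "soil_type")
  if (any(!(plots$stand_density > 0))) {
    stop("stand_density must be > 0", call. = FALSE)
  }
  if (any(plots$stand_age < 1 | plots$stand_age != round(plots$stand_age))) {
    stop("stand_age must be a positive integer", call. = FALSE)
  }
  # landform/altitude consistency: warn only (plots below 200 m exist)
  expected <- landform_from_altitude(plots$altitude_m)
  mismatch <- which(plots$altitude_m >= 200 & expected != plots$landform)
  if (length(mismatch) > 0) {
    warning("landform label inconsistent with altitude band for plot(s): ",
            paste(plots$plot_id[mismatch], collapse = ", "), call. = FALSE)
  }
  plots
}

derive_tree_fields <- function(trees) {
  trees$hblc_m <- trees$height_m - trees$crown_length_m
  trees$live_crown_ratio <- ifelse(trees$height_m > 0,
                                   trees$crown_length_m / trees$height_m, NA_real_)
  trees
}

#' Read and validate a two-table plot inventory
#'
#' Reads the tree-level and plot-level tables (comma-separated, UTF-8, one
#' header row), validates every record invariant, checks referential
#' integrity between the two tables, and derives the height to base of the
#' live crown (`hblc_m = height_m - crown_length_m`) and the live crown
#' ratio (`crown_length_m / height_m`).
#'
#' @param tree_path path to the tree table
#'   (`plot_id,dbh_cm,height_m,crown_width_m,crown_length_m`).
#' @param plot_path path to the plot table
#'   (`plot_id,city,stand_age,altitude_m,slope_direction,landform,soil_type,
#'   stand_density` and optional `temperature_c,precipitation_mm`).
#' @param quiet suppress the row-count message.
#' @return a list with data frames `trees` and `plots`.
#' @export
read_inventory <- function(tree_path, plot_path, quiet = FALSE) {
  for (p in c(tree_path, plot_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  trees <- utils::read.csv(tree_path, stringsAsFactors = FALSE)
  plots <- utils::read.csv(plot_path, stringsAsFactors = FALSE)
  trees <- validate_trees(trees)
  plots <- validate_plots(plots)
  orphans <- setdiff(unique(trees$plot_id), plots$plot_id)
  if (length(orphans) > 0) {
    stop("tree records reference unknown plot_id(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  trees <- derive_tree_fields(trees)
  if (!quiet) {
    message(sprintf("read %d trees in %d plots (%d cities)",
                    nrow(trees), nrow(plots), length(unique(plots$city))))
  }
  list(trees = trees, plots = plots)
}

#' Write a result table as delimited text
#'
#' Comma-separated, UTF-8, `.` decimal, one header row.  Values survive a
#' write/read round trip to at least 12 significant digits.  Objects with an
#' `as.data.frame` method (e.g. [bin_dbh()] results) are coerced first.
#'
#' @param records a data frame (or coercible object); may have zero rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) stop("records must be non-null", call. = FALSE)
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    if (is.integer(x)) x else signif(x, 15)
  })
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_inventory
#' @param path a delimited file written by [write_table()].
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
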