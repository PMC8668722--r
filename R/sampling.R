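# Presence handling and constrained pseudo-absence generation.

#' Eligible terrestrial background cells
#'
#' Coastal-breeding species are modelled against a terrestrial background
#' restricted to a band along the coast: all terrestrially valid cells whose
#' `distance_from_sea` is at most `coastal_band_m` (default 20 km). Coastal
#' cells (distance zero) are always included.
#'
#' @param grid A [realm_grid()] carrying the `distance_from_sea` layer (see
#'   [distance_variables()]).
#' @param config A [multirealm_config()].
#' @return An n x 2 matrix of (row, col) cells, ordered by row then column.
#' @export
terrestrial_background <- function(grid, config) {
  if (!"distance_from_sea" %in% layer_names(grid))
    stop("layer 'distance_from_sea' missing; run distance_variables() first",
         call. = FALSE)
  cells <- mask_cells(grid$terrestrial_valid)
  d <- layer_at(grid, "distance_from_sea", cells)
  out <- cells[!is.na(d) & d <= config$coastal_band_m, , drop = FALSE]
  if (!nrow(out)) warning("terrestrial background is empty")
  out
}

#' Eligible marine background cells
#'
#' Marine areas beyond foraging range are unavailable to a coastal breeder, so
#' the marine background is limited by distance from land. The species' mean
#' maximum foraging distance is treated as a 90th-percentile distance and the
#' background cutoff as the nominal 100th percentile,
#' `mmfd_m * exclusion_factor` (factor default 10/9; 1 gives a plain MMFD
#' cutoff).
#'
#' @param grid A [realm_grid()] carrying the `distance_from_land` layer.
#' @param config A [multirealm_config()].
#' @return An n x 2 matrix of (row, col) cells, ordered by row then column.
#' @export
marine_background <- function(grid, config) {
  if (!"distance_from_land" %in% layer_names(grid))
    stop("layer 'distance_from_land' missing; run distance_variables() first",
         call. = FALSE)
  cells <- mask_cells(grid$marine_valid)
  d <- layer_at(grid, "distance_from_land", cells)
  cutoff <- config$mmfd_m * config$exclusion_factor
  out <- cells[!is.na(d) & d <= cutoff, , drop = FALSE]
  if (!nrow(out)) warning("marine background is empty")
  out
}

background_cells <- function(grid, model_type, config) {
  if (focal_realm(model_type) == "terrestrial") terrestrial_background(grid, config)
  else marine_background(grid, config)
}

cell_key <- function(cells) paste(cells[, 1], cells[, 2], sep = ":")

#' Draw replicate pseudo-absence sets
#'
#' Pseudo-absences are drawn uniformly at random, without replacement within a
#' set, from the background cells not occupied by a presence. Replicate sets
#' are drawn independently (they may overlap each other) and each is
#' reproducible from the master seed and its set index. A balanced diagnostic
#' set with exactly as many pseudo-absences as presences (prevalence 0.5) is
#' drawn as well.
#'
#' @param background n x 2 matrix of eligible background cells.
#' @param presences m x 2 matrix of presence cells.
#' @param n Pseudo-absences per set.
#' @param n_sets Number of replicate sets.
#' @param seed Master seed; set `i` uses a seed derived from `(seed, i)`.
#' @return An `occurrence_data` list: `presences`, `pa_sets` (list of n x 2
#'   matrices), `balanced_set`, `seed`.
#' @export
draw_pseudo_absences <- function(background, presences, n, n_sets, seed) {
  presences <- as.matrix(presences)
  eligible <- background[!cell_key(background) %in% cell_key(presences), ,
                         drop = FALSE]
  if (nrow(eligible) < n)
    stop(sprintf("pseudo-absence sampling error: need %d cells, only %d eligible",
                 n, nrow(eligible)), call. = FALSE)
  draw_one <- function(size, index) {
    set.seed(derive_seed(seed, "pseudo_absence", index))
    eligible[sample.int(nrow(eligible), size), , drop = FALSE]
  }
  pa_sets <- lapply(seq_len(n_sets), function(i) draw_one(n, i))
  n_bal <- min(nrow(presences), nrow(eligible))
  if (n_bal < nrow(presences))
    warning("balanced set truncated: fewer eligible cells than presences")
  structure(list(presences = presences, pa_sets = pa_sets,
                 balanced_set = draw_one(n_bal, n_sets + 1L), seed = seed),
            class = "occurrence_data")
}

#' @export
print.occurrence_data <- function(x, ...) {
  cat(sprintf("occurrence_data: %d presences, %d pseudo-absence sets of %d, balanced set of %d (seed %d)\n",
              nrow(x$presences), length(x$pa_sets),
              if (length(x$pa_sets)) nrow(x$pa_sets[[1]]) else 0L,
              nrow(x$balanced_set), x$seed))
  invisible(x)
}

#' Read presence cells from CSV
#'
#' Accepts either `row`/`col` columns (1-based cell indices) or `lon`/`lat`
#' columns, which are snapped to the containing grid cell.
#'
#' @param path CSV file path.
#' @param grid A [realm_grid()] (needed for snapping and bounds checks).
#' @return An n x 2 matrix of (row, col) presence cells (duplicates removed).
#' @export
read_presences_csv <- function(path, grid) {
  tab <- utils::read.csv(path, comment.char = "#")
  if (all(c("row", "col") %in% names(tab))) {
    cells <- cbind(row = as.integer(tab$row), col = as.integer(tab$col))
  } else if (all(c("lon", "lat") %in% names(tab))) {
    cells <- snap_to_cell(grid, tab$lon, tab$lat)
  } else stop("presence CSV needs columns row/col or lon/lat", call. = FALSE)
  if (any(cells[, 1] < 1 | cells[, 1] > grid$n_rows |
          cells[, 2] < 1 | cells[, 2] > grid$n_cols))
    stop("presence outside the grid", call. = FALSE)
  unique(cells)
}

#' Snap lon/lat points to their containing cell
#'
#' @param grid A [realm_grid()].
#' @param lon,lat Numeric vectors in degrees.
#' @return An n x 2 matrix of (row, col).
#' @export
snap_to_cell <- function(grid, lon, lat) {
  col <- as.integer(round((lon - grid$origin_lon) / grid$cell_size)) + 1L
  row <- as.integer(round((grid$origin_lat - lat) / grid$cell_size)) + 1L
  cbind(row = row, col = col)
}
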