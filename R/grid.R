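#' Two-realm gridded covariate stack
#'
#' A `realm_grid` holds environmental layers on a common regular lon/lat grid,
#' each layer tagged as belonging to the terrestrial or the marine realm and
#' carrying a per-cell validity mask. Rows are counted from the north (row 1 is
#' the northernmost), columns from the west; coordinates refer to cell centres.
#' A cell that is valid in both realms is a *coastal* cell and belongs to both
#' realms simultaneously — this is what makes the distance-to-other-realm
#' variables zero at the coast.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param origin_lon,origin_lat Degrees of the centre of the north-west cell.
#' @param cell_size Cell size in degrees (the seabird analyses that motivated
#'   this package use 5 arc-minutes, i.e. 1/12 degree).
#' @param terrestrial_valid,marine_valid Optional logical matrices
#'   (`n_rows x n_cols`) giving the realm validity masks. If omitted they are
#'   accumulated as the union of each realm's layer masks.
#' @return An object of class `realm_grid`.
#' @seealso [add_layer()], [cell_center()], [write_grid_csv()]
#' @export
realm_grid <- function(n_rows, n_cols, origin_lon, origin_lat,
                       cell_size = 1 / 12,
                       terrestrial_valid = NULL, marine_valid = NULL) {
  stopifnot_scalar_number(n_rows, "n_rows", positive = TRUE)
  stopifnot_scalar_number(n_cols, "n_cols", positive = TRUE)
  stopifnot_scalar_number(cell_size, "cell_size", positive = TRUE)
  stopifnot_scalar_number(origin_lon, "origin_lon")
  stopifnot_scalar_number(origin_lat, "origin_lat")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  empty <- matrix(FALSE, n_rows, n_cols)
  g <- structure(list(
    n_rows = n_rows, n_cols = n_cols,
    origin_lon = origin_lon, origin_lat = origin_lat,
    cell_size = cell_size,
    layers = list(),
    terrestrial_valid = if (is.null(terrestrial_valid)) empty else terrestrial_valid,
    marine_valid = if (is.null(marine_valid)) empty else marine_valid
  ), class = "realm_grid")
  validate_realm_grid(g)
}

validate_realm_grid <- function(g) {
  dims <- c(g$n_rows, g$n_cols)
  for (m in list(g$terrestrial_valid, g$marine_valid)) {
    if (!is.logical(m) || !identical(dim(m), as.integer(dims)))
      stop("realm masks must be logical n_rows x n_cols matrices", call. = FALSE)
  }
  for (nm in names(g$layers)) {
    ly <- g$layers[[nm]]
    if (!ly$realm %in% c("terrestrial", "marine"))
      stop(sprintf("layer '%s': unknown realm tag '%s'", nm, ly$realm), call. = FALSE)
    if (!identical(dim(ly$values), as.integer(dims)))
      stop(sprintf("layer '%s': dimension mismatch", nm), call. = FALSE)
    realm_mask <- realm_mask(g, ly$realm)
    if (any(ly$valid & !realm_mask))
      stop(sprintf("layer '%s': validity mask exceeds its realm mask", nm), call. = FALSE)
  }
  g
}

#' @export
print.realm_grid <- function(x, ...) {
  cat(sprintf("realm_grid: %d x %d cells, %.6g deg resolution\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  origin (NW cell centre): %.4f lon, %.4f lat\n",
              x$origin_lon, x$origin_lat))
  cat(sprintf("  terrestrial-valid: %d, marine-valid: %d, coastal (both): %d\n",
              sum(x$terrestrial_valid), sum(x$marine_valid),
              sum(x$terrestrial_valid & x$marine_valid)))
  tags <- vapply(x$layers, `[[`, "", "realm")
  for (realm in c("terrestrial", "marine")) {
    nm <- names(tags)[tags == realm]
    if (length(nm)) cat(sprintf("  %s layers: %s\n", realm, paste(nm, collapse = ", ")))
  }
  invisible(x)
}

realm_mask <- function(grid, realm) {
  switch(realm,
         terrestrial = grid$terrestrial_valid,
         marine = grid$marine_valid,
         stop(sprintf("unknown realm tag '%s'", realm), call. = FALSE))
}

#' Register an environmental layer on a grid
#'
#' @param grid A [realm_grid()].
#' @param name Layer name (e.g. `"SST"`, `"temperature"`).
#' @param realm `"terrestrial"` or `"marine"`.
#' @param values Numeric matrix `n_rows x n_cols`; cells outside `valid` may be `NA`.
#' @param valid Optional logical validity mask; defaults to `!is.na(values)`.
#'   The realm's mask is grown to the union of its layers' masks.
#' @return The grid with the layer registered.
#' @export
add_layer <- function(grid, name, realm, values, valid = NULL) {
  if (!inherits(grid, "realm_grid")) stop("not a realm_grid", call. = FALSE)
  if (!realm %in% c("terrestrial", "marine"))
    stop(sprintf("unknown realm tag '%s'", realm), call. = FALSE)
  if (!is.matrix(values) || nrow(values) != grid$n_rows ||
      ncol(values) != grid$n_cols)
    stop(sprintf("layer '%s': values must be a %d x %d matrix", name,
                 grid$n_rows, grid$n_cols), call. = FALSE)
  storage.mode(values) <- "double"
  if (is.null(valid)) valid <- !is.na(values)
  storage.mode(valid) <- "logical"
  grid$layers[[name]] <- list(realm = realm, values = values, valid = valid)
  if (realm == "terrestrial") grid$terrestrial_valid <- grid$terrestrial_valid | valid
  else grid$marine_valid <- grid$marine_valid | valid
  validate_realm_grid(grid)
}

#' Longitude/latitude of cell centres
#'
#' Row 1 is the northernmost row, column 1 the westernmost column:
#' `lon = origin_lon + (col - 1) * cell_size`,
#' `lat = origin_lat - (row - 1) * cell_size`.
#'
#' @param grid A [realm_grid()].
#' @param row,col Integer vectors of 1-based cell indices (recycled).
#' @return A two-column matrix with columns `lon`, `lat`.
#' @export
cell_center <- function(grid, row, col) {
  if (any(row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols))
    stop("cell index out of bounds", call. = FALSE)
  cbind(lon = grid$origin_lon + (col - 1) * grid$cell_size,
        lat = grid$origin_lat - (row - 1) * grid$cell_size)
}

# Cells of a logical mask as a (row, col) matrix ordered by row, then column —
# the package-wide deterministic enumeration order (used for tie-breaking).
mask_cells <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("row", "col")
  idx
}

# Area of each cell in km^2 from the spherical quadrilateral formula
# R^2 * dlambda * (sin(lat_n) - sin(lat_s)); depends on the row only.
cell_area_km2 <- function(grid, row) {
  to_rad <- pi / 180
  lat_c <- grid$origin_lat - (row - 1) * grid$cell_size
  lat_n <- pmin(lat_c + grid$cell_size / 2, 90) * to_rad
  lat_s <- pmax(lat_c - grid$cell_size / 2, -90) * to_rad
  r_km <- .EARTH_RADIUS_M / 1000
  r_km^2 * (grid$cell_size * to_rad) * (sin(lat_n) - sin(lat_s))
}

# Fetch a layer's values at cells (matrix rows), NA where invalid.
layer_at <- function(grid, name, cells) {
  ly <- grid$layers[[name]]
  if (is.null(ly)) stop(sprintf("missing layer '%s'", name), call. = FALSE)
  idx <- cbind(cells[, 1], cells[, 2])
  out <- ly$values[idx]
  out[!ly$valid[idx]] <- NA_real_
  out
}

layer_names <- function(grid, realm = NULL) {
  tags <- vapply(grid$layers, `[[`, "", "realm")
  if (is.null(realm)) names(tags) else names(tags)[tags == realm]
}
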