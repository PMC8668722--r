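# Cross-realm covariate engineering: nearest-other-realm maps, distance-to-
# coast layers, foraging-buffer aggregation of marine conditions onto
# terrestrial cells, nearest-terrestrial inheritance onto marine cells, and
# landmass area/isolation.

other_realm <- function(realm) {
  if (realm == "terrestrial") "marine" else "terrestrial"
}

#' Nearest valid cell of the other realm
#'
#' For every cell valid in `source_realm`, finds the cell of the other realm
#' whose centre is nearest by great-circle distance. Coastal cells (valid in
#' both realms) map to themselves at distance zero. Ties are broken
#' deterministically towards the lowest row, then the lowest column.
#'
#' @param grid A [realm_grid()].
#' @param source_realm `"terrestrial"` or `"marine"`.
#' @return A `cross_realm_map`: list with `source_realm`, `cells` (n x 2 matrix
#'   of source row/col, ordered by row then column), `nearest` (n x 2 matrix of
#'   the matched other-realm cells) and `distance_m`.
#' @export
nearest_other_realm <- function(grid, source_realm) {
  src_mask <- realm_mask(grid, source_realm)
  dst_mask <- realm_mask(grid, other_realm(source_realm))
  if (!any(src_mask))
    stop(sprintf("no valid cells in source realm '%s'", source_realm), call. = FALSE)
  if (!any(dst_mask))
    stop(sprintf("no valid cells in realm '%s'", other_realm(source_realm)),
         call. = FALSE)
  src <- mask_cells(src_mask)
  dst <- mask_cells(dst_mask)
  nearest <- matrix(NA_integer_, nrow(src), 2, dimnames = list(NULL, c("row", "col")))
  dist_m <- numeric(nrow(src))

  both <- src_mask & dst_mask
  is_both <- both[src]
  nearest[is_both, ] <- src[is_both, , drop = FALSE]
  # dist_m already 0 for coastal cells
  todo <- which(!is_both)
  if (length(todo)) {
    d <- cross_dist_m(cell_center(grid, src[todo, 1], src[todo, 2]),
                      cell_center(grid, dst[, 1], dst[, 2]))
    # dst is enumerated by (row, col); the first cell within 1 mm of the row
    # minimum wins, so exact geometric ties (symmetric cells, whose computed
    # distances can differ by rounding) break deterministically to the lowest
    # row, then the lowest column
    jmin <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_along(todo), jmin)]
    j <- max.col(d <= dmin + 1e-3, ties.method = "first")
    nearest[todo, ] <- dst[j, , drop = FALSE]
    dist_m[todo] <- d[cbind(seq_along(todo), j)]
  }
  structure(list(source_realm = source_realm, cells = src,
                 nearest = nearest, distance_m = dist_m),
            class = "cross_realm_map")
}

#' Distance-to-coast layers
#'
#' Registers two derived layers: `distance_from_land` on the marine realm (the
#' distance from each marine cell to the nearest terrestrially valid cell) and
#' `distance_from_sea` on the terrestrial realm (mirrored). For a cell with
#' valid values in both realms the distance is zero in both layers.
#'
#' @param grid A [realm_grid()] with both realm masks non-empty.
#' @return The grid with the two layers added (metres).
#' @export
distance_variables <- function(grid) {
  for (spec in list(c("marine", "distance_from_land"),
                    c("terrestrial", "distance_from_sea"))) {
    cm <- nearest_other_realm(grid, spec[1])
    vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    vals[cm$cells] <- cm$distance_m
    grid <- add_layer(grid, spec[2], spec[1], vals)
  }
  grid
}

new_augmented <- function(tab, model_type, covariates, mmfd_m = NA_real_) {
  structure(tab, class = c("augmented_covariates", "data.frame"),
            model_type = model_type, covariates = covariates, mmfd_m = mmfd_m)
}

local_table <- function(grid, realm) {
  cells <- mask_cells(realm_mask(grid, realm))
  vars <- layer_names(grid, realm)
  tab <- data.frame(row = cells[, 1], col = cells[, 2])
  for (v in vars) tab[[v]] <- layer_at(grid, v, cells)
  list(tab = tab, vars = vars, cells = cells)
}

#' Terrestrial table with buffered marine conditions
#'
#' The first way of combining realms: each terrestrial cell keeps its local
#' terrestrial values and gains, for every marine variable X, the mean
#' (`mean_X`) and sample standard deviation (`X_variation`) of X over all
#' marine cells within the species' mean maximum foraging distance (MMFD) of
#' the cell's *nearest coast cell* (its nearest marine-valid cell). The buffer
#' is centred on the coast cell, not the terrestrial cell itself, so far-inland
#' cells summarise the sea off their nearest stretch of coast.
#'
#' Buffer membership is centre-to-centre great-circle distance `<= mmfd_m`; the
#' coast cell itself is always a member, so the sample set is never empty. A
#' single-cell buffer yields variation 0. The member count is returned in
#' `n_buffer_cells`.
#'
#' @param grid A [realm_grid()] with at least one marine layer.
#' @param config A [multirealm_config()] supplying `mmfd_m`.
#' @return An `augmented_covariates` data frame (model type `TerrWithMar`).
#' @export
terrestrial_with_marine <- function(grid, config) {
  mar_vars <- layer_names(grid, "marine")
  if (!length(mar_vars)) stop("no marine layers registered", call. = FALSE)
  stopifnot_scalar_number(config$mmfd_m, "mmfd_m", positive = TRUE)
  loc <- local_table(grid, "terrestrial")
  cm <- nearest_other_realm(grid, "terrestrial")
  coast <- unique(cm$nearest)
  mar <- mask_cells(grid$marine_valid)
  d <- cross_dist_m(cell_center(grid, coast[, 1], coast[, 2]),
                    cell_center(grid, mar[, 1], mar[, 2]))
  mar_vals <- vapply(mar_vars, function(v) layer_at(grid, v, mar),
                     numeric(nrow(mar)))
  key <- function(cells) paste(cells[, 1], cells[, 2])
  stats_per_coast <- lapply(seq_len(nrow(coast)), function(i) {
    member <- d[i, ] <= config$mmfd_m
    if (!any(member)) stop("empty buffer: nearest coast cell not marine-valid")
    x <- mar_vals[member, , drop = FALSE]
    n_ok <- colSums(!is.na(x))
    mu <- colMeans(x, na.rm = TRUE)
    mu[n_ok == 0] <- NA_real_
    sdv <- apply(x, 2, function(col) stats::sd(col, na.rm = TRUE))
    sdv[n_ok == 1] <- 0  # single-cell coves stay modelable
    sdv[n_ok == 0] <- NA_real_
    c(mu, sdv, n = sum(member))
  })
  sm <- do.call(rbind, stats_per_coast)
  rownames(sm) <- key(coast)
  at <- sm[key(cm$nearest), , drop = FALSE]
  p <- length(mar_vars)
  tab <- loc$tab
  for (j in seq_len(p)) {
    tab[[paste0("mean_", mar_vars[j])]] <- at[, j]
    tab[[paste0(mar_vars[j], "_variation")]] <- at[, p + j]
  }
  tab$n_buffer_cells <- as.integer(at[, 2 * p + 1])
  covs <- c(loc$vars, paste0("mean_", mar_vars), paste0(mar_vars, "_variation"))
  new_augmented(tab, "TerrWithMar", covs, mmfd_m = config$mmfd_m)
}

#' Marine table with nearest-terrestrial conditions
#'
#' The second way of combining realms: each marine cell keeps its local marine
#' values and inherits, for every terrestrial variable Y, the value of Y at its
#' nearest terrestrially valid cell (column `nearest_Y`). The same nearest-cell
#' map underlies the `distance_from_land` layer, so the two are consistent.
#' Coastal cells inherit their own terrestrial values.
#'
#' @param grid A [realm_grid()] with at least one terrestrial layer.
#' @param config A [multirealm_config()] (present for interface symmetry).
#' @return An `augmented_covariates` data frame (model type `MarWithTerr`).
#' @export
marine_with_terrestrial <- function(grid, config = multirealm_config()) {
  terr_vars <- layer_names(grid, "terrestrial")
  if (!length(terr_vars)) stop("no terrestrial layers registered", call. = FALSE)
  loc <- local_table(grid, "marine")
  cm <- nearest_other_realm(grid, "marine")
  tab <- loc$tab
  for (v in terr_vars)
    tab[[paste0("nearest_", v)]] <- layer_at(grid, v, cm$nearest)
  covs <- c(loc$vars, paste0("nearest_", terr_vars))
  new_augmented(tab, "MarWithTerr", covs)
}

#' Build the covariate table for one of the four model types
#'
#' @param grid A [realm_grid()].
#' @param approach One of `"TerrOnly"`, `"MarOnly"`, `"TerrWithMar"`,
#'   `"MarWithTerr"`.
#' @param config A [multirealm_config()].
#' @return An `augmented_covariates` data frame: one row per focal-realm cell
#'   (`row`, `col` index columns), one column per covariate. The covariate
#'   names, model type and MMFD are carried as attributes.
#' @export
augment_covariates <- function(grid, approach, config = multirealm_config()) {
  approach <- match.arg(approach,
                        c("TerrOnly", "MarOnly", "TerrWithMar", "MarWithTerr"))
  switch(approach,
    TerrOnly = {
      loc <- local_table(grid, "terrestrial")
      new_augmented(loc$tab, "TerrOnly", loc$vars)
    },
    MarOnly = {
      loc <- local_table(grid, "marine")
      new_augmented(loc$tab, "MarOnly", loc$vars)
    },
    TerrWithMar = terrestrial_with_marine(grid, config),
    MarWithTerr = marine_with_terrestrial(grid, config))
}

focal_realm <- function(model_type) {
  if (model_type %in% c("TerrOnly", "TerrWithMar")) "terrestrial" else "marine"
}

#' Write an augmented covariate table as CSV with a provenance header
#'
#' @param covs An `augmented_covariates` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariates_csv <- function(covs, path) {
  hdr <- c(sprintf("# model_type=%s", attr(covs, "model_type")),
           sprintf("# mmfd_m=%.17g", attr(covs, "mmfd_m")),
           sprintf("# covariates=%s", paste(attr(covs, "covariates"), collapse = ";")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(covs), con, row.names = FALSE)
  invisible(path)
}

#' Label landmasses and compute their area and isolation
#'
#' Connected components of the terrestrial validity mask. Area is reported both
#' as a cell count and in km^2 (spherical quadrilateral cell areas, so
#' high-latitude cells weigh less). Isolation is the minimum great-circle
#' centre-to-centre distance from a landmass to any cell of a strictly larger
#' (by km^2) landmass; the largest landmass — and any landmass with no strictly
#' larger neighbour, e.g. under exact area ties — has missing isolation.
#'
#' @param grid A [realm_grid()] with a non-empty terrestrial mask.
#' @param connectivity 8 (default: diagonally touching cells are one landmass)
#'   or 4.
#' @return A data frame with one row per landmass: `landmass` (label), `n_cells`,
#'   `area_km2`, `isolation_m`; the label matrix is attached as attribute
#'   `labels`.
#' @export
label_landmasses <- function(grid, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  mask <- grid$terrestrial_valid
  if (!any(mask)) stop("terrestrial mask is empty", call. = FALSE)
  cells <- mask_cells(mask)
  n <- nrow(cells)
  id <- matrix(0L, grid$n_rows, grid$n_cols)
  id[cells] <- seq_len(n)
  off <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    off <- rbind(off, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    nb <- cbind(cells[, 1] + off[k, 1], cells[, 2] + off[k, 2])
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid$n_rows &
          nb[, 2] >= 1 & nb[, 2] <= grid$n_cols
    ok[ok] <- id[nb[ok, , drop = FALSE]] > 0L
    if (any(ok))
      edges <- rbind(edges, cbind(id[cells[ok, , drop = FALSE]],
                                  id[nb[ok, , drop = FALSE]]))
  }
  gph <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(), 0, 2) else edges, directed = FALSE)
  gph <- igraph::add_vertices(gph, max(0L, n - igraph::vcount(gph)))
  comp <- igraph::components(gph)$membership[seq_len(n)]
  labels <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  labels[cells] <- comp
  k <- max(comp)
  areas <- as.numeric(tapply(cell_area_km2(grid, cells[, 1]),
                             factor(comp, levels = seq_len(k)), sum))
  counts <- tabulate(comp, nbins = k)
  centers <- cell_center(grid, cells[, 1], cells[, 2])
  iso <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    larger <- which(areas > areas[i])
    if (!length(larger)) next
    own <- comp == i
    other <- comp %in% larger
    d <- cross_dist_m(centers[own, , drop = FALSE], centers[other, , drop = FALSE])
    iso[i] <- min(d)
  }
  out <- data.frame(landmass = seq_len(k), n_cells = counts,
                    area_km2 = as.numeric(areas), isolation_m = iso)
  attr(out, "labels") <- labels
  out
}
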