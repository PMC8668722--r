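# Synthetic seascapes and virtual species: reproducible, download-free stand-
# ins for gridded environmental databases and real occurrence data, with a
# known generative suitability so that model behaviour can be verified.

# Smooth a matrix with a separable Gaussian kernel, renormalising at the
# edges (convolution of the value grid divided by convolution of a ones grid).
gauss_smooth <- function(mat, length_scale) {
  hw <- max(1L, ceiling(3 * length_scale))
  w <- stats::dnorm(-hw:hw, sd = length_scale)
  smooth_1d <- function(m) {
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m)); norm <- acc
    for (k in -hw:hw) {
      src <- pmin(pmax(seq_len(n) + k, 1L), n)  # replicate edges
      acc <- acc + w[k + hw + 1L] * m[src, , drop = FALSE]
      norm <- norm + w[k + hw + 1L]
    }
    acc / norm
  }
  t(smooth_1d(t(smooth_1d(mat))))
}

# A standardised Gaussian random field: seeded white noise, Gaussian kernel
# smoothing, then centred and scaled to unit variance.
random_field <- function(n_rows, n_cols, length_scale, seed) {
  set.seed(seed)
  f <- gauss_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                    length_scale)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic two-realm seascape
#'
#' Builds an archipelago: one or more meandering north-south island strips of
#' land separated by open sea, every coastline a one-cell fringe valid in both
#' realms. With the default strip width of 8 cells (about 40 km at 5
#' arc-minutes) every terrestrial cell lies within a 20-km coastal band — the
#' geometry of the narrow islands and peninsulas where seabirds breed. Every
#' environmental variable is a smoothed Gaussian random field (standardised to
#' mean 0, SD 1), independent across variables, reproducible from the seed.
#'
#' @param n_rows,n_cols Grid dimensions (at least 8 x 8).
#' @param coastline_complexity Relative amplitude of each strip's meander in
#'   `[0,1]`; 0 gives straight coasts. Default 0.3.
#' @param n_terr_vars,n_mar_vars Number of terrestrial / marine variables
#'   (named `terr1..`, `mar1..`). Default 3 each.
#' @param seed Integer seed.
#' @param cell_size Degrees per cell, default 5 arc-minutes.
#' @param origin_lon,origin_lat North-west cell centre; the default places the
#'   world at seabird latitudes (60 N).
#' @param length_scale Gaussian smoothing length scale in cells, default 5.
#' @param land_width Width of each land strip in cells (>= 2), default 8.
#' @param n_strips Number of island strips, default 2. Each strip meanders
#'   within its own longitudinal zone so strips do not merge.
#' @return A [realm_grid()].
#' @export
generate_seascape <- function(n_rows, n_cols, coastline_complexity = 0.3,
                              n_terr_vars = 3, n_mar_vars = 3, seed = 1L,
                              cell_size = 1 / 12, origin_lon = -10,
                              origin_lat = 60, length_scale = 5,
                              land_width = 8, n_strips = 2) {
  if (n_rows < 8 || n_cols < 8)
    stop("seascape needs at least 8 x 8 cells", call. = FALSE)
  land_width <- as.integer(land_width); n_strips <- as.integer(n_strips)
  zone <- n_cols %/% n_strips
  if (land_width < 2 || land_width > zone - 2)
    stop("land_width must be in [2, n_cols/n_strips - 2]", call. = FALSE)
  terr_mask <- matrix(FALSE, n_rows, n_cols)
  mar_mask <- matrix(TRUE, n_rows, n_cols)
  cols <- seq_len(n_cols)
  for (k in seq_len(n_strips)) {
    set.seed(derive_seed(seed, "coastline", k))
    wig <- as.numeric(gauss_smooth(matrix(stats::rnorm(n_rows), ncol = 1),
                                   length_scale))
    if (stats::sd(wig) > 0) wig <- wig / stats::sd(wig)
    z0 <- (k - 1L) * zone
    west <- round(z0 + zone / 2 - land_width / 2 +
                    coastline_complexity * (zone / 4) * wig)
    west <- pmin(pmax(west, z0 + 2L), z0 + zone - land_width)
    east <- west + land_width - 1L
    strip <- outer(west, cols, `<=`) & outer(east, cols, `>=`)
    terr_mask <- terr_mask | strip
    # interior of the strip is land-only; the fringes stay marine-valid
    mar_mask <- mar_mask & !(outer(west, cols, `<`) & outer(east, cols, `>`))
  }
  g <- realm_grid(n_rows, n_cols, origin_lon, origin_lat, cell_size)
  add_field <- function(g, name, realm, mask, index) {
    f <- random_field(n_rows, n_cols, length_scale,
                      derive_seed(seed, paste0("field_", realm), index))
    f[!mask] <- NA_real_
    add_layer(g, name, realm, f)
  }
  for (i in seq_len(n_terr_vars))
    g <- add_field(g, paste0("terr", i), "terrestrial", terr_mask, i)
  for (i in seq_len(n_mar_vars))
    g <- add_field(g, paste0("mar", i), "marine", mar_mask, i)
  g
}

#' Define a virtual species
#'
#' A virtual species has a known logistic suitability over named covariates —
#' which may be cross-realm features such as `mean_mar1` — so that the
#' recovered models can be checked against the generative truth.
#'
#' @param coefficients Named numeric vector of effects per standard deviation
#'   of each covariate (covariates are standardised internally when
#'   suitability is evaluated). At least one must be non-zero.
#' @param intercept Intercept on the logit scale; controls prevalence.
#' @param realm Realm of occupancy, `"terrestrial"` or `"marine"`.
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(coefficients, intercept = 0,
                            realm = c("terrestrial", "marine")) {
  realm <- match.arg(realm)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be named by covariate", call. = FALSE)
  if (all(coefficients == 0))
    stop("at least one coefficient must be non-zero", call. = FALSE)
  structure(list(coefficients = coefficients, intercept = intercept,
                 realm = realm), class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("virtual_species (%s realm): logit(p) = %.3g %s\n", x$realm,
              x$intercept,
              paste(sprintf("%+.3g*%s", x$coefficients, names(x$coefficients)),
                    collapse = " ")))
  invisible(x)
}

#' True suitability of a virtual species over a covariate table
#'
#' Inverse-logit of the species' linear predictor. Each referenced covariate
#' is standardised over the table's rows, so coefficients are effects per SD.
#'
#' @param species A [virtual_species()].
#' @param covs An `augmented_covariates` table (or any data frame containing
#'   the referenced covariates).
#' @return Numeric vector of probabilities, one per row of `covs`.
#' @export
true_suitability <- function(species, covs) {
  missing <- setdiff(names(species$coefficients), names(covs))
  if (length(missing))
    stop(sprintf("covariate(s) not in table: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  eta <- rep(species$intercept, nrow(covs))
  for (v in names(species$coefficients)) {
    x <- covs[[v]]
    s <- stats::sd(x, na.rm = TRUE)
    z <- if (is.na(s) || s == 0) 0 * x else (x - mean(x, na.rm = TRUE)) / s
    eta <- eta + species$coefficients[[v]] * z
  }
  stats::plogis(eta)
}

#' Sample presence cells from a true suitability surface
#'
#' Bernoulli draw per cell with probability proportional to suitability,
#' rescaled so the expected presence count is approximately the target.
#'
#' @param suitability Per-cell probabilities.
#' @param cells n x 2 matrix of the corresponding (row, col) cells.
#' @param n_presence_target Expected number of presences.
#' @param seed Integer seed.
#' @return m x 2 matrix of presence cells.
#' @export
sample_occurrences <- function(suitability, cells, n_presence_target, seed = 1L) {
  if (n_presence_target > length(suitability))
    stop("presence target exceeds the number of cells", call. = FALSE)
  tot <- sum(suitability)
  if (tot == 0) {
    p <- rep(0, length(suitability))
  } else if (sum(suitability > 0) <= n_presence_target) {
    p <- as.numeric(suitability > 0)
  } else {
    # scale so the expected count hits the target despite clipping at 1
    expected <- function(s) sum(pmin(s * suitability, 1)) - n_presence_target
    upper <- 1
    while (expected(upper) < 0) upper <- upper * 2
    s <- stats::uniroot(expected, c(0, upper), tol = 1e-10)$root
    p <- pmin(s * suitability, 1)
  }
  set.seed(derive_seed(seed, "occurrences"))
  hit <- stats::runif(length(p)) < p
  cells[hit, , drop = FALSE]
}

#' Simulate a complete multi-realm study world
#'
#' Convenience wrapper tying the generator together: an island-strip seascape
#' with distance layers, a run configuration, a terrestrial virtual species,
#' and sampled presence cells. The species' truth combines a local terrestrial
#' variable (`terr1`) with the foraging-buffer mean of a marine variable
#' (`mean_mar1`) — the cross-realm dependence of a breeding seabird whose
#' colonies track nearby marine conditions. Because the land strip is narrow,
#' every terrestrial cell lies in the coastal background band, so presences
#' and pseudo-absences differ by environment rather than by distance from the
#' sea. This is the standard world used throughout the package's simulation
#' experiments.
#'
#' @param seed Integer seed driving every random stage.
#' @param n_rows,n_cols Grid size, default 60 x 60.
#' @param n_presence_target Expected presences, default 300.
#' @param mmfd_m Foraging distance, default 16.6 km (roseate-tern-like, a
#'   short-range coastal forager whose marine driver stays local).
#' @param beta_terr,beta_mar Per-SD effects of the terrestrial driver and the
#'   buffered marine driver; defaults 1 and 2 (marine-dominated, as observed
#'   for short-range coastal seabirds).
#' @param n_pseudo,n_sets Pseudo-absence count and number of sets for the
#'   configuration; defaults 300 and 1, giving a prevalence near 0.5 against
#'   the ~660 unoccupied terrestrial cells of a default world.
#' @param ... Further arguments to [multirealm_config()].
#' @return List: `grid`, `config`, `covariates` (TerrWithMar table), `species`,
#'   `suitability`, `presences`.
#' @export
simulate_multirealm_world <- function(seed = 1L, n_rows = 60, n_cols = 60,
                                      n_presence_target = 300, mmfd_m = 16600,
                                      beta_terr = 3, beta_mar = 6,
                                      n_pseudo = 300, n_sets = 1, ...) {
  grid <- generate_seascape(n_rows, n_cols, seed = seed)
  grid <- distance_variables(grid)
  config <- multirealm_config(mmfd_m = mmfd_m, n_pseudo = n_pseudo,
                              n_sets = n_sets, seed = seed, ...)
  covs <- terrestrial_with_marine(grid, config)
  species <- virtual_species(
    c(terr1 = beta_terr, mean_mar1 = beta_mar),
    intercept = -6, realm = "terrestrial")
  suit <- true_suitability(species, covs)
  presences <- sample_occurrences(suit, as.matrix(covs[, c("row", "col")]),
                                  n_presence_target, seed)
  list(grid = grid, config = config, covariates = covs, species = species,
       suitability = suit, presences = presences)
}
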