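# Gridded-CSV serialisation. One file carries the grid geometry in '#' header
# lines and one column per variable; values are printed with "%.17g" so a
# write -> read round trip is bit-stable for doubles and masks.

#' Write a grid to gridded CSV
#'
#' The file starts with `#`-prefixed metadata lines (grid geometry and the
#' realm tag of every variable), followed by a CSV table with columns `row`,
#' `col` and one column per layer; cells invalid for a layer are written as
#' `NA`. Only cells valid in at least one layer are written.
#'
#' @param grid A [realm_grid()].
#' @param path Output file path.
#' @param layers Layer names to write (default: all).
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path, layers = layer_names(grid)) {
  any_valid <- Reduce(`|`, lapply(grid$layers[layers], `[[`, "valid"),
                      matrix(FALSE, grid$n_rows, grid$n_cols))
  cells <- mask_cells(any_valid | grid$terrestrial_valid | grid$marine_valid)
  hdr <- c(
    "# mrsdm_grid v1",
    sprintf("# n_rows=%d", grid$n_rows),
    sprintf("# n_cols=%d", grid$n_cols),
    sprintf("# origin_lon=%.17g", grid$origin_lon),
    sprintf("# origin_lat=%.17g", grid$origin_lat),
    sprintf("# cell_size=%.17g", grid$cell_size),
    vapply(layers, function(nm)
      sprintf("# realm.%s=%s", nm, grid$layers[[nm]]$realm), "")
  )
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  cols <- lapply(layers, function(nm) num(layer_at(grid, nm, cells)))
  body <- do.call(paste, c(list(cells[, 1], cells[, 2]), cols, sep = ","))
  writeLines(c(hdr, paste(c("row", "col", layers), collapse = ","), body), path)
  invisible(path)
}

parse_grid_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  kv <- kv[grepl("=", kv)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Read a gridded CSV written by [write_grid_csv()]
#'
#' @param path File path.
#' @param realm_tags Optional named character vector overriding the realm tag
#'   of each variable (names are variable names, values `"terrestrial"` or
#'   `"marine"`); by default tags come from the file header.
#' @return A [realm_grid()].
#' @export
read_grid_csv <- function(path, realm_tags = NULL) {
  lines <- readLines(path)
  meta <- parse_grid_header(lines)
  need <- c("n_rows", "n_cols", "origin_lon", "origin_lat", "cell_size")
  if (!all(need %in% names(meta)))
    stop(sprintf("'%s' is not a gridded CSV: missing %s", path,
                 paste(setdiff(need, names(meta)), collapse = ", ")), call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = body, check.names = FALSE)
  vars <- setdiff(names(tab), c("row", "col"))
  tags <- meta[paste0("realm.", vars)]
  names(tags) <- vars
  if (!is.null(realm_tags)) tags[names(realm_tags)] <- realm_tags
  g <- realm_grid(as.integer(meta$n_rows), as.integer(meta$n_cols),
                  as.numeric(meta$origin_lon), as.numeric(meta$origin_lat),
                  as.numeric(meta$cell_size))
  for (v in vars) {
    tag <- tags[[v]]
    if (is.null(tag) || is.na(tag))
      stop(sprintf("no realm tag for variable '%s'", v), call. = FALSE)
    vals <- matrix(NA_real_, g$n_rows, g$n_cols)
    vals[cbind(tab$row, tab$col)] <- tab[[v]]
    g <- add_layer(g, v, tag, vals)
  }
  g
}

#' Load and align gridded CSV files into one two-realm grid
#'
#' All files must share extent and resolution to within 1e-9 degrees; layers
#' from every file are merged into a single [realm_grid()].
#'
#' @param paths Character vector of gridded CSV paths.
#' @param realm_tags Optional named character vector of realm overrides,
#'   passed to [read_grid_csv()].
#' @return A [realm_grid()] with all layers registered.
#' @export
load_grid <- function(paths, realm_tags = NULL) {
  grids <- lapply(paths, read_grid_csv, realm_tags = realm_tags)
  g <- grids[[1]]
  for (h in grids[-1]) {
    geom_g <- c(g$origin_lon, g$origin_lat, g$cell_size)
    geom_h <- c(h$origin_lon, h$origin_lat, h$cell_size)
    if (g$n_rows != h$n_rows || g$n_cols != h$n_cols ||
        any(abs(geom_g - geom_h) > 1e-9))
      stop("grid alignment error: extents or resolutions differ", call. = FALSE)
    for (nm in names(h$layers))
      g <- add_layer(g, nm, h$layers[[nm]]$realm, h$layers[[nm]]$values,
                     h$layers[[nm]]$valid)
  }
  g
}
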