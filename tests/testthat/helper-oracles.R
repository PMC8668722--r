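# Fixture builders and independent brute-force oracles. The oracles use plain
# double loops over cells and never share code with the package's vectorised
# implementations.

# A grid with random realm masks and one random layer per realm.
random_mask_grid <- function(seed, n_rows, n_cols, p_terr = 0.45, p_mar = 0.45,
                             cell_size = 1 / 12, origin_lat = 58) {
  set.seed(seed)
  terr <- matrix(runif(n_rows * n_cols) < p_terr, n_rows, n_cols)
  mar <- matrix(runif(n_rows * n_cols) < p_mar, n_rows, n_cols)
  # guarantee both realms are non-empty
  terr[1, 1] <- TRUE; mar[n_rows, n_cols] <- TRUE
  g <- realm_grid(n_rows, n_cols, origin_lon = -5, origin_lat = origin_lat,
                  cell_size = cell_size)
  tv <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols); tv[!terr] <- NA
  mv <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols); mv[!mar] <- NA
  g <- add_layer(g, "tvar", "terrestrial", tv)
  add_layer(g, "mvar", "marine", mv)
}

# Scalar haversine, written independently of the package kernel.
oracle_dist <- function(lon1, lat1, lon2, lat2) {
  R <- 6371008.8
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(sqrt(min(max(a, 0), 1)))
}

oracle_center <- function(g, r, c) {
  c(g$origin_lon + (c - 1) * g$cell_size, g$origin_lat - (r - 1) * g$cell_size)
}

# Exhaustive nearest-other-realm search with (row, col) tie-break.
oracle_nearest <- function(g, source_realm) {
  src_mask <- if (source_realm == "terrestrial") g$terrestrial_valid else g$marine_valid
  dst_mask <- if (source_realm == "terrestrial") g$marine_valid else g$terrestrial_valid
  out <- NULL
  for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols)) {
    if (!src_mask[r, c]) next
    best <- NULL; best_d <- Inf
    for (r2 in seq_len(g$n_rows)) for (c2 in seq_len(g$n_cols)) {
      if (!dst_mask[r2, c2]) next
      a <- oracle_center(g, r, c); b <- oracle_center(g, r2, c2)
      d <- oracle_dist(a[1], a[2], b[1], b[2])
      # ties within 1 mm keep the earlier (row, col) cell
      if (d < best_d - 1e-3) { best_d <- d; best <- c(r2, c2) }
    }
    out <- rbind(out, c(r, c, best, best_d))
  }
  colnames(out) <- c("row", "col", "nrow", "ncol", "dist")
  out
}

# Exhaustive buffer statistics for every terrestrial cell: nearest marine
# cell, then mean/SD of a marine layer over marine cells within the radius.
oracle_buffer_stats <- function(g, layer, mmfd_m) {
  near <- oracle_nearest(g, "terrestrial")
  vals <- g$layers[[layer]]$values
  mar_mask <- g$marine_valid
  out <- NULL
  for (i in seq_len(nrow(near))) {
    cc <- near[i, c("nrow", "ncol")]
    a <- oracle_center(g, cc[1], cc[2])
    s <- c()
    for (r2 in seq_len(g$n_rows)) for (c2 in seq_len(g$n_cols)) {
      if (!mar_mask[r2, c2]) next
      b <- oracle_center(g, r2, c2)
      if (oracle_dist(a[1], a[2], b[1], b[2]) <= mmfd_m)
        s <- c(s, vals[r2, c2])
    }
    n_ok <- sum(!is.na(s))
    out <- rbind(out, c(near[i, "row"], near[i, "col"],
                        mean = if (n_ok) mean(s, na.rm = TRUE) else NA,
                        sd = if (n_ok > 1) sd(s, na.rm = TRUE) else if (n_ok == 1) 0 else NA,
                        n = length(s)))
  }
  out
}

# Exhaustive background filter.
oracle_background <- function(g, realm, cutoff_m) {
  src_mask <- if (realm == "terrestrial") g$terrestrial_valid else g$marine_valid
  near <- oracle_nearest(g, realm)
  keep <- near[near[, "dist"] <= cutoff_m, c("row", "col"), drop = FALSE]
  keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
}

# Exhaustive landmass labelling (flood fill) + isolation by pairwise scan.
oracle_landmasses <- function(g, connectivity = 8) {
  mask <- g$terrestrial_valid
  lab <- matrix(0L, g$n_rows, g$n_cols)
  nb <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(0,-1), c(0,1), c(1,0))
  next_id <- 0L
  for (r in seq_len(g$n_rows)) for (c in seq_len(g$n_cols)) {
    if (!mask[r, c] || lab[r, c] > 0) next
    next_id <- next_id + 1L
    queue <- list(c(r, c)); lab[r, c] <- next_id
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        rr <- cur[1] + nb[k, 1]; cc <- cur[2] + nb[k, 2]
        if (rr >= 1 && rr <= g$n_rows && cc >= 1 && cc <= g$n_cols &&
            mask[rr, cc] && lab[rr, cc] == 0) {
          lab[rr, cc] <- next_id
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  # areas via the same spherical formula, computed independently
  R_km <- 6371008.8 / 1000
  area_of_row <- function(r) {
    lat <- g$origin_lat - (r - 1) * g$cell_size
    latn <- min(lat + g$cell_size / 2, 90) * pi / 180
    lats <- max(lat - g$cell_size / 2, -90) * pi / 180
    R_km^2 * (g$cell_size * pi / 180) * (sin(latn) - sin(lats))
  }
  ids <- seq_len(next_id)
  areas <- vapply(ids, function(i) {
    sum(vapply(which(lab == i), function(idx) {
      area_of_row(((idx - 1) %% g$n_rows) + 1)
    }, 0))
  }, 0)
  iso <- rep(NA_real_, next_id)
  for (i in ids) {
    larger <- ids[areas > areas[i]]
    if (!length(larger)) next
    best <- Inf
    own <- which(lab == i, arr.ind = TRUE)
    oth <- which(matrix(lab %in% larger, g$n_rows), arr.ind = TRUE)
    for (a in seq_len(nrow(own))) for (b in seq_len(nrow(oth))) {
      p <- oracle_center(g, own[a, 1], own[a, 2])
      q <- oracle_center(g, oth[b, 1], oth[b, 2])
      best <- min(best, oracle_dist(p[1], p[2], q[1], q[2]))
    }
    iso[i] <- best
  }
  list(labels = lab, areas = areas, isolation = iso)
}

# Exhaustive pairwise AUC (ties count one half).
oracle_auc <- function(pred, lab) {
  pos <- pred[lab == 1]; neg <- pred[lab == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# A tiny 1 x 3 coastline: terrestrial-only, coastal (both), marine-only.
strip_1x3 <- function(cell_size = 1 / 12) {
  g <- realm_grid(1, 3, origin_lon = 0, origin_lat = 0, cell_size = cell_size)
  g <- add_layer(g, "temperature", "terrestrial",
                 matrix(c(21, 15, NA), 1, 3))
  add_layer(g, "SST", "marine", matrix(c(NA, 8, 10), 1, 3))
}

# A separable two-class toy dataset.
separable_toy <- function(n = 60, seed = 42) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  data.frame(x1 = y * 4 + rnorm(n, sd = 0.3), x2 = rnorm(n), y = y)
}
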