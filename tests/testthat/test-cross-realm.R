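test_that("coastal-zero rule: both-realm cells map to themselves at 0 m", {
  g <- strip_1x3()
  cm <- nearest_other_realm(g, "terrestrial")
  # cell (1,2) is coastal: nearest marine cell is itself
  i <- which(cm$cells[, 1] == 1 & cm$cells[, 2] == 2)
  expect_equal(unname(cm$nearest[i, ]), c(1, 2))
  expect_identical(cm$distance_m[i], 0)
  # land-only cell (1,1): nearest marine cell is (1,2), one cell width away
  j <- which(cm$cells[, 2] == 1)
  expect_equal(unname(cm$nearest[j, ]), c(1, 2))
  width <- great_circle_m(0, 0, 1 / 12, 0)
  expect_equal(cm$distance_m[j], width, tolerance = 1e-12)
})

test_that("exact distance ties break to the lowest row, then column", {
  # integer-degree geometry makes the east and west neighbours exactly
  # equidistant; the deterministic winner is the lower column
  g <- realm_grid(1, 3, origin_lon = 0, origin_lat = 0, cell_size = 1)
  g <- add_layer(g, "t", "terrestrial", matrix(c(NA, 1, NA), 1, 3))
  g <- add_layer(g, "m", "marine", matrix(c(1, NA, 1), 1, 3))
  cm <- nearest_other_realm(g, "terrestrial")
  expect_equal(unname(cm$nearest[1, ]), c(1, 1))
})

test_that("nearest-other-realm errors when the other realm is empty", {
  g <- realm_grid(2, 2, 0, 0, 1 / 12)
  g <- add_layer(g, "t", "terrestrial", matrix(1, 2, 2))
  expect_error(nearest_other_realm(g, "terrestrial"), "marine")
})

test_that("nearest maps equal exhaustive search on random grids", {
  for (seed in c(101, 202, 303)) {
    g <- random_mask_grid(seed, 12, 14)
    for (realm in c("terrestrial", "marine")) {
      cm <- nearest_other_realm(g, realm)
      orc <- oracle_nearest(g, realm)
      expect_equal(cm$cells, orc[, c("row", "col")], ignore_attr = TRUE)
      # minimal distances agree, and every chosen cell attains the minimum
      # (symmetric geometries produce exact ties; either member is a valid
      # nearest cell, so cells are compared through their distances)
      expect_equal(cm$distance_m, unname(orc[, "dist"]), tolerance = 1e-9)
      chosen <- vapply(seq_len(nrow(cm$cells)), function(i) {
        a <- oracle_center(g, cm$cells[i, 1], cm$cells[i, 2])
        b <- oracle_center(g, cm$nearest[i, 1], cm$nearest[i, 2])
        oracle_dist(a[1], a[2], b[1], b[2])
      }, 0)
      expect_true(all(chosen <= orc[, "dist"] + 1e-6))
      other_mask <- if (realm == "terrestrial") g$marine_valid else g$terrestrial_valid
      expect_true(all(other_mask[cm$nearest]))
    }
  }
})

test_that("distance layers honour the coastal-zero rule and map invariants", {
  g <- distance_variables(random_mask_grid(55, 15, 15))
  both <- which(g$terrestrial_valid & g$marine_valid)
  if (length(both)) {
    expect_true(all(g$layers$distance_from_land$values[both] == 0))
    expect_true(all(g$layers$distance_from_sea$values[both] == 0))
  }
  d <- g$layers$distance_from_land$values[g$marine_valid]
  expect_true(all(d >= 0))
  # straight-coast geometry: two cells offshore = two cell widths
  s <- realm_grid(1, 5, 0, 0, 1 / 12)
  s <- add_layer(s, "t", "terrestrial", matrix(c(1, NA, NA, NA, NA), 1, 5))
  s <- add_layer(s, "m", "marine", matrix(c(NA, 1, 1, 1, 1), 1, 5))
  s <- distance_variables(s)
  expect_equal(s$layers$distance_from_land$values[1, 3],
               great_circle_m(0, 0, 2 / 12, 0), tolerance = 1e-12)
})

test_that("buffer mean and variation follow the sample-SD hand computation", {
  # three marine cells holding SST 10, 12, 14 all within reach of the coast
  g <- realm_grid(1, 4, 0, 60, 1 / 12)
  g <- add_layer(g, "elev", "terrestrial", matrix(c(5, NA, NA, NA), 1, 4))
  g <- add_layer(g, "SST", "marine", matrix(c(NA, 10, 12, 14), 1, 4))
  cfg <- multirealm_config(mmfd_m = 50000)  # reaches all three cells
  tab <- terrestrial_with_marine(g, cfg)
  expect_equal(tab$mean_SST, 12)
  expect_equal(tab$SST_variation, 2)       # sample SD, n - 1 denominator
  expect_equal(tab$n_buffer_cells, 3L)
  # degenerate radius: only the coast cell itself
  tab0 <- terrestrial_with_marine(g, multirealm_config(mmfd_m = 1))
  expect_equal(tab0$mean_SST, 10)
  expect_equal(tab0$SST_variation, 0)
  expect_equal(tab0$n_buffer_cells, 1L)
})

test_that("buffer statistics equal the brute-force scan on a random seascape", {
  g <- random_mask_grid(77, 10, 12)
  cfg <- multirealm_config(mmfd_m = 25000)
  tab <- terrestrial_with_marine(g, cfg)
  orc <- oracle_buffer_stats(g, "mvar", cfg$mmfd_m)
  expect_equal(cbind(tab$row, tab$col), orc[, 1:2], ignore_attr = TRUE)
  expect_equal(tab$mean_mvar, unname(orc[, "mean"]), tolerance = 1e-12)
  expect_equal(tab$mvar_variation, unname(orc[, "sd"]), tolerance = 1e-12)
  expect_equal(tab$n_buffer_cells, as.integer(orc[, "n"]))
})

test_that("enlarging the foraging radius never shrinks buffer membership", {
  g <- random_mask_grid(88, 12, 12)
  radii <- c(10000, 20000, 40000, 80000)
  sizes <- sapply(radii, function(r)
    terrestrial_with_marine(g, multirealm_config(mmfd_m = r))$n_buffer_cells)
  expect_true(all(apply(sizes, 1, diff) >= 0))
})

test_that("marine cells inherit their nearest terrestrial values", {
  g <- strip_1x3()
  tab <- marine_with_terrestrial(g)
  # coastal cell (1,2) inherits its own terrestrial temperature (15);
  # open-sea cell (1,3) inherits from the nearest terrestrial cell (1,2)
  expect_equal(tab$nearest_temperature[tab$col == 2], 15)
  expect_equal(tab$nearest_temperature[tab$col == 3], 15)
  # single-candidate geometry
  s <- realm_grid(1, 2, 0, 0, 1 / 12)
  s <- add_layer(s, "temperature", "terrestrial", matrix(c(21, NA), 1, 2))
  s <- add_layer(s, "SST", "marine", matrix(c(NA, 9), 1, 2))
  expect_equal(marine_with_terrestrial(s)$nearest_temperature, 21)
})

test_that("nearest-terrestrial inheritance matches brute force on random grids", {
  g <- random_mask_grid(99, 11, 13)
  tab <- marine_with_terrestrial(g)
  orc <- oracle_nearest(g, "marine")
  inherited <- g$layers$tvar$values[orc[, c("nrow", "ncol")]]
  expect_equal(tab$nearest_tvar, unname(inherited))
})

test_that("augmented tables only contain focal-realm rows", {
  g <- random_mask_grid(123, 10, 10)
  cfg <- multirealm_config(mmfd_m = 30000)
  twm <- terrestrial_with_marine(g, cfg)
  expect_true(all(g$terrestrial_valid[cbind(twm$row, twm$col)]))
  expect_equal(nrow(twm), sum(g$terrestrial_valid))
  mwt <- marine_with_terrestrial(g, cfg)
  expect_true(all(g$marine_valid[cbind(mwt$row, mwt$col)]))
  expect_equal(nrow(mwt), sum(g$marine_valid))
  expect_true(all(twm[, grep("_variation$", names(twm))] >= 0, na.rm = TRUE))
})

test_that("landmass labelling, area and isolation match the flood-fill oracle", {
  # two blobs of 3 and 5 cells
  m <- matrix(FALSE, 7, 9)
  m[2, 2:4] <- TRUE                 # 3-cell blob
  m[5:6, 6:7] <- TRUE; m[6, 8] <- TRUE  # 5-cell blob
  g <- realm_grid(7, 9, 0, 50, 1 / 12, terrestrial_valid = m,
                  marine_valid = matrix(FALSE, 7, 9))
  vals <- matrix(NA_real_, 7, 9); vals[m] <- 1
  g <- add_layer(g, "t", "terrestrial", vals)
  lt <- label_landmasses(g)
  expect_equal(sort(lt$n_cells), c(3L, 5L))
  orc <- oracle_landmasses(g)
  expect_equal(sort(lt$area_km2), sort(orc$areas), tolerance = 1e-12)
  # the 3-cell blob's isolation equals the brute-force minimum distance
  small <- which.min(lt$n_cells)
  expect_equal(lt$isolation_m[small], min(orc$isolation, na.rm = TRUE),
               tolerance = 1e-9)
  # the larger blob has no larger neighbour
  expect_true(is.na(lt$isolation_m[which.max(lt$n_cells)]))
})

test_that("single landmass and exact area ties yield missing isolation", {
  m <- matrix(FALSE, 5, 5); m[2:3, 2:3] <- TRUE
  g <- realm_grid(5, 5, 0, 50, 1 / 12, terrestrial_valid = m,
                  marine_valid = matrix(FALSE, 5, 5))
  lt <- label_landmasses(g)
  expect_equal(nrow(lt), 1L)
  expect_true(is.na(lt$isolation_m))
  # equal-area blobs on the same rows: strictly-larger comparison fails both ways
  m2 <- matrix(FALSE, 5, 7); m2[2:3, 2] <- TRUE; m2[2:3, 6] <- TRUE
  g2 <- realm_grid(5, 7, 0, 50, 1 / 12, terrestrial_valid = m2,
                   marine_valid = matrix(FALSE, 5, 7))
  lt2 <- label_landmasses(g2)
  expect_equal(nrow(lt2), 2L)
  expect_true(all(is.na(lt2$isolation_m)))
})

test_that("connectivity flag separates diagonal neighbours", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  g <- realm_grid(4, 4, 0, 50, 1 / 12, terrestrial_valid = m,
                  marine_valid = matrix(FALSE, 4, 4))
  expect_equal(nrow(label_landmasses(g, connectivity = 8)), 1L)
  expect_equal(nrow(label_landmasses(g, connectivity = 4)), 2L)
})
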