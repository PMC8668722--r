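# End-to-end behaviour of the mrsdm() fitting function and its methods.
# One small world is fitted once and inspected by several tests.

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- simulate_multirealm_world(seed = 21, n_rows = 32, n_cols = 32,
                                     n_presence_target = 120, n_pseudo = 90)
      fit <- mrsdm(w$grid, w$presences, "TerrWithMar", w$config,
                   learners = c("glm", "rf"))
      cache <<- list(w = w, fit = fit)
    }
    cache
  }
})

test_that("single-realm tables carry only focal-realm covariates", {
  w <- small_world()$w
  terr_only <- augment_covariates(w$grid, "TerrOnly", w$config)
  tags <- vapply(w$grid$layers, `[[`, "", "realm")
  expect_true(all(attr(terr_only, "covariates") %in%
                    names(tags)[tags == "terrestrial"]))
  mar_only <- augment_covariates(w$grid, "MarOnly", w$config)
  expect_true(all(attr(mar_only, "covariates") %in%
                    names(tags)[tags == "marine"]))
})

test_that("cross-realm augmentation adds the documented column pairs", {
  w <- small_world()$w
  twm <- augment_covariates(w$grid, "TerrWithMar", w$config)
  mar_vars <- layer_names(w$grid, "marine")
  for (v in mar_vars) {
    expect_true(paste0("mean_", v) %in% names(twm))
    expect_true(paste0(v, "_variation") %in% names(twm))
  }
  # exactly two derived columns per marine variable
  expect_length(attr(twm, "covariates"),
                length(layer_names(w$grid, "terrestrial")) + 2 * length(mar_vars))
  mwt <- augment_covariates(w$grid, "MarWithTerr", w$config)
  for (v in layer_names(w$grid, "terrestrial"))
    expect_true(paste0("nearest_", v) %in% names(mwt))
})

test_that("the fitted object is coherent and its methods run", {
  fit <- small_world()$fit
  expect_s3_class(fit, "mrsdm")
  # record grid: repeats x learners x pa-sets
  expect_equal(nrow(fit$validation),
               fit$config$n_repeats * 2 * fit$config$n_sets)
  expect_true(all(fit$ensemble$mean >= 0 & fit$ensemble$mean <= 1))
  expect_true(all(fit$ensemble$variance >= 0))
  expect_true(all(fit$full_tss[fit$gated] > fit$config$tss_gate))
  expect_gt(fit$spearman_validation_full, 0.7)
  # retained variable pairs respect the collinearity threshold
  keep <- as.data.frame(fit$covariates)[, fit$best_set]
  keep <- keep[complete.cases(keep), ]
  cm <- abs(cor(keep))
  expect_lt(max(cm[upper.tri(cm)]), 1)
  expect_output(print(fit), "mrsdm fit")
  s <- summary(fit)
  expect_output(print(s), "Cross-validated accuracy")
  expect_equal(predict(fit), fit$ensemble$mean)
  newd <- as.data.frame(fit$covariates)[1:5, fit$best_set]
  p <- predict(fit, newd[complete.cases(newd), , drop = FALSE])
  expect_true(all(p >= 0 & p <= 1))
  imp <- fit$importance
  expect_true(all(imp$mean >= 0 & imp$mean <= 1, na.rm = TRUE))
  # the generative marine driver is among the recovered top variables
  expect_true("mean_mar1" %in% imp$variable[order(-imp$mean)][1:3])
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("marine-realm approaches run on a marine virtual species", {
  w <- small_world()$w
  mwt <- augment_covariates(w$grid, "MarWithTerr", w$config)
  sp <- virtual_species(c(mar1 = 3, nearest_terr1 = 2), intercept = -4,
                        realm = "marine")
  suit <- true_suitability(sp, mwt)
  pres <- sample_occurrences(suit, as.matrix(mwt[, c("row", "col")]), 150,
                             seed = 31)
  # nearest_distance_from_sea is constant (zero at every coast cell) and is
  # excluded from screening with a warning by design
  fit <- suppressWarnings(
    mrsdm(w$grid, pres, "MarWithTerr", w$config, learners = "glm",
          importance = FALSE))
  expect_s3_class(fit, "mrsdm")
  expect_gt(mean(fit$validation$tss), 0.3)
  expect_true(all(startsWith(setdiff(fit$best_set,
                                     layer_names(w$grid, "marine")),
                             "nearest_")))
})

test_that("approach comparison ranks by mean TSS with documented tie rules", {
  fake <- function(ap, tss, sd_ = 0.02, rho = 0.95) {
    list(approach = ap,
         validation = data.frame(tss = tss, roc_auc = tss + 0.1),
         spearman_validation_full = rho)
  }
  a <- fake("TerrWithMar", c(0.81, 0.83, 0.85))
  b <- fake("TerrOnly", c(0.74, 0.76, 0.78))
  cmp <- compare_approaches(list(TerrWithMar = a, TerrOnly = b))
  expect_equal(cmp$approach[1], "TerrWithMar")
  expect_true(cmp$best[1] && !cmp$best[2])
  # equal means: lower SD wins, then the name breaks remaining ties
  c1 <- fake("A", c(0.7, 0.8))
  c2 <- fake("B", c(0.74, 0.76))
  cmp2 <- compare_approaches(list(A = c1, B = c2))
  expect_equal(cmp2$approach[1], "B")
  # ranking is invariant to input order
  cmp3 <- compare_approaches(list(B = c2, A = c1))
  expect_equal(cmp3$approach, cmp2$approach)
})

test_that("run_all writes reproducible outputs and a usable manifest", {
  w <- simulate_multirealm_world(seed = 33, n_rows = 24, n_cols = 24,
                                 n_presence_target = 70, n_pseudo = 50)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_all(w$grid, w$presences, w$config, approaches = "TerrWithMar",
                learners = "glm", out_dir = d1)
  r2 <- run_all(w$grid, w$presences, w$config, approaches = "TerrWithMar",
                learners = "glm", out_dir = d2)
  expect_identical(unname(r1$hashes), unname(r2$hashes))
  man <- jsonlite::read_json(file.path(d1, "TerrWithMar_manifest.json"))
  expect_equal(man$approach, "TerrWithMar")
  expect_equal(man$config$seed, 33)
})
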