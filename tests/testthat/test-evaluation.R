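test_that("stratified split partitions each class at the training fraction", {
  y <- rep(c(1, 0), each = 10)
  sp <- split_data(y, 0.7, seed = 2)
  expect_equal(sum(y[sp$train] == 1), 7)
  expect_equal(sum(y[sp$train] == 0), 7)
  expect_equal(sort(c(sp$train, sp$validation)), seq_along(y))
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_identical(sp, split_data(y, 0.7, seed = 2))
  expect_false(identical(sp$train, split_data(y, 0.7, seed = 3)$train))
  expect_error(split_data(c(1, 1, 1, 0), 0.7), "at least 2 rows")
})

test_that("TSS at the optimal threshold reproduces the hand confusion matrix", {
  # TP = 9, FN = 1, TN = 8, FP = 2 at any threshold in (0.1, 0.9]
  preds <- c(rep(0.9, 9), 0.1, rep(0.1, 8), rep(0.9, 2))
  labels <- c(rep(1, 10), rep(0, 10))
  m <- tss_at_best_threshold(preds, labels)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$tss, 0.7)
  # tie rule: the smallest optimal threshold is returned
  expect_equal(m$threshold, 0.101)
  # perfect separation reaches TSS 1
  perfect <- tss_at_best_threshold(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$tss, 1)
  expect_error(tss_at_best_threshold(runif(5), rep(1, 5)), "both classes")
})

test_that("TSS identity holds across random evaluations", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    preds <- runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    m <- tss_at_best_threshold(preds, labels)
    expect_equal(m$tss, m$sensitivity + m$specificity - 1, tolerance = 1e-12)
    expect_true(m$tss >= -1 && m$tss <= 1)
  }
})

test_that("rank AUC equals exhaustive pairwise comparison, ties half-counted", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 1)), 2 / 3)
  set.seed(14)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    preds <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(preds, labels), oracle_auc(preds, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(15)
  preds <- runif(300)
  labels <- rbinom(300, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, preds, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(preds, labels), ref, tolerance = 1e-12)
})

test_that("metrics are at chance level when labels are shuffled", {
  set.seed(16)
  n <- 5000
  preds <- runif(n)
  labels <- sample(rep(0:1, n / 2))
  expect_lt(abs(tss_at_best_threshold(preds, labels)$tss), 0.05)
  auc <- roc_auc(preds, labels)
  expect_gt(auc, 0.45); expect_lt(auc, 0.55)
})

test_that("repeated validation yields the full record grid and aggregates", {
  toy <- separable_toy(n = 80, seed = 18)
  cfg <- multirealm_config(n_repeats = 5, seed = 44)
  res <- repeated_validation(toy[, c("x1", "x2")], toy$y,
                             c("glm", "rf"), cfg, pa_index = 2L)
  expect_equal(nrow(res$records), 5 * 2)
  expect_setequal(unique(res$records$learner), c("glm", "rf"))
  expect_true(all(res$records$pa_set == 2))
  # separable data: every repeat reaches high skill
  expect_true(all(res$records$tss > 0.9))
  # aggregation equals direct recomputation from the raw records
  agg <- aggregate(tss ~ learner, data = res$records, FUN = mean)
  manual <- tapply(res$records$tss, res$records$learner, mean)
  expect_equal(agg$tss, as.numeric(manual[agg$learner]))
  # TSS identity asserted on every record
  expect_equal(res$records$tss,
               res$records$sensitivity + res$records$specificity - 1,
               tolerance = 1e-12)
})

test_that("a model that ignores a variable has importance exactly zero", {
  register_learner("ignore_x2",
    fit = function(x, y, config, seed)
      list(coef = suppressWarnings(
             stats::coef(stats::glm(y ~ x1, data = cbind(y = y, x),
                                    family = stats::binomial()))),
           converged = TRUE, iterations = 1L),
    predict = function(state, x)
      stats::plogis(state$coef[1] + state$coef[2] * x$x1))
  toy <- separable_toy(n = 100, seed = 19)
  fit <- fit_sdm_learner("ignore_x2", toy[, c("x1", "x2")], toy$y)
  imp <- permutation_importance(fit, toy[, c("x1", "x2")], "x2", n_perm = 5)
  expect_identical(imp$importance, 0)
  expect_identical(imp$sd, 0)
})

test_that("a single-variable identity model has importance near one", {
  register_learner("identity_x",
    fit = function(x, y, config, seed) list(converged = TRUE, iterations = 0L),
    predict = function(state, x) x$x1)
  n <- 10000
  set.seed(20)
  rows <- data.frame(x1 = runif(n))
  fit <- fit_sdm_learner("identity_x", rows, rep(0:1, n / 2))
  imp <- permutation_importance(fit, rows, "x1", seed = 6, n_perm = 10)
  expect_gt(imp$importance, 0.9)
  expect_length(imp$values, 10)
  expect_false(is.na(imp$sd))  # dispersion over permutation seeds is reported
})

test_that("importance grows with true effect size in a GLM simulation", {
  set.seed(23)
  n <- 1500; p <- 8
  betas <- seq(0.2, 2, length.out = p)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("v", 1:p)
  y <- rbinom(n, 1, plogis(as.matrix(x) %*% betas))
  fit <- fit_sdm_learner("glm", x, y)
  imp <- importance_table(list(m = fit), x, seed = 3, n_perm = 3)
  expect_gt(cor(betas, imp$mean, method = "spearman"), 0.8)
})
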