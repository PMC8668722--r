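# Repeated internal validation and accuracy metrics.

#' Stratified train/validation split
#'
#' Splits row indices so that `train_frac` of each class (presences and
#' pseudo-absences separately) lands in the training set; the split is an
#' exact partition and reproducible from the seed.
#'
#' @param y 0/1 label vector.
#' @param train_frac Training fraction, default 0.7.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_data <- function(y, train_frac = 0.7, seed = 1L) {
  y <- as.integer(y)
  if (any(table(factor(y, levels = c(0, 1))) < 2))
    stop("each class needs at least 2 rows to split", call. = FALSE)
  set.seed(seed)
  train <- integer()
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_tr <- round(train_frac * length(idx))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(y), train))
}

#' TSS at the optimal threshold
#'
#' Scans thresholds 0, 0.001, ..., 1; at each, cells with suitability at or
#' above the threshold are predicted present, giving sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP) and the true skill statistic
#' TSS = sensitivity + specificity - 1. Returns the threshold maximising TSS
#' (ties resolved to the smallest threshold).
#'
#' @param predictions Suitabilities in `[0,1]`.
#' @param labels 0/1 labels (both classes required).
#' @return List: `threshold`, `sensitivity`, `specificity`, `tss`.
#' @export
tss_at_best_threshold <- function(predictions, labels) {
  labels <- as.integer(labels)
  pos <- predictions[labels == 1]
  neg <- predictions[labels == 0]
  if (!length(pos) || !length(neg))
    stop("both classes required to compute TSS", call. = FALSE)
  thresholds <- seq(0, 1, by = 0.001)
  sens <- vapply(thresholds, function(t) sum(pos >= t), 0) / length(pos)
  spec <- vapply(thresholds, function(t) sum(neg < t), 0) / length(neg)
  tss <- sens + spec - 1
  i <- which.max(tss)  # first maximum = smallest threshold
  list(threshold = thresholds[i], sensitivity = sens[i],
       specificity = spec[i], tss = tss[i])
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen presence is scored above a randomly
#' chosen absence, ties counting one half (rank / Mann-Whitney formulation;
#' identical to the trapezoidal area under the ROC curve).
#'
#' @param predictions Numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(predictions, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes required to compute AUC", call. = FALSE)
  r <- rank(predictions)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Repeated 70/30 validation of the base learners
#'
#' For each repeat the labelled rows are split (stratified by class), each
#' learner is calibrated on the training split and evaluated on the held-out
#' split with threshold-optimised TSS, sensitivity, specificity and ROC AUC.
#' Repeats differ only by the derived split seed.
#'
#' @param x Data frame of covariates (complete rows).
#' @param y 0/1 labels.
#' @param learners Character vector of registered learner names.
#' @param config A [multirealm_config()] (`train_frac`, `n_repeats`, seed).
#' @param pa_index Index of the pseudo-absence set these rows came from
#'   (recorded in every row and mixed into the derived seeds).
#' @return List of class `validation_result`: `records` (one row per learner x
#'   repeat: metrics plus threshold and convergence flag) and `models` (the
#'   fitted validation models, named `learner.repeat`).
#' @export
repeated_validation <- function(x, y, learners, config = multirealm_config(),
                                pa_index = 1L) {
  records <- list(); models <- list()
  for (rep_i in seq_len(config$n_repeats)) {
    sp <- split_data(y, config$train_frac,
                     derive_seed(config$seed, "split", pa_index * 10L + rep_i))
    for (ln in learners) {
      rec <- data.frame(learner = ln, pa_set = pa_index, rep = rep_i,
                        threshold = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, tss = NA_real_,
                        roc_auc = NA_real_, converged = NA, error = NA_character_)
      fit <- tryCatch(
        fit_sdm_learner(ln, x[sp$train, , drop = FALSE], y[sp$train], config,
                        seed = derive_seed(config$seed, "fit",
                                           pa_index * 10L + rep_i)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        rec$error <- conditionMessage(fit)
      } else {
        p <- predict(fit, x[sp$validation, , drop = FALSE])
        m <- tss_at_best_threshold(p, y[sp$validation])
        rec$threshold <- m$threshold; rec$sensitivity <- m$sensitivity
        rec$specificity <- m$specificity; rec$tss <- m$tss
        rec$roc_auc <- roc_auc(p, y[sp$validation])
        rec$converged <- fit$converged
        models[[paste(ln, rep_i, sep = ".")]] <- fit
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  structure(list(records = do.call(rbind, records), models = models),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  agg <- stats::aggregate(cbind(tss, roc_auc) ~ learner, data = x$records, FUN = mean)
  cat(sprintf("validation_result: %d records (%d models)\n",
              nrow(x$records), length(x$models)))
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Permutation importance of one covariate
#'
#' The covariate's column is shuffled (seeded), the fitted model re-predicts,
#' and Pearson's r is computed between the reference and the permuted
#' predictions. Importance is `1 - r`, clipped to `[0,1]`: 0 means the
#' variable has almost no impact on the model, 1 that shuffling it destroys
#' the prediction. Repeated over `n_perm` shuffles; mean and SD are reported.
#'
#' @param model A `fitted_sdm`.
#' @param rows Data frame containing the model's variable set.
#' @param variable Covariate name to permute.
#' @param seed Integer seed for the shuffles.
#' @param n_perm Number of permutations, default 10.
#' @return List: `importance` (mean), `sd`, `values`. If the reference
#'   predictions are constant, importance is undefined and returned as `NA`.
#' @export
permutation_importance <- function(model, rows, variable, seed = 1L,
                                   n_perm = 10L) {
  if (!variable %in% model$variables)
    stop(sprintf("'%s' is not in the model's variable set", variable), call. = FALSE)
  ref <- predict(model, rows)
  if (stats::sd(ref) == 0)
    return(list(importance = NA_real_, sd = NA_real_, values = rep(NA_real_, n_perm)))
  vals <- vapply(seq_len(n_perm), function(i) {
    set.seed(derive_seed(seed, "permute", i))
    perm <- rows
    perm[[variable]] <- perm[[variable]][sample.int(nrow(perm))]
    p <- predict(model, perm)
    if (identical(p, ref)) return(0)  # variable ignored by the model
    r <- stats::cor(ref, p)
    if (is.na(r)) r <- 0  # permuted predictions constant: no agreement signal
    min(max(1 - r, 0), 1)
  }, 0)
  list(importance = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Permutation importance table across models
#'
#' @param models List of `fitted_sdm` objects.
#' @param rows Data frame of covariate rows to predict on.
#' @param variables Covariates to assess (default: union of the models' sets).
#' @param seed,n_perm Passed to [permutation_importance()].
#' @return Data frame: `variable`, per-model mean importance columns, and
#'   `mean` / `sd` across models.
#' @export
importance_table <- function(models, rows, variables = NULL, seed = 1L,
                             n_perm = 10L) {
  if (is.null(variables))
    variables <- unique(unlist(lapply(models, `[[`, "variables")))
  per_model <- vapply(models, function(m) {
    vapply(variables, function(v) {
      if (!v %in% m$variables) return(NA_real_)
      permutation_importance(m, rows, v, seed = seed, n_perm = n_perm)$importance
    }, 0)
  }, numeric(length(variables)))
  per_model <- matrix(per_model, nrow = length(variables),
                      dimnames = list(variables, names(models)))
  data.frame(variable = variables,
             per_model,
             mean = apply(per_model, 1, mean, na.rm = TRUE),
             sd = apply(per_model, 1, stats::sd, na.rm = TRUE),
             row.names = NULL, check.names = FALSE)
}
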