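#' Fit a multi-realm species distribution model
#'
#' Runs the full single-approach pipeline: builds the approach's covariate
#' table (cross-realm augmentation where applicable), restricts the background
#' (coastal band on land, foraging range at sea), draws replicate
#' pseudo-absence sets, screens collinearity and enumerates candidate variable
#' sets, runs repeated 70/30 validation of every learner on every candidate
#' set and pseudo-absence set, selects the variable set with the highest mean
#' cross-validated TSS, fits full-data models, gates them on cross-validated
#' TSS, projects a TSS-weighted ensemble with across-model variance, checks
#' Spearman agreement between the validation-data and full-data ensembles,
#' and (optionally) computes permutation variable importance.
#'
#' @param grid A [realm_grid()] with layers for both realms; the distance
#'   layers are derived automatically if absent.
#' @param presences n x 2 matrix (row, col) of presence cells in the
#'   approach's focal realm, or a data frame with `row`/`col` columns.
#' @param approach One of `"TerrOnly"`, `"MarOnly"`, `"TerrWithMar"`,
#'   `"MarWithTerr"`.
#' @param config A [multirealm_config()].
#' @param learners Registered learner names, default `c("glm", "rf", "ann")`.
#' @param importance Compute the permutation importance table? Default `TRUE`.
#' @return An object of class `mrsdm`; see [summary.mrsdm()],
#'   [predict.mrsdm()], [plot.mrsdm()].
#' @examples
#' \donttest{
#' world <- simulate_multirealm_world(seed = 7, n_rows = 40, n_cols = 40,
#'                                    n_presence_target = 150, n_pseudo = 120)
#' fit <- mrsdm(world$grid, world$presences, "TerrWithMar", world$config,
#'              learners = c("glm", "rf"))
#' summary(fit)
#' }
#' @export
mrsdm <- function(grid, presences, approach, config = multirealm_config(),
                  learners = c("glm", "rf", "ann"), importance = TRUE) {
  cl <- match.call()
  approach <- match.arg(approach,
                        c("TerrOnly", "MarOnly", "TerrWithMar", "MarWithTerr"))
  if (!all(c("distance_from_land", "distance_from_sea") %in% layer_names(grid)))
    grid <- distance_variables(grid)
  presences <- as.matrix(as.data.frame(presences)[, c("row", "col")])

  covs <- augment_covariates(grid, approach, config)
  cov_names <- attr(covs, "covariates")
  key <- cell_key(as.matrix(covs[, c("row", "col")]))
  in_realm <- cell_key(presences) %in% key
  if (!all(in_realm)) {
    warning(sprintf("%d presence(s) outside the focal realm dropped",
                    sum(!in_realm)))
    presences <- presences[in_realm, , drop = FALSE]
  }
  if (nrow(presences) < 4)
    stop("too few presences in the focal realm", call. = FALSE)

  background <- background_cells(grid, approach, config)
  occ <- draw_pseudo_absences(background, presences, config$n_pseudo,
                              config$n_sets, config$seed)

  screen <- pearson_screen(covs, config$collinearity_threshold)
  var_sets <- variable_set_permutations(cov_names, screen)

  labelled <- function(pa_cells) {
    cells <- rbind(presences, pa_cells)
    i <- match(cell_key(cells), key)
    x <- as.data.frame(covs)[i, cov_names, drop = FALSE]
    y <- rep(c(1L, 0L), c(nrow(presences), nrow(pa_cells)))
    ok <- stats::complete.cases(x)
    list(x = x[ok, , drop = FALSE], y = y[ok], dropped = sum(!ok))
  }
  datasets <- lapply(occ$pa_sets, labelled)

  # candidate-set selection: mean cross-validated TSS over learners, repeats
  # and pseudo-absence sets ("whichever member of a covarying pair produces
  # the stronger model overall")
  set_runs <- lapply(seq_along(var_sets), function(si) {
    vs <- var_sets[[si]]
    runs <- lapply(seq_along(datasets), function(pi) {
      d <- datasets[[pi]]
      repeated_validation(d$x[, vs, drop = FALSE], d$y, learners, config,
                          pa_index = pi)
    })
    records <- do.call(rbind, lapply(runs, `[[`, "records"))
    records$set <- si
    list(records = records, runs = runs,
         mean_tss = mean(records$tss, na.rm = TRUE))
  })
  mean_tss_by_set <- vapply(set_runs, `[[`, 0, "mean_tss")
  best <- which.max(mean_tss_by_set)
  best_set <- var_sets[[best]]
  validation <- set_runs[[best]]$records
  val_models <- do.call(c, lapply(set_runs[[best]]$runs, `[[`, "models"))
  names(val_models) <- unlist(lapply(seq_along(set_runs[[best]]$runs),
    function(pi) paste0("pa", pi, ".",
                        names(set_runs[[best]]$runs[[pi]]$models))))

  # full-data models (one per learner x pseudo-absence set), gated on the
  # cross-validated mean TSS of the matching learner/pa-set
  cv_tss <- stats::aggregate(tss ~ learner + pa_set, data = validation,
                             FUN = mean, na.rm = TRUE)
  full_models <- list(); full_tss <- numeric()
  for (pi in seq_along(datasets)) {
    d <- datasets[[pi]]
    for (ln in learners) {
      nm <- paste0(ln, ".pa", pi)
      fit <- tryCatch(
        fit_sdm_learner(ln, d$x[, best_set, drop = FALSE], d$y, config,
                        seed = derive_seed(config$seed, "full_fit", pi)),
        error = function(e) NULL)
      if (is.null(fit)) next
      full_models[[nm]] <- fit
      full_tss[nm] <- cv_tss$tss[cv_tss$learner == ln & cv_tss$pa_set == pi]
    }
  }
  # a fit whose models all fall below the gate keeps its validation table
  # (the accuracy report simply has no ensemble row) rather than failing
  gated <- tryCatch(gate_models(full_tss, config$tss_gate),
                    error = function(e) {
                      warning(conditionMessage(e), "; ensemble not built",
                              call. = FALSE)
                      character()
                    })

  # ensemble projection over every focal-realm cell with complete covariates
  proj_ok <- stats::complete.cases(
    as.data.frame(covs)[, best_set, drop = FALSE])
  proj_rows <- as.data.frame(covs)[proj_ok, best_set, drop = FALSE]
  proj_cells <- as.matrix(covs[proj_ok, c("row", "col")])
  ensemble <- NULL; rho <- NA_real_
  if (length(gated)) {
    member_maps <- vapply(full_models[gated], predict, numeric(nrow(proj_rows)),
                          newdata = proj_rows)
    rng <- apply(member_maps, 2, range)
    scaled <- rescale_predictions(member_maps)
    ens <- weighted_ensemble(scaled, full_tss[gated])
    ensemble <- list(cells = proj_cells, mean = ens$mean,
                     variance = ens$variance, weights = full_tss[gated],
                     member_range = rng)

    # validation-data ensemble (models calibrated on 70% splits), gated and
    # weighted by their own validation TSS
    vrec <- validation[!is.na(validation$tss), ]
    vkeys <- paste0("pa", vrec$pa_set, ".", vrec$learner, ".", vrec$rep)
    vtss <- stats::setNames(vrec$tss, vkeys)
    vgate <- tryCatch(gate_models(vtss, config$tss_gate),
                      error = function(e) NULL)
    if (!is.null(vgate)) {
      vmaps <- vapply(val_models[vgate], predict, numeric(nrow(proj_rows)),
                      newdata = proj_rows)
      keep <- apply(vmaps, 2, function(m) diff(range(m)) > 0)
      if (any(keep)) {
        vens <- weighted_ensemble(rescale_predictions(vmaps[, keep, drop = FALSE]),
                                  vtss[vgate][keep])
        rho <- validation_full_agreement(vens$mean, ens$mean)
      }
    }
  }

  imp <- NULL
  if (importance && length(gated))
    imp <- importance_table(full_models[gated], proj_rows,
                            variables = best_set,
                            seed = derive_seed(config$seed, "importance"))

  manifest <- list(package_version = as.character(utils::packageVersion("mrsdm")),
                   approach = approach, learners = learners,
                   config = unclass(config),
                   n_presences = nrow(presences),
                   n_background = nrow(background),
                   n_projected_cells = nrow(proj_rows),
                   n_candidate_sets = length(var_sets))
  structure(list(call = cl, approach = approach, config = config,
                 learners = learners, covariates = covs, occurrences = occ,
                 screen = screen, variable_sets = var_sets,
                 set_mean_tss = mean_tss_by_set, best_set = best_set,
                 validation = validation, validation_models = val_models,
                 full_models = full_models, full_tss = full_tss, gated = gated,
                 ensemble = ensemble,
                 spearman_validation_full = rho, importance = imp,
                 manifest = manifest),
            class = "mrsdm")
}

#' @export
print.mrsdm <- function(x, ...) {
  cat(sprintf("mrsdm fit — approach %s\n", x$approach))
  cat(sprintf("  %d presences, %d pseudo-absence set(s) of %d; %d candidate variable set(s)\n",
              nrow(x$occurrences$presences), length(x$occurrences$pa_sets),
              x$config$n_pseudo, length(x$variable_sets)))
  cat(sprintf("  best set (%d covariates): %s\n", length(x$best_set),
              paste(x$best_set, collapse = ", ")))
  cat(sprintf("  mean cross-validated TSS %.3f; ensemble of %d/%d models; Spearman validation-vs-full %.3f\n",
              mean(x$validation$tss, na.rm = TRUE), length(x$gated),
              length(x$full_models), x$spearman_validation_full))
  invisible(x)
}

#' Summarise a multi-realm SDM fit
#'
#' Mean and SD of the cross-validated TSS and ROC AUC per learner (the shape
#' of a standard SDM accuracy table), the ensemble roster with weights, and
#' the validation-vs-full agreement.
#'
#' @param object An `mrsdm` object.
#' @param ... Unused.
#' @return A list of class `summary.mrsdm`.
#' @export
summary.mrsdm <- function(object, ...) {
  rec <- object$validation
  agg <- do.call(rbind, lapply(split(rec, rec$learner), function(d)
    data.frame(learner = d$learner[1],
               tss_mean = mean(d$tss, na.rm = TRUE),
               tss_sd = stats::sd(d$tss, na.rm = TRUE),
               roc_mean = mean(d$roc_auc, na.rm = TRUE),
               roc_sd = stats::sd(d$roc_auc, na.rm = TRUE))))
  rownames(agg) <- NULL
  structure(list(approach = object$approach, by_learner = agg,
                 overall_tss = mean(rec$tss, na.rm = TRUE),
                 overall_roc = mean(rec$roc_auc, na.rm = TRUE),
                 gated = object$gated, weights = object$ensemble$weights,
                 spearman = object$spearman_validation_full,
                 importance = object$importance),
            class = "summary.mrsdm")
}

#' @export
print.summary.mrsdm <- function(x, ...) {
  cat(sprintf("Approach %s: mean TSS %.3f, mean ROC %.3f, Spearman rho %.3f\n",
              x$approach, x$overall_tss, x$overall_roc, x$spearman))
  cat("Cross-validated accuracy by learner (mean (SD)):\n")
  with(x$by_learner, for (i in seq_along(learner))
    cat(sprintf("  %-4s TSS %.3f (%.3f)  ROC %.3f (%.3f)\n", learner[i],
                tss_mean[i], tss_sd[i], roc_mean[i], roc_sd[i])))
  cat(sprintf("Ensemble members (TSS weights): %s\n",
              paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                    collapse = ", ")))
  if (!is.null(x$importance)) {
    top <- x$importance[order(-x$importance$mean), c("variable", "mean", "sd")]
    cat("Top variable importances (1 - Pearson r, mean +/- SD across models):\n")
    for (i in seq_len(min(5, nrow(top))))
      cat(sprintf("  %-20s %.3f +/- %.3f\n", top$variable[i], top$mean[i],
                  top$sd[i]))
  }
  invisible(x)
}

#' Predict ensemble suitability
#'
#' @param object An `mrsdm` object.
#' @param newdata Optional data frame containing the fit's selected covariates;
#'   if omitted, the fitted ensemble map over the projected cells is returned.
#'   New predictions are rescaled with each member's training projection range
#'   so they are comparable to the fitted map.
#' @param ... Unused.
#' @return Numeric vector of ensemble mean suitabilities in `[0,1]`.
#' @export
predict.mrsdm <- function(object, newdata = NULL, ...) {
  if (is.null(object$ensemble))
    stop("no ensemble available: every model fell below the TSS gate",
         call. = FALSE)
  if (is.null(newdata)) return(object$ensemble$mean)
  maps <- vapply(object$full_models[object$gated], predict,
                 numeric(nrow(newdata)), newdata = newdata)
  maps <- matrix(maps, nrow = nrow(newdata))
  rng <- object$ensemble$member_range
  for (j in seq_len(ncol(maps)))
    maps[, j] <- pmin(pmax((maps[, j] - rng[1, j]) / (rng[2, j] - rng[1, j]), 0), 1)
  as.numeric(maps %*% object$ensemble$weights) / sum(object$ensemble$weights)
}

#' Map an mrsdm ensemble
#'
#' Draws the ensemble mean suitability and (optionally) the across-model
#' variance as gridded images, with presences overlaid.
#'
#' @param x An `mrsdm` object.
#' @param which `"mean"`, `"variance"`, or both (default).
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.mrsdm <- function(x, which = c("mean", "variance"), ...) {
  if (is.null(x$ensemble))
    stop("no ensemble available: every model fell below the TSS gate",
         call. = FALSE)
  which <- match.arg(which, several.ok = TRUE)
  cells <- x$ensemble$cells
  nr <- max(cells[, 1]); nc <- max(cells[, 2])
  op <- graphics::par(mfrow = c(1, length(which)), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  for (w in which) {
    z <- matrix(NA_real_, nr, nc)
    z[cells] <- x$ensemble[[if (w == "mean") "mean" else "variance"]]
    graphics::image(seq_len(nc), seq_len(nr), t(z[nr:1, , drop = FALSE]),
                    main = paste("ensemble", w), xlab = "", ylab = "",
                    col = grDevices::hcl.colors(64, "viridis"), ...)
    pr <- x$occurrences$presences
    graphics::points(pr[, 2], nr - pr[, 1] + 1, pch = ".", cex = 2, col = "red")
  }
  invisible(x)
}

#' Rank fitted approaches by cross-validated accuracy
#'
#' @param ... Named `mrsdm` objects (or a single list of them). Names default
#'   to each fit's approach.
#' @return Data frame ranked by mean validation TSS (ties: lower SD, then
#'   name), with the best approach flagged.
#' @export
compare_approaches <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "mrsdm")) fits <- fits[[1]]
  if (length(fits) < 2) stop("need at least two approaches", call. = FALSE)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- vapply(fits, function(f)
      if (inherits(f, "mrsdm")) f$approach else "unnamed", "")
  rows <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tss <- f$validation$tss; roc <- f$validation$roc_auc
    data.frame(approach = nm, tss_mean = mean(tss, na.rm = TRUE),
               tss_sd = stats::sd(tss, na.rm = TRUE),
               roc_mean = mean(roc, na.rm = TRUE),
               roc_sd = stats::sd(roc, na.rm = TRUE),
               spearman = f$spearman_validation_full)
  }))
  o <- order(-rows$tss_mean, rows$tss_sd, rows$approach)
  rows <- rows[o, , drop = FALSE]
  rows$best <- seq_len(nrow(rows)) == 1
  rownames(rows) <- NULL
  rows
}

#' Write a run manifest as JSON
#'
#' The manifest snapshots the configuration, seeds and problem sizes of a fit,
#' sufficient to re-run it bit-identically.
#'
#' @param fit An `mrsdm` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fit, path) {
  jsonlite::write_json(fit$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
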