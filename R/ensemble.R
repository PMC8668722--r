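# TSS-gated, TSS-weighted ensemble projection with across-model variance.

#' Gate models on their cross-validated TSS
#'
#' Only models with substantial skill enter the ensemble: TSS strictly above
#' the gate (default 0.6). Gating uses the cross-validated mean TSS of the
#' corresponding learner rather than a full-data training TSS, which would be
#' circular.
#'
#' @param tss Named numeric vector of cross-validated TSS values, one per
#'   candidate model.
#' @param tss_gate Gate, default 0.6 (strict inequality).
#' @return The names of the retained models.
#' @export
gate_models <- function(tss, tss_gate = 0.6) {
  keep <- names(tss)[tss > tss_gate]
  if (!length(keep))
    stop(sprintf("no model passed the TSS gate %.2f (TSS: %s)", tss_gate,
                 paste(sprintf("%s=%.3f", names(tss), tss), collapse = ", ")),
         call. = FALSE)
  keep
}

#' Min-max rescale member predictions to a common scale
#'
#' Each member map is affinely rescaled to span `[0,1]` over the projected
#' cells, putting all members on the same numerical scale before weighting;
#' cell rank order is preserved exactly.
#'
#' @param maps Numeric matrix, one column per member model, one row per cell.
#' @return Matrix of the same shape with each column spanning `[0,1]`.
#' @export
rescale_predictions <- function(maps) {
  maps <- as.matrix(maps)
  rng <- apply(maps, 2, range)
  if (any(rng[1, ] == rng[2, ]))
    stop("constant member map cannot be rescaled", call. = FALSE)
  sweep(sweep(maps, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
}

#' TSS-weighted ensemble of member maps
#'
#' Per cell, the ensemble suitability is the weighted mean of the member
#' values, weighted by each model's accuracy (TSS); the uncertainty map is the
#' unweighted across-model variance (sample variance; 0 with one member).
#'
#' @param maps Numeric matrix, one column per member, one row per cell.
#' @param weights Positive weights (TSS of each member), length `ncol(maps)`.
#' @return List of class `ensemble_result`: `mean`, `variance`, `weights`,
#'   `members`.
#' @export
weighted_ensemble <- function(maps, weights) {
  maps <- as.matrix(maps)
  if (length(weights) != ncol(maps))
    stop("one weight per member map required", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  m <- as.numeric(maps %*% weights) / sum(weights)
  v <- if (ncol(maps) > 1) apply(maps, 1, stats::var) else rep(0, nrow(maps))
  structure(list(mean = m, variance = v, weights = weights,
                 members = colnames(maps)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %d cells, %d member model(s)\n",
              length(x$mean), length(x$weights)))
  if (!is.null(x$members))
    cat(sprintf("  members: %s\n",
                paste(sprintf("%s (w=%.3f)", x$members, x$weights), collapse = ", ")))
  cat(sprintf("  mean suitability %.3f (range %.3f-%.3f), mean variance %.4f\n",
              mean(x$mean), min(x$mean), max(x$mean), mean(x$variance)))
  invisible(x)
}

#' Agreement between validation-data and full-data ensembles
#'
#' Spearman rank correlation between two ensemble maps over identical cells.
#' High agreement indicates that accuracy measured on the internally validated
#' models carries over to the full-data ensemble.
#'
#' @param map_validation,map_full Numeric vectors over the same cells.
#' @return Spearman's rho.
#' @export
validation_full_agreement <- function(map_validation, map_full) {
  if (length(map_validation) != length(map_full) || length(map_full) < 3)
    stop("need two maps over the same >= 3 cells", call. = FALSE)
  stats::cor(map_validation, map_full, method = "spearman")
}
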