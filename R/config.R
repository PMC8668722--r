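#' Configuration for a multi-realm SDM run
#'
#' Collects the species- and study-level parameters. Defaults follow common
#' seabird SDM practice: pseudo-absence sets of 10,000 points, a 20-km coastal
#' band for the terrestrial background, a Pearson r = 0.7 collinearity
#' threshold, 70/30 training splits repeated five times, and a TSS > 0.6
#' ensemble gate.
#'
#' @param mmfd_m Mean maximum foraging distance (MMFD) in metres — the radius
#'   of the marine buffer around each terrestrial cell's nearest coast cell and
#'   the basis of the marine background limit. Species-specific; e.g. 40 km for
#'   Atlantic puffin, 200 km for northern gannet, 16.6 km for roseate tern.
#' @param coastal_band_m Width of the coastal band restricting the terrestrial
#'   background, metres. Default 20,000.
#' @param exclusion_factor The MMFD is treated as a 90th-percentile foraging
#'   distance; marine background beyond `mmfd_m * exclusion_factor` (a nominal
#'   100th-percentile distance) is excluded. Default 10/9 (linear percentile
#'   scaling); set to 1 for a plain MMFD cutoff.
#' @param n_pseudo Pseudo-absences per set. Default 10,000.
#' @param n_sets Number of replicate pseudo-absence sets. Default 5.
#' @param collinearity_threshold Absolute Pearson correlation above which two
#'   covariates are treated as covarying. Default 0.7.
#' @param train_frac Fraction of presences and pseudo-absences placed in the
#'   training split. Default 0.7.
#' @param n_repeats Number of repeated train/validation splits. Default 5.
#' @param tss_gate Minimum cross-validated TSS (strict) for a model to enter
#'   the ensemble. Default 0.6.
#' @param max_iter Iteration cap for iterative learners; on non-convergence it
#'   is escalated once to `max_iter_escalated`. Defaults 100 and 1000.
#' @param max_iter_escalated See `max_iter`.
#' @param seed Integer master seed; every stage seed is derived from it.
#' @return A list of class `multirealm_config`.
#' @export
multirealm_config <- function(mmfd_m = 40000, coastal_band_m = 20000,
                              exclusion_factor = 10 / 9,
                              n_pseudo = 10000, n_sets = 5,
                              collinearity_threshold = 0.7,
                              train_frac = 0.7, n_repeats = 5,
                              tss_gate = 0.6,
                              max_iter = 100, max_iter_escalated = 1000,
                              seed = 1L) {
  cfg <- list(mmfd_m = mmfd_m, coastal_band_m = coastal_band_m,
              exclusion_factor = exclusion_factor,
              n_pseudo = as.integer(n_pseudo), n_sets = as.integer(n_sets),
              collinearity_threshold = collinearity_threshold,
              train_frac = train_frac, n_repeats = as.integer(n_repeats),
              tss_gate = tss_gate, max_iter = as.integer(max_iter),
              max_iter_escalated = as.integer(max_iter_escalated),
              seed = as.integer(seed))
  stopifnot_scalar_number(cfg$mmfd_m, "mmfd_m", positive = TRUE)
  stopifnot_scalar_number(cfg$coastal_band_m, "coastal_band_m", positive = TRUE)
  if (cfg$exclusion_factor < 1) stop("'exclusion_factor' must be >= 1", call. = FALSE)
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stop("'train_frac' must be in (0, 1)", call. = FALSE)
  if (cfg$tss_gate < 0 || cfg$tss_gate > 1)
    stop("'tss_gate' must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "multirealm_config")
}

#' @export
print.multirealm_config <- function(x, ...) {
  cat("multirealm_config:\n")
  cat(sprintf("  MMFD %.1f km (x %.3f exclusion), coastal band %.1f km\n",
              x$mmfd_m / 1000, x$exclusion_factor, x$coastal_band_m / 1000))
  cat(sprintf("  %d pseudo-absences x %d sets; %d%%/%d%% split x %d repeats\n",
              x$n_pseudo, x$n_sets, round(100 * x$train_frac),
              round(100 * (1 - x$train_frac)), x$n_repeats))
  cat(sprintf("  collinearity |r| > %.2f; ensemble gate TSS > %.2f; seed %d\n",
              x$collinearity_threshold, x$tss_gate, x$seed))
  invisible(x)
}

#' Read a run configuration from a YAML sidecar
#'
#' Recognised keys are the arguments of [multirealm_config()]; unknown keys
#' are an error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [multirealm_config()].
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(multirealm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(multirealm_config, vals)
}
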