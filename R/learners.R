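# Pluggable base-learner layer. Every learner is registered by name with a
# fit and a predict function behind one interface; fitted models predict
# habitat suitability in [0, 1] and are bit-reproducible from (data, seed).
#
# Shipped defaults mirror common SDM practice:
#   glm — logistic regression with linear + quadratic terms, no interactions
#   rf  — random forest, 500 trees
#   ann — single-hidden-layer neural network, size ceiling(sqrt(p)),
#         standardised inputs, mild weight decay
#   gam — penalised thin-plate splines (mgcv), logit link
# Iterative learners try max_iter iterations (default 100) and escalate once
# to max_iter_escalated (default 1000) if they have not converged.

.learner_registry <- new.env(parent = emptyenv())

#' Register a learner
#'
#' @param name Learner name (lower case by convention).
#' @param fit `function(x, y, config, seed)` returning an opaque state list
#'   with at least `converged` (logical) and `iterations` (integer).
#' @param predict `function(state, x)` returning suitabilities in `[0,1]`.
#' @return `name`, invisibly.
#' @export
register_learner <- function(name, fit, predict) {
  assign(name, list(fit = fit, predict = predict), envir = .learner_registry)
  invisible(name)
}

#' Names of the registered learners
#' @return Character vector.
#' @export
list_learners <- function() sort(ls(.learner_registry))

#' Fit one base learner
#'
#' @param name A registered learner name (see [list_learners()]).
#' @param x Data frame of covariates (complete, finite).
#' @param y 0/1 vector: 1 = presence, 0 = pseudo-absence. Both classes must
#'   be present.
#' @param config A [multirealm_config()] (iteration caps).
#' @param seed Integer seed; fitting is deterministic given (x, y, seed).
#' @return A `fitted_sdm` object.
#' @export
fit_sdm_learner <- function(name, x, y, config = multirealm_config(), seed = 1L) {
  entry <- get0(name, envir = .learner_registry)
  if (is.null(entry))
    stop(sprintf("unknown learner '%s' (registered: %s)", name,
                 paste(list_learners(), collapse = ", ")), call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  if (!all(vapply(x, function(v) all(is.finite(v)), TRUE)))
    stop("non-finite covariate values in training rows", call. = FALSE)
  set.seed(derive_seed(seed, paste0("fit_", name)))
  state <- entry$fit(x, y, config, seed)
  structure(list(learner = name, variables = names(x), state = state,
                 converged = isTRUE(state$converged),
                 iterations = state$iterations, seed = seed),
            class = "fitted_sdm")
}

#' Predict habitat suitability
#'
#' @param object A `fitted_sdm`.
#' @param newdata Data frame containing the model's variable set.
#' @param ... Unused.
#' @return Numeric vector of suitabilities, clipped to `[0,1]`.
#' @export
predict.fitted_sdm <- function(object, newdata, ...) {
  missing <- setdiff(object$variables, names(newdata))
  if (length(missing))
    stop(sprintf("newdata lacks variable(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  entry <- get(object$learner, envir = .learner_registry)
  p <- entry$predict(object$state, newdata[, object$variables, drop = FALSE])
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("fitted_sdm: %s on %d covariates (%sconverged, %s iterations, seed %d)\n",
              x$learner, length(x$variables), if (x$converged) "" else "NOT ",
              x$iterations %||% "?", x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quadratic_formula <- function(vars, response = "..y") {
  rhs <- paste(c(vars, sprintf("I(%s^2)", vars)), collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

fit_glm_learner <- function(x, y, config, seed) {
  dat <- cbind(..y = y, x)
  fml <- quadratic_formula(names(x))
  fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial(),
                                     control = stats::glm.control(maxit = config$max_iter)))
  iters <- config$max_iter
  if (!fit$converged) {
    fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial(),
                                       control = stats::glm.control(maxit = config$max_iter_escalated)))
    iters <- config$max_iter_escalated
  }
  list(fit = fit, converged = fit$converged, iterations = iters)
}

predict_glm_learner <- function(state, x) {
  suppressWarnings(stats::predict(state$fit, newdata = x, type = "response"))
}

fit_rf_learner <- function(x, y, config, seed) {
  fit <- randomForest::randomForest(x, factor(y, levels = c(0, 1)), ntree = 500)
  list(fit = fit, converged = TRUE, iterations = NA_integer_)
}

predict_rf_learner <- function(state, x) {
  stats::predict(state$fit, newdata = x, type = "prob")[, "1"]
}

fit_ann_learner <- function(x, y, config, seed) {
  center <- vapply(x, mean, 0); scale <- vapply(x, stats::sd, 0)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(as.matrix(x), 2, center), 2, scale, "/")
  size <- ceiling(sqrt(ncol(x)))
  run <- function(maxit) nnet::nnet(xs, y, size = size, decay = 0.01,
                                    entropy = TRUE, maxit = maxit, trace = FALSE)
  fit <- run(config$max_iter)
  iters <- config$max_iter
  if (fit$convergence != 0) {  # iteration cap hit: escalate once
    fit <- run(config$max_iter_escalated)
    iters <- config$max_iter_escalated
  }
  list(fit = fit, center = center, scale = scale,
       converged = fit$convergence == 0, iterations = iters)
}

predict_ann_learner <- function(state, x) {
  xs <- sweep(sweep(as.matrix(x), 2, state$center), 2, state$scale, "/")
  as.numeric(stats::predict(state$fit, xs))
}

fit_gam_learner <- function(x, y, config, seed) {
  # spline basis dimension limited by the number of distinct values
  k <- vapply(x, function(v) max(3, min(10, length(unique(v)) - 1)), 0)
  rhs <- paste(sprintf("s(%s, k = %d)", names(x), k), collapse = " + ")
  fml <- stats::as.formula(paste("..y ~", rhs))
  dat <- cbind(..y = y, x)
  fit <- mgcv::gam(fml, data = dat, family = stats::binomial(), method = "REML",
                   control = mgcv::gam.control(maxit = config$max_iter))
  list(fit = fit, converged = fit$converged %||% TRUE,
       iterations = config$max_iter)
}

predict_gam_learner <- function(state, x) {
  as.numeric(mgcv::predict.gam(state$fit, newdata = x, type = "response"))
}

register_default_learners <- function() {
  register_learner("glm", fit_glm_learner, predict_glm_learner)
  register_learner("rf", fit_rf_learner, predict_rf_learner)
  register_learner("ann", fit_ann_learner, predict_ann_learner)
  register_learner("gam", fit_gam_learner, predict_gam_learner)
}

.onLoad <- function(libname, pkgname) register_default_learners()
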