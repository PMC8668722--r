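# Collinearity screening and variable-set permutations.

#' Flag highly covarying covariate pairs
#'
#' Pearson correlation on complete cases; any unordered pair with |r| above
#' the threshold is flagged. Constant columns have no defined correlation and
#' are excluded with a warning.
#'
#' @param tab Data frame of covariates (an `augmented_covariates` table is
#'   reduced to its covariate columns automatically).
#' @param threshold Absolute correlation cutoff, default 0.7.
#' @return Data frame with columns `var1`, `var2`, `r` (possibly zero rows).
#' @export
pearson_screen <- function(tab, threshold = 0.7) {
  if (inherits(tab, "augmented_covariates"))
    tab <- as.data.frame(tab)[, attr(tab, "covariates"), drop = FALSE]
  tab <- tab[, vapply(tab, is.numeric, TRUE), drop = FALSE]
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (ncol(tab) < 2 || nrow(tab) < 3)
    stop("need at least 2 numeric covariates and 3 complete rows", call. = FALSE)
  const <- vapply(tab, function(x) stats::sd(x) == 0, TRUE)
  if (any(const)) {
    warning(sprintf("constant column(s) excluded from screening: %s",
                    paste(names(tab)[const], collapse = ", ")))
    tab <- tab[, !const, drop = FALSE]
  }
  if (ncol(tab) < 2)
    return(data.frame(var1 = character(), var2 = character(), r = numeric()))
  r <- stats::cor(tab)
  idx <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  out <- data.frame(var1 = colnames(r)[idx[, 1]], var2 = colnames(r)[idx[, 2]],
                    r = r[idx])
  out[order(out$var1, out$var2), , drop = FALSE]
}

#' Enumerate candidate variable sets from covarying pairs
#'
#' For each covarying pair one member must be dropped; with k disjoint pairs
#' this yields 2^k candidate sets (two extra model permutations for one pair,
#' four for two). Pairs sharing a variable are resolved jointly: within each
#' connected group of pairs, the candidate retentions are the maximal subsets
#' containing no flagged pair, so no candidate set retains both members of any
#' pair and no variable is dropped needlessly.
#'
#' @param all_vars Character vector of all covariate names.
#' @param pairs Data frame from [pearson_screen()].
#' @return List of character vectors (candidate variable sets), each with a
#'   `dropped` attribute naming the variables removed. With no pairs, a single
#'   set containing `all_vars`.
#' @export
variable_set_permutations <- function(all_vars, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0)
    return(list(structure(all_vars, dropped = character())))
  pvars <- unique(c(pairs$var1, pairs$var2))
  adj <- function(keep) {
    # TRUE if 'keep' contains both members of some flagged pair
    any(pairs$var1 %in% keep & pairs$var2 %in% keep)
  }
  gph <- igraph::graph_from_data_frame(pairs[, c("var1", "var2")],
                                       directed = FALSE)
  comp <- igraph::components(gph)$membership
  groups <- split(names(comp), comp)
  per_group <- lapply(groups, function(vs) {
    subsets <- lapply(seq_len(2^length(vs)) - 1L, function(b)
      vs[bitwAnd(b, 2^(seq_along(vs) - 1L)) > 0])
    valid <- Filter(Negate(adj), subsets)
    sizes <- lengths(valid)
    maximal <- valid[vapply(seq_along(valid), function(i) {
      !any(vapply(valid, function(w)
        length(w) > sizes[i] && all(valid[[i]] %in% w), TRUE))
    }, TRUE)]
    maximal
  })
  combos <- expand.grid(lapply(per_group, seq_along))
  lapply(seq_len(nrow(combos)), function(i) {
    keep_paired <- unlist(lapply(seq_along(groups), function(gi)
      per_group[[gi]][[combos[i, gi]]]), use.names = FALSE)
    keep <- all_vars[!all_vars %in% setdiff(pvars, keep_paired)]
    structure(keep, dropped = setdiff(pvars, keep_paired))
  })
}
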