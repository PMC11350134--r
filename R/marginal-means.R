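# Estimated marginal means over a balanced reference grid, and pairwise
# differences against the standard pipeline design.

# Reference grid: all combinations of every factor's levels, covariates
# fixed at their data means.
reference_grid <- function(fit) {
  if (!length(fit$xlevels)) {
    return(data.frame(row.names = 1L))
  }
  grid <- expand.grid(fit$xlevels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (v in names(grid)) grid[[v]] <- factor(grid[[v]], levels = fit$xlevels[[v]])
  grid
}

grid_model_matrix <- function(fit, grid) {
  response <- all.vars(fit$formula)[1]
  covs <- setdiff(names(fit$covariate_means), response)
  for (v in covs) grid[[v]] <- fit$covariate_means[[v]]
  tt <- stats::delete.response(fit$terms)
  stats::model.matrix(tt, grid, contrasts.arg = fit$contrasts)
}

#' Estimated marginal means of a model factor
#'
#' Model-based means per factor level, averaged over a balanced grid of the
#' other factors' levels (equal weights) with covariates at their means.
#' Standard errors come from the robust covariance via the delta method;
#' 95% CI = estimate +/- 1.96 SE.
#'
#' @param fit A `cl_gee` fit.
#' @param factor Name of a factor in the model.
#' @return Tibble of class `cl_marginal_means` with `level`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`; the contrast matrix and
#'   covariance are kept as attributes for [pairwise_deltas()].
#' @export
marginal_means <- function(fit, factor) {
  stopifnot(inherits(fit, "cl_gee"))
  if (!factor %in% names(fit$xlevels)) {
    stop_cl("argument_error", paste0("'", factor, "' is not a factor in the model"))
  }
  grid <- reference_grid(fit)
  mm <- grid_model_matrix(fit, grid)
  levels <- fit$xlevels[[factor]]
  l_mat <- t(vapply(levels, function(lv) {
    colMeans(mm[grid[[factor]] == lv, , drop = FALSE])
  }, numeric(ncol(mm))))
  est <- as.vector(l_mat %*% fit$coefficients)
  se <- sqrt(rowSums((l_mat %*% fit$vcov) * l_mat))
  out <- tibble::tibble(
    level = levels, estimate = est, std.error = se,
    conf.low = est - 1.96 * se, conf.high = est + 1.96 * se
  )
  attr(out, "L") <- l_mat
  attr(out, "vcov") <- fit$vcov
  attr(out, "factor") <- factor
  class(out) <- c("cl_marginal_means", class(out))
  out
}

#' Pairwise differences of marginal means against a reference level
#'
#' Delta-CL per level relative to the reference, with delta-method SE and
#' 95% CI.  Rows are flagged `relevant` when the absolute difference reaches
#' the test-retest relevance threshold (3 CL by default).
#'
#' @param mm A [marginal_means()] result.
#' @param reference_level Reference factor level (present in `mm`).
#' @param threshold Relevance threshold in CL (default 3).
#' @return Tibble with `level`, `delta`, `std.error`, `conf.low`,
#'   `conf.high`, `relevant`.
#' @export
pairwise_deltas <- function(mm, reference_level, threshold = 3) {
  stopifnot(inherits(mm, "cl_marginal_means"))
  if (!reference_level %in% mm$level) {
    stop_cl("argument_error", paste0("reference level not present: ", reference_level))
  }
  l_mat <- attr(mm, "L")
  v <- attr(mm, "vcov")
  ref <- l_mat[match(reference_level, mm$level), ]
  d_mat <- sweep(l_mat, 2, ref)
  delta <- mm$estimate - mm$estimate[match(reference_level, mm$level)]
  se <- sqrt(rowSums((d_mat %*% v) * d_mat))
  tibble::tibble(
    level = mm$level, reference = reference_level, delta = delta,
    std.error = se, conf.low = delta - 1.96 * se, conf.high = delta + 1.96 * se,
    relevant = abs(delta) >= threshold
  )
}
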