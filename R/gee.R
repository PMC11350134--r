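# Gaussian identity-link generalized estimating equations with an
# exchangeable (or independence) working correlation, clustered by subject,
# with robust sandwich covariance.  All cluster-level sums are vectorised via
# rowsum(), so fits are fast enough for simulation studies.

#' Specify a Centiloid bias/precision model
#'
#' Declarative model specification: between-subject factors, within-subject
#' (pipeline design) factors, covariates, and interaction pairs, clustered
#' by subject.  [spec_formula()] turns it into the model formula.
#'
#' @param response Response column (default `"cl"`).
#' @param between,within,covariates Character vectors of column names.
#' @param interactions List of character pairs, each an interaction term.
#' @param cluster Cluster id column (default `"subject_id"`).
#' @return An object of class `cl_model_spec`.
#' @export
model_spec <- function(response = "cl", between = character(), within = character(),
                       covariates = character(), interactions = list(),
                       cluster = "subject_id") {
  mains <- c(between, within, covariates)
  for (pair in interactions) {
    if (!all(pair %in% mains)) {
      stop_cl("configuration_error",
              paste0("interaction (", paste(pair, collapse = ":"),
                     ") has a component that is not a main effect"))
    }
  }
  structure(
    list(response = response, between = between, within = within,
         covariates = covariates, interactions = interactions, cluster = cluster),
    class = "cl_model_spec"
  )
}

#' @rdname model_spec
#' @param spec A `cl_model_spec`.
#' @export
spec_formula <- function(spec) {
  stopifnot(inherits(spec, "cl_model_spec"))
  terms <- c(
    spec$between, spec$within, spec$covariates,
    vapply(spec$interactions, paste, character(1), collapse = ":")
  )
  if (!length(terms)) terms <- "1"
  stats::as.formula(paste(spec$response, "~", paste(terms, collapse = " + ")))
}

#' Bias-model specifications
#'
#' The four bias models: the main technical-factor model, and the secondary
#' models adding age, brain atrophy, or harmonisation status together with
#' their interactions with the pipeline design factors.
#'
#' @param model Integer 1-4 selecting the model.
#' @return A [model_spec()].
#' @export
bias_model_spec <- function(model = 1L) {
  design <- c("rr", "rr_type", "t_type", "space")
  tracer_int <- lapply(design, function(f) c("tracer", f))
  base <- list(between = c("diagnosis", "tracer"), within = design)
  extra <- switch(as.character(model),
    "1" = list(covariates = character(), interactions = tracer_int),
    "2" = list(covariates = "age",
               interactions = c(tracer_int, lapply(design, function(f) c("age", f)))),
    "3" = list(covariates = "atrophy",
               interactions = c(tracer_int, lapply(design, function(f) c("atrophy", f)))),
    "4" = list(covariates = character(),
               interactions = c(tracer_int, lapply(design, function(f) c("harmonized", f)))),
    stop_cl("configuration_error", "model must be 1, 2, 3 or 4")
  )
  within <- if (model == 4L) c(base$within, "harmonized") else base$within
  model_spec(between = base$between, within = within,
             covariates = extra$covariates, interactions = extra$interactions)
}

#' Precision-model specification
#'
#' CL regressed on the pipeline identity alone (within-subject factor).
#' @return A [model_spec()].
#' @export
precision_model_spec <- function() model_spec(within = "pipeline_id")

# Prepare the design: sum-to-zero contrasts on every factor so joint Type III
# tests are invariant to level ordering.
build_design <- function(formula, data) {
  mf_vars <- all.vars(formula)
  missing <- setdiff(mf_vars, names(data))
  if (length(missing)) {
    stop_cl("configuration_error",
            paste0("columns missing from data: ", paste(missing, collapse = ", ")))
  }
  data <- as.data.frame(data)[mf_vars]
  for (v in names(data)) {
    if (is.character(data[[v]]) || is.logical(data[[v]])) {
      data[[v]] <- factor(data[[v]], levels = sort(unique(data[[v]])))
    }
  }
  tt <- stats::terms(formula, data = data)
  mf <- stats::model.frame(tt, data)
  fac <- names(mf)[vapply(mf, is.factor, logical(1))]
  contrasts_arg <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  x <- stats::model.matrix(tt, mf, contrasts.arg = contrasts_arg)
  list(
    x = x, y = stats::model.response(mf), terms = tt,
    assign = attr(x, "assign"),
    xlevels = stats::.getXlevels(tt, mf),
    contrasts = attr(x, "contrasts"),
    covariate_means = vapply(mf[vapply(mf, is.numeric, logical(1))], mean, numeric(1))
  )
}

#' Fit a GEE to a long Centiloid table
#'
#' Gaussian family, identity link, clustered by subject, with an
#' exchangeable (default) or independence working correlation and robust
#' sandwich covariance.  Deterministic given the data.  With the
#' independence structure on complete data the coefficients equal ordinary
#' least squares.
#'
#' @param data Long measurement table (one row per measurement).
#' @param formula Model formula, or a [model_spec()].
#' @param id Cluster id column name (default `"subject_id"`, or the spec's).
#' @param corstr Working correlation: `"exchangeable"` or `"independence"`.
#' @param maxit,tol Iteration controls.
#' @return An object of class `cl_gee` with `coefficients`, robust `vcov`,
#'   model-based `vcov_model`, working correlation `alpha`, dispersion
#'   `phi`, term bookkeeping for Wald tests and marginal means.
#' @export
fit_gee <- function(data, formula, id = NULL,
                    corstr = c("exchangeable", "independence"),
                    maxit = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  if (inherits(formula, "cl_model_spec")) {
    if (is.null(id)) id <- formula$cluster
    formula <- spec_formula(formula)
  }
  if (is.null(id)) id <- "subject_id"
  if (!id %in% names(data)) {
    stop_cl("configuration_error", paste0("cluster column not in data: ", id))
  }

  des <- build_design(formula, data)
  x <- des$x; y <- des$y
  cluster <- factor(data[[id]])
  n <- length(y); p <- ncol(x)
  csize <- as.vector(table(cluster))
  n_clusters <- length(csize)

  if (corstr == "exchangeable" && all(csize == 1L)) {
    warn_cl("degenerate_correlation",
            "all clusters have a single observation; falling back to independence")
    corstr <- "independence"
  }

  xtx <- crossprod(x)
  xty <- crossprod(x, y)
  sizes <- csize  # rowsum() output and table() are both sorted by level

  solve_beta <- function(alpha) {
    if (alpha == 0) return(solve(xtx, xty))
    cs_x <- rowsum(x, cluster)            # cluster sums of columns
    cs_y <- rowsum(y, cluster)[, 1]
    ci <- alpha / (1 + (sizes - 1) * alpha)
    a <- xtx - crossprod(cs_x, ci * cs_x)
    b <- xty - crossprod(cs_x, ci * cs_y)
    solve(a, b)
  }

  alpha <- 0
  beta <- solve_beta(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    e <- as.vector(y - x %*% beta)
    phi <- sum(e^2) / (n - p)
    if (corstr == "exchangeable") {
      se_c <- rowsum(e, cluster)[, 1]
      se2_c <- rowsum(e^2, cluster)[, 1]
      num <- sum(se_c^2 - se2_c) / 2
      den <- phi * (sum(sizes * (sizes - 1)) / 2 - p)
      alpha_new <- if (den > 0) num / den else 0
      alpha_new <- min(max(alpha_new, 0), 0.995)
    } else {
      alpha_new <- 0
    }
    beta_new <- solve_beta(alpha_new)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    alpha <- alpha_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warn_cl("nonconvergence", "GEE did not converge; estimates flagged")

  e <- as.vector(y - x %*% beta)
  phi <- sum(e^2) / (n - p)
  ci <- if (alpha > 0) alpha / (1 + (sizes - 1) * alpha) else rep(0, n_clusters)
  cs_x <- rowsum(x, cluster)
  cs_e <- rowsum(e, cluster)[, 1]
  xte <- rowsum(x * e, cluster)           # per-cluster X_i' e_i
  u <- xte - (ci * cs_e) * cs_x           # per-cluster X_i' R_i^{-1} e_i (x 1-alpha)
  bread <- xtx - crossprod(cs_x, ci * cs_x)
  meat <- crossprod(u)
  bread_inv <- solve(bread)
  vcov_rob <- bread_inv %*% meat %*% bread_inv
  # scalar (1-alpha) factors cancel in the sandwich; model-based needs them
  vcov_model <- phi * (1 - alpha) * bread_inv
  dimnames(vcov_rob) <- dimnames(vcov_model) <- list(colnames(x), colnames(x))

  structure(
    list(
      coefficients = stats::setNames(as.vector(beta), colnames(x)),
      vcov = vcov_rob, vcov_model = vcov_model,
      alpha = alpha, phi = phi, corstr = corstr,
      n_obs = n, n_clusters = n_clusters, converged = converged,
      formula = formula, terms = des$terms, assign = des$assign,
      xlevels = des$xlevels, contrasts = des$contrasts,
      covariate_means = des$covariate_means,
      residuals = e
    ),
    class = "cl_gee"
  )
}

#' @export
coef.cl_gee <- function(object, ...) object$coefficients

#' @export
vcov.cl_gee <- function(object, ...) object$vcov

#' @export
print.cl_gee <- function(x, ...) {
  cat("<cl_gee> ", x$corstr, " working correlation",
      if (x$corstr == "exchangeable") sprintf(" (alpha = %.3f)", x$alpha),
      ", ", x$n_obs, " obs in ", x$n_clusters, " clusters\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a fitted GEE
#'
#' @param x A `cl_gee` fit.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, robust `std.error`, `statistic`
#'   (z), `p.value`.
#' @method tidy cl_gee
#' @export
tidy.cl_gee <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients), estimate = unname(x$coefficients),
    std.error = unname(se), statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' One-row model summary of a fitted GEE
#'
#' @param x A `cl_gee` fit.
#' @param ... Unused.
#' @return Tibble with sample sizes, working correlation, dispersion,
#'   convergence flag.
#' @method glance cl_gee
#' @export
glance.cl_gee <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_clusters = x$n_clusters, corstr = x$corstr,
    alpha = x$alpha, phi = x$phi, converged = x$converged
  )
}

#' Type III Wald tests for a fitted GEE
#'
#' For every model term, the joint Wald chi-square that all of the term's
#' coefficients are zero, using the robust covariance and adjusting for all
#' other terms (sum-to-zero coding makes the tests invariant to factor level
#' order).  A singular covariance sub-block is handled with a pseudo-inverse
#' and a warning.
#'
#' @param fit A `cl_gee` fit.
#' @param include_intercept Include the intercept row (default TRUE).
#' @return Tibble with `term`, `wald_chisq`, `df`, `p.value`.
#' @export
wald_type3 <- function(fit, include_intercept = TRUE) {
  stopifnot(inherits(fit, "cl_gee"))
  if (!fit$converged) warn_cl("nonconvergence", "Wald tests from a non-converged fit")
  labels <- attr(fit$terms, "term.labels")
  ids <- seq_along(labels)
  if (include_intercept && attr(fit$terms, "intercept") == 1) {
    labels <- c("(Intercept)", labels)
    ids <- c(0L, ids)
  }
  rows <- purrr::map2(labels, ids, function(lab, k) {
    idx <- which(fit$assign == k)
    b <- fit$coefficients[idx]
    v <- fit$vcov[idx, idx, drop = FALSE]
    chi2 <- tryCatch(
      as.numeric(t(b) %*% solve(v, b)),
      error = function(err) {
        warn_cl("singular_covariance",
                paste0("singular covariance block for term ", lab, "; using pseudo-inverse"))
        sv <- svd(v)
        pos <- sv$d > max(sv$d) * 1e-12
        vinv <- sv$v[, pos, drop = FALSE] %*%
          ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
        as.numeric(t(b) %*% vinv %*% b)
      }
    )
    tibble::tibble(term = lab, wald_chisq = chi2, df = length(idx),
                   p.value = stats::pchisq(chi2, length(idx), lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}
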