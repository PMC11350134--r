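# Precision analyses: within/between-pipeline variance decomposition,
# confidence-interval interpolation at clinical cutoffs, ICC(2,1) and
# Bland-Altman agreement.

#' Within- and between-pipeline variance decomposition
#'
#' Two-way additive decomposition `CL_ip = mu + s_i + pi_p + e_ip` over
#' subjects i and pipelines p: the between-pipeline SD is the SD of the
#' pipeline effects `pi_p`; the within-pipeline SD is the residual SD
#' (mean-square based, so an injected residual sigma is recovered
#' unbiasedly).  95% half-widths are 1.96 x SD.  A GEE-based cross-check
#' mode computes the between-pipeline SD from the pipeline marginal means of
#' the `CL ~ pipeline` model instead.
#'
#' @param table Long table (one stratum).
#' @param stratum Label stored in the result (e.g. `"negative"`).
#' @param harmonized Restrict to this harmonisation status (default TRUE).
#' @param method `"anova"` (two-way means, default) or `"gee"` (marginal-mean
#'   cross-check).
#' @param strict Error on missing subject x pipeline cells instead of
#'   imputing them from subject + pipeline means (default FALSE).
#' @return An object of class `cl_precision`: one-row tibble with
#'   `stratum`, `within_sd`, `between_sd`, `within_ci_halfwidth`,
#'   `between_ci_halfwidth`, `stratum_mean_cl`, `n_subjects`, `n_pipelines`.
#' @export
variance_decomposition <- function(table, stratum = "all", harmonized = TRUE,
                                   method = c("anova", "gee"), strict = FALSE) {
  method <- match.arg(method)
  sub <- table[table$harmonized == harmonized, ]
  if (length(unique(sub$pipeline_id)) < 2L || length(unique(sub$subject_id)) < 2L) {
    stop_cl("insufficient_data", "need at least 2 subjects and 2 pipelines")
  }
  wide <- tidyr::pivot_wider(sub[, c("subject_id", "pipeline_id", "cl")],
                             names_from = "pipeline_id", values_from = "cl")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$subject_id
  if (anyNA(m)) {
    if (strict) stop_cl("insufficient_data", "missing subject x pipeline cells")
    warn_cl("imputed_cells", "missing cells imputed from subject + pipeline means")
    mu0 <- mean(m, na.rm = TRUE)
    ri <- rowMeans(m, na.rm = TRUE) - mu0
    cj <- colMeans(m, na.rm = TRUE) - mu0
    pred <- outer(ri, cj, `+`) + mu0
    m[is.na(m)] <- pred[is.na(m)]
  }
  n_i <- nrow(m); n_p <- ncol(m)
  mu <- mean(m)
  pipe_eff <- colMeans(m) - mu
  subj_eff <- rowMeans(m) - mu
  resid <- m - outer(subj_eff, pipe_eff, `+`) - mu

  if (method == "anova") {
    between_sd <- sqrt(sum(pipe_eff^2) / (n_p - 1))
    within_sd <- sqrt(sum(resid^2) / ((n_i - 1) * (n_p - 1)))
  } else {
    fit <- fit_gee(sub, precision_model_spec())
    mm <- marginal_means(fit, "pipeline_id")
    between_sd <- stats::sd(mm$estimate)
    within_sd <- sqrt(sum(resid^2) / ((n_i - 1) * (n_p - 1)))
  }

  out <- tibble::tibble(
    stratum = stratum, within_sd = within_sd, between_sd = between_sd,
    within_ci_halfwidth = 1.96 * within_sd,
    between_ci_halfwidth = 1.96 * between_sd,
    stratum_mean_cl = mu, n_subjects = n_i, n_pipelines = n_p
  )
  class(out) <- c("cl_precision", class(out))
  out
}

#' Interpolate the within-pipeline CI half-width at a Centiloid value
#'
#' Linear interpolation of the 95% CI half-width between the two stratum
#' anchor points (stratum mean CL, within-pipeline half-width), evaluated at
#' arbitrary CL values - by convention the amyloid-positivity cutoffs 12 and
#' 24.  Values outside the anchor range are linearly extrapolated and
#' flagged.
#'
#' @param neg,pos `cl_precision` rows for the negative and positive strata
#'   (negative anchor must sit at a lower mean CL).
#' @param cl_value Numeric vector of CL values to evaluate (default
#'   `c(12, 24)`).
#' @return Tibble with `cl`, `ci_halfwidth`, `extrapolated`.
#' @export
interpolate_ci <- function(neg, pos, cl_value = c(12, 24)) {
  x1 <- neg$stratum_mean_cl; y1 <- neg$within_ci_halfwidth
  x2 <- pos$stratum_mean_cl; y2 <- pos$within_ci_halfwidth
  if (x1 == x2) stop_cl("interpolation_error", "anchor CL values coincide")
  if (!(x1 < x2)) stop_cl("interpolation_error", "negative anchor must lie below positive anchor")
  slope <- (y2 - y1) / (x2 - x1)
  tibble::tibble(
    cl = cl_value,
    ci_halfwidth = y1 + slope * (cl_value - x1),
    extrapolated = cl_value < x1 | cl_value > x2
  )
}

#' ICC(2,1) agreement of paired measurements
#'
#' Two-way random effects, absolute agreement, single measurement, from the
#' two-way mean squares, with the F test of the ICC.  Identical pairs with
#' zero residual variance report an ICC of 1 (degenerate flag when the total
#' variance is zero).
#'
#' @param x,y Paired numeric vectors (>= 3 pairs), e.g. CL before/after
#'   harmonisation.
#' @return Tibble with `icc`, `f`, `df1`, `df2`, `p.value`, `n`,
#'   `degenerate`.
#' @export
icc_agreement <- function(x, y) {
  if (length(x) != length(y)) stop_cl("argument_error", "paired vectors must match")
  n <- length(x)
  if (n < 3L) stop_cl("insufficient_data", "ICC needs at least 3 pairs")
  m <- cbind(x, y)
  k <- 2L
  grand <- mean(m)
  if (sum((m - grand)^2) == 0) {
    return(tibble::tibble(icc = 1, f = NA_real_, df1 = n - 1L,
                          df2 = n - 1L, p.value = NA_real_, n = n, degenerate = TRUE))
  }
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  f <- if (mse > 0) msr / mse else Inf
  p <- if (is.finite(f)) stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE) else 0
  tibble::tibble(icc = icc, f = f, df1 = n - 1L, df2 = (n - 1L) * (k - 1L),
                 p.value = p, n = n, degenerate = FALSE)
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are oriented `harmonized - original`.  Reports the mean
#' difference with its 95% CI (`mean +/- 1.96 SD / sqrt(n)`) and the limits
#' of agreement (`mean +/- 1.96 SD`), with the per-pair means retained for
#' plotting.
#'
#' @param original,harmonized Paired numeric vectors (>= 2 pairs).
#' @return An object of class `cl_bland_altman`: list with one-row `stats`
#'   tibble and per-pair `data`.
#' @export
bland_altman <- function(original, harmonized) {
  if (length(original) != length(harmonized)) {
    stop_cl("argument_error", "paired vectors must match")
  }
  n <- length(original)
  if (n < 2L) stop_cl("insufficient_data", "Bland-Altman needs at least 2 pairs")
  diffs <- harmonized - original
  m <- mean(diffs); s <- stats::sd(diffs)
  stats <- tibble::tibble(
    mean_diff = m, sd_diff = s,
    ci_low = m - 1.96 * s / sqrt(n), ci_high = m + 1.96 * s / sqrt(n),
    loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = n
  )
  structure(
    list(stats = stats,
         data = tibble::tibble(mean = (original + harmonized) / 2, diff = diffs)),
    class = "cl_bland_altman"
  )
}

#' @export
print.cl_bland_altman <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<cl_bland_altman> n = %d, mean diff %.2f +/- %.2f (95%% CI %.2f to %.2f), LoA [%.2f, %.2f]\n",
    s$n, s$mean_diff, s$sd_diff, s$ci_low, s$ci_high, s$loa_low, s$loa_high
  ))
  invisible(x)
}

#' Tidy a Bland-Altman result
#'
#' @param x A `cl_bland_altman` object.
#' @param ... Unused.
#' @return The one-row stats tibble.
#' @method tidy cl_bland_altman
#' @export
tidy.cl_bland_altman <- function(x, ...) x$stats
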