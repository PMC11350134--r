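# Direct table-level simulation of Centiloid measurements: an additive
# factorial model with subject random intercepts, bypassing the imaging
# chain.  Used for calibrating and validating the statistical battery
# (type-I error, offset recovery, variance-component recovery).

#' Simulate a long Centiloid table from an additive factor model
#'
#' Each subject contributes the full within-subject factorial (rr x rr_type
#' x t_type x space); the response is
#' `baseline + subject_intercept + sum(level effects) + residual`.
#' Effects are supplied as named vectors of per-level offsets; omitted
#' factors have zero effect (a null factor).
#'
#' @param n_subjects Number of subjects.
#' @param effects Named list of named numeric vectors, e.g.
#'   `list(rr = c(WCB = 0, CGM = 2, Pons = -15, WCB_BSTM = -1))`.  Allowed
#'   names: `rr`, `rr_type`, `t_type`, `space`, `tracer`, `diagnosis`.
#' @param baseline Grand intercept in CL.
#' @param sigma_subject Between-subject SD (cluster random intercept).
#' @param sigma_resid Residual (within-subject) SD.
#' @param tracer_mix,diagnosis_mix Between-subject allocation fractions.
#' @param age_effect Slope of a centred age covariate on CL (age drawn
#'   N(71, 6.7)); 0 keeps age a pure noise column.
#' @param seed Integer seed.
#' @return Long tibble with the design columns, `subject_id`, `tracer`,
#'   `diagnosis`, `age`, `pipeline_id`, `harmonized` (all TRUE) and `cl`.
#' @export
simulate_cl_table <- function(n_subjects, effects = list(), baseline = 20,
                              sigma_subject = 30, sigma_resid = 3,
                              tracer_mix = c(FMM = 0.39, FBB = 0.23, FBP = 0.38),
                              diagnosis_mix = c(SCD = 0.32, MCI = 0.45, dementia = 0.23),
                              age_effect = 0, seed = 1L) {
  allowed <- c("rr", "rr_type", "t_type", "space", "tracer", "diagnosis")
  if (!all(names(effects) %in% allowed)) {
    stop_cl("configuration_error", paste0(
      "unknown effect factor(s): ",
      paste(setdiff(names(effects), allowed), collapse = ", ")
    ))
  }
  with_seed_cl(seed, {
    subjects <- tibble::tibble(
      subject_id = sprintf("sim-%05d", seq_len(n_subjects)),
      tracer = sample(names(tracer_mix), n_subjects, TRUE, tracer_mix),
      diagnosis = sample(names(diagnosis_mix), n_subjects, TRUE, diagnosis_mix),
      age = stats::rnorm(n_subjects, 71, 6.7),
      s_i = stats::rnorm(n_subjects, 0, sigma_subject)
    )
    tab <- tidyr::crossing(subjects, enumerate_pipelines())
    eff <- numeric(nrow(tab))
    for (f in names(effects)) {
      v <- effects[[f]]
      lv <- tab[[f]]
      bad <- setdiff(unique(lv), names(v))
      if (length(bad)) {
        stop_cl("configuration_error", paste0(
          "effect for factor ", f, " missing level(s): ", paste(bad, collapse = ", ")
        ))
      }
      eff <- eff + unname(v[lv])
    }
    tab$cl <- baseline + tab$s_i + eff +
      age_effect * (tab$age - 71) + stats::rnorm(nrow(tab), 0, sigma_resid)
    tab$harmonized <- TRUE
    dplyr::select(tab, "subject_id", "tracer", "diagnosis", "age", "harmonized",
                  "rr", "rr_type", "t_type", "space", "pipeline_id", "cl")
  })
}

#' Simulate a subject x pipeline table with fixed variance components
#'
#' Additive generation `CL_ip = mu + s_i + pi_p + e_ip` where the pipeline
#' effects `pi_p` are a fixed vector rescaled to have SD exactly
#' `sigma_between`, so [variance_decomposition()] recovery can be assessed
#' against known ground truth.
#'
#' @param n_subjects,n_pipelines Table dimensions.
#' @param mu Grand mean CL.
#' @param sigma_subject,sigma_between,sigma_within Component SDs.
#' @param seed Integer seed.
#' @return Long tibble with `subject_id`, `pipeline_id`, `harmonized`, `cl`.
#' @export
simulate_variance_table <- function(n_subjects = 500, n_pipelines = 32,
                                    mu = 20, sigma_subject = 30,
                                    sigma_between = 3, sigma_within = 2,
                                    seed = 1L) {
  with_seed_cl(seed, {
    pi_p <- seq(-1, 1, length.out = n_pipelines)
    pi_p <- pi_p - mean(pi_p)
    pi_p <- pi_p / stats::sd(pi_p) * sigma_between
    s_i <- stats::rnorm(n_subjects, 0, sigma_subject)
    eps <- matrix(stats::rnorm(n_subjects * n_pipelines, 0, sigma_within),
                  n_subjects, n_pipelines)
    cl <- mu + outer(s_i, pi_p, `+`) + eps
    tibble::tibble(
      subject_id = rep(sprintf("sim-%05d", seq_len(n_subjects)), n_pipelines),
      pipeline_id = rep(sprintf("pipe-%02d", seq_len(n_pipelines)), each = n_subjects),
      harmonized = TRUE,
      cl = as.vector(cl)
    )
  })
}
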