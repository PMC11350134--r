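# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

template_32 <- function() {
  cached("t32", function() build_template(phantom_spec(c(32L, 32L, 32L), 2)))
}

template_48 <- function() {
  cached("t48", function() build_template(phantom_spec(c(48L, 48L, 48L), 2)))
}

# Noise-free tracer profiles, optionally with the age-dependent white-matter
# slope switched off (removes every age-driven bias pathway).
quiet_profiles <- function(age_slope = FALSE) {
  p <- tracer_profiles()
  p$noise_sd <- 0
  if (!age_slope) p$wm_age_slope <- 0
  p
}

# Idealised cohort configuration: no noise, no smoothing, no atrophy, no
# rigid jitter - the conditions under which the SUVr -> CL chain is exact.
ideal_cohort_config <- function(n_subjects = 3) {
  cohort_config(
    n_subjects = n_subjects, profiles = quiet_profiles(),
    native_fwhm_range = c(0, 0), harmonize_to = 0,
    jitter_translation_sd = 0, jitter_rotation_sd = 0,
    atrophy_by_diagnosis = list(SCD = c(mean = 1, sd = 0),
                                MCI = c(mean = 1, sd = 0),
                                dementia = c(mean = 1, sd = 0)),
    grid_shape = c(32L, 32L, 32L)
  )
}

make_rigid_for_test <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  centistress:::make_rigid(angles, translation)
}

# Independent ordinary-least-squares oracle via the normal equations.
ols_oracle <- function(x, y) {
  as.vector(solve(crossprod(x), crossprod(x, y)))
}

# Small long table for the stratification / correlation tests: hand-built,
# one row per subject x pipeline, standard-pipeline CL set explicitly.
toy_long_table <- function(std_cl, harmonized = TRUE) {
  n <- length(std_cl)
  subjects <- tibble::tibble(
    subject_id = sprintf("toy-%02d", seq_len(n)),
    tracer = rep(c("FMM", "FBB", "FBP"), length.out = n),
    diagnosis = rep(c("SCD", "MCI", "dementia"), length.out = n),
    age = seq(60, 80, length.out = n),
    atrophy = seq(0.8, 1.0, length.out = n),
    true_cl = std_cl,
    native_fwhm = 6,
    group = ifelse(std_cl > 24, "positive", "negative")
  )
  tab <- tidyr::crossing(subjects, enumerate_pipelines())
  tab$harmonized <- harmonized
  tab$suvr <- 1.5
  # every pipeline reports the subject's standard CL unless a test perturbs it
  tab$cl <- tab$true_cl
  dplyr::select(tab, dplyr::all_of(c(
    "subject_id", "tracer", "diagnosis", "age", "atrophy", "true_cl",
    "native_fwhm", "harmonized", "rr", "rr_type", "t_type", "space",
    "pipeline_id", "suvr", "cl", "group"
  )))
}
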