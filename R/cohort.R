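# Synthetic cohort generation: per-subject ground truth and PET-like images
# in native resolution and harmonised to a common effective resolution.

#' Cohort configuration
#'
#' Defines the statistical structure of the synthetic cohort: a two-group
#' amyloid mixture (negative/positive, split at CL 24), memory-clinic-like
#' age and diagnosis composition, diagnosis-coupled atrophy, tracer
#' allocation, and scanner resolutions.  Defaults emulate a memory-clinic
#' sample quantified with the three 18F tracers, where the FMM/FBB subsample
#' has both original and harmonised scans and the FBP subsample only
#' harmonised ones.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param group_mix Fraction of amyloid-positive subjects.
#' @param cl_negative,cl_positive `c(mean, sd)` of true CL per group.
#' @param age `c(mean, sd, min, max)` of age in years.
#' @param diagnosis_mix Named fractions for SCD/MCI/dementia (sum to 1).
#' @param atrophy_by_diagnosis Named list of `c(mean, sd)` retained-GM
#'   fractions per diagnosis.
#' @param atrophy_bounds Lower/upper clamp for atrophy.
#' @param tracer_mix Named allocation fractions over tracers (sum to 1).
#' @param dual_image_tracers Tracers whose subjects get both original and
#'   harmonised images.
#' @param native_fwhm_range Scanner point-spread FWHM range in mm.
#' @param harmonize_to Target effective resolution in mm.
#' @param grid_shape,voxel_size Phantom grid (see [phantom_spec()]).
#' @param jitter_translation_sd,jitter_rotation_sd Rigid misalignment scales
#'   (mm / degrees); 0 disables jitter.
#' @param background_uptake Extracerebral intensity relative to WCB.
#' @param noise_sd Per-region noise SD override (NULL keeps each tracer's).
#' @param profiles Tracer profile table override (NULL uses
#'   [tracer_profiles()]); lets idealised studies switch off noise or the
#'   age-dependent white-matter slope in one place.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60L,
                          group_mix = 0.5,
                          cl_negative = c(mean = 2, sd = 8),
                          cl_positive = c(mean = 75, sd = 20),
                          age = c(mean = 71, sd = 6.7, min = 55, max = 90),
                          diagnosis_mix = c(SCD = 0.32, MCI = 0.45, dementia = 0.23),
                          atrophy_by_diagnosis = list(
                            SCD = c(mean = 0.95, sd = 0.03),
                            MCI = c(mean = 0.90, sd = 0.04),
                            dementia = c(mean = 0.85, sd = 0.05)
                          ),
                          atrophy_bounds = c(0.70, 1.00),
                          tracer_mix = c(FMM = 0.39, FBB = 0.23, FBP = 0.38),
                          dual_image_tracers = c("FMM", "FBB"),
                          native_fwhm_range = c(5, 8),
                          harmonize_to = 8,
                          grid_shape = c(48L, 48L, 48L),
                          voxel_size = 2,
                          jitter_translation_sd = 0.5,
                          jitter_rotation_sd = 0.5,
                          background_uptake = 0.3,
                          noise_sd = NULL,
                          profiles = NULL) {
  if (!is_scalar_number(n_subjects) || n_subjects < 1) {
    stop_cl("configuration_error", "n_subjects must be >= 1")
  }
  if (group_mix < 0 || group_mix > 1) {
    stop_cl("configuration_error", "group_mix must lie in [0, 1]")
  }
  if (abs(sum(diagnosis_mix) - 1) > 1e-8 || any(diagnosis_mix < 0)) {
    stop_cl("configuration_error", "diagnosis_mix fractions must be >= 0 and sum to 1")
  }
  if (abs(sum(tracer_mix) - 1) > 1e-8 || any(tracer_mix < 0)) {
    stop_cl("configuration_error", "tracer_mix fractions must be >= 0 and sum to 1")
  }
  if (!all(names(tracer_mix) %in% tracer_profiles()$name)) {
    stop_cl("configuration_error", "tracer_mix names must be known tracers")
  }
  if (native_fwhm_range[2] > harmonize_to) {
    stop_cl("configuration_error", "native FWHM must not exceed the harmonisation target")
  }
  structure(as.list(environment()), class = "cohort_config")
}

draw_subject_params <- function(cfg, n) {
  positive <- stats::runif(n) < cfg$group_mix
  true_cl <- ifelse(
    positive,
    stats::rnorm(n, cfg$cl_positive[["mean"]], cfg$cl_positive[["sd"]]),
    stats::rnorm(n, cfg$cl_negative[["mean"]], cfg$cl_negative[["sd"]])
  )
  age <- pmin(pmax(stats::rnorm(n, cfg$age[["mean"]], cfg$age[["sd"]]),
                   cfg$age[["min"]]), cfg$age[["max"]])
  diagnosis <- sample(names(cfg$diagnosis_mix), n, replace = TRUE,
                      prob = cfg$diagnosis_mix)
  atrophy <- vapply(diagnosis, function(dx) {
    p <- cfg$atrophy_by_diagnosis[[dx]]
    stats::rnorm(1, p[["mean"]], p[["sd"]])
  }, numeric(1))
  atrophy <- pmin(pmax(atrophy, cfg$atrophy_bounds[1]), cfg$atrophy_bounds[2])
  tracer <- sample(names(cfg$tracer_mix), n, replace = TRUE, prob = cfg$tracer_mix)
  native_fwhm <- stats::runif(n, cfg$native_fwhm_range[1], cfg$native_fwhm_range[2])
  tibble::tibble(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    tracer = tracer,
    diagnosis = diagnosis,
    age = age,
    atrophy = atrophy,
    true_cl = true_cl,
    native_fwhm = native_fwhm,
    # group label assigned from true load, before any measurement noise
    group = ifelse(true_cl > 24, "positive", "negative")
  )
}

#' Generate a synthetic amyloid-PET cohort
#'
#' Draws per-subject ground truth from the configuration, morphs the template
#' per subject (atrophy + rigid jitter), simulates tracer uptake, applies the
#' native scanner point-spread, and harmonises to the target resolution.
#' Fully reproducible: every subject uses a child seed derived by stable
#' hashing of its id from the root seed.
#'
#' @param cfg A [cohort_config()].
#' @param seed Root integer seed.
#' @param template Optional pre-built template `label_map` (must match the
#'   configured grid).
#' @param images Simulate the per-subject images (default TRUE); FALSE
#'   returns the ground-truth table alone, for purely statistical studies of
#'   the cohort composition.
#' @return An object of class `cl_cohort`: list with `subjects` (ground-truth
#'   tibble), `data` (per-subject labels, affine and images), `template`,
#'   `template_masks`, `cfg`, `seed`.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1L, template = NULL,
                            images = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.null(template)) {
    template <- build_template(phantom_spec(cfg$grid_shape, cfg$voxel_size))
  }
  profiles <- cfg$profiles %||% tracer_profiles()
  if (!is.null(cfg$noise_sd)) profiles$noise_sd <- cfg$noise_sd

  subjects <- with_seed_cl(seed, draw_subject_params(cfg, as.integer(cfg$n_subjects)))

  if (!images) {
    return(structure(
      list(subjects = subjects, data = list(), template = template,
           template_masks = template_masks(template), cfg = cfg, seed = seed),
      class = "cl_cohort"
    ))
  }

  data <- lapply(seq_len(nrow(subjects)), function(i) {
    p <- subjects[i, ]
    cs <- child_seed(seed, p$subject_id)
    morph <- morph_subject(template, p, seed = cs,
                           jitter_translation_sd = cfg$jitter_translation_sd,
                           jitter_rotation_sd = cfg$jitter_rotation_sd)
    tracer <- tracer_profile(p$tracer, profiles)
    ideal <- simulate_uptake(morph$labels, p, tracer, seed = cs + 1L,
                             background_uptake = cfg$background_uptake)
    original <- apply_psf(ideal, p$native_fwhm)
    harmonized <- harmonize_image(original, cfg$harmonize_to)
    list(
      labels = morph$labels,
      affine = morph$affine,
      original = if (p$tracer %in% cfg$dual_image_tracers) original else NULL,
      harmonized = harmonized
    )
  })
  names(data) <- subjects$subject_id

  structure(
    list(subjects = subjects, data = data, template = template,
         template_masks = template_masks(template), cfg = cfg, seed = seed),
    class = "cl_cohort"
  )
}

#' @export
print.cl_cohort <- function(x, ...) {
  cat("<cl_cohort> ", nrow(x$subjects), " subjects, grid ",
      paste(dim(x$template$grid), collapse = " x "), " @ ",
      x$template$voxel_size, " mm, seed ", x$seed, "\n", sep = "")
  print(dplyr::count(x$subjects, .data$tracer, .data$group))
  invisible(x)
}
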