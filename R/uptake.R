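# Tracer uptake simulation: piecewise-constant compartment intensities whose
# ideal (unsmoothed) target/WCB SUVr is an exact linear function of the true
# amyloid load, with age-dependent white-matter binding.

#' Simulate tracer uptake on a subject label map
#'
#' Intensities are constant within each compartment (before noise), scaled so
#' the whole-cerebellum mean is 1:
#' * cortical target = tracer SUVr at `true_cl`, linearly interpolated between
#'   `suvr_yc` (0 CL) and `suvr_ad100` (100 CL) and extrapolated outside;
#' * white matter (cerebral, cerebellar, pons) =
#'   `wm_uptake_base + wm_age_slope * (age - 70)`;
#' * cerebellar grey solves the whole-cerebellum normalisation;
#' * deep grey = 1; background (scalp/CSF) = `background_uptake`.
#'
#' Multiplicative Gaussian noise (SD `noise_sd`) is applied per region.
#'
#' @param labels Subject `label_map`.
#' @param params Subject parameters (needs `true_cl`, `age`, `tracer`).
#' @param tracer Tracer profile row matching `params$tracer`.
#' @param seed Integer seed for the regional noise.
#' @param background_uptake Extracerebral/CSF intensity relative to the
#'   whole-cerebellum mean (default 0.3).
#' @return A `volume_image` with `effective_fwhm = 0`.
#' @export
simulate_uptake <- function(labels, params, tracer = tracer_profile(params$tracer),
                            seed = 1L, background_uptake = 0.3) {
  stopifnot(inherits(labels, "label_map"))
  tracer <- tracer_profile(tracer)
  if (!identical(as.character(tracer$name), as.character(params$tracer))) {
    stop_cl("argument_error", "tracer profile does not match params$tracer")
  }
  if (!is_scalar_number(params$true_cl)) {
    stop_cl("argument_error", "true_cl must be finite")
  }

  wm <- tracer$wm_uptake_base + tracer$wm_age_slope * (params$age - 70)
  suvr_t <- tracer$suvr_yc + (tracer$suvr_ad100 - tracer$suvr_yc) * params$true_cl / 100

  lb <- cl_labels()
  n_cgm <- sum(labels$grid == lb[["cerebellar_GM"]])
  n_cwm <- sum(labels$grid == lb[["cerebellar_WM"]])
  # cerebellar GM level solving (n_cgm * g + n_cwm * wm) / (n_cgm + n_cwm) = 1
  g <- ((n_cgm + n_cwm) - n_cwm * wm) / n_cgm

  intensities <- c(
    background = background_uptake,
    cortical_target_GM = suvr_t,
    other_GM = 1,
    cerebral_WM = wm,
    cerebellar_GM = g,
    cerebellar_WM = wm,
    brainstem_pons = wm
  )
  if (any(intensities < 0)) {
    bad <- names(intensities)[intensities < 0]
    stop_cl("model_parameter_error",
            paste0("negative region intensity for: ", paste(bad, collapse = ", ")))
  }

  if (tracer$noise_sd > 0) {
    factors <- with_seed_cl(seed, 1 + stats::rnorm(length(intensities), 0, tracer$noise_sd))
    if (any(intensities * factors < 0)) {
      stop_cl("model_parameter_error", "noise drove a region intensity negative")
    }
    intensities <- intensities * factors
  }

  grid <- array(intensities[labels$grid + 1L], dim = dim(labels$grid))
  volume_image(grid, labels$voxel_size, effective_fwhm = 0)
}
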