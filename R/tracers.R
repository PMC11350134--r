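# Tracer profiles: dynamic range and white-matter binding behaviour of the
# amyloid PET tracers emulated by the simulator.

#' Default tracer profiles
#'
#' One row per tracer: a PiB-like anchor tracer and the three approved
#' 18F tracers (flutemetamol FMM, florbetaben FBB, florbetapir FBP).
#'
#' `suvr_yc` / `suvr_ad100` anchor the tracer's target-to-whole-cerebellum
#' SUVr at 0 and 100 CL of true amyloid load.  `wm_uptake_base` is the
#' white-matter to whole-cerebellum intensity ratio at age 70 and
#' `wm_age_slope` its per-year change; the 18F profiles differ mainly in
#' white-matter behaviour, ordered FBB > FBP > FMM in age sensitivity so the
#' pons-referenced bias pattern across tracers has the observed ordering.
#' `noise_sd` is the per-region multiplicative noise SD.
#'
#' @return Tibble with columns `name`, `suvr_yc`, `suvr_ad100`,
#'   `wm_uptake_base`, `wm_age_slope`, `noise_sd`.
#' @export
tracer_profiles <- function() {
  tibble::tribble(
    ~name,  ~suvr_yc, ~suvr_ad100, ~wm_uptake_base, ~wm_age_slope, ~noise_sd,
    "PiB",  1.05,     2.08,        1.70,            0.000,         0.015,
    "FMM",  1.00,     1.61,        2.20,            0.004,         0.015,
    "FBB",  1.00,     1.76,        2.00,            0.020,         0.015,
    "FBP",  1.00,     1.67,        1.80,            0.010,         0.015
  )
}

#' Look up (and validate) one tracer profile
#'
#' @param name Tracer name (`"PiB"`, `"FMM"`, `"FBB"`, `"FBP"`) or a one-row
#'   data frame with the profile columns.
#' @param profiles Profile table, defaults to [tracer_profiles()].
#' @return One-row tibble.
#' @export
tracer_profile <- function(name, profiles = tracer_profiles()) {
  prof <- if (is.data.frame(name)) tibble::as_tibble(name) else profiles[profiles$name == name, ]
  if (nrow(prof) != 1L) {
    stop_cl("argument_error", paste0("unknown tracer: ", name))
  }
  if (!(prof$suvr_ad100 > prof$suvr_yc && prof$suvr_yc > 0)) {
    stop_cl("model_parameter_error", "tracer profile requires suvr_ad100 > suvr_yc > 0")
  }
  if (prof$noise_sd < 0) {
    stop_cl("model_parameter_error", "noise_sd must be >= 0")
  }
  prof
}
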