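# Centiloid calibration: anchor fitting, the linear SUVr -> CL transform,
# level-2 tracer-to-PiB conversion, and standard validation criteria.

#' Fit Centiloid anchors from calibration groups
#'
#' Stores the young-control (0 CL) and typical-AD (100 CL) group mean SUVr,
#' which define the Centiloid scale for one tracer/pipeline.
#'
#' @param yc_suvrs,ad_suvrs Non-empty numeric vectors of group SUVr values.
#' @return An object of class `cl_anchors` with `suvr_yc_mean`,
#'   `suvr_ad_mean`.
#' @export
fit_anchors <- function(yc_suvrs, ad_suvrs) {
  if (!length(yc_suvrs) || !length(ad_suvrs)) {
    stop_cl("calibration_error", "both calibration groups must be non-empty")
  }
  yc <- mean(yc_suvrs)
  ad <- mean(ad_suvrs)
  if (!(ad > yc)) {
    stop_cl("calibration_error", "AD-group mean SUVr must exceed the young-control mean")
  }
  structure(list(suvr_yc_mean = yc, suvr_ad_mean = ad), class = "cl_anchors")
}

#' Convert SUVr to Centiloids
#'
#' The standard linear transform: `100 * (suvr - yc) / (ad - yc)`, anchored
#' at the young-control mean (0 CL) and typical-AD mean (100 CL).
#'
#' @param suvr Numeric vector of SUVr values.
#' @param anchors A [fit_anchors()] object.
#' @return CL values (same length as `suvr`).
#' @export
suvr_to_cl <- function(suvr, anchors) {
  stopifnot(inherits(anchors, "cl_anchors"))
  100 * (suvr - anchors$suvr_yc_mean) / (anchors$suvr_ad_mean - anchors$suvr_yc_mean)
}

#' Fit the level-2 tracer conversion
#'
#' Ordinary least squares of PiB SUVr on tracer SUVr from paired calibration
#' scans; downstream Centiloid conversion maps tracer SUVr to PiB-equivalent
#' SUVr through this line before applying the PiB anchors.
#'
#' @param tracer_suvrs,pib_suvrs Paired numeric vectors (>= 3 pairs).
#' @return An object of class `cl_conversion` with `slope`, `intercept`,
#'   `r2`, `n_pairs`.
#' @export
fit_level2 <- function(tracer_suvrs, pib_suvrs) {
  if (length(tracer_suvrs) != length(pib_suvrs)) {
    stop_cl("fit_error", "paired SUVr vectors must have equal length")
  }
  if (length(tracer_suvrs) < 3L) {
    stop_cl("fit_error", "level-2 calibration needs at least 3 pairs")
  }
  if (stats::var(tracer_suvrs) == 0) {
    stop_cl("fit_error", "tracer SUVr has zero variance; cannot fit a conversion line")
  }
  fit <- stats::lm(pib_suvrs ~ tracer_suvrs)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pib_suvrs - mean(pib_suvrs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r2, n_pairs = length(tracer_suvrs)),
    class = "cl_conversion"
  )
}

#' Validate a fitted conversion against the standard criteria
#'
#' Named pass/fail checks mirroring the standard Centiloid calibration
#' acceptance rules: determination coefficient above threshold, positive
#' slope, minimum pair count.  Failures are reported, never raised.
#'
#' @param eq A [fit_level2()] object.
#' @param r2_min Minimum R-squared (default 0.70).
#' @param n_min Minimum number of pairs (default 3).
#' @return An object of class `cl_calibration_report` with `criteria`
#'   (named logical) and `overall`.
#' @export
validate_calibration <- function(eq, r2_min = 0.70, n_min = 3L) {
  stopifnot(inherits(eq, "cl_conversion"))
  criteria <- c(
    r2_above_threshold = eq$r2 > r2_min,
    positive_slope = eq$slope > 0,
    enough_pairs = eq$n_pairs >= n_min
  )
  structure(
    list(criteria = criteria, overall = all(criteria),
         thresholds = list(r2_min = r2_min, n_min = n_min)),
    class = "cl_calibration_report"
  )
}

# Quantify one noise-free calibration image under every pipeline.  The
# calibration subjects are idealised: no atrophy, no rigid misalignment, so
# native and MNI grids coincide and the subject masks equal the template
# tissue masks.
calibration_suvrs <- function(true_cl, age, tracer, template, pipelines, fwhm,
                              background_uptake = 0.3) {
  params <- list(true_cl = true_cl, age = age, tracer = tracer$name, atrophy = 1)
  noise_free <- tracer
  noise_free$noise_sd <- 0
  labels <- template
  img <- simulate_uptake(labels, params, noise_free, background_uptake = background_uptake)
  img <- apply_psf(img, fwhm)
  tm <- template_masks(template)
  sm <- subject_masks(labels)
  vapply(seq_len(nrow(pipelines)), function(q) {
    pl <- pipelines[q, ]
    rr_set <- if (pl$rr_type == "GAAIN") tm else sm
    t_set <- if (pl$t_type == "GAAIN") tm else sm
    compute_suvr(img, t_set$target, rr_set$rr[[pl$rr]])
  }, numeric(1))
}

#' Build the calibration bank
#'
#' Calibrates every (tracer, pipeline) combination against simulated
#' noise-free calibration groups: a young-control group at 0 CL (age 65) and
#' a typical-AD group at 100 CL (age 70), no atrophy, processed at the
#' harmonised resolution.  PiB anchors define the scale per pipeline; each
#' 18F tracer gets a level-2 PiB-on-tracer conversion line fitted on the
#' paired groups and validated against the standard criteria.
#'
#' @param template Template `label_map`.
#' @param pipelines Pipeline table (default all 32).
#' @param tracers Tracer profile table (must include `PiB`).
#' @param fwhm Effective resolution the calibration scans are processed at
#'   (default 8 mm; use 0 for ideal-resolution calibration).
#' @param n_group Nominal calibration group size (noise-free members are
#'   identical; the size enters the level-2 pair count).
#' @param yc_age,ad_age Ages of the calibration groups.
#' @param background_uptake Extracerebral intensity relative to WCB.
#' @return Tibble of class `cl_calibration_bank`: one row per (tracer,
#'   pipeline) with anchors, conversion line, validation results.
#' @export
build_calibration_bank <- function(template, pipelines = enumerate_pipelines(),
                                   tracers = tracer_profiles(), fwhm = 8,
                                   n_group = 5L, yc_age = 65, ad_age = 70,
                                   background_uptake = 0.3) {
  if (!"PiB" %in% tracers$name) {
    stop_cl("calibration_error", "the anchor tracer PiB must be in the profile table")
  }
  suvr_tab <- lapply(seq_len(nrow(tracers)), function(t) {
    tr <- tracers[t, ]
    list(
      yc = calibration_suvrs(0, yc_age, tr, template, pipelines, fwhm, background_uptake),
      ad = calibration_suvrs(100, ad_age, tr, template, pipelines, fwhm, background_uptake)
    )
  })
  names(suvr_tab) <- tracers$name
  pib <- suvr_tab[["PiB"]]

  rows <- purrr::map(tracers$name, function(tn) {
    purrr::map(seq_len(nrow(pipelines)), function(q) {
      anchors <- fit_anchors(rep(pib$yc[q], n_group), rep(pib$ad[q], n_group))
      if (tn == "PiB") {
        conv <- structure(list(slope = 1, intercept = 0, r2 = 1,
                               n_pairs = 2L * n_group), class = "cl_conversion")
      } else {
        conv <- fit_level2(
          c(rep(suvr_tab[[tn]]$yc[q], n_group), rep(suvr_tab[[tn]]$ad[q], n_group)),
          c(rep(pib$yc[q], n_group), rep(pib$ad[q], n_group))
        )
      }
      rep_ <- validate_calibration(conv)
      tibble::tibble(
        tracer = tn, pipeline_id = pipelines$pipeline_id[q],
        suvr_yc_mean = anchors$suvr_yc_mean, suvr_ad_mean = anchors$suvr_ad_mean,
        slope = conv$slope, intercept = conv$intercept, r2 = conv$r2,
        n_pairs = conv$n_pairs, overall = rep_$overall,
        provenance = "simulated"
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  class(rows) <- c("cl_calibration_bank", class(rows))
  rows
}

#' Convert measured SUVr to Centiloids through the bank
#'
#' Applies the tracer's level-2 conversion to PiB-equivalent SUVr, then the
#' pipeline's PiB anchors.  Vectorised over measurements.
#'
#' @param suvr,tracer,pipeline_id Parallel vectors of measurements.
#' @param bank A [build_calibration_bank()] table.
#' @return CL values.
#' @export
cl_from_suvr <- function(suvr, tracer, pipeline_id, bank) {
  key <- paste(tracer, pipeline_id)
  idx <- match(key, paste(bank$tracer, bank$pipeline_id))
  if (anyNA(idx)) {
    stop_cl("configuration_error", paste0(
      "no calibration for: ", paste(utils::head(unique(key[is.na(idx)]), 5), collapse = "; ")
    ))
  }
  pib_eq <- bank$slope[idx] * suvr + bank$intercept[idx]
  100 * (pib_eq - bank$suvr_yc_mean[idx]) /
    (bank$suvr_ad_mean[idx] - bank$suvr_yc_mean[idx])
}

#' Persist / load a calibration bank as JSON
#'
#' @param bank A calibration bank tibble.
#' @param path File path.
#' @return `read_calibration_bank()` returns the bank tibble.
#' @export
write_calibration_bank <- function(bank, path) {
  jsonlite::write_json(as.data.frame(bank), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_calibration_bank
#' @export
read_calibration_bank <- function(path) {
  rows <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(rows) <- c("cl_calibration_bank", class(rows))
  rows
}
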