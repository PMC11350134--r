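# SUVr extraction and cohort-level quantification across pipelines.

#' Compute a standard uptake value ratio
#'
#' Mean intensity in the target mask divided by the mean intensity in the
#' reference-region mask, both on the image grid.
#'
#' @param img A `volume_image` (or plain 3-D array).
#' @param target_mask,rr_mask Logical arrays on the image grid.
#' @return SUVr (dimensionless scalar).
#' @export
compute_suvr <- function(img, target_mask, rr_mask) {
  grid <- if (inherits(img, "volume_image")) img$grid else img
  if (!identical(dim(grid), dim(target_mask)) || !identical(dim(grid), dim(rr_mask))) {
    stop_cl("alignment_error", "mask grids do not match the image grid")
  }
  if (!any(target_mask) || !any(rr_mask)) {
    stop_cl("mask_error", "empty target or reference-region mask")
  }
  rr_mean <- mean(grid[rr_mask])
  if (rr_mean <= 0) {
    stop_cl("measurement_error", "reference-region mean is not positive")
  }
  mean(grid[target_mask]) / rr_mean
}

# Precompute, for one subject and one image version, everything needed to
# quantify all pipelines: images and mask sets in both spaces.
prepare_subject_spaces <- function(img, subj, cohort) {
  tm <- cohort$template_masks
  sm <- subject_masks(subj$labels)
  mni <- to_quant_space(img, sm, "MNI", subj$affine, cohort$template)
  nat <- to_quant_space(img, tm, "native", subj$affine, cohort$template)
  list(
    img = list(MNI = mni$img$grid, native = img$grid),
    masks = list(
      MNI = list(GAAIN = tm, subject = mni$masks),
      native = list(GAAIN = nat$masks, subject = sm)
    )
  )
}

#' Quantify a cohort across pipelines
#'
#' Runs every requested pipeline on every subject and image version and
#' converts SUVr to Centiloids through the calibration bank, producing the
#' tidy long measurement table that all statistics operate on.  A subject
#' with both original and harmonised images contributes
#' `2 * nrow(pipelines)` rows (64 for the full factorial); harmonised-only
#' subjects contribute `nrow(pipelines)` rows.
#'
#' @param cohort A `cl_cohort` from [generate_cohort()].
#' @param pipelines Pipeline table from [enumerate_pipelines()].
#' @param calib_bank Calibration bank from [build_calibration_bank()].
#' @return Long tibble with columns `subject_id, tracer, diagnosis, age,
#'   atrophy, true_cl, native_fwhm, harmonized, rr, rr_type, t_type, space,
#'   pipeline_id, suvr, cl, group`.
#' @export
quantify_cohort <- function(cohort, pipelines = enumerate_pipelines(),
                            calib_bank) {
  stopifnot(inherits(cohort, "cl_cohort"))
  if (nrow(pipelines) == 0L) {
    return(empty_long_table())
  }
  needed <- unique(paste(cohort$subjects$tracer, pipelines$pipeline_id))
  have <- paste(calib_bank$tracer, calib_bank$pipeline_id)
  if (!all(needed %in% have)) {
    stop_cl("configuration_error", paste0(
      "missing calibration for: ",
      paste(utils::head(setdiff(needed, have), 5), collapse = "; ")
    ))
  }

  rows <- purrr::map(seq_len(nrow(cohort$subjects)), function(i) {
    p <- cohort$subjects[i, ]
    subj <- cohort$data[[p$subject_id]]
    versions <- list()
    if (!is.null(subj$original)) versions$original <- subj$original
    versions$harmonized <- subj$harmonized

    purrr::imap(versions, function(img, vname) {
      spaces <- prepare_subject_spaces(img, subj, cohort)
      suvr <- vapply(seq_len(nrow(pipelines)), function(q) {
        pl <- pipelines[q, ]
        ms <- spaces$masks[[pl$space]][[pl$rr_type]]
        tms <- spaces$masks[[pl$space]][[pl$t_type]]
        compute_suvr(spaces$img[[pl$space]], tms$target, ms$rr[[pl$rr]])
      }, numeric(1))
      dplyr::bind_cols(
        p[rep(1L, nrow(pipelines)), ],
        tibble::tibble(harmonized = vname == "harmonized"),
        pipelines,
        tibble::tibble(suvr = suvr)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  rows$cl <- cl_from_suvr(rows$suvr, rows$tracer, rows$pipeline_id, calib_bank)
  dplyr::select(
    rows, "subject_id", "tracer", "diagnosis", "age", "atrophy", "true_cl",
    "native_fwhm", "harmonized", "rr", "rr_type", "t_type", "space",
    "pipeline_id", "suvr", "cl", "group"
  )
}

empty_long_table <- function() {
  tibble::tibble(
    subject_id = character(), tracer = character(), diagnosis = character(),
    age = numeric(), atrophy = numeric(), true_cl = numeric(),
    native_fwhm = numeric(), harmonized = logical(), rr = character(),
    rr_type = character(), t_type = character(), space = character(),
    pipeline_id = character(), suvr = numeric(), cl = numeric(),
    group = character()
  )
}
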