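# Reference-region and cortical-target mask construction, and movement of
# images/masks between the quantification spaces.

RR_NAMES <- c("WCB", "CGM", "Pons", "WCB_BSTM")

masks_from_labels <- function(labels, dilate_target) {
  lb <- cl_labels()
  cgm <- labels$grid == lb[["cerebellar_GM"]]
  cwm <- labels$grid == lb[["cerebellar_WM"]]
  pons <- labels$grid == lb[["brainstem_pons"]]
  target <- labels$grid == lb[["cortical_target_GM"]]
  if (dilate_target) {
    # one-voxel dilation into cerebral WM: emulates a template cortical ROI
    # overlapping white matter
    wm <- labels$grid == lb[["cerebral_WM"]]
    shell <- wm & boundary_voxels(!target)
    target <- target | shell
  }
  list(
    rr = list(WCB = cgm | cwm, CGM = cgm, Pons = pons, WCB_BSTM = cgm | cwm | pons),
    target = target
  )
}

validate_mask_set <- function(m, what) {
  empties <- c(
    names(m$rr)[!vapply(m$rr, any, logical(1))],
    if (!any(m$target)) "target"
  )
  if (length(empties)) {
    stop_cl("mask_error", paste0(what, " mask(s) empty: ", paste(empties, collapse = ", ")))
  }
  m
}

#' GAAIN-style template masks
#'
#' Fixed masks derived once from the template labels: WCB = cerebellar grey
#' plus cerebellar white; CGM = cerebellar grey; Pons = brainstem; WCB_BSTM =
#' WCB plus brainstem.  The GAAIN-style cortical target is the template
#' cortical grey dilated by one voxel into white matter, emulating a template
#' ROI that overlaps WM.
#'
#' @param template Template `label_map`.
#' @return A `mask_set`: list of binary reference-region masks, a target
#'   mask, and provenance `"GAAIN"`.
#' @export
template_masks <- function(template) {
  stopifnot(inherits(template, "label_map"))
  m <- validate_mask_set(masks_from_labels(template, dilate_target = TRUE), "template")
  structure(c(m, list(provenance = "GAAIN", voxel_size = template$voxel_size)),
            class = "mask_set")
}

#' Subject-based masks
#'
#' Masks taken from the subject's own label map without dilation: exact
#' individual tissue delineation.
#'
#' @param subject_labels Subject `label_map`.
#' @return A `mask_set` with provenance `"subject"`.
#' @export
subject_masks <- function(subject_labels) {
  stopifnot(inherits(subject_labels, "label_map"))
  m <- validate_mask_set(masks_from_labels(subject_labels, dilate_target = FALSE), "subject")
  structure(c(m, list(provenance = "subject", voxel_size = subject_labels$voxel_size)),
            class = "mask_set")
}

resample_mask_set <- function(masks, dst_dim, vox_map) {
  out <- masks
  out$rr <- lapply(masks$rr, function(m) {
    resample_array(m + 0, dst_dim, vox_map, method = "nearest") > 0.5
  })
  out$target <- resample_array(masks$target + 0, dst_dim, vox_map, method = "nearest") > 0.5
  validate_mask_set(out, paste0(masks$provenance, " (resampled)"))
}

#' Move an image and mask set into the quantification space
#'
#' MNI space: the image is resampled onto the template grid through the
#' recorded subject -> template rigid transform (trilinear); masks that are
#' already template-defined stay put, subject-defined masks are resampled to
#' the template grid (nearest-neighbour).  Native space: the image is
#' untouched and template-defined masks are resampled onto the subject grid
#' (nearest-neighbour).
#'
#' @param img Subject-space `volume_image`.
#' @param masks A `mask_set` (template- or subject-provenance).
#' @param space `"MNI"` or `"native"`.
#' @param affine 4x4 subject -> template world rigid transform.
#' @param template Template `label_map` (defines the MNI grid).
#' @return List with `img` and `masks` on a common grid.
#' @export
to_quant_space <- function(img, masks, space = c("MNI", "native"), affine,
                           template) {
  space <- match.arg(space)
  stopifnot(inherits(img, "volume_image"), inherits(masks, "mask_set"))
  if (space == "MNI") {
    vm <- vox_map_to_template(img$affine, template$affine, affine)
    out_img <- img
    out_img$grid <- resample_array(img$grid, dim(template$grid), vm, method = "trilinear")
    out_img$affine <- template$affine
    out_masks <- if (masks$provenance == "GAAIN") masks else
      resample_mask_set(masks, dim(template$grid), vm)
    list(img = out_img, masks = out_masks)
  } else {
    out_masks <- if (masks$provenance == "subject") masks else {
      vm <- vox_map_to_template(template$affine, img$affine, affine, inverse = TRUE)
      resample_mask_set(masks, dim(img$grid), vm)
    }
    list(img = img, masks = out_masks)
  }
}
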