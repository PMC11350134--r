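# Subject morphing: global grey-matter atrophy by boundary erosion, plus a
# small rigid misalignment recording the subject -> template transform.

# Voxels of `comp` (logical array) with at least one 6-neighbour outside it.
boundary_voxels <- function(comp) {
  d <- dim(comp)
  interior <- comp
  shift <- function(arr, axis, by) {
    out <- array(FALSE, d)
    n <- d[axis]
    idx_src <- if (by > 0) 2:n else 1:(n - 1)
    idx_dst <- if (by > 0) 1:(n - 1) else 2:n
    if (axis == 1) out[idx_dst, , ] <- arr[idx_src, , ]
    if (axis == 2) out[, idx_dst, ] <- arr[, idx_src, ]
    if (axis == 3) out[, , idx_dst] <- arr[, , idx_src]
    out
  }
  for (axis in 1:3) for (by in c(1L, -1L)) {
    interior <- interior & shift(comp, axis, by)
  }
  comp & !interior
}

#' Morph the template into an individual subject
#'
#' Emulates global grey-matter atrophy by eroding each grey-matter
#' compartment (cortical target, deep grey, cerebellar grey) from its
#' boundary until the retained grey-matter fraction matches
#' `params$atrophy`; eroded voxels become background (CSF).  `atrophy` is the
#' grey-matter volume retained relative to the template, i.e. the subject's
#' GM/TIV normalised to the template's GM/TIV (the intracranial volume is
#' fixed).  A small random rigid transform (seeded) records the subject ->
#' template alignment.
#'
#' @param template Template `label_map` from [build_template()].
#' @param params One-row subject parameter data frame (or list) with at least
#'   `atrophy` in (0, 1].
#' @param seed Integer seed for the erosion order and rigid jitter.
#' @param jitter_translation_sd Rigid jitter translation SD in mm (0 disables).
#' @param jitter_rotation_sd Rigid jitter rotation SD in degrees (0 disables).
#' @return List with `labels` (subject `label_map`) and `affine` (4x4
#'   subject -> template world rigid transform).
#' @export
morph_subject <- function(template, params, seed = 1L,
                          jitter_translation_sd = 0.5,
                          jitter_rotation_sd = 0.5) {
  stopifnot(inherits(template, "label_map"))
  a <- params$atrophy
  if (!is_scalar_number(a) || a <= 0 || a > 1) {
    stop_cl("argument_error", "atrophy must lie in (0, 1]")
  }
  if (a < 0.05) {
    stop_cl("degenerate_subject",
            sprintf("atrophy %.3f leaves no viable grey matter", a))
  }

  with_seed_cl(seed, {
    grid <- template$grid
    lb <- cl_labels()
    if (a < 1) {
      for (comp_name in GM_LABELS) {
        code <- lb[[comp_name]]
        comp <- grid == code
        n0 <- sum(comp)
        target_n <- round(a * n0)
        if (target_n < 1L) {
          stop_cl("degenerate_subject",
                  sprintf("compartment %s empties at atrophy %.3f", comp_name, a))
        }
        need <- n0 - target_n
        while (need > 0L) {
          b_idx <- which(boundary_voxels(comp))
          if (length(b_idx) == 0L) {
            stop_cl("degenerate_subject",
                    sprintf("compartment %s disintegrated during erosion", comp_name))
          }
          take <- if (length(b_idx) <= need) b_idx else sample(b_idx, need)
          comp[take] <- FALSE
          grid[take] <- lb[["background"]]
          need <- need - length(take)
        }
        if (sum(comp) == 0L) {
          stop_cl("degenerate_subject",
                  sprintf("compartment %s is empty after erosion", comp_name))
        }
      }
    }
    affine <- if (jitter_translation_sd > 0 || jitter_rotation_sd > 0) {
      make_rigid(
        angles = stats::rnorm(3, 0, jitter_rotation_sd) * pi / 180,
        translation = stats::rnorm(3, 0, jitter_translation_sd)
      )
    } else {
      diag(4)
    }
    list(labels = new_label_map(grid, template$voxel_size), affine = affine)
  })
}

#' Realised grey-matter fraction of a subject relative to the template
#'
#' @param subject_labels,template Subject and template `label_map`s.
#' @return Retained GM voxel fraction (1 for an unatrophied subject).
#' @export
realized_atrophy <- function(subject_labels, template) {
  gm_voxel_count(subject_labels) / gm_voxel_count(template)
}
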