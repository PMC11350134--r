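# Digital brain phantom: tissue geometry and label maps.
#
# The phantom replaces real anatomy with nested ellipsoids that preserve the
# adjacency relations driving partial-volume spill-in: a cortical grey-matter
# ribbon over a cerebral white-matter core (with a deep grey nucleus inside),
# a cerebellum with a grey shell over a white core, and a pons/brainstem
# column touching both the cerebellum and the cerebral white matter.

#' Tissue labels used by the phantom
#'
#' Integer codes for the seven tissue compartments of the label map.
#' @return Named integer vector.
#' @export
cl_labels <- function() {
  c(
    background = 0L, cortical_target_GM = 1L, other_GM = 2L, cerebral_WM = 3L,
    cerebellar_GM = 4L, cerebellar_WM = 5L, brainstem_pons = 6L
  )
}

GM_LABELS <- c("cortical_target_GM", "other_GM", "cerebellar_GM")

#' Phantom specification
#'
#' Defines the voxel grid and the tissue geometry of the digital phantom.
#' Geometry defaults scale with the grid so the same relative anatomy is
#' produced at any resolution.
#'
#' @param grid_shape Integer triple, voxels per axis (each >= 32).
#' @param voxel_size Isotropic voxel size in mm (> 0).
#' @param geometry Geometry list as produced by [default_geometry()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L), voxel_size = 2,
                         geometry = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L)) {
    stop_cl("geometry_error", "grid_shape must be three integers, each >= 32")
  }
  if (!is_scalar_number(voxel_size) || voxel_size <= 0) {
    stop_cl("geometry_error", "voxel_size must be a positive number")
  }
  if (is.null(geometry)) {
    geometry <- default_geometry(min(grid_shape) * voxel_size / 2)
  }
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size, geometry = geometry),
    class = "phantom_spec"
  )
}

#' Default phantom geometry
#'
#' All coordinates are world mm relative to the grid centre; `half_extent` is
#' half the shortest grid extent, so the anatomy keeps a fixed relative margin
#' from the grid boundary (needed so smoothing does not push signal off-grid).
#'
#' @param half_extent Half the shortest grid extent in mm.
#' @return Geometry list with ellipsoid/cylinder parameters per compartment.
#' @export
default_geometry <- function(half_extent) {
  r <- half_extent
  list(
    cerebrum_center = c(0, 0, 0.25) * r,
    cerebrum_semi = c(0.66, 0.72, 0.52) * r,
    cerebral_wm_scale = 0.72,
    deep_gm_semi = c(0.20, 0.22, 0.16) * r,
    cerebellum_center = c(0, -0.30, -0.42) * r,
    cerebellum_semi = c(0.42, 0.32, 0.26) * r,
    cerebellar_wm_scale = 0.62,
    pons_center_xy = c(0, 0.05) * r,
    pons_radius = 0.14 * r,
    pons_z = c(-0.55, 0.05) * r
  )
}

inside_ellipsoid <- function(x, y, z, center, semi) {
  ((x - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 +
    ((z - center[3]) / semi[3])^2 <= 1
}

#' Build the template label map
#'
#' Deterministically paints the phantom compartments onto the voxel grid.
#' Every reference region used by the Centiloid pipelines (whole cerebellum,
#' cerebellar grey, pons, whole cerebellum + brainstem) is non-empty in a
#' valid template.
#'
#' @param spec A [phantom_spec()].
#' @return A `label_map`: list with integer array `grid`, `voxel_size`,
#'   `affine` (voxel-index to world mm).
#' @export
build_template <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size
  g <- spec$geometry
  lb <- cl_labels()

  iv <- grid_index_vectors(d)
  x <- (iv$i - (d[1] + 1) / 2) * vs
  y <- (iv$j - (d[2] + 1) / 2) * vs
  z <- (iv$k - (d[3] + 1) / 2) * vs

  lab <- integer(prod(d))

  cer <- inside_ellipsoid(x, y, z, g$cerebrum_center, g$cerebrum_semi)
  wm <- inside_ellipsoid(x, y, z, g$cerebrum_center, g$cerebrum_semi * g$cerebral_wm_scale)
  deep <- inside_ellipsoid(x, y, z, g$cerebrum_center, g$deep_gm_semi)
  lab[cer] <- lb[["cortical_target_GM"]]
  lab[wm] <- lb[["cerebral_WM"]]
  lab[deep] <- lb[["other_GM"]]

  cb <- inside_ellipsoid(x, y, z, g$cerebellum_center, g$cerebellum_semi)
  cbwm <- inside_ellipsoid(x, y, z, g$cerebellum_center, g$cerebellum_semi * g$cerebellar_wm_scale)
  lab[cb] <- lb[["cerebellar_GM"]]
  lab[cbwm] <- lb[["cerebellar_WM"]]

  pons <- (x - g$pons_center_xy[1])^2 + (y - g$pons_center_xy[2])^2 <= g$pons_radius^2 &
    z >= g$pons_z[1] & z <= g$pons_z[2]
  lab[pons] <- lb[["brainstem_pons"]]

  grid <- array(lab, dim = d)

  # every compartment present (a zero-radius pons, say, is a geometry error)
  missing <- setdiff(lb, sort(unique(lab)))
  if (length(missing)) {
    stop_cl("geometry_error", paste0(
      "empty compartment(s): ",
      paste(names(lb)[match(missing, lb)], collapse = ", ")
    ))
  }
  # anatomy must not touch the grid boundary
  edge <- c(
    grid[c(1, d[1]), , ], grid[, c(1, d[2]), ], grid[, , c(1, d[3])]
  )
  if (any(edge != lb[["background"]])) {
    stop_cl("geometry_error", "compartment reaches the grid boundary; enlarge the grid")
  }

  new_label_map(grid, vs)
}

new_label_map <- function(grid, voxel_size) {
  structure(
    list(grid = grid, voxel_size = voxel_size,
         affine = grid_affine(dim(grid), voxel_size)),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  counts <- table(factor(x$grid, levels = cl_labels(), labels = names(cl_labels())))
  cat("<label_map> ", paste(dim(x$grid), collapse = " x "),
      " voxels @ ", x$voxel_size, " mm\n", sep = "")
  print(counts)
  invisible(x)
}

# Logical array marking one named compartment.
label_region <- function(labels, name) {
  labels$grid == cl_labels()[[name]]
}

# GM voxel count (cortical target + deep + cerebellar GM).
gm_voxel_count <- function(labels) {
  sum(labels$grid %in% cl_labels()[GM_LABELS])
}
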