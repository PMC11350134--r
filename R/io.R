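# File formats: the long measurement table (CSV), NIfTI volumes, and the
# report exporter.

LONG_TABLE_REQUIRED <- c(
  "subject_id", "tracer", "diagnosis", "age", "atrophy", "true_cl",
  "native_fwhm", "harmonized", "rr", "rr_type", "t_type", "space",
  "pipeline_id", "suvr", "cl", "group"
)

#' Write / read the long measurement table
#'
#' CSV with the documented header.  Reading validates the required columns
#' and types, preserves unknown columns untouched, and rejects duplicate
#' (subject, pipeline, harmonisation) keys.
#'
#' @param table Long table tibble.
#' @param path CSV file path.
#' @return `read_long_table()` returns the validated tibble.
#' @export
write_long_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_long_table
#' @export
read_long_table <- function(path) {
  if (!file.exists(path)) stop_cl("io_error", paste0("no such file: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(LONG_TABLE_REQUIRED, names(tab))
  if (length(missing)) {
    stop_cl("io_error", paste0(
      "long table is missing required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  num_cols <- c("age", "atrophy", "true_cl", "native_fwhm", "suvr", "cl")
  for (v in num_cols) {
    if (!is.numeric(tab[[v]])) {
      stop_cl("io_error", paste0("column ", v, " must be numeric"))
    }
  }
  if (!is.logical(tab$harmonized)) {
    stop_cl("io_error", "column harmonized must be logical (TRUE/FALSE)")
  }
  key <- paste(tab$subject_id, tab$pipeline_id, tab$harmonized)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop_cl("duplicate_key", paste0(
      "duplicate (subject, pipeline, harmonized) key(s): ",
      paste(utils::head(unique(dup), 3), collapse = "; ")
    ))
  }
  tab
}

#' Write / read a volume as NIfTI-1
#'
#' World coordinates in mm with the affine stored in the header (sform).
#'
#' @param vol A `volume_image` or `label_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param effective_fwhm Effective resolution to attach on read (mm).
#' @return `read_volume()` returns a `volume_image`.
#' @export
write_volume <- function(vol, path) {
  grid <- vol$grid
  if (inherits(vol, "label_map")) storage.mode(grid) <- "integer"
  img <- RNifti::asNifti(grid)
  # RNifti xforms map 0-based voxel indices; ours map 1-based
  aff <- vol$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(1, 3)
  RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::pixdim(img) <- rep(vol$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, effective_fwhm = 0) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  volume_image(array(as.vector(img), dim = dim(img)), vs,
               effective_fwhm = effective_fwhm)
}

format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-15, "<1e-15", formatC(p, format = "g", digits = 3)))
}

#' Export analysis results to deterministic files
#'
#' Writes whichever result components are present: Wald tables
#' (`wald_table.csv`), marginal means (`marginal_means.csv`), pairwise
#' deltas (`deltas.csv`), precision results (`precision.csv`), agreement
#' stats (`agreement.csv`), the calibration bank
#' (`calibration_bank.json`) and the long table (`long_table.csv`).
#' File names are fixed so re-export is idempotent.
#'
#' @param results Named list; recognised names: `wald`, `marginal_means`,
#'   `deltas`, `precision`, `agreement`, `calibration_bank`, `long_table`.
#'   Tables may be single tibbles or named lists of tibbles (bound with a
#'   `set` column).
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of written paths.
#' @export
export_report <- function(results, dir) {
  known <- c("wald", "marginal_means", "deltas", "precision", "agreement",
             "calibration_bank", "long_table")
  present <- intersect(names(results), known)
  if (!length(present)) stop_cl("io_error", "no results to export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  bind_sets <- function(x) {
    if (is.data.frame(x)) return(tibble::as_tibble(x))
    dplyr::bind_rows(purrr::imap(x, function(tab, nm) {
      dplyr::mutate(tibble::as_tibble(tab), set = nm, .before = 1)
    }))
  }
  written <- character()
  emit <- function(tab, name) {
    p <- file.path(dir, name)
    readr::write_csv(tab, p)
    written <<- c(written, p)
  }
  if ("wald" %in% present) {
    tab <- bind_sets(results$wald)
    tab$p_display <- format_p(tab$p.value)
    emit(tab, "wald_table.csv")
  }
  if ("marginal_means" %in% present) emit(bind_sets(results$marginal_means), "marginal_means.csv")
  if ("deltas" %in% present) emit(bind_sets(results$deltas), "deltas.csv")
  if ("precision" %in% present) emit(bind_sets(results$precision), "precision.csv")
  if ("agreement" %in% present) emit(bind_sets(results$agreement), "agreement.csv")
  if ("long_table" %in% present) {
    emit(results$long_table, "long_table.csv")
  }
  if ("calibration_bank" %in% present) {
    p <- file.path(dir, "calibration_bank.json")
    write_calibration_bank(results$calibration_bank, p)
    written <- c(written, p)
  }
  invisible(written)
}
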