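# The factorial family of Centiloid quantification pipelines.

#' Enumerate the 32 Centiloid quantification pipelines
#'
#' Full factorial of reference region (WCB, CGM, Pons, WCB_BSTM), reference
#' region type (GAAIN template vs subject-based), cortical target type
#' (GAAIN vs subject-based) and quantification space (MNI vs native), in
#' deterministic lexicographic order.
#'
#' @param rr,rr_type,t_type,space Optional subsets of factor levels to
#'   restrict the factorial.
#' @return Tibble with columns `rr`, `rr_type`, `t_type`, `space`,
#'   `pipeline_id`.
#' @export
enumerate_pipelines <- function(rr = c("WCB", "CGM", "Pons", "WCB_BSTM"),
                                rr_type = c("GAAIN", "subject"),
                                t_type = c("GAAIN", "subject"),
                                space = c("MNI", "native")) {
  rr <- match.arg(rr, several.ok = TRUE)
  rr_type <- match.arg(rr_type, several.ok = TRUE)
  t_type <- match.arg(t_type, several.ok = TRUE)
  space <- match.arg(space, several.ok = TRUE)
  grid <- tidyr::expand_grid(rr = rr, rr_type = rr_type, t_type = t_type, space = space)
  grid <- dplyr::arrange(grid, .data$rr, .data$rr_type, .data$t_type, .data$space)
  dplyr::mutate(grid, pipeline_id = paste(.data$rr, .data$rr_type, .data$t_type,
                                          .data$space, sep = "-"))
}

#' Identifier of the standard Centiloid pipeline
#'
#' The reference design: whole cerebellum, GAAIN reference-region and target
#' masks, MNI space.
#'
#' @return Character scalar `"WCB-GAAIN-GAAIN-MNI"`.
#' @export
standard_pipeline_id <- function() "WCB-GAAIN-GAAIN-MNI"
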