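# Bias analyses on the long measurement table: amyloid stratification and
# the age / atrophy correlation analyses.

#' Stratify a long table by amyloid positivity
#'
#' Each subject is assigned wholly to one stratum by their standard-pipeline
#' Centiloid (harmonised scan): positive iff CL > cutoff (strictly).
#'
#' @param table Long measurement table.
#' @param cutoff Positivity cutoff in CL (default 24).
#' @param pipeline Pipeline used for stratification (default the standard
#'   pipeline).
#' @param harmonized Use the harmonised measurement (default TRUE).
#' @return List with `negative` and `positive` tibbles (each gains a
#'   `stratum` column); together a partition of the input rows.
#' @export
stratify_amyloid <- function(table, cutoff = 24, pipeline = standard_pipeline_id(),
                             harmonized = TRUE) {
  std <- table[table$pipeline_id == pipeline & table$harmonized == harmonized, ]
  missing <- setdiff(unique(table$subject_id), std$subject_id)
  if (length(missing)) {
    stop_cl("stratification_error", paste0(
      "subjects missing the standard-pipeline record: ",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  status <- stats::setNames(ifelse(std$cl > cutoff, "positive", "negative"),
                            std$subject_id)
  table$stratum <- unname(status[table$subject_id])
  list(
    negative = tibble::as_tibble(table[table$stratum == "negative", ]),
    positive = tibble::as_tibble(table[table$stratum == "positive", ])
  )
}

# Subject-level CL difference between two settings of one design factor,
# holding every other design factor at the standard configuration.
subject_deltas <- function(table, factor, level_a, level_b,
                           harmonized = TRUE) {
  fixed <- list(rr = "WCB", rr_type = "GAAIN", t_type = "GAAIN", space = "MNI")
  fixed[[factor]] <- NULL
  keep <- table$harmonized == harmonized
  for (f in names(fixed)) keep <- keep & table[[f]] == fixed[[f]]
  sub <- table[keep, ]
  wide <- tidyr::pivot_wider(
    sub[, c("subject_id", "age", "atrophy", "diagnosis", "group", factor, "cl")],
    names_from = dplyr::all_of(factor), values_from = "cl"
  )
  wide$delta <- wide[[level_a]] - wide[[level_b]]
  wide[!is.na(wide$delta), ]
}

#' Age correlations of reference-region CL differences
#'
#' Spearman rank correlation between age and the subject-level CL
#' difference between two reference-region choices (other design factors at
#' the standard configuration), for each requested contrast.
#'
#' @param table Long table (typically one stratum).
#' @param contrasts List of RR pairs `c(a, b)`; delta = CL(a) - CL(b).
#' @param harmonized Use harmonised measurements (default TRUE).
#' @return Tibble with `contrast`, `rho`, `p.value`, `n`, `degenerate`.
#' @export
factor_age_correlations <- function(table,
                                    contrasts = list(c("WCB", "WCB_BSTM"),
                                                     c("WCB", "Pons"),
                                                     c("CGM", "WCB")),
                                    harmonized = TRUE) {
  rows <- purrr::map(contrasts, function(ct) {
    d <- subject_deltas(table, "rr", ct[1], ct[2], harmonized)
    if (nrow(d) < 3L) {
      stop_cl("insufficient_data",
              paste0("fewer than 3 subjects for contrast ", ct[1], "-", ct[2]))
    }
    if (stats::sd(d$delta) == 0 || stats::sd(d$age) == 0) {
      tibble::tibble(contrast = paste0(ct[1], "-", ct[2]), rho = 0,
                     p.value = NA_real_, n = nrow(d), degenerate = TRUE)
    } else {
      cr <- suppressWarnings(
        stats::cor.test(d$age, d$delta, method = "spearman", exact = FALSE)
      )
      tibble::tibble(contrast = paste0(ct[1], "-", ct[2]),
                     rho = unname(cr$estimate), p.value = cr$p.value,
                     n = nrow(d), degenerate = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Atrophy sensitivity of the cortical-target definition
#'
#' Pearson correlation between the retained grey-matter fraction and the
#' subject-level CL difference between subject-based and GAAIN cortical
#' targets (other factors at the standard configuration), plus the mean +/-
#' SD of that difference among dementia subjects (intended for the
#' amyloid-positive stratum).
#'
#' @param table Long table (typically the positive stratum).
#' @param harmonized Use harmonised measurements (default TRUE).
#' @return List with `r`, `p.value`, `n`, `degenerate`, and
#'   `dementia_subgroup` (tibble `mean`, `sd`, `n`; all-NA when empty).
#' @export
atrophy_target_analysis <- function(table, harmonized = TRUE) {
  d <- subject_deltas(table, "t_type", "subject", "GAAIN", harmonized)
  if (nrow(d) < 3L) {
    stop_cl("insufficient_data", "fewer than 3 subjects with both target types")
  }
  if (stats::sd(d$delta) == 0 || stats::sd(d$atrophy) == 0) {
    r <- 0; p <- NA_real_; degenerate <- TRUE
  } else {
    cr <- stats::cor.test(d$atrophy, d$delta, method = "pearson")
    r <- unname(cr$estimate); p <- cr$p.value; degenerate <- FALSE
  }
  dem <- d[d$diagnosis == "dementia", ]
  subgroup <- if (nrow(dem)) {
    tibble::tibble(mean = mean(dem$delta), sd = stats::sd(dem$delta), n = nrow(dem))
  } else {
    tibble::tibble(mean = NA_real_, sd = NA_real_, n = 0L)
  }
  list(r = r, p.value = p, n = nrow(d), degenerate = degenerate,
       dementia_subgroup = subgroup)
}
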