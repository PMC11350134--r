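# End-to-end orchestration: simulate -> calibrate -> quantify -> stratify ->
# bias models -> precision models -> export, with a reproducibility manifest.

#' Run configuration
#'
#' @param cohort A [cohort_config()].
#' @param pipelines `"all"` or a character vector of pipeline ids.
#' @param models Which bias models (1-4) to fit; the precision model always
#'   runs when both strata are populated.
#' @param calibration_fwhm Effective resolution of the calibration scans.
#' @param cutoff Amyloid-positivity cutoff in CL.
#' @param out_dir Output directory (NULL disables file export).
#' @param seed Root seed.
#' @return An object of class `cl_run_config`.
#' @export
run_config <- function(cohort = cohort_config(), pipelines = "all",
                       models = 1L, calibration_fwhm = 8, cutoff = 24,
                       out_dir = NULL, seed = 1L) {
  all_ids <- enumerate_pipelines()$pipeline_id
  if (!identical(pipelines, "all")) {
    bad <- setdiff(pipelines, all_ids)
    if (length(bad)) {
      stop_cl("configuration_error", paste0(
        "unknown pipeline id(s): ", paste(bad, collapse = ", ")
      ))
    }
  }
  if (!all(models %in% 1:4)) {
    stop_cl("configuration_error", "models must be a subset of 1:4")
  }
  structure(as.list(environment())[c("cohort", "pipelines", "models",
                                     "calibration_fwhm", "cutoff", "out_dir", "seed")],
            class = "cl_run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; the `cohort` mapping is
#' forwarded to [cohort_config()].
#'
#' @param path YAML file path.
#' @return A `cl_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$atrophy_by_diagnosis)) {
    cohort_args$atrophy_by_diagnosis <-
      lapply(cohort_args$atrophy_by_diagnosis, unlist)
  }
  for (nm in c("cl_negative", "cl_positive", "age", "diagnosis_mix", "tracer_mix")) {
    if (!is.null(cohort_args[[nm]])) cohort_args[[nm]] <- unlist(cohort_args[[nm]])
  }
  run_config(
    cohort = do.call(cohort_config, cohort_args),
    pipelines = y$pipelines %||% "all",
    models = as.integer(y$models %||% 1L),
    calibration_fwhm = y$calibration_fwhm %||% 8,
    cutoff = y$cutoff %||% 24,
    out_dir = y$out_dir,
    seed = as.integer(y$seed %||% 1L)
  )
}

run_stage <- function(name, quiet, expr) {
  t0 <- Sys.time()
  result <- tryCatch(expr, error = function(e) {
    stop_cl("stage_error", paste0("stage '", name, "' failed: ", conditionMessage(e)),
            stage = name, parent = e)
  })
  if (!quiet) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  result
}

#' Run the full stress-testing pipeline
#'
#' Executes simulate -> calibrate -> quantify -> stratify -> bias models ->
#' precision models, optionally exports all tables, and returns a manifest
#' recording the seed, configuration hash, and per-stage row counts.
#' Identical configuration and seed yield identical table hashes.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress stage logging (default FALSE).
#' @return List with `manifest`, `long_table`, `strata`, `bias`,
#'   `precision`, `agreement`, `calibration_bank`.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "cl_run_config"))
  pipelines <- enumerate_pipelines()
  if (!identical(cfg$pipelines, "all")) {
    pipelines <- pipelines[pipelines$pipeline_id %in% cfg$pipelines, ]
  }

  template <- run_stage("template", quiet, {
    build_template(phantom_spec(cfg$cohort$grid_shape, cfg$cohort$voxel_size))
  })
  bank <- run_stage("calibrate", quiet, {
    build_calibration_bank(template, enumerate_pipelines(),
                           fwhm = cfg$calibration_fwhm,
                           background_uptake = cfg$cohort$background_uptake)
  })
  cohort <- run_stage("simulate", quiet, {
    generate_cohort(cfg$cohort, seed = cfg$seed, template = template)
  })
  long_table <- run_stage("quantify", quiet, {
    quantify_cohort(cohort, pipelines, bank)
  })

  can_stratify <- standard_pipeline_id() %in% pipelines$pipeline_id
  strata <- bias <- precision <- agreement <- NULL

  if (can_stratify) {
    strata <- run_stage("stratify", quiet, {
      stratify_amyloid(long_table, cutoff = cfg$cutoff)
    })
    multi_factor <- nrow(pipelines) == nrow(enumerate_pipelines())
    if (multi_factor) {
      bias <- run_stage("bias", quiet, {
        purrr::imap(strata, function(tab, stratum) {
          if (length(unique(tab$subject_id)) < 3L) return(NULL)
          purrr::map(cfg$models, function(m) {
            sub <- if (m == 4L) {
              dual <- tab$subject_id %in% tab$subject_id[!tab$harmonized]
              tab[dual, ]
            } else {
              tab[tab$harmonized, ]
            }
            if (!nrow(sub)) return(NULL)
            fit <- fit_gee(sub, bias_model_spec(m))
            mm <- purrr::map(c("rr", "rr_type", "t_type", "space"),
                             ~ marginal_means(fit, .x))
            names(mm) <- c("rr", "rr_type", "t_type", "space")
            refs <- c(rr = "WCB", rr_type = "GAAIN", t_type = "GAAIN", space = "MNI")
            deltas <- purrr::imap(mm, ~ pairwise_deltas(.x, refs[[.y]]))
            list(model = m, fit = fit, wald = wald_type3(fit),
                 marginal_means = mm, deltas = deltas)
          }) |> stats::setNames(paste0("model", cfg$models))
        })
      })
      precision <- run_stage("precision", quiet, {
        res <- purrr::imap(strata, function(tab, stratum) {
          if (length(unique(tab$subject_id)) < 2L) return(NULL)
          variance_decomposition(tab, stratum = stratum)
        })
        if (!is.null(res$negative) && !is.null(res$positive)) {
          res$interpolated <- interpolate_ci(res$negative, res$positive,
                                             c(12, 24, seq(0, 100, 10)))
        }
        res
      })
      agreement <- run_stage("agreement", quiet, {
        std <- long_table[long_table$pipeline_id == standard_pipeline_id(), ]
        wide <- tidyr::pivot_wider(std[, c("subject_id", "harmonized", "cl")],
                                   names_from = "harmonized", values_from = "cl")
        dual <- wide[!is.na(wide$`FALSE`) & !is.na(wide$`TRUE`), ]
        if (nrow(dual) >= 3) {
          list(icc = icc_agreement(dual$`FALSE`, dual$`TRUE`),
               bland_altman = bland_altman(dual$`FALSE`, dual$`TRUE`))
        } else NULL
      })
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("centistress")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    n_pipelines = nrow(pipelines),
    n_subjects = nrow(cohort$subjects),
    n_rows = nrow(long_table),
    rows_per_dual_subject = 2L * nrow(pipelines),
    long_table_hash = rlang::hash(long_table),
    stratum_sizes = if (!is.null(strata)) {
      vapply(strata, function(s) length(unique(s$subject_id)), integer(1))
    }
  )

  if (!is.null(cfg$out_dir)) {
    run_stage("export", quiet, {
      results <- list(long_table = long_table, calibration_bank = bank)
      if (!is.null(bias)) {
        results$wald <- purrr::imap(bias, function(models, stratum) {
          dplyr::bind_rows(purrr::map(models, function(m) {
            if (is.null(m)) return(NULL)
            dplyr::mutate(m$wald, model = m$model, .before = 1)
          }))
        })
        results$deltas <- purrr::imap(bias, function(models, stratum) {
          m1 <- models[[1]]
          if (is.null(m1)) return(NULL)
          dplyr::bind_rows(purrr::imap(m1$deltas, function(d, f) {
            dplyr::mutate(d, factor = f, .before = 1)
          }))
        })
      }
      if (!is.null(precision)) {
        results$precision <- dplyr::bind_rows(
          precision[intersect(names(precision), c("negative", "positive"))]
        )
      }
      if (!is.null(agreement)) {
        icc_tab <- dplyr::rename(agreement$icc, n_pairs = "n")
        ba_tab <- dplyr::select(agreement$bland_altman$stats, -"n")
        results$agreement <- dplyr::bind_cols(icc_tab, ba_tab)
      }
      export_report(results, cfg$out_dir)
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    })
  }

  list(manifest = manifest, long_table = long_table, strata = strata,
       bias = bias, precision = precision, agreement = agreement,
       calibration_bank = bank, cohort = cohort)
}
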