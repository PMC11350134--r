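# Pipeline factory, masks, quantification spaces and SUVr extraction.

test_that("the pipeline factory spans the full factorial exactly once", {
  all32 <- enumerate_pipelines()
  expect_equal(nrow(all32), 32L)
  expect_equal(length(unique(all32$pipeline_id)), 32L)
  expect_true(standard_pipeline_id() %in% all32$pipeline_id)
  expect_equal(nrow(enumerate_pipelines(rr = "WCB")), 8L)
  # deterministic order
  expect_identical(all32$pipeline_id, sort(all32$pipeline_id))
})

test_that("template and subject masks satisfy the containment relations", {
  tpl <- template_32()
  tm <- template_masks(tpl)
  expect_identical(tm$provenance, "GAAIN")
  expect_true(all(tm$rr$CGM <= tm$rr$WCB))
  expect_gt(sum(tm$rr$WCB), sum(tm$rr$CGM))          # strict subset
  expect_true(all(tm$rr$WCB <= tm$rr$WCB_BSTM))
  expect_false(any(tm$rr$Pons & tm$rr$WCB))

  sm <- subject_masks(tpl)
  expect_identical(sm$provenance, "subject")
  # GAAIN target carries the one-voxel WM dilation; subject target does not
  expect_gt(sum(tm$target), sum(sm$target))
  lb <- cl_labels()
  extra <- tm$target & !sm$target
  expect_true(all(tpl$grid[extra] == lb[["cerebral_WM"]]))

  # an atrophied subject has strictly smaller grey-matter masks
  m08 <- morph_subject(tpl, list(atrophy = 0.8), seed = 2)
  sm08 <- subject_masks(m08$labels)
  expect_lt(sum(sm08$target), sum(sm$target))
  expect_lt(sum(sm08$rr$CGM), sum(sm$rr$CGM))
})

test_that("space handling is exact for identity and whole-voxel translations", {
  tpl <- template_32()
  tm <- template_masks(tpl)
  tr <- tracer_profile("FMM", quiet_profiles())
  img <- simulate_uptake(tpl, list(true_cl = 30, age = 70, tracer = "FMM"), tr)

  idm <- to_quant_space(img, tm, "MNI", diag(4), tpl)
  expect_equal(idm$img$grid, img$grid, tolerance = 1e-12)
  idn <- to_quant_space(img, tm, "native", diag(4), tpl)
  expect_identical(idn$masks$rr$WCB, tm$rr$WCB)  # bit-identical round trip

  # one-voxel pure translation conserves nearest-neighbour mask volume
  shift <- make_rigid_for_test(translation = c(2, 0, 0))
  shifted <- to_quant_space(img, tm, "native", shift, tpl)
  expect_equal(sum(shifted$masks$rr$WCB), sum(tm$rr$WCB))

  singular <- diag(4); singular[1, 1] <- 0
  expect_error(to_quant_space(img, tm, "MNI", singular, tpl),
               class = "centistress_transform_error")
})

test_that("SUVr is the target/reference mean ratio with the expected invariances", {
  arr <- array(1.2, c(32, 32, 32))
  t_mask <- array(FALSE, c(32, 32, 32)); t_mask[1:4, 1, 1] <- TRUE
  r_mask <- array(FALSE, c(32, 32, 32)); r_mask[5:8, 1, 1] <- TRUE
  arr[t_mask] <- 1.8
  img <- volume_image(arr, 2)
  expect_equal(compute_suvr(img, t_mask, r_mask), 1.5)
  expect_equal(compute_suvr(img, t_mask, t_mask), 1)
  expect_equal(compute_suvr(volume_image(array(0.7, c(32, 32, 32)), 2), t_mask, r_mask), 1)
  # invariant under global intensity rescaling
  img2 <- volume_image(arr * 3.7, 2)
  expect_equal(compute_suvr(img2, t_mask, r_mask), compute_suvr(img, t_mask, r_mask))

  expect_error(compute_suvr(img, t_mask, array(FALSE, c(32, 32, 32))),
               class = "centistress_mask_error")
  expect_error(compute_suvr(img, t_mask[1:16, , ], r_mask[1:16, , ]),
               class = "centistress_alignment_error")
  zero <- volume_image(array(0, c(32, 32, 32)), 2)
  expect_error(compute_suvr(zero, t_mask, r_mask),
               class = "centistress_measurement_error")
})

test_that("cohort quantification yields the documented row structure", {
  tpl <- template_32()
  bank <- cached("bank32_ideal", function() {
    build_calibration_bank(tpl, tracers = quiet_profiles(), fwhm = 0)
  })
  cfg <- ideal_cohort_config(2)
  coh <- generate_cohort(cfg, seed = 12, template = tpl)
  # force one dual-image and one harmonised-only subject
  coh$subjects$tracer <- c("FMM", "FBP")
  coh$data <- lapply(seq_along(coh$data), function(i) {
    d <- coh$data[[i]]
    if (coh$subjects$tracer[i] == "FBP") d$original <- NULL else
      d$original <- d$harmonized
    d
  })
  names(coh$data) <- coh$subjects$subject_id

  lt <- quantify_cohort(coh, enumerate_pipelines(), bank)
  counts <- table(lt$subject_id)
  expect_equal(unname(counts[coh$subjects$subject_id[1]]), 64L)
  expect_equal(unname(counts[coh$subjects$subject_id[2]]), 32L)
  # balanced factorial within subject and harmonisation status
  bal <- dplyr::count(lt, subject_id, harmonized, rr, rr_type, t_type, space)
  expect_true(all(bal$n == 1L))
  expect_named(lt, c("subject_id", "tracer", "diagnosis", "age", "atrophy",
                     "true_cl", "native_fwhm", "harmonized", "rr", "rr_type",
                     "t_type", "space", "pipeline_id", "suvr", "cl", "group"))

  expect_equal(nrow(quantify_cohort(coh, enumerate_pipelines()[0, ], bank)), 0L)
  expect_error(quantify_cohort(coh, enumerate_pipelines(), bank[bank$tracer == "PiB", ]),
               class = "centistress_configuration_error")
})

test_that("idealised subjects collapse all pipelines onto the true Centiloid", {
  tpl <- template_32()
  bank <- cached("bank32_ideal", function() {
    build_calibration_bank(tpl, tracers = quiet_profiles(), fwhm = 0)
  })
  coh <- generate_cohort(ideal_cohort_config(3), seed = 7, template = tpl)
  lt <- quantify_cohort(coh, enumerate_pipelines(), bank)
  # anchor property: the measured chain returns true_cl exactly
  expect_lt(max(abs(lt$cl - lt$true_cl)), 1e-9)
  # between-pipeline variability collapses when its physical causes are gone
  spread <- tapply(lt$cl, lt$subject_id, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-6)
})
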