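# Phantom construction, morphing, uptake and resolution operators.

test_that("template construction is deterministic and anatomically complete", {
  spec <- phantom_spec(c(32L, 32L, 32L), 2)
  t1 <- build_template(spec)
  t2 <- build_template(spec)
  expect_identical(t1$grid, t2$grid)
  # all seven compartments present, hence every reference region non-empty
  expect_setequal(sort(unique(as.vector(t1$grid))), unname(cl_labels()))
  m <- template_masks(t1)
  for (rr in names(m$rr)) expect_gt(sum(m$rr[[rr]]), 0)
})

test_that("degenerate geometry is rejected", {
  geom <- default_geometry(32)
  geom$pons_radius <- 0
  expect_error(build_template(phantom_spec(c(32L, 32L, 32L), 2, geometry = geom)),
               class = "centistress_geometry_error")
  expect_error(phantom_spec(c(16L, 32L, 32L), 2),
               class = "centistress_geometry_error")
})

test_that("atrophy morphing hits the requested GM fraction and is monotone", {
  tpl <- template_32()
  none <- morph_subject(tpl, list(atrophy = 1), seed = 5,
                        jitter_translation_sd = 0, jitter_rotation_sd = 0)
  expect_identical(none$labels$grid, tpl$grid)
  expect_equal(none$affine, diag(4))

  m08 <- morph_subject(tpl, list(atrophy = 0.8), seed = 5)
  expect_lt(abs(realized_atrophy(m08$labels, tpl) - 0.8), 0.02)
  # eroded voxels become background, nothing else changes label
  changed <- tpl$grid != m08$labels$grid
  expect_true(all(m08$labels$grid[changed] == 0L))

  counts <- vapply(c(1, 0.9, 0.8, 0.7), function(a) {
    gm <- morph_subject(tpl, list(atrophy = a), seed = 5)$labels
    sum(gm$grid %in% cl_labels()[c("cortical_target_GM", "other_GM", "cerebellar_GM")])
  }, numeric(1))
  expect_true(all(diff(counts) < 0))

  expect_error(morph_subject(tpl, list(atrophy = 0.01), seed = 5),
               class = "centistress_degenerate_subject")
})

test_that("uptake anchors the ideal SUVr linearly in true amyloid load", {
  tpl <- template_32()
  masks <- subject_masks(tpl)
  tr <- tracer_profile("FMM", quiet_profiles(age_slope = TRUE))
  suvr_at <- function(cl) {
    img <- simulate_uptake(tpl, list(true_cl = cl, age = 70, tracer = "FMM"), tr)
    compute_suvr(img, masks$target, masks$rr$WCB)
  }
  expect_equal(suvr_at(0), tr$suvr_yc, tolerance = 1e-12)
  expect_equal(suvr_at(100), tr$suvr_ad100, tolerance = 1e-12)
  # linear interpolation between the anchors and extrapolation beyond them
  tr2 <- tr
  tr2$suvr_yc <- 1; tr2$suvr_ad100 <- 2
  img50 <- simulate_uptake(tpl, list(true_cl = 50, age = 70, tracer = "FMM"), tr2)
  expect_equal(compute_suvr(img50, masks$target, masks$rr$WCB), 1.5, tolerance = 1e-12)
  img150 <- simulate_uptake(tpl, list(true_cl = 150, age = 70, tracer = "FMM"), tr2)
  expect_equal(compute_suvr(img150, masks$target, masks$rr$WCB), 2.5, tolerance = 1e-12)
})

test_that("impossible uptake parameters raise a model-parameter error", {
  tpl <- template_32()
  tr <- tracer_profile("FBB", quiet_profiles())
  tr$wm_uptake_base <- -1
  expect_error(
    simulate_uptake(tpl, list(true_cl = 0, age = 70, tracer = "FBB"), tr),
    class = "centistress_model_parameter_error"
  )
})

test_that("point-spread smoothing conserves mass and matches the Gaussian", {
  tpl <- template_32()
  tr <- tracer_profile("FMM", quiet_profiles())
  img <- simulate_uptake(tpl, list(true_cl = 40, age = 70, tracer = "FMM"), tr)

  expect_identical(apply_psf(img, 0)$grid, img$grid)
  sm <- apply_psf(img, 6)
  expect_equal(sum(sm$grid), sum(img$grid), tolerance = 1e-6)
  expect_equal(sm$effective_fwhm, 6)
  expect_error(apply_psf(img, -1), class = "centistress_argument_error")

  # single-voxel impulse reproduces the sampled discrete Gaussian profile
  delta <- array(0, c(32, 32, 32))
  delta[16, 16, 16] <- 1
  out <- apply_psf(volume_image(delta, 2), 6)$grid
  sigma_vox <- 6 / (2 * sqrt(2 * log(2))) / 2
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k <- k / sum(k)
  expected <- k * k[r + 1]^2  # separable product along one axis
  expect_equal(out[16 + (-r:r), 16, 16], expected, tolerance = 1e-10)
})

test_that("smoothing pulls pure-compartment means toward their surroundings monotonically", {
  tpl <- template_48()
  tr <- tracer_profile("FBB", quiet_profiles())
  img <- simulate_uptake(tpl, list(true_cl = 100, age = 70, tracer = "FBB"), tr)
  tm <- template_masks(tpl)
  fwhms <- c(0, 3, 6, 9)
  cgm <- vapply(fwhms, function(f) mean(apply_psf(img, f)$grid[tm$rr$CGM]), numeric(1))
  pons <- vapply(fwhms, function(f) mean(apply_psf(img, f)$grid[tm$rr$Pons]), numeric(1))
  # white matter spills INTO the cerebellar-grey shell; the hot pons loses
  # signal to its colder surroundings
  expect_true(all(diff(cgm) > 0))
  expect_true(all(diff(pons) < 0))
})

test_that("harmonisation follows the quadrature rule and refuses to sharpen", {
  tpl <- template_32()
  tr <- tracer_profile("FBP", quiet_profiles())
  img <- simulate_uptake(tpl, list(true_cl = 20, age = 70, tracer = "FBP"), tr)

  at8 <- harmonize_image(apply_psf(img, 8), 8)
  expect_equal(at8$effective_fwhm, 8)
  expect_equal(at8$grid, apply_psf(img, 8)$grid, tolerance = 1e-12)

  # 5 mm -> 8 mm applies the quadrature-complement kernel sqrt(64 - 25);
  # two-stage discrete smoothing matches the one-shot 8 mm kernel up to
  # kernel-sampling error
  via5 <- harmonize_image(apply_psf(img, 5), 8)
  expect_equal(via5$effective_fwhm, 8)
  direct <- apply_psf(img, 8)
  expect_equal(via5$grid, direct$grid, tolerance = 1e-5)

  expect_error(harmonize_image(apply_psf(img, 9), 8),
               class = "centistress_cannot_sharpen")
})

test_that("cohort generation is seeded, reproducible and respects the group mix", {
  cfg <- ideal_cohort_config(4)
  c1 <- generate_cohort(cfg, seed = 99)
  c2 <- generate_cohort(cfg, seed = 99)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$data[[1]]$harmonized$grid, c2$data[[1]]$harmonized$grid)

  # all-negative configuration
  cfg0 <- cohort_config(n_subjects = 50, group_mix = 0)
  neg <- generate_cohort(cfg0, seed = 3, images = FALSE)$subjects
  expect_true(all(neg$true_cl < 24))

  # realised positive fraction within binomial 99% bounds at n = 500
  cfg5 <- cohort_config(n_subjects = 500, group_mix = 0.5)
  subj <- generate_cohort(cfg5, seed = 17, images = FALSE)$subjects
  frac <- mean(subj$group == "positive")
  half <- stats::qnorm(0.995) * sqrt(0.5 * 0.5 / 500)
  expect_gt(frac, 0.5 - half - 0.01)  # small allowance for group overlap
  expect_lt(frac, 0.5 + half + 0.01)
})
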