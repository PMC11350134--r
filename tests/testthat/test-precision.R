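# Variance decomposition, CI interpolation, ICC(2,1) and Bland-Altman.

test_that("variance decomposition separates pipeline shifts from residual noise", {
  tab <- toy_long_table(std_cl = c(0, 10, 20, 30))
  vd <- variance_decomposition(tab)
  expect_equal(vd$within_sd, 0)
  expect_equal(vd$between_sd, 0)

  # adding a constant to one pipeline moves between, not within
  shifted <- tab
  sel <- shifted$pipeline_id == standard_pipeline_id()
  shifted$cl[sel] <- shifted$cl[sel] + 7
  vd2 <- variance_decomposition(shifted)
  expect_gt(vd2$between_sd, 0)
  expect_equal(vd2$within_sd, 0, tolerance = 1e-10)

  expect_error(variance_decomposition(tab[tab$subject_id == "toy-01", ]),
               class = "centistress_insufficient_data")
})

test_that("injected variance components are recovered", {
  tab <- simulate_variance_table(n_subjects = 200, n_pipelines = 32,
                                 sigma_between = 3, sigma_within = 2, seed = 6)
  vd <- variance_decomposition(tab)
  expect_lt(abs(vd$within_sd - 2) / 2, 0.05)
  expect_lt(abs(vd$between_sd - 3) / 3, 0.05)
  # GEE marginal-mean route agrees on the between-pipeline spread
  vd_gee <- variance_decomposition(tab, method = "gee")
  expect_equal(vd_gee$between_sd, vd$between_sd, tolerance = 0.02)
})

test_that("unbalanced tables are imputed with a warning, or rejected in strict mode", {
  tab <- toy_long_table(std_cl = c(0, 10, 20))
  holey <- tab[-5, ]
  expect_warning(vd <- variance_decomposition(holey),
                 class = "centistress_imputed_cells")
  expect_true(is.finite(vd$within_sd))
  expect_error(variance_decomposition(holey, strict = TRUE),
               class = "centistress_insufficient_data")
})

test_that("CI interpolation is exact at the anchors and affine between them", {
  neg <- tibble::tibble(stratum_mean_cl = 3.45, within_ci_halfwidth = 2.70)
  pos <- tibble::tibble(stratum_mean_cl = 81.2, within_ci_halfwidth = 7.43)
  expect_equal(interpolate_ci(neg, pos, 3.45)$ci_halfwidth, 2.70)
  expect_equal(interpolate_ci(neg, pos, 81.2)$ci_halfwidth, 7.43)
  mid <- (3.45 + 81.2) / 2
  expect_equal(interpolate_ci(neg, pos, mid)$ci_halfwidth, (2.70 + 7.43) / 2)
  # affine: zero second difference on any 3-point grid, and the 12->24 step
  # equals 12 times the slope
  grid <- interpolate_ci(neg, pos, c(12, 18, 24))
  expect_equal(diff(diff(grid$ci_halfwidth)), 0, tolerance = 1e-12)
  slope <- (7.43 - 2.70) / (81.2 - 3.45)
  expect_equal(grid$ci_halfwidth[3] - grid$ci_halfwidth[1], 12 * slope)
  expect_false(any(grid$extrapolated))
  expect_true(interpolate_ci(neg, pos, 90)$extrapolated)

  same <- tibble::tibble(stratum_mean_cl = 3.45, within_ci_halfwidth = 2.70)
  expect_error(interpolate_ci(same, same, 12),
               class = "centistress_interpolation_error")
})

test_that("ICC(2,1) matches the mean-squares oracle and penalises offsets", {
  x <- c(1, 5, 9, 13, 2)
  expect_equal(icc_agreement(x, x)$icc, 1)

  # large constant offset with small between-subject spread -> low ICC
  off <- icc_agreement(x, x + 50)
  expect_lt(off$icc, 0.2)

  # oracle: two-way mean squares from aov() on the long layout
  withr::with_seed(12, {
    a <- rnorm(30, 10, 4)
    b <- a + rnorm(30, 1, 2)
  })
  res <- icc_agreement(a, b)
  long <- data.frame(y = c(a, b),
                     subj = factor(rep(seq_along(a), 2)),
                     rater = factor(rep(1:2, each = length(a))))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- length(a); k <- 2
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(res$icc, oracle, tolerance = 1e-10)

  # uncorrelated pairs hover near zero
  withr::with_seed(8, {
    u <- rnorm(1000); v <- rnorm(1000)
  })
  expect_lt(abs(icc_agreement(u, v)$icc), 0.1)

  expect_error(icc_agreement(1:2, 1:2), class = "centistress_insufficient_data")
  expect_true(icc_agreement(rep(1, 5), rep(1, 5))$degenerate)
})

test_that("Bland-Altman reproduces the hand-calculated example", {
  ba <- bland_altman(c(0, 0, 0), c(1, 2, 3))
  expect_equal(ba$stats$mean_diff, 2)
  expect_equal(ba$stats$sd_diff, 1)
  expect_equal(ba$stats$loa_low, 2 - 1.96)
  expect_equal(ba$stats$loa_high, 2 + 1.96)

  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$stats$mean_diff, 0)
  expect_equal(same$stats$sd_diff, 0)

  shift <- bland_altman(c(1, 2, 3), c(3, 4, 5))
  expect_equal(shift$stats$mean_diff, 2)
  expect_equal(shift$stats$loa_low, 2)
  expect_equal(shift$stats$loa_high, 2)

  expect_error(bland_altman(1, 2), class = "centistress_insufficient_data")
})

test_that("limits of agreement cover about 95% of Gaussian differences", {
  withr::with_seed(99, {
    orig <- rnorm(1e4, 50, 10)
    harm <- orig + rnorm(1e4, 1, 3)
  })
  ba <- bland_altman(orig, harm)
  inside <- mean(ba$data$diff >= ba$stats$loa_low & ba$data$diff <= ba$stats$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("plot methods return ggplot objects", {
  ba <- bland_altman(c(1, 2, 3, 4), c(2, 2.5, 3.2, 5))
  expect_s3_class(autoplot(ba), "ggplot")
  tab <- simulate_cl_table(10, seed = 2)
  mm <- marginal_means(fit_gee(tab, cl ~ rr), "rr")
  expect_s3_class(autoplot(mm), "ggplot")
  neg <- tibble::tibble(stratum_mean_cl = 2, within_ci_halfwidth = 3)
  pos <- tibble::tibble(stratum_mean_cl = 70, within_ci_halfwidth = 7)
  expect_s3_class(plot_ci_interpolation(neg, pos), "ggplot")
})
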