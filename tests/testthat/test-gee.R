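# The GEE engine: oracle equivalences, invariances, Wald tests.

test_that("independence GEE reproduces ordinary least squares exactly", {
  tab <- simulate_cl_table(
    40, effects = list(rr = c(WCB = 0, CGM = 4, Pons = -12, WCB_BSTM = -2)),
    seed = 21
  )
  fit <- fit_gee(tab, cl ~ rr + rr_type + t_type + space, corstr = "independence")
  # hand-rolled normal-equations oracle on the identical design
  des <- centistress:::build_design(cl ~ rr + rr_type + t_type + space, tab)
  beta <- ols_oracle(des$x, des$y)
  expect_lt(max(abs(fit$coefficients - beta)), 1e-8)
})

test_that("duplicating every cluster leaves the estimating equations unchanged", {
  tab <- simulate_cl_table(25, effects = list(space = c(MNI = 0, native = 2)), seed = 4)
  dup <- tab
  dup$subject_id <- paste0(dup$subject_id, "-copy")
  both <- dplyr::bind_rows(tab, dup)
  f1 <- fit_gee(tab, cl ~ rr + space)
  f2 <- fit_gee(both, cl ~ rr + space)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
})

test_that("a constant response yields zero effects and single-row clusters fall back", {
  tab <- simulate_cl_table(10, seed = 8)
  tab$cl <- 42
  fit <- fit_gee(tab, cl ~ rr + space)
  expect_equal(unname(fit$coefficients[1]), 42)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-10)

  # one row per subject, cycling through pipelines so factors keep >1 level
  single <- tab |>
    dplyr::group_by(subject_id) |>
    dplyr::slice((dplyr::cur_group_id() - 1L) %% 32L + 1L) |>
    dplyr::ungroup()
  expect_warning(fit_gee(single, cl ~ rr, corstr = "exchangeable"),
                 class = "centistress_degenerate_correlation")
})

test_that("the exchangeable structure recovers the intra-cluster correlation", {
  # compound symmetry: subject SD 10, residual SD 5 -> alpha = 100/125
  tab <- simulate_cl_table(400, sigma_subject = 10, sigma_resid = 5, seed = 31)
  fit <- fit_gee(tab, cl ~ rr, corstr = "exchangeable")
  expect_true(fit$converged)
  expect_equal(fit$alpha, 100 / 125, tolerance = 0.05)
})

test_that("single-df Wald chi-square equals the squared robust z", {
  tab <- simulate_cl_table(60, effects = list(space = c(MNI = 0, native = 3)), seed = 13)
  fit <- fit_gee(tab, cl ~ space + rr_type)
  wt <- wald_type3(fit)
  td <- tidy(fit)
  for (term in c("space", "rr_type")) {
    idx <- which(fit$assign == match(term, attr(fit$terms, "term.labels")))
    z2 <- (td$estimate[idx] / td$std.error[idx])^2
    expect_equal(wt$wald_chisq[wt$term == term], z2, tolerance = 1e-8)
    expect_equal(wt$df[wt$term == term], 1L)
  }
})

test_that("Type III chi-squares are invariant to factor level reordering", {
  tab <- simulate_cl_table(
    50, effects = list(rr = c(WCB = 0, CGM = 5, Pons = -9, WCB_BSTM = 1)),
    seed = 77
  )
  fit1 <- fit_gee(tab, cl ~ rr + space)
  # reorder by renaming levels so the sorted order changes
  tab2 <- tab
  tab2$rr <- c(WCB = "z_WCB", CGM = "a_CGM", Pons = "m_Pons",
               WCB_BSTM = "b_WCB_BSTM")[tab2$rr]
  fit2 <- fit_gee(tab2, cl ~ rr + space)
  w1 <- wald_type3(fit1)
  w2 <- wald_type3(fit2)
  expect_equal(w1$wald_chisq[w1$term == "rr"], w2$wald_chisq[w2$term == "rr"],
               tolerance = 1e-8)
  expect_equal(w1$wald_chisq[w1$term == "space"], w2$wald_chisq[w2$term == "space"],
               tolerance = 1e-8)
})

test_that("tidy and glance expose the fit in broom shape", {
  tab <- simulate_cl_table(20, seed = 5)
  fit <- fit_gee(tab, cl ~ rr)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 4L)  # intercept + 3 sum-coded rr columns
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 20L)
  expect_true(gl$converged)
})

test_that("the model-spec builder reproduces the published model structure", {
  s1 <- bias_model_spec(1)
  f1 <- spec_formula(s1)
  expect_true(all(c("diagnosis", "tracer", "rr", "rr_type", "t_type", "space")
                  %in% all.vars(f1)))
  expect_false("age" %in% all.vars(f1))
  expect_true("age" %in% all.vars(spec_formula(bias_model_spec(2))))
  expect_true("atrophy" %in% all.vars(spec_formula(bias_model_spec(3))))
  expect_true("harmonized" %in% all.vars(spec_formula(bias_model_spec(4))))
  expect_error(model_spec(within = "rr", interactions = list(c("rr", "age"))),
               class = "centistress_configuration_error")
})
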