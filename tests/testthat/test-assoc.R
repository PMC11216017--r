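test_that("standardization produces exact mean-0 SD-1 (population) values", {
  # log of {e, e^2, e^3} is {1,2,3}: population SD sqrt(2/3)
  z <- transform_standardize(exp(1:3), log_transform = TRUE)
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3))
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  # without log, same result for {1,2,3}
  expect_equal(transform_standardize(c(1, 2, 3)), z)

  expect_error(transform_standardize(c(-1, 2), log_transform = TRUE),
               "nonpositive")
  expect_error(transform_standardize(rep(5, 4)), "zero variance")
})

test_that("fit_model agrees with a hand-rolled normal-equations solver", {
  d <- simulate_association_data(200, beta = 3, seed = 5)
  res <- fit_model(d, "nonactive_hr", "exposure", c("age", "bmi"))

  z <- transform_standardize(d$exposure)
  X <- cbind(1, z, d$age, d$bmi)
  y <- d$nonactive_hr
  bhat <- solve(crossprod(X), crossprod(X, y))
  rss <- sum((y - X %*% bhat)^2)
  vcov <- rss / (nrow(X) - ncol(X)) * solve(crossprod(X))
  expect_equal(res$beta, bhat[2], tolerance = 1e-8)
  expect_equal(res$se, sqrt(vcov[2, 2]), tolerance = 1e-8)
  expect_equal(res$n, 200L)

  # an exactly collinear pair of covariates is refused, not silently
  # dropped
  d$age2 <- 2 * d$age
  expect_error(fit_model(d, "nonactive_hr", "exposure",
                         c("age", "age2", "bmi")), "rank-deficient")
  expect_error(fit_model(d, "nonactive_hr", "exposure", c("nope")),
               "not in data")
})

test_that("fit_model recovers a planted per-SD effect", {
  d <- simulate_association_data(2000, beta = -2.4, seed = 11)
  covars <- setdiff(model_covariates("nonactive_hr", "model2"),
                    "hr_lowering_med")
  res <- fit_model(d, "nonactive_hr", "exposure", covars)
  expect_lt(abs(res$beta - (-2.4)), 3 * res$se)

  d0 <- simulate_association_data(2000, beta = 0, seed = 12)
  res0 <- fit_model(d0, "nonactive_hr", "exposure", covars)
  expect_lt(abs(res0$beta), 4 * res0$se)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.4), 0.4)

  for (s in 1:10) {
    set.seed(100 + s)
    p <- runif(20)^2
    expect_equal(bh_adjust(p), brute_bh(p))
  }
  # families are adjusted independently
  set.seed(3)
  p <- runif(12)
  fam <- rep(c("a", "b"), each = 6)
  expect_equal(bh_adjust(p, fam), c(brute_bh(p[1:6]), brute_bh(p[7:12])))
  # adjustment never decreases a p-value and is order-equivariant
  expect_true(all(bh_adjust(p) >= p))
  o <- sample(12)
  expect_equal(bh_adjust(p[o]), bh_adjust(p)[o])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("effect modifiers use the documented category boundaries", {
  d <- tibble::tibble(age = c(40, 50, 50, 60), bmi = c(24.9, 25, 29.9, 30))
  m <- derive_modifiers(d)
  # BMI boundaries are left-inclusive: 25.0 is overweight, 30.0 obese
  expect_equal(m$bmi_cat, c("normal", "overweight", "overweight", "obese"))
  # median age 50; ties go to the younger group
  expect_equal(m$age_group, c("younger", "younger", "younger", "older"))
})

test_that("interaction analysis returns joint tests and strata", {
  g <- generate_summaries(cohort_params(n_participants = 400, seed = 41))
  tab <- build_analysis_table(g$watch_summaries, g$cpet_results,
                              g$covariates)
  ia <- interaction_analysis(tab, "peak_vo2", "nonactive_hr", "sex",
                             log_exposure = TRUE)
  expect_true(ia$interaction$p_interaction >= 0 &&
                ia$interaction$p_interaction <= 1)
  expect_setequal(ia$strata$stratum, c("female", "male"))
  expect_true(all(is.finite(ia$strata$beta)))

  # three BMI strata
  ib <- interaction_analysis(tab, "peak_vo2", "nonactive_hr", "bmi_cat",
                             log_exposure = TRUE)
  expect_setequal(ib$strata$stratum, c("normal", "overweight", "obese"))

  # a stratum below the minimum size is reported missing, not fitted
  ic <- interaction_analysis(tab, "peak_vo2", "nonactive_hr", "sex",
                             log_exposure = TRUE, min_stratum = 10000)
  expect_true(all(is.na(ic$strata$beta)))
  expect_true(all(ic$strata$n > 0))

  tab1 <- tab
  tab1$sex <- "female"
  expect_error(interaction_analysis(tab1, "peak_vo2", "nonactive_hr",
                                    "sex"), "fewer than 2")
})

test_that("the battery covers the grid and the sensitivity variants", {
  g <- generate_summaries(cohort_params(n_participants = 500, seed = 43))
  cfg <- analysis_config(rer_sensitivity = TRUE,
                         adjust_steps_in_hr_model = TRUE,
                         expanded_step_sample = TRUE, role_swap = TRUE)
  res <- run_battery(g$watch_summaries, g$cpet_results, g$covariates,
                     config = cfg)

  prim <- res[res$analysis == "primary", ]
  # 6 exposures x 2 outcomes x 2 models
  expect_equal(nrow(prim), 24)
  expect_equal(sort(unique(res$analysis)),
               sort(c("primary", "rer_sensitivity", "step_adjusted",
                      "expanded_steps", "role_swap")))
  expect_true(all(res$p_fdr >= res$p_raw - 1e-12))
  expect_true(all(res$p_fdr <= 1))

  # FDR families are outcome-by-model cells of 6 in the primary grid
  fam <- split(prim, paste(prim$outcome, prim$model))
  expect_true(all(vapply(fam, nrow, integer(1)) == 6L))
  for (f in fam) expect_equal(f$p_fdr, brute_bh(f$p_raw))

  # effort restriction can only shrink the sample
  rer <- res[res$analysis == "rer_sensitivity", ]
  expect_true(all(rer$n <= max(prim$n)))
  # the expanded step sample can only grow it
  exp_n <- res$n[res$analysis == "expanded_steps" & res$model == "model1"]
  prim_steps_n <- prim$n[prim$outcome == "daily_steps" &
                           prim$model == "model1"]
  expect_true(all(exp_n >= prim_steps_n))

  # role swap: 6 rows, daily steps as exposure, and for the strongly
  # linked measures the direction matches the primary analysis
  rs <- res[res$analysis == "role_swap", ]
  expect_equal(nrow(rs), 6)
  expect_true(all(rs$exposure == "daily_steps"))
  for (m in c("peak_vo2", "vat_vo2")) {
    b_prim <- prim$beta[prim$outcome == "daily_steps" &
                          prim$model == "model2" & prim$exposure == m]
    b_swap <- rs$beta[rs$outcome == m]
    expect_equal(sign(b_swap), sign(b_prim))
  }
})

test_that("invalid analysis configurations are refused", {
  expect_error(analysis_config(outcomes = "bogus"), "arg")
  expect_error(analysis_config(
    extra_covariates = list(daily_steps = "hr_lowering_med")),
    "only\\s+in the nonactive-HR")
  expect_error(analysis_config(
    extra_covariates = list(nonactive_hr = "median_wear_hours")),
    "only in the")
})
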