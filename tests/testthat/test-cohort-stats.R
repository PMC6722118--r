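prep_cohort <- function(spec) {
  transform_variables(generate_cohort(spec), percent_col = "true_percent")
}

test_that("exclusion rules follow the age threshold and missingness", {
  co <- tibble::tibble(core_id = c("a", "b", "c"),
                       subject_id = c("s1", "s2", "s3"),
                       sex = factor(c("male", "female", "male")),
                       age = c(17, 18, 40))
  kept <- apply_exclusions(co)
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$subject_id, c("s2", "s3"))
  co$sex[3] <- NA
  kept <- apply_exclusions(co)
  expect_equal(nrow(kept), 1)
  log <- exclusion_log(kept)
  expect_equal(log$n_rows[log$reason == "age_under_18"], 1)
  expect_equal(log$n_rows[log$reason == "missing_sex_age_or_unevaluable"], 1)
})

test_that("exclusion counts always balance the input count", {
  set.seed(12)
  for (i in 1:5) {
    co <- generate_cohort(cohort_spec(
      n_subjects = 150, seed = i,
      n_underage_subjects = sample(0:6, 1),
      n_missing_or_unevaluable = sample(0:10, 1)))
    kept <- apply_exclusions(co)
    expect_equal(nrow(kept) + sum(exclusion_log(kept)$n_rows), nrow(co))
  }
})

test_that("transforms are the documented sqrt and log maps", {
  co <- tibble::tibble(percent_positive = c(25, 0, 100, NA),
                       heart_weight = c(403, NA, 350, 500), bmi = c(25, 30, NA, 20))
  tr <- transform_variables(co)
  expect_equal(tr$sqrt_fraction, c(0.5, 0, 1, NA))
  expect_equal(tr$log_heart_weight[1], log(403))
  expect_equal(tr$log_heart_weight[1], 5.999, tolerance = 1e-3)
  expect_true(is.na(tr$log_heart_weight[2]))
  # round trip
  ok <- !is.na(tr$sqrt_fraction)
  expect_equal(100 * tr$sqrt_fraction[ok]^2, co$percent_positive[ok],
               tolerance = 1e-10)
  expect_error(transform_variables(tibble::tibble(percent_positive = -1)),
               class = "mosaicquant_validation_error")
})

test_that("noiseless cohorts identify the sex effect exactly", {
  sp <- control_only_spec(n_subjects = 80, subject_sd = 0, tma_sd = 0,
                          residual_sd = 0, seed = 44)
  fit <- fit_mixed_model(prep_cohort(sp))
  est <- fit$coefficients$estimate[fit$coefficients$term == "sexmale"]
  expect_equal(est, 0.097, tolerance = 1e-6)
  # t statistics are estimate / SE by construction
  expect_equal(fit$coefficients$statistic,
               fit$coefficients$estimate / fit$coefficients$std.error,
               tolerance = 1e-8)
})

test_that("at the zero-variance boundary the fit collapses to OLS", {
  # balanced antithetic construction: subject means carry no extra spread and
  # the two TMA means are identical, so both variance components are
  # estimated at the boundary and GLS = OLS
  set.seed(15)
  n <- 40
  sub <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                        sex = factor(rep(c("female", "male"), each = n / 2),
                                     levels = c("female", "male")),
                        age = seq(30, 70, length.out = n),
                        e = rnorm(n, 0, 0.03))
  dat <- dplyr::bind_rows(
    dplyr::mutate(sub, tma_id = "TMA1", eps = e),
    dplyr::mutate(sub, tma_id = "TMA2", eps = -e))
  dat$sqrt_fraction <- 0.3 + 0.097 * (dat$sex == "male") -
    0.0002 * dat$age + dat$eps
  fit <- fit_mixed_model(dat)
  expect_true(fit$singular)
  ols <- stats::lm(sqrt_fraction ~ age + sex, data = dat)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("p-values use the normal approximation on t by default", {
  fit <- fit_mixed_model(prep_cohort(cohort_spec(n_subjects = 100, seed = 2)))
  co <- fit$coefficients
  expect_equal(co$p.value, 2 * pnorm(-abs(co$statistic)), tolerance = 1e-12)
  satt <- fit_mixed_model(prep_cohort(cohort_spec(n_subjects = 100, seed = 2)),
                          df_method = "satterthwaite")
  expect_true(all(satt$coefficients$df > 0))
})

test_that("a single-TMA design reports a degenerate TMA variance", {
  sp <- cohort_spec(n_subjects = 60, n_tmas = 1, tma_sd = 0, seed = 3)
  dat <- prep_cohort(sp)
  fit <- fit_mixed_model(dat)
  v <- fit$variance_components
  # unidentifiable TMA variance is near zero relative to the outcome spread
  expect_lt(v$variance[v$group == "tma_id"], 0.01 * var(dat$sqrt_fraction))
  expect_true(fit$singular)
})

test_that("residuals vanish on noiseless data and are orthogonal to the design", {
  sp0 <- control_only_spec(n_subjects = 60, subject_sd = 0, tma_sd = 0,
                           residual_sd = 0, seed = 8)
  r0 <- compute_residuals(prep_cohort(sp0))
  expect_lt(max(abs(r0$residual)), 1e-8)
  # conditional residuals satisfy the least-squares orthogonality exactly
  dat <- compute_residuals(prep_cohort(cohort_spec(n_subjects = 150, seed = 10)),
                           type = "conditional")
  X <- stats::model.matrix(~ age + sex, data = dat)
  dots <- crossprod(X, dat$residual) / nrow(dat)
  expect_lt(max(abs(dots)), 1e-6)
})

test_that("residualisation recovers a planted disease shift", {
  eff <- cohort_spec()$disease_effects_sqrt_scale[["HCM"]]
  dat <- compute_residuals(prep_cohort(cohort_spec(n_subjects = 500, seed = 77)))
  hcm <- dat$residual[dat$disease == "HCM"]
  ctl <- dat$residual[dat$disease == "Control"]
  gap <- mean(hcm) - mean(ctl)
  se <- sqrt(var(hcm) / length(hcm) + var(ctl) / length(ctl))
  expect_lt(abs(gap - eff), 3 * se)
})

test_that("the model suite runs its four analyses and logs missingness", {
  dat <- prep_cohort(cohort_spec(n_subjects = 250, seed = 19))
  suite <- run_model_suite(dat)
  expect_equal(suite$model, c("main", "disease", "heart_weight", "hcm"))
  expect_true(all(suite$status == "converged"))
  hw_dropped <- suite$n_dropped[suite$model == "heart_weight"]
  expect_equal(hw_dropped, sum(is.na(dat$heart_weight)))
  tidied <- tidy(suite)
  expect_true(all(c("model", "term", "estimate", "p.value") %in% names(tidied)))
  expect_true("sexmale" %in% tidied$term)
})

test_that("a planted HCM effect is detected by the disease model", {
  hits <- vapply(1:8, function(i) {
    dat <- prep_cohort(cohort_spec(n_subjects = 250, seed = 400 + i))
    fit <- fit_mixed_model(dat, model_spec(c("age", "sex", "disease")))
    co <- fit$coefficients
    row <- co[co$term == "diseaseHCM", ]
    row$estimate > 0 && row$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("tidiers expose broom-shaped output", {
  fit <- fit_mixed_model(prep_cohort(cohort_spec(n_subjects = 80, seed = 1)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("effect", "term", "estimate", "std.error", "statistic",
                     "p.value"))
  expect_named(glance(fit), c("n_obs", "n_subjects", "n_dropped", "sigma",
                              "REML", "converged", "singular"))
  rp <- tidy(fit, effects = "ran_pars")
  expect_true(all(c("subject_id", "tma_id", "Residual") %in% rp$group))
})
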