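test_that("deviation table subtracts predicted from observed per the sign convention", {
  p <- hare_params()
  tt <- tiny_tables(t_obs = 10, Ta = 5)
  dev <- compute_deviations(tt$records, tt$env, p)
  # positive deviation <=> more active than balance requires
  expect_equal(dev$deviation, dev$t_obs - dev$t_pred)
  expect_equal(unique(round(dev$t_pred, 2)), 10.54)
  expect_equal(unique(round(dev$deviation, 2)), -0.54)
  expect_equal(dev$below_tnz, rep(0L, nrow(dev)))

  # a record observed exactly at prediction has deviation 0
  tt2 <- tiny_tables(t_obs = required_activity_time(5, 1.35, p)$t_pred, Ta = 5)
  dev2 <- compute_deviations(tt2$records, tt2$env, p)
  expect_equal(dev2$deviation, rep(0, nrow(dev2)), tolerance = 1e-12)

  bad <- dplyr::mutate(tt$records, mass = NA_real_)
  expect_error(compute_deviations(bad, tt$env, p), "mass")
  expect_error(compute_deviations(dplyr::mutate(tt$records, date = date + 999),
                                  tt$env, p), "join")
})

test_that("TNZ subsetting keeps warm rows and re-standardizes covariates", {
  p <- hare_params() # TLC = -5
  env <- simulate_environment(10, seed = 91)
  env$Ta <- c(rep(0, 6), rep(-10, 4)) # 6 warm, 4 cold days
  cohort <- simulate_cohort(1, p, 1.35, 0, sigma_b = 0, seed = 92)
  act <- simulate_activity(cohort, env, p, effect_params(sigma_e = 0.3), seed = 93)
  dev <- compute_deviations(act, env, p)

  warm <- subset_tnz(dev)
  expect_equal(nrow(warm), 6)
  expect_true(all(warm$below_tnz == 0))

  # standardize-then-subset recomputes the z-scores on the subset
  z_first <- subset_tnz(standardize_covariates(dev))
  expect_equal(mean(z_first$wind), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z_first$snow), 1, tolerance = 1e-9)
  expect_equal(z_first$wind, standardize_covariates(warm)$wind)

  all_cold <- dplyr::mutate(dev, below_tnz = 1L)
  expect_error(subset_tnz(all_cold), "lower critical")
})

test_that("standardization uses the sample SD, is idempotent, and flags constants", {
  tbl <- tibble::tibble(wind = c(0, 10), snow = c(1, 3), lunar = c(0.1, 0.5))
  z <- standardize_covariates(tbl)
  expect_equal(z$wind, c(-1, 1) / sqrt(2))
  std <- attr(z, "standardization")
  expect_equal(std$sd[std$column == "wind"], stats::sd(c(0, 10)))

  z2 <- standardize_covariates(z)
  expect_equal(z2$wind, z$wind, tolerance = 1e-12)
  expect_equal(z2$snow, z$snow, tolerance = 1e-12)

  expect_error(standardize_covariates(dplyr::mutate(tbl, snow = 2)), "zero-SD")
})

test_that("degenerate random effects collapse the LMM onto ordinary least squares", {
  p <- hare_params()
  d <- simulate_study("hare-like", seed = 101, n = 12, n_days = 20,
                      eff = effect_params(beta_wind = -0.05, beta_snow = -0.04,
                                          sigma_b = 0, sigma_e = 0.5,
                                          nocturnality = 0.77))
  dev <- standardize_covariates(subset_tnz(compute_deviations(d$activity, d$env, p)))
  fit <- suppressMessages(fit_deviation_lmm(dev))
  expect_lt(fit$sigma2_b, 1e-3)
  ols <- stats::lm(deviation ~ wind + snow + lunar + day_of_winter * sex, data = dev)
  expect_equal(fit$fixed$estimate, unname(stats::coef(ols)), tolerance = 1e-3)
  expect_equal(fit$n_groups, 12)
})

test_that("tidy and glance expose the fitted quantities, reproducibly", {
  p <- hare_params()
  d <- simulate_study("hare-like", seed = 111, n = 10, n_days = 15)
  dev <- standardize_covariates(subset_tnz(compute_deviations(d$activity, d$env, p)))
  f1 <- fit_deviation_lmm(dev)
  f2 <- fit_deviation_lmm(dev)
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-4)
  expect_equal(glance(f1)$aicc, glance(f2)$aicc, tolerance = 1e-4)
  expect_named(tidy(f1), c("term", "estimate", "std_error", "statistic",
                           "p_value", "conf_low", "conf_high"))
  g <- glance(f1)
  expect_equal(g$intercept_share, f1$sigma2_b / (f1$sigma2_b + f1$sigma2_e))
  expect_true(g$n_groups <= g$n_obs)
  # variant formulas add the advertised terms
  full <- fit_deviation_lmm(
    standardize_covariates(compute_deviations(d$activity, d$env, p)),
    include_tnz_term = TRUE, include_mass = TRUE
  )
  expect_true(all(c("below_tnz", "mass") %in% tidy(full)$term))
})

test_that("AICc applies the small-sample penalty and ranks intercept models", {
  expect_equal(aicc(100, 2, 10), 100 + 12 / 7)
  expect_equal(aicc(100, 2, 1e9), 100, tolerance = 1e-6)
  expect_error(aicc(100, 5, 6))

  # data dominated by individual differences: the random intercept must
  # improve AICc over the fixed-effects-only fit
  p <- hare_params()
  d <- simulate_study("hare-like", seed = 121, n = 15, n_days = 15,
                      eff = effect_params(sigma_b = 1.5, sigma_e = 0.5,
                                          nocturnality = 0.77))
  dev <- standardize_covariates(subset_tnz(compute_deviations(d$activity, d$env, p)))
  mixed <- fit_deviation_lmm(dev, REML = FALSE)
  ols <- stats::lm(deviation ~ wind + snow + lunar + day_of_winter * sex, data = dev)
  k_ols <- length(stats::coef(ols)) + 1
  aicc_ols <- aicc(stats::AIC(ols), k_ols, nrow(dev))
  expect_lt(mixed$aicc, aicc_ols)
})

test_that("random-intercept share is the intraclass variance ratio", {
  expect_equal(random_intercept_share(list(sigma2_b = 2, sigma2_e = 2)), 0.5)
  expect_equal(random_intercept_share(list(sigma2_b = 0, sigma2_e = 3)), 0)
  expect_equal(random_intercept_share(list(sigma2_b = 1, sigma2_e = 4)), 0.2)
  expect_error(random_intercept_share(list(sigma2_b = 0, sigma2_e = 0)))

  # invariant to shifting all deviations by a constant
  p <- hare_params()
  d <- simulate_study("hare-like", seed = 131, n = 10, n_days = 12)
  dev <- standardize_covariates(subset_tnz(compute_deviations(d$activity, d$env, p)))
  f <- fit_deviation_lmm(dev)
  f_shift <- fit_deviation_lmm(dplyr::mutate(dev, deviation = deviation + 5))
  expect_equal(random_intercept_share(f_shift), random_intercept_share(f),
               tolerance = 1e-6)
})

test_that("standardized coefficients back-transform to the raw-covariate fit", {
  p <- hare_params()
  d <- simulate_study("hare-like", seed = 141, n = 14, n_days = 20)
  dev_raw <- subset_tnz(compute_deviations(d$activity, d$env, p))
  dev_z <- standardize_covariates(dev_raw)

  fit_z <- fit_deviation_lmm(dev_z)
  fit_raw <- fit_deviation_lmm(dev_raw)
  back <- raw_scale_effects(fit_z)
  raw_est <- fit_raw$fixed$estimate[match(back$term, fit_raw$fixed$term)]
  expect_equal(back$estimate_raw, raw_est, tolerance = 1e-6)

  expect_error(raw_scale_effects(fit_raw), "standardized")
})

test_that("activity effects translate into energy with the printed hare arithmetic", {
  p <- hare_params()
  out <- coefficient_to_energy(beta = -0.065, delta_covariate = 20,
                               Ta = 0, M = 1.35, p = p)
  expect_equal(out$delta_t_h, -1.3)
  expect_equal(out$delta_neg_kj, -56, tolerance = 1e-3)
  expect_equal(out$pct_of_balance_time, -12.3, tolerance = 0.01)
  expect_equal(out$pct_of_daily_ee, -7.4, tolerance = 0.01)

  zero <- coefficient_to_energy(0, 20, Ta = 0, M = 1.35, p = p)
  expect_equal(unlist(zero), c(delta_t_h = 0, delta_neg_kj = 0,
                               pct_of_balance_time = 0, pct_of_daily_ee = 0))
  expect_error(coefficient_to_energy(-0.1, 20, Ta = -60, M = 1.35, p = p),
               "infeasible")
})

test_that("the prediction exchange table carries targets and observed NEG", {
  p <- porcupine_params()
  d <- simulate_study("porcupine-like", seed = 151, n = 5, n_days = 6)
  out <- predict_activity(d$activity, d$env, p)
  expect_named(out, c("individual_id", "date", "Ta_C", "mass_kg", "t_pred_h",
                      "feasible", "neg_target_kJ", "neg_obs_kJ"))
  expect_equal(out$neg_target_kJ, -39.8 * out$mass_kg^0.75)
  expect_equal(out$neg_obs_kJ,
               predict_daily_neg(out$Ta_C, d$activity$t_obs, out$mass_kg, p))
})
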