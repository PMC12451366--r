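test_that("clinical simulation matches its generating distributions", {
  # empty case keeps the schema
  empty <- simulate_clinical(0, seed = 1)
  expect_identical(nrow(empty), 0L)
  expect_named(empty, c("age", "sex", "hpv", "tnm"))

  # law of large numbers against the stated parameters
  big <- simulate_clinical(1e5, seed = 42)
  expect_lt(abs(mean(big$age) - 65), 0.1)
  expect_lt(abs(mean(big$sex) - 0.30), 0.01)
  expect_lt(abs(mean(big$hpv) - 0.30), 0.01)
  freq <- tabulate(big$tnm, 4) / nrow(big)
  expect_true(all(abs(freq - c(0.22, 0.13, 0.25, 0.40)) < 0.01))

  # degenerate stage distribution
  deg <- simulate_clinical(50, clinical_params(tnm_probs = c(1, 0, 0, 0)),
                           seed = 3)
  expect_true(all(deg$tnm == 1))

  # determinism and argument validation
  expect_identical(simulate_clinical(20, seed = 9), simulate_clinical(20, seed = 9))
  expect_error(simulate_clinical(-1), "nonnegative")
})

test_that("Fernandez-Steel skewed normal hits its requested moments", {
  z <- rsnorm_fs(2e5, mean = 3, sd = 2, xi = 2, seed = 7)
  expect_lt(abs(mean(z) - 3), 0.02)
  expect_lt(abs(sd(z) - 2) / 2, 0.01)
  expect_gt(mean(((z - 3) / 2)^3), 0.3)  # right-skewed at xi = 2

  sym <- rsnorm_fs(2e5, xi = 1, seed = 8)
  expect_lt(abs(mean(sym^3)), 0.02)      # xi = 1 is symmetric
})

test_that("expression simulation obeys its mean-dispersion model", {
  # tau forced constant, symmetric shape, literal-sd reading: per-transcript
  # sd converges to (exp(mu1)/1.3) * tau
  tau <- 0.13
  tp <- transcript_params(n_transcripts = 3, mu0 = 4, sigma0 = 1e-9,
                          mu_tau = log(tau), sigma_tau_log = 0,
                          skewness = 1, dispersion_scale = "sd")
  ex <- simulate_expression(1e5, tp, seed = 11)
  target_sd <- exp(4) / 1.3 * tau
  for (j in 1:3)
    expect_lt(abs(sd(ex$expression[, j]) - target_sd) / target_sd, 0.02)

  # default variance reading: one transcript with mu1 = 2.3, tau1 = 1 has
  # sample mean exp(2.3) within 3 Monte-Carlo standard errors
  tp2 <- transcript_params(n_transcripts = 2, mu0 = 2.3, sigma0 = 1e-9,
                           mu_tau = 0, sigma_tau_log = 0)
  ex2 <- simulate_expression(1e4, tp2, seed = 12)
  sd_theory <- sqrt(exp(2.3) / 1.3)
  expect_lt(abs(mean(ex2$expression[, 1]) - exp(2.3)),
            3 * sd_theory / sqrt(1e4) + 0.02)

  # truncation floor holds and parameters are returned for oracle use
  tp3 <- transcript_params(n_transcripts = 50, expression_floor = 0.01)
  ex3 <- simulate_expression(200, tp3, seed = 13)
  expect_true(all(ex3$expression >= 0.01))
  expect_identical(nrow(ex3$transcript_params), 50L)
})

test_that("true coefficient draw has the stated structure", {
  coefs <- draw_true_coefficients(coefficient_spec(), 15000, seed = 4)
  expect_identical(sum(coefs$transcript != 0), 200L)
  expect_identical(sum(coefs$transcript < 0), 100L)
  expect_identical(sum(coefs$transcript > 0), 100L)
  expect_true(all(coefs$transcript[coefs$negative_idx] > -0.1 &
                    coefs$transcript[coefs$negative_idx] < -0.01))
  expect_true(all(coefs$transcript[coefs$positive_idx] > 0.01 &
                    coefs$transcript[coefs$positive_idx] < 0.1))
  expect_identical(unname(coefs$clinical), c(0.02, -0.8, 0.3, -0.5))
  expect_identical(draw_true_coefficients(coefficient_spec(), 15000, seed = 4),
                   coefs)
  expect_error(draw_true_coefficients(coefficient_spec(), 100), "exceeds")
})

test_that("inverse-transform event times match closed forms", {
  # identity baseline, lp = 0: unit exponential
  mech <- survival_mechanism(shape = 1, scale = 1, censor_rate = 0)
  s1 <- simulate_survival_times(rep(0, 1e5), mech, seed = 21)
  expect_gt(suppressWarnings(ks.test(s1$latent_time, pexp, 1))$p.value, 0.01)

  # exponential baseline with rate lambda0 and lp = b: Exp(lambda0 * e^b)
  lambda0 <- 0.4; b <- 0.7
  mech2 <- survival_mechanism(shape = 1, scale = 1 / lambda0, censor_rate = 0)
  s2 <- simulate_survival_times(rep(b, 1e5), mech2, seed = 22)
  expect_gt(suppressWarnings(ks.test(s2$latent_time, pexp,
                                     lambda0 * exp(b)))$p.value, 0.01)

  # Weibull baseline: T ~ Weibull(shape, scale) at lp = 0
  mech3 <- survival_mechanism(shape = 1.7, scale = 2, censor_rate = 0)
  s3 <- simulate_survival_times(rep(0, 1e5), mech3, seed = 23)
  expect_gt(suppressWarnings(ks.test(s3$latent_time, pweibull, 1.7, 2))$p.value,
            0.01)

  # monotonicity: with identical uniforms, larger lp means earlier events
  lp_a <- c(1, 0.5, 2); lp_b <- c(0, -0.5, 1)
  ta <- simulate_survival_times(lp_a, mech, seed = 30)$latent_time
  tb <- simulate_survival_times(lp_b, mech, seed = 30)$latent_time
  expect_true(all(ta < tb))
})

test_that("bounded table baselines censor draws beyond their range", {
  tab <- data.frame(time = c(0, 1, 2, 3), H0 = c(0, 0.2, 0.5, 0.7))
  mech <- survival_mechanism(baseline = tab, horizon_years = 5,
                             censor_rate = 0)
  s <- simulate_survival_times(rep(-2, 500), mech, seed = 31)
  over <- s$latent_time == Inf
  expect_gt(sum(over), 0)
  expect_true(all(s$time[over] == 5))
  expect_true(all(s$event[over] == 0))
  # interpolation inverts the table exactly on its range
  expect_equal(baseline_cumhaz_inv(mech, c(0.1, 0.35, 0.6)),
               c(0.5, 1.5, 2.5), tolerance = 1e-12)
  expect_equal(baseline_cumhaz(mech, c(0.5, 1.5, 2.5)), c(0.1, 0.35, 0.6),
               tolerance = 1e-12)
})

test_that("cohorts are reproducible with recomputable linear predictors", {
  gp <- small_gp()
  coh <- generate_cohort(60, gp, seed = 14)
  expect_identical(dim(cohort_features(coh)),
                   c(60L, 4L + gp$transcripts$n_transcripts))
  expect_identical(generate_cohort(60, gp, seed = 14)[c("time", "event")],
                   coh[c("time", "event")])
  expect_identical(coh$log_expression, log1p(coh$expression))

  # true_lp is beta'x centered within cohort, to machine precision
  lp_raw <- drop(as.matrix(coh$clinical[, c("age", "sex", "tnm", "hpv")]) %*%
                   coh$coefficients$clinical +
                   coh$log_expression %*% coh$coefficients$transcript)
  expect_equal(coh$true_lp, lp_raw - mean(lp_raw), tolerance = 1e-12)
})

test_that("null coefficients give chance-level oracle discrimination", {
  gp <- noise_gp(p = 10)
  coh <- generate_cohort(8000, gp, seed = 15)
  # with no signal, true_lp is pure centering noise; AUC against outcome ~ 0.5
  a <- auc_cd(coh$true_lp, coh$time, coh$event, 3)
  expect_lt(abs(as.numeric(a) - 0.5), 0.02)
})

test_that("proportional hazards are preserved through the inversion", {
  # one strong covariate; an unpenalized Cox fit recovers its coefficient
  set.seed(16)
  z <- rnorm(1e4)
  lp <- 1.0 * z - mean(z)
  mech <- survival_mechanism(censor_rate = 0.078)
  s <- simulate_survival_times(lp, mech, seed = 17)
  fit <- survival::coxph(survival::Surv(s$time, s$event) ~ z)
  expect_lt(abs(unname(coef(fit)) - 1.0) / 1.0, 0.1)
})

test_that("censoring calibration hits its target fraction", {
  gp <- small_gp()
  rate <- calibrate_censoring_rate(gp, target = 0.5, n = 3000, seed = 18)
  mech <- gp$mechanism
  mech$censor_rate <- rate
  gp2 <- generating_parameters(gp$clinical, gp$transcripts, gp$coefficients,
                               mech, coef_seed = gp$coef_seed)
  coh <- generate_cohort(3000, gp2, seed = 19)
  expect_lt(abs(mean(1 - coh$event) - 0.5), 0.04)
})
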