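test_that("one-standard-error rule selects the documented lambda", {
  # hand-evaluated: min 7.0 at lambda=2, se 0.6, threshold 7.6; the only
  # larger lambda within the threshold is lambda=2 itself (8 > 7.6 at
  # lambda=3), so the rule returns 2
  expect_equal(select_lambda_1se(c(10, 8, 7, 7.5), c(1, 1, 0.6, 1),
                                 c(4, 3, 2, 1)), 2)
  # with a generous se at the minimum, the sparser neighbor qualifies
  expect_equal(select_lambda_1se(c(10, 8, 7, 7.5), c(1, 1, 1.2, 1),
                                 c(4, 3, 2, 1)), 3)
  # monotone decreasing loss with tiny se collapses onto lambda_min
  cvm <- c(10, 9, 8, 7, 6.99)
  expect_equal(select_lambda_1se(cvm, rep(1e-6, 5), c(5, 4, 3, 2, 1)), 1)
  # flat loss resolves toward sparsity (largest lambda)
  expect_equal(select_lambda_1se(rep(3, 4), rep(0.1, 4), c(4, 3, 2, 1)), 4)
  expect_error(select_lambda_1se(numeric(0), numeric(0), numeric(0)), "empty")
  expect_error(select_lambda_1se(1:3, 1:3, c(1, 2, 3)), "decreasing")
})

test_that("Breslow estimator matches the hand computation", {
  # times 1,2,3; events 1,1,0; eta = 0: H0(2) = 1/3 + 1/2
  br <- coxvalsim:::breslow_cumhaz(c(1, 2, 3), c(1, 1, 0), rep(0, 3))
  expect_equal(coxvalsim:::breslow_eval(br, 2), 1 / 3 + 1 / 2, tolerance = 1e-12)
  expect_equal(coxvalsim:::breslow_eval(br, 0), 0)
  expect_equal(coxvalsim:::breslow_eval(br, 1.5), 1 / 3, tolerance = 1e-12)
  # tied events share one risk-set denominator
  br2 <- coxvalsim:::breslow_cumhaz(c(1, 1, 2), c(1, 1, 0), rep(0, 3))
  expect_equal(br2$hazard[1], 2 / 3, tolerance = 1e-12)
})

test_that("penalized Cox CV behaves on signal, noise and edge cases", {
  # a single strong feature is selected at lambda_1se
  set.seed(31)
  n <- 500
  x <- cbind(strong = rnorm(n), matrix(rnorm(n * 5), n))
  colnames(x) <- c("strong", paste0("noise", 1:5))
  s <- simulate_survival_times(x[, 1] * 1.0,
                               survival_mechanism(censor_rate = 0.05),
                               seed = 32)
  fit <- coxnet_cv(x, s$time, s$event, penalty_config(alpha = 0.95), seed = 33)
  expect_gt(abs(coef(fit)[["strong"]]), 0)
  expect_gte(fit$lambda_1se, fit$lambda_min)

  # pure-noise p >> n: the null model is the usual outcome
  nulls <- vapply(1:20, function(s0) {
    set.seed(400 + s0)
    xn <- matrix(rnorm(50 * 1000), 50)
    colnames(xn) <- paste0("g", 1:1000)
    sn <- simulate_survival_times(rep(0, 50),
                                  survival_mechanism(censor_rate = 0.078),
                                  seed = 500 + s0)
    coxnet_cv(xn, sn$time, sn$event, penalty_config(), seed = s0)$is_null_model
  }, logical(1))
  expect_gt(mean(nulls), 0.5)

  # CV is reproducible for a fixed seed
  fit2 <- coxnet_cv(x, s$time, s$event, penalty_config(alpha = 0.95), seed = 33)
  expect_identical(fit$cv_mean, fit2$cv_mean)
  expect_identical(fit$lambda_1se, fit2$lambda_1se)

  # zero events is an explicit error
  expect_error(coxnet_cv(x, s$time, rep(0, n), penalty_config()),
               "at least 2 events")
})

test_that("weak penalties approach the unpenalized Cox fit", {
  set.seed(34)
  n <- 2000
  x <- cbind(a = rnorm(n), b = rnorm(n))
  s <- simulate_survival_times(0.8 * x[, 1] - 0.5 * x[, 2],
                               survival_mechanism(censor_rate = 0.05),
                               seed = 35)
  ref <- survival::coxph(survival::Surv(s$time, s$event) ~ x)
  near0 <- coxnet_refit(x, s$time, s$event, penalty_config(alpha = 0.5),
                        lambda = 1e-7)
  expect_equal(unname(coef(near0)), unname(coef(ref)), tolerance = 1e-3)
})

test_that("survival predictions compose the Breslow baseline correctly", {
  set.seed(36)
  x <- cbind(a = rnorm(40), b = rnorm(40))
  s <- simulate_survival_times(x[, 1], survival_mechanism(censor_rate = 0.1),
                               seed = 37)
  fit <- coxnet_refit(x, s$time, s$event, penalty_config(alpha = 0.5),
                      lambda = 0.05)
  times <- c(0, 1, 2, 3)
  sp <- predict(fit, x, type = "survival", times = times)
  expect_equal(unname(sp[, 1]), rep(1, 40))              # S(0) = 1
  expect_true(all(diff(t(sp)) <= 1e-12))                 # nonincreasing in t
  expect_true(all(sp >= 0 & sp <= 1))
  # monotone in eta: higher risk, lower survival
  lp <- predict(fit, x, type = "lp")
  ord <- order(lp)
  expect_true(all(diff(sp[ord, 4]) <= 1e-12))

  # a forced-null model predicts one shared curve exp(-H0)
  nullfit <- coxnet_refit(x, s$time, s$event, penalty_config(alpha = 0.95),
                          lambda = 10)
  expect_true(nullfit$is_null_model)
  expect_equal(unname(predict(nullfit, x, type = "lp")), rep(0, 40))
  spn <- predict(nullfit, x, type = "survival", times = 2)
  expect_equal(length(unique(spn[, 1])), 1L)
  expect_equal(unname(spn[1, 1]),
               exp(-coxvalsim:::breslow_eval(nullfit$breslow, 2)))

  # linear predictor is the plain dot product
  toyb <- fit
  toyb$beta <- c(a = 2, b = -1)
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(predict(toyb, m, type = "lp")),
               drop(m %*% c(2, -1)))
  # schema mismatch is an error
  bad <- m
  colnames(bad) <- c("b", "a")
  expect_error(predict(toyb, bad, type = "lp"), "do not match")
  expect_error(predict(fit, x, type = "survival", times = -1), "nonnegative")
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(38)
  x <- cbind(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  s <- simulate_survival_times(x[, 1], survival_mechanism(censor_rate = 0.1),
                               seed = 39)
  fit <- coxnet_refit(x, s$time, s$event, penalty_config(alpha = 0.5),
                      lambda = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  coxnet_to_json(fit, path)
  back <- coxnet_from_json(path)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(predict(back, x, type = "survival", times = c(1, 2)),
               predict(fit, x, type = "survival", times = c(1, 2)),
               tolerance = 1e-10)
})
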