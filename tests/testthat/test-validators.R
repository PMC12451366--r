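test_that("0.632+ combination satisfies its arithmetic identities", {
  cmb <- coxvalsim:::combine_632plus
  # worked example: R = 0.5, w = 0.632/0.816, error 0.2549
  r <- cmb(0.1, 0.3, 0.5)
  expect_equal(r$R, 0.5)
  expect_equal(r$w, 0.632 / 0.816, tolerance = 1e-12)
  expect_equal(r$estimate, (1 - 0.632 / 0.816) * 0.1 + 0.632 / 0.816 * 0.3,
               tolerance = 1e-12)
  # no overfitting: plain 0.632 estimator
  r2 <- cmb(0.2, 0.2, 0.5)
  expect_equal(r2$R, 0)
  expect_equal(r2$w, 0.632)
  # maximal overfitting: estimate pinned at the no-information rate
  r3 <- cmb(0.05, 0.7, 0.5)
  expect_equal(r3$R, 1)
  expect_equal(r3$w, 1)
  expect_equal(r3$estimate, 0.5)
  # weight always within [0.632, 1]
  set.seed(70)
  for (i in 1:200) {
    app <- runif(1, 0, 0.6); oob <- runif(1, 0, 0.8)
    w <- cmb(app, oob, 0.5)$w
    expect_gte(w, 0.632); expect_lte(w, 1)
  }
})

test_that("train-test validation discriminates signal from noise", {
  # strong signal: held-out 3y AUC is high
  coh <- generate_cohort(400, strong_gp(), seed = 71)
  est <- validate_train_test(coh, penalty_config(alpha = 0.95),
                             strategy_config(), seed = 72)
  expect_gt(est$auc_3y, 0.9)
  # deterministic given the seed
  est2 <- validate_train_test(coh, penalty_config(alpha = 0.95),
                              strategy_config(), seed = 72)
  expect_equal(est$auc_3y, est2$auc_3y)
  expect_equal(est$diagnostics$n_train, 280)
  expect_equal(est$diagnostics$n_test, 120)

  # pure noise at n = 50: near-chance on average
  aucs <- vapply(1:10, function(s) {
    cohn <- generate_cohort(50, noise_gp(), seed = 7000 + s)
    validate_train_test(cohn, penalty_config(), strategy_config(),
                        seed = s)$auc_3y
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.12)
})

test_that("conventional bootstrap shows the classic resample geometry", {
  coh <- generate_cohort(80, small_gp(), seed = 73)
  fit <- coxnet_cv(cohort_features(coh), coh$time, coh$event,
                   penalty_config(), seed = 74)
  est <- validate_bootstrap(coh, penalty_config(),
                            strategy_config(bootstrap_iters = 40), seed = 75,
                            full_fit = fit)
  # expected distinct-subject fraction ~ 0.632 <=> OOB fraction ~ 0.368
  expect_lt(abs(est$diagnostics$mean_oob_size / 80 - 0.368), 0.04)

  # B = 1 equals a single fit-evaluate pass
  est1 <- validate_bootstrap(coh, penalty_config(),
                             strategy_config(bootstrap_iters = 1), seed = 76,
                             full_fit = fit)
  idx <- coxvalsim:::with_seed(derive_seed(76, 4L, 1L),
                               sample.int(80, 80, replace = TRUE))
  x <- cohort_features(coh)
  m <- coxnet_refit(x[idx, ], coh$time[idx], coh$event[idx],
                    penalty_config(), lambda = fit$lambda_1se,
                    lambda_path = fit$lambda)
  a <- auc_cd(predict(m, x, type = "lp"), coh$time, coh$event, 3,
              censoring_km(coh$time, coh$event))
  expect_equal(est1$auc_3y, as.numeric(a), tolerance = 1e-12)
})

test_that("bootstrap optimism exceeds split-sample estimates on noise", {
  # paired comparison over replicate small-n noise cohorts
  pairs <- vapply(1:10, function(s) {
    coh <- generate_cohort(50, noise_gp(), seed = 7100 + s)
    fit <- coxnet_cv(cohort_features(coh), coh$time, coh$event,
                     penalty_config(), seed = s)
    bt <- validate_bootstrap(coh, penalty_config(),
                             strategy_config(bootstrap_iters = 20),
                             seed = s, full_fit = fit)
    tt <- validate_train_test(coh, penalty_config(), strategy_config(),
                              seed = s, full_fit = fit)
    c(bt = bt$auc_3y, tt = tt$auc_3y)
  }, numeric(2))
  expect_gt(mean(pairs["bt", ], na.rm = TRUE), mean(pairs["tt", ], na.rm = TRUE))
})

test_that("0.632+ bootstrap stays between apparent and out-of-bag", {
  coh <- generate_cohort(60, small_gp(), seed = 77)
  fit <- coxnet_cv(cohort_features(coh), coh$time, coh$event,
                   penalty_config(), seed = 78)
  est <- validate_bootstrap_632plus(coh, penalty_config(),
                                    strategy_config(bootstrap_iters = 30),
                                    seed = 79, full_fit = fit)
  d <- est$diagnostics
  expect_true(all(d$w >= 0.632 - 1e-12 & d$w <= 1 + 1e-12))
  # the combined AUC lies between the OOB and apparent AUCs
  lo <- min(d$apparent$auc_3y, max(d$oob$auc_3y, 0.5))
  hi <- max(d$apparent$auc_3y, max(d$oob$auc_3y, 0.5))
  expect_gte(est$auc_3y, lo - 1e-9)
  expect_lte(est$auc_3y, hi + 1e-9)
  expect_equal(est$strategy, "bootstrap_632plus")
})

test_that("K-fold CV partitions exactly and reduces to leave-one-out", {
  coh <- generate_cohort(100, small_gp(), seed = 80)
  fit <- coxnet_cv(cohort_features(coh), coh$time, coh$event,
                   penalty_config(), seed = 81)
  est <- validate_kfold_cv(coh, penalty_config(),
                           strategy_config(cv_repeats = 2), seed = 82,
                           full_fit = fit)
  expect_identical(nrow(est$per_repetition), 2L)
  # every fold partition covers all subjects exactly once
  part <- coxvalsim:::valid_partition(coh$event, 5, derive_seed(82, 8L, 1L), 10)
  expect_identical(sort(unique(part$folds)), 1:5)
  expect_identical(length(part$folds), 100L)
  expect_true(all(abs(tabulate(part$folds, 5) - 20) <= 2))

  # K = n on an all-events toy equals a manual leave-one-out pass
  set.seed(83)
  xf <- matrix(rnorm(12 * 5), 12)
  lp <- xf[, 1]
  s <- simulate_survival_times(lp, survival_mechanism(censor_rate = 0), seed = 84)
  toy <- toy_cohort(xf, s$time, s$event)  # no censoring: all events by 5y?
  toy$event <- rep(1L, 12); toy$time <- pmin(s$latent_time, 4.9)
  fit_t <- coxnet_cv(cohort_features(toy), toy$time, toy$event,
                     penalty_config(cv_folds = 4), seed = 85)
  est_loo <- validate_kfold_cv(toy, penalty_config(cv_folds = 4),
                               strategy_config(cv_folds = 12, cv_repeats = 1),
                               seed = 86, full_fit = fit_t)
  # manual LOO with the same lambda
  x <- cohort_features(toy)
  risk <- numeric(12)
  for (i in 1:12) {
    m <- coxnet_refit(x[-i, ], toy$time[-i], toy$event[-i],
                      penalty_config(cv_folds = 4), lambda = fit_t$lambda_1se,
                      lambda_path = fit_t$lambda)
    risk[i] <- predict(m, x[i, , drop = FALSE], type = "lp")
  }
  a <- auc_cd(risk, toy$time, toy$event, 3, censoring_km(toy$time, toy$event))
  expect_equal(est_loo$auc_3y, as.numeric(a), tolerance = 1e-10)

  # strong signal comes through pooled out-of-fold predictions
  cohs <- generate_cohort(300, strong_gp(), seed = 87)
  fits <- coxnet_cv(cohort_features(cohs), cohs$time, cohs$event,
                    penalty_config(alpha = 0.95), seed = 88)
  ests <- validate_kfold_cv(cohs, penalty_config(alpha = 0.95),
                            strategy_config(cv_repeats = 1), seed = 89,
                            full_fit = fits)
  expect_gt(ests$auc_3y, 0.9)
})

test_that("nested CV never leaks the outer fold into tuning", {
  coh <- generate_cohort(90, small_gp(), seed = 90)
  est <- validate_nested_cv(coh, penalty_config(),
                            strategy_config(ncv_repeats = 2), seed = 91)
  expect_identical(nrow(est$per_repetition), 2L)
  parts <- est$diagnostics$partitions
  expect_identical(length(parts), 2L)
  for (folds in parts) {
    expect_identical(length(folds), 90L)
    expect_identical(sort(unique(folds)), 1:5)
    # bookkeeping invariant: outer test fold disjoint from its training set
    for (fk in 1:5)
      expect_length(intersect(which(folds == fk), which(folds != fk)), 0)
  }

  # pooling consistency: an independent re-implementation of the outer loop
  # with the same seed stream reproduces the estimate
  x <- cohort_features(coh)
  part <- coxvalsim:::valid_partition(coh$event, 5, derive_seed(91, 10L, 1L), 10)
  risk <- numeric(90); grid <- seq(0, 3, 0.1)
  surv <- matrix(NA_real_, 90, length(grid))
  pen <- penalty_config(); pen$cv_folds <- 5L
  for (fk in 1:5) {
    test <- part$folds == fk
    m <- coxnet_cv(x[!test, ], coh$time[!test], coh$event[!test], pen,
                   seed = derive_seed(91, 11L, 1L, fk))
    risk[test] <- predict(m, x[test, , drop = FALSE], type = "lp")
    surv[test, ] <- predict(m, x[test, , drop = FALSE], type = "survival",
                            times = grid)
  }
  G <- censoring_km(coh$time, coh$event)
  expect_equal(est$per_repetition$auc_3y[1],
               as.numeric(auc_cd(risk, coh$time, coh$event, 3, G)),
               tolerance = 1e-10)
})

test_that("independent validation honors the oracle and the null model", {
  gp <- strong_gp()
  coh <- generate_cohort(300, gp, seed = 92)
  ind <- generate_cohort(400, gp, seed = 93)
  fit <- coxnet_cv(cohort_features(coh), coh$time, coh$event,
                   penalty_config(alpha = 0.95), seed = 94)
  est <- validate_independent(fit, ind)
  expect_gt(est$auc_3y, 0.85)

  # a null model scores exactly 0.5 by the tie rule
  x <- cohort_features(coh)
  nullfit <- coxnet_refit(x, coh$time, coh$event, penalty_config(alpha = 0.95),
                          lambda = 50)
  expect_true(nullfit$is_null_model)
  est0 <- validate_independent(nullfit, ind)
  expect_equal(est0$auc_3y, 0.5)
  expect_equal(est0$c_index, 0.5)

  # oracle risk scores on the independent set give the oracle AUC
  orc <- oracle_performance(ind)
  a <- auc_cd(ind$true_lp, ind$time, ind$event, 3,
              censoring_km(ind$time, ind$event))
  expect_equal(orc$auc_3y, as.numeric(a))
})
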