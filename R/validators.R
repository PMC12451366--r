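#' Resampling strategy configuration
#'
#' Parameters of the five internal-validation strategies.  The
#' `lambda_policy` controls where the penalty is tuned: `"fixed_full_data"`
#' (default) fixes lambda-1SE by cross-validation on the full dataset
#' before resampling, for strategies other than nested CV (which always
#' tunes in its inner loop); `"refit_per_resample"` re-tunes lambda on each
#' resampled training set.
#'
#' @param train_fraction training fraction for the train-test split.
#' @param bootstrap_iters number of bootstrap iterations B.
#' @param cv_folds K for (repeated) K-fold cross-validation.
#' @param cv_repeats repetitions of K-fold cross-validation.
#' @param ncv_outer,ncv_inner outer / inner fold counts for nested CV.
#' @param ncv_repeats repeats of the whole nested-CV procedure.
#' @param lambda_policy `"fixed_full_data"` or `"refit_per_resample"`.
#' @param max_split_attempts resampling attempts before an eventless
#'   split/fold is reported as undefined.
#' @return an object of class `strategy_config`.
#' @export
strategy_config <- function(train_fraction = 0.7, bootstrap_iters = 100,
                            cv_folds = 5, cv_repeats = 10,
                            ncv_outer = 5, ncv_inner = 5, ncv_repeats = 5,
                            lambda_policy = c("fixed_full_data",
                                              "refit_per_resample"),
                            max_split_attempts = 10) {
  stopifnot(train_fraction > 0, train_fraction < 1, bootstrap_iters >= 1,
            cv_folds >= 2, cv_repeats >= 1, ncv_outer >= 2, ncv_inner >= 2,
            ncv_repeats >= 1, max_split_attempts >= 1)
  structure(list(train_fraction = train_fraction,
                 bootstrap_iters = as.integer(bootstrap_iters),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 ncv_outer = as.integer(ncv_outer),
                 ncv_inner = as.integer(ncv_inner),
                 ncv_repeats = as.integer(ncv_repeats),
                 lambda_policy = match.arg(lambda_policy),
                 max_split_attempts = as.integer(max_split_attempts)),
            class = "strategy_config")
}

## Evaluation-grid constants: AUC horizons 1-5y by 0.1; Brier integration
## grid 0-3y by 0.1; 3-year values are read at the grid point exactly 3.0.
auc_grid <- function() seq(1, 5, by = 0.1)
ibs_grid <- function(t_max = 3) seq(0, t_max, by = 0.1)

metric_bundle <- function(risk, surv, time, event, G = censoring_km(time, event)) {
  curve <- auc_curve(risk, time, event, auc_grid(), G)
  list(auc_curve = curve,
       auc_3y = curve$auc[abs(curve$time - 3) < 1e-9],
       c_index = as.numeric(harrell_c(risk, time, event)),
       ibs_3y = ibs(surv, time, event, ibs_grid(), 3, G))
}

new_validation_estimate <- function(strategy, auc_curve, auc_3y, c_index,
                                    ibs_3y, diagnostics = list(),
                                    per_repetition = NULL) {
  structure(list(strategy = strategy, auc_curve = auc_curve,
                 auc_3y = auc_3y, c_index = c_index, ibs_3y = ibs_3y,
                 diagnostics = diagnostics, per_repetition = per_repetition),
            class = "validation_estimate")
}

#' @export
print.validation_estimate <- function(x, ...) {
  cat(sprintf("Validation estimate [%s]\n", x$strategy))
  cat(sprintf("  3y AUC %.3f | C-index %.3f | 3y IBS %.4f\n",
              x$auc_3y, x$c_index, x$ibs_3y))
  d <- x$diagnostics
  if (!is.null(d$null_model_fraction))
    cat(sprintf("  null-model fraction: %.2f\n", d$null_model_fraction))
  if (!is.null(d$n_skipped) && d$n_skipped > 0)
    cat(sprintf("  skipped resamples: %d\n", d$n_skipped))
  invisible(x)
}

## Fit a model on a resampled training set under the lambda policy.
fit_resample <- function(x, time, event, penalty, cfg, seed, full_fit) {
  if (cfg$lambda_policy == "fixed_full_data") {
    coxnet_refit(x, time, event, penalty, lambda = full_fit$lambda_1se,
                 lambda_path = full_fit$lambda)
  } else {
    coxnet_cv(x, time, event, penalty, seed = seed)
  }
}

ensure_full_fit <- function(full_fit, x, time, event, penalty, seed) {
  if (!is.null(full_fit)) return(full_fit)
  coxnet_cv(x, time, event, penalty, seed = derive_seed(seed, 1000L))
}

mean_auc_curves <- function(curves) {
  if (!length(curves)) return(NULL)
  times <- curves[[1]]$time
  m <- vapply(curves, function(cv) cv$auc, numeric(length(times)))
  m <- matrix(m, nrow = length(times))
  data.frame(time = times, auc = rowMeans(m, na.rm = TRUE),
             n_evaluable = rowSums(!is.na(m)))
}

namean <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)

#' Train-test (split-sample) validation
#'
#' Randomly splits the cohort into a training fraction (model derivation)
#' and a testing fraction (evaluation); metrics are computed on the test
#' split.  An eventless test or near-eventless train split triggers a
#' fresh split (up to `max_split_attempts`, logged), after which the
#' estimate is flagged undefined.
#'
#' @param cohort a `cox_cohort`.
#' @param penalty a [penalty_config()].
#' @param cfg a [strategy_config()].
#' @param seed RNG seed.
#' @param full_fit optional precomputed full-data [coxnet_cv()] (used under
#'   the fixed-lambda policy; computed internally when missing).
#' @return a `validation_estimate`.
#' @export
validate_train_test <- function(cohort, penalty = penalty_config(),
                                cfg = strategy_config(), seed = NULL,
                                full_fit = NULL) {
  x <- cohort_features(cohort)
  time <- cohort$time; event <- cohort$event
  n <- length(time)
  if (cfg$lambda_policy == "fixed_full_data")
    full_fit <- ensure_full_fit(full_fit, x, time, event, penalty, seed)
  n_train <- floor(cfg$train_fraction * n)
  for (attempt in seq_len(cfg$max_split_attempts)) {
    idx <- with_seed(derive_seed(seed, 2L, attempt),
                     sample.int(n, n_train))
    test <- setdiff(seq_len(n), idx)
    if (sum(event[test]) >= 1 && sum(event[idx]) >= 2) {
      if (attempt > 1) vs_log("train-test: resampled split %d times", attempt - 1)
      model <- fit_resample(x[idx, , drop = FALSE], time[idx], event[idx],
                            penalty, cfg, derive_seed(seed, 3L, attempt),
                            full_fit)
      xt <- x[test, , drop = FALSE]
      risk <- predict(model, xt, type = "lp")
      surv <- predict(model, xt, type = "survival", times = ibs_grid())
      mb <- metric_bundle(risk, surv, time[test], event[test])
      return(new_validation_estimate(
        "train_test", mb$auc_curve, mb$auc_3y, mb$c_index, mb$ibs_3y,
        diagnostics = list(null_model_fraction = as.numeric(model$is_null_model),
                           split_attempts = attempt,
                           n_train = n_train, n_test = length(test))))
    }
  }
  vs_log("train-test: no valid split in %d attempts", cfg$max_split_attempts)
  new_validation_estimate("train_test", NULL, NA_real_, NA_real_, NA_real_,
                          diagnostics = list(split_attempts = cfg$max_split_attempts,
                                             undefined = TRUE))
}

#' Conventional bootstrap validation
#'
#' For each of B iterations, the training set is a with-replacement
#' bootstrap sample of size n and the testing set is the full original
#' dataset; the estimate is the mean of the per-iteration metrics.  The
#' train/test overlap this entails is the source of the optimism this
#' strategy exhibits.  Degenerate bootstrap samples (< 2 events) are
#' skipped and logged.
#'
#' @inheritParams validate_train_test
#' @return a `validation_estimate`.
#' @export
validate_bootstrap <- function(cohort, penalty = penalty_config(),
                               cfg = strategy_config(), seed = NULL,
                               full_fit = NULL) {
  x <- cohort_features(cohort)
  time <- cohort$time; event <- cohort$event
  n <- length(time)
  if (cfg$lambda_policy == "fixed_full_data")
    full_fit <- ensure_full_fit(full_fit, x, time, event, penalty, seed)
  G <- censoring_km(time, event)
  surv_times <- ibs_grid()
  rows <- list(); curves <- list(); skipped <- 0L; nulls <- 0L; oob_sizes <- c()
  for (b in seq_len(cfg$bootstrap_iters)) {
    idx <- with_seed(derive_seed(seed, 4L, b), sample.int(n, n, replace = TRUE))
    if (sum(event[idx]) < 2) { skipped <- skipped + 1L; next }
    model <- fit_resample(x[idx, , drop = FALSE], time[idx], event[idx],
                          penalty, cfg, derive_seed(seed, 5L, b), full_fit)
    nulls <- nulls + model$is_null_model
    oob_sizes <- c(oob_sizes, n - length(unique(idx)))
    risk <- predict(model, x, type = "lp")
    surv <- predict(model, x, type = "survival", times = surv_times)
    mb <- metric_bundle(risk, surv, time, event, G)
    rows[[length(rows) + 1L]] <- data.frame(iteration = b, auc_3y = mb$auc_3y,
                                            c_index = mb$c_index,
                                            ibs_3y = mb$ibs_3y)
    curves[[length(curves) + 1L]] <- mb$auc_curve
  }
  if (skipped > 0) vs_log("bootstrap: skipped %d degenerate samples", skipped)
  per <- do.call(rbind, rows)
  new_validation_estimate(
    "bootstrap", mean_auc_curves(curves),
    namean(per$auc_3y), namean(per$c_index), namean(per$ibs_3y),
    diagnostics = list(n_iterations = nrow(per), n_skipped = skipped,
                       null_model_fraction = nulls / max(nrow(per), 1),
                       mean_oob_size = mean(oob_sizes)),
    per_repetition = per)
}

## 0.632+ combination on the error scale (Efron & Tibshirani).
## err_oob is clipped at the no-information error gamma; the relative
## overfitting ratio R drives the weight w in [0.632, 1].
combine_632plus <- function(err_app, err_oob, gamma) {
  if (is.na(err_app) || is.na(err_oob) || is.na(gamma))
    return(list(estimate = NA_real_, w = NA_real_, R = NA_real_))
  err_oob_p <- min(err_oob, gamma)
  R <- if (err_oob_p > err_app && gamma > err_app)
    (err_oob_p - err_app) / (gamma - err_app) else 0
  R <- min(max(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  list(estimate = (1 - w) * err_app + w * err_oob_p, w = w, R = R)
}

## No-information Brier curve: every prediction paired with every outcome.
## Separable into (mean squared survival prediction) x (IPCW case weight)
## + (mean squared failure prediction) x (IPCW control weight).
noinfo_brier <- function(surv_matrix, time, event, times, G) {
  gi <- G$Gminus(time)
  vapply(seq_along(times), function(j) {
    t <- times[j]
    s <- surv_matrix[, j]
    case <- time <= t & event == 1 & gi > 0
    ctrl <- time > t
    gt <- G$G(t)
    a <- mean(ifelse(case, 1 / gi, 0))
    b <- if (gt > 0) mean(ctrl) / gt else 0
    mean(s^2) * a + mean((1 - s)^2) * b
  }, numeric(1))
}

#' 0.632+ bootstrap validation
#'
#' Combines the apparent error (full-data model evaluated on the full
#' data) with the out-of-bag bootstrap error (each iteration's model
#' evaluated on the subjects absent from its bootstrap sample), weighted by
#' the relative overfitting ratio against the no-information error rate
#' (0.5 for AUC and C-index; the all-pairings Brier rate for IBS).
#' Metrics are computed on the error scale (1 - AUC, 1 - C, Brier) and
#' back-transformed.
#'
#' @inheritParams validate_train_test
#' @return a `validation_estimate`; diagnostics include the 0.632+ weights
#'   and the out-of-bag evaluability counts.
#' @export
validate_bootstrap_632plus <- function(cohort, penalty = penalty_config(),
                                       cfg = strategy_config(), seed = NULL,
                                       full_fit = NULL) {
  x <- cohort_features(cohort)
  time <- cohort$time; event <- cohort$event
  n <- length(time)
  full_fit <- ensure_full_fit(full_fit, x, time, event, penalty, seed)
  G <- censoring_km(time, event)
  surv_times <- ibs_grid()

  risk_app <- predict(full_fit, x, type = "lp")
  surv_app <- predict(full_fit, x, type = "survival", times = surv_times)
  app <- metric_bundle(risk_app, surv_app, time, event, G)
  gamma_ibs <- {
    gb <- noinfo_brier(surv_app, time, event, surv_times, G)
    sum(diff(surv_times) * (gb[-1] + gb[-length(gb)]) / 2) / max(surv_times)
  }

  rows <- list(); curves <- list(); skipped <- 0L; nulls <- 0L
  for (b in seq_len(cfg$bootstrap_iters)) {
    idx <- with_seed(derive_seed(seed, 6L, b), sample.int(n, n, replace = TRUE))
    oob <- setdiff(seq_len(n), idx)
    if (sum(event[idx]) < 2 || length(oob) < 2 || sum(event[oob]) < 1) {
      skipped <- skipped + 1L; next
    }
    model <- fit_resample(x[idx, , drop = FALSE], time[idx], event[idx],
                          penalty, cfg, derive_seed(seed, 7L, b), full_fit)
    nulls <- nulls + model$is_null_model
    xo <- x[oob, , drop = FALSE]
    risk <- predict(model, xo, type = "lp")
    surv <- predict(model, xo, type = "survival", times = surv_times)
    mb <- metric_bundle(risk, surv, time[oob], event[oob])
    rows[[length(rows) + 1L]] <- data.frame(iteration = b, auc_3y = mb$auc_3y,
                                            c_index = mb$c_index,
                                            ibs_3y = mb$ibs_3y,
                                            oob_size = length(oob))
    curves[[length(curves) + 1L]] <- mb$auc_curve
  }
  if (skipped > 0) vs_log("0.632+: skipped %d degenerate samples", skipped)
  per <- do.call(rbind, rows)

  comb_auc <- combine_632plus(1 - app$auc_3y, 1 - namean(per$auc_3y), 0.5)
  comb_c <- combine_632plus(1 - app$c_index, 1 - namean(per$c_index), 0.5)
  comb_ibs <- combine_632plus(app$ibs_3y, namean(per$ibs_3y), gamma_ibs)

  oob_curve <- mean_auc_curves(curves)
  curve_632 <- NULL
  if (!is.null(oob_curve)) {
    est <- mapply(function(a_app, a_oob) {
      combine_632plus(1 - a_app, 1 - a_oob, 0.5)$estimate
    }, app$auc_curve$auc, oob_curve$auc)
    curve_632 <- data.frame(time = oob_curve$time, auc = 1 - est,
                            n_evaluable = oob_curve$n_evaluable)
  }

  new_validation_estimate(
    "bootstrap_632plus", curve_632,
    1 - comb_auc$estimate, 1 - comb_c$estimate, comb_ibs$estimate,
    diagnostics = list(n_iterations = nrow(per), n_skipped = skipped,
                       null_model_fraction = nulls / max(nrow(per), 1),
                       mean_oob_size = namean(per$oob_size),
                       apparent = list(auc_3y = app$auc_3y,
                                       c_index = app$c_index,
                                       ibs_3y = app$ibs_3y),
                       oob = list(auc_3y = namean(per$auc_3y),
                                  c_index = namean(per$c_index),
                                  ibs_3y = namean(per$ibs_3y)),
                       gamma_ibs = gamma_ibs,
                       w = c(auc = comb_auc$w, c_index = comb_c$w,
                             ibs = comb_ibs$w),
                       R = c(auc = comb_auc$R, c_index = comb_c$R,
                             ibs = comb_ibs$R),
                       n_undefined_oob = sum(is.na(per$auc_3y))),
    per_repetition = per)
}

## Draw an event-stratified K-fold partition in which every fold holds at
## least one event and every training complement at least two.
valid_partition <- function(event, k, seed, max_attempts) {
  for (attempt in seq_len(max_attempts)) {
    folds <- stratified_folds(event, k, derive_seed(seed, attempt))
    ok <- all(vapply(seq_len(k), function(fk)
      sum(event[folds == fk]) >= 1 && sum(event[folds != fk]) >= 2,
      logical(1)))
    if (ok) return(list(folds = folds, attempts = attempt))
  }
  NULL
}

#' Repeated K-fold cross-validation
#'
#' Per repetition: an event-stratified partition into K folds; each fold is
#' predicted by the model fitted on the other K-1 folds; the out-of-fold
#' predictions are pooled (each subject predicted exactly once per
#' repetition) and metrics are computed once per repetition on the pooled
#' predictions.  The estimate is the mean over repetitions.
#'
#' @inheritParams validate_train_test
#' @return a `validation_estimate` with a `per_repetition` table.
#' @export
validate_kfold_cv <- function(cohort, penalty = penalty_config(),
                              cfg = strategy_config(), seed = NULL,
                              full_fit = NULL) {
  x <- cohort_features(cohort)
  time <- cohort$time; event <- cohort$event
  n <- length(time)
  if (cfg$lambda_policy == "fixed_full_data")
    full_fit <- ensure_full_fit(full_fit, x, time, event, penalty, seed)
  G <- censoring_km(time, event)
  surv_times <- ibs_grid()
  rows <- list(); curves <- list(); nulls <- 0L; nfits <- 0L; repart <- 0L
  for (r in seq_len(cfg$cv_repeats)) {
    part <- valid_partition(event, cfg$cv_folds, derive_seed(seed, 8L, r),
                            cfg$max_split_attempts)
    if (is.null(part)) {
      vs_log("k-fold CV: no valid partition at repetition %d", r)
      next
    }
    repart <- repart + (part$attempts - 1L)
    risk <- numeric(n); surv <- matrix(NA_real_, n, length(surv_times))
    for (fk in seq_len(cfg$cv_folds)) {
      test <- part$folds == fk
      model <- fit_resample(x[!test, , drop = FALSE], time[!test], event[!test],
                            penalty, cfg, derive_seed(seed, 9L, r, fk),
                            full_fit)
      nulls <- nulls + model$is_null_model; nfits <- nfits + 1L
      xt <- x[test, , drop = FALSE]
      risk[test] <- predict(model, xt, type = "lp")
      surv[test, ] <- predict(model, xt, type = "survival", times = surv_times)
    }
    mb <- metric_bundle(risk, surv, time, event, G)
    rows[[length(rows) + 1L]] <- data.frame(repetition = r, auc_3y = mb$auc_3y,
                                            c_index = mb$c_index,
                                            ibs_3y = mb$ibs_3y)
    curves[[length(curves) + 1L]] <- mb$auc_curve
  }
  per <- do.call(rbind, rows)
  new_validation_estimate(
    "kfold_cv", mean_auc_curves(curves),
    namean(per$auc_3y), namean(per$c_index), namean(per$ibs_3y),
    diagnostics = list(n_repetitions = nrow(per),
                       null_model_fraction = nulls / max(nfits, 1),
                       n_repartitions = repart),
    per_repetition = per)
}

#' Repeated nested cross-validation
#'
#' Per repeat: an event-stratified outer partition; within each outer
#' training set an inner J-fold cross-validation selects lambda-1SE, the
#' model is refitted on the full outer training set at that lambda, and
#' applied to the held-out outer fold.  Outer predictions are pooled per
#' repeat, metrics computed per repeat, and averaged over repeats.  The
#' outer test fold never informs lambda selection.
#'
#' @inheritParams validate_train_test
#' @return a `validation_estimate`; `diagnostics$partitions` records the
#'   per-repeat outer fold assignment for leakage auditing.
#' @export
validate_nested_cv <- function(cohort, penalty = penalty_config(),
                               cfg = strategy_config(), seed = NULL,
                               full_fit = NULL) {
  x <- cohort_features(cohort)
  time <- cohort$time; event <- cohort$event
  n <- length(time)
  G <- censoring_km(time, event)
  surv_times <- ibs_grid()
  inner_penalty <- penalty
  inner_penalty$cv_folds <- cfg$ncv_inner
  rows <- list(); curves <- list(); partitions <- list()
  nulls <- 0L; nfits <- 0L
  for (r in seq_len(cfg$ncv_repeats)) {
    part <- valid_partition(event, cfg$ncv_outer, derive_seed(seed, 10L, r),
                            cfg$max_split_attempts)
    if (is.null(part)) {
      vs_log("nested CV: no valid outer partition at repeat %d", r)
      next
    }
    partitions[[r]] <- part$folds
    risk <- numeric(n); surv <- matrix(NA_real_, n, length(surv_times))
    for (fk in seq_len(cfg$ncv_outer)) {
      test <- part$folds == fk
      model <- coxnet_cv(x[!test, , drop = FALSE], time[!test], event[!test],
                         inner_penalty, seed = derive_seed(seed, 11L, r, fk))
      nulls <- nulls + model$is_null_model; nfits <- nfits + 1L
      xt <- x[test, , drop = FALSE]
      risk[test] <- predict(model, xt, type = "lp")
      surv[test, ] <- predict(model, xt, type = "survival", times = surv_times)
    }
    mb <- metric_bundle(risk, surv, time, event, G)
    rows[[length(rows) + 1L]] <- data.frame(repeat_ = r, auc_3y = mb$auc_3y,
                                            c_index = mb$c_index,
                                            ibs_3y = mb$ibs_3y)
    curves[[length(curves) + 1L]] <- mb$auc_curve
  }
  per <- do.call(rbind, rows)
  new_validation_estimate(
    "nested_cv", mean_auc_curves(curves),
    namean(per$auc_3y), namean(per$c_index), namean(per$ibs_3y),
    diagnostics = list(n_repeats = nrow(per),
                       null_model_fraction = nulls / max(nfits, 1),
                       partitions = partitions),
    per_repetition = per)
}

#' Independent (external) validation on a second cohort
#'
#' Evaluates a model fitted once on the full training cohort on an
#' independently generated cohort from the same mechanism.
#'
#' @param full_fit a full-data [coxnet_cv()] (lambda-1SE model).
#' @param independent a `cox_cohort` generated with a disjoint seed.
#' @return a `validation_estimate`.
#' @export
validate_independent <- function(full_fit, independent) {
  x <- cohort_features(independent)
  risk <- predict(full_fit, x, type = "lp")
  surv <- predict(full_fit, x, type = "survival", times = ibs_grid())
  mb <- metric_bundle(risk, surv, independent$time, independent$event)
  new_validation_estimate(
    "independent", mb$auc_curve, mb$auc_3y, mb$c_index, mb$ibs_3y,
    diagnostics = list(null_model_fraction = as.numeric(full_fit$is_null_model),
                       n_independent = length(independent$time)))
}

#' Run a named validation strategy
#'
#' Dispatch helper mapping strategy names (`"train_test"`, `"bootstrap"`,
#' `"bootstrap_632plus"`, `"kfold_cv"`, `"nested_cv"`) to their
#' implementations.
#'
#' @inheritParams validate_train_test
#' @param strategy strategy name.
#' @return a `validation_estimate`.
#' @export
run_strategy <- function(strategy, cohort, penalty = penalty_config(),
                         cfg = strategy_config(), seed = NULL,
                         full_fit = NULL) {
  fn <- switch(strategy,
               train_test = validate_train_test,
               bootstrap = validate_bootstrap,
               bootstrap_632plus = validate_bootstrap_632plus,
               kfold_cv = validate_kfold_cv,
               nested_cv = validate_nested_cv,
               stopf("unknown strategy '%s'", strategy))
  fn(cohort, penalty, cfg, seed = seed, full_fit = full_fit)
}

#' Serialize a validation estimate to JSON
#'
#' @param estimate a `validation_estimate`.
#' @param path output file.
#' @param config optional configuration to record alongside.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
validation_to_json <- function(estimate, path, config = NULL, seed = NULL) {
  obj <- list(strategy = estimate$strategy, auc_3y = estimate$auc_3y,
              c_index = estimate$c_index, ibs_3y = estimate$ibs_3y,
              auc_curve = estimate$auc_curve,
              diagnostics = estimate$diagnostics[setdiff(names(estimate$diagnostics),
                                                         "partitions")],
              per_repetition = estimate$per_repetition,
              config = config, seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
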