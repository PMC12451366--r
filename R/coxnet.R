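#' Elastic-net penalty configuration
#'
#' @param alpha elastic-net mixing parameter in [0, 1]: 0.05 "ridge-like",
#'   0.5 "elastic net", 0.95 "lasso-like".
#' @param nlambda number of penalty values on the path.
#' @param lambda_min_ratio smallest lambda as a fraction of the largest;
#'   `NULL` uses the solver default.
#' @param cv_folds number of cross-validation folds for lambda selection.
#' @param standardize standardize features before penalization (coefficients
#'   are reported on the original scale).
#' @return an object of class `penalty_config`.
#' @export
penalty_config <- function(alpha = 0.95, nlambda = 50,
                           lambda_min_ratio = 0.05, cv_folds = 10,
                           standardize = TRUE) {
  stopifnot(alpha >= 0, alpha <= 1, cv_folds >= 2, nlambda >= 2)
  structure(list(alpha = alpha, nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 cv_folds = as.integer(cv_folds),
                 standardize = isTRUE(standardize)),
            class = "penalty_config")
}

## Breslow-ties Cox partial-likelihood deviance: D = -2 * pl(eta).
## Tied event times share a single risk-set denominator.
cox_deviance <- function(eta, time, event) {
  ev <- which(event == 1)
  if (!length(ev)) return(0)
  ord <- order(time)
  w <- exp(eta[ord])
  tt <- time[ord]
  ee <- event[ord]
  # sum of exp(eta) over the risk set {j : time_j >= t}, per sorted position
  rs <- rev(cumsum(rev(w)))
  first_at_time <- !duplicated(tt)
  denom_at <- rs[first_at_time]
  tkey <- cumsum(first_at_time)            # distinct-time index per position
  ll <- sum(eta[ord][ee == 1]) - sum(log(denom_at[tkey[ee == 1]]))
  -2 * ll
}

#' Select the penalty by the one-standard-error rule
#'
#' Returns the largest lambda whose cross-validated loss is within one
#' standard error of the minimum, i.e. favoring the sparsest model whose
#' performance is statistically indistinguishable from the best.
#'
#' @param cv_mean mean CV loss per lambda.
#' @param cv_se standard error of the CV loss per lambda.
#' @param lambda strictly decreasing penalty path.
#' @return the selected lambda.
#' @export
select_lambda_1se <- function(cv_mean, cv_se, lambda) {
  if (!length(lambda)) stopf("empty lambda path")
  if (length(cv_mean) != length(lambda) || length(cv_se) != length(lambda))
    stopf("cv_mean, cv_se and lambda must have equal lengths")
  if (is.unsorted(rev(lambda), strictly = TRUE))
    stopf("lambda path must be strictly decreasing")
  i_min <- which.min(cv_mean)
  thresh <- cv_mean[i_min] + cv_se[i_min]
  lambda[min(which(cv_mean <= thresh))]
}

## Breslow estimator of the cumulative baseline hazard on training data.
## Returns a step-function representation: H0(t) = sum_{event times <= t}
## d_k / sum_{j at risk} exp(eta_j).
breslow_cumhaz <- function(time, event, eta) {
  ord <- order(time)
  tt <- time[ord]; ee <- event[ord]; w <- exp(eta[ord])
  rs <- rev(cumsum(rev(w)))
  first_at_time <- !duplicated(tt)
  dt <- tt[first_at_time]
  denom <- rs[first_at_time]
  tkey <- cumsum(first_at_time)
  d <- vapply(seq_along(dt), function(k) sum(ee[tkey == k]), numeric(1))
  keep <- d > 0
  inc <- d[keep] / denom[keep]
  structure(list(time = dt[keep], hazard = inc, H0 = cumsum(inc)),
            class = "breslow_cumhaz")
}

breslow_eval <- function(br, t) {
  stopifnot(all(t >= 0))
  if (!length(br$time)) return(rep(0, length(t)))
  f <- stats::stepfun(br$time, c(0, br$H0))
  f(t)
}

check_survival_input <- function(x, time, event) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(time) || length(time) != length(event))
    stopf("x, time and event dimensions disagree")
  if (any(!is.finite(x))) stopf("features must be finite")
  if (any(time <= 0)) stopf("times must be positive")
  if (!all(event %in% c(0, 1))) stopf("event must be coded 0/1")
  if (sum(event) < 2) stopf("need at least 2 events to fit a Cox model")
  x
}

#' Fit an elastic-net penalized Cox model with cross-validated lambda
#'
#' Fits the regularization path by penalized Cox partial likelihood
#' (delegated to `glmnet`), then runs the package's own K-fold
#' cross-validation driver: event-stratified fold assignment, per-fold
#' partial-likelihood deviance (Verweij-van Houwelingen form,
#' `D_all(beta_k) - D_train(beta_k)`, per event), and one-standard-error
#' lambda selection.  The Breslow baseline cumulative hazard is estimated
#' on the training data at the selected lambda.
#'
#' A model with no nonzero coefficients at the selected lambda is a valid
#' result (`is_null_model`), not an error: downstream metrics score its
#' constant risk as AUC = C = 0.5 by the tie rule, and its survival curve
#' is the Breslow (covariate-free) curve.
#'
#' @param x feature matrix (n x p); columns are clinical covariates and/or
#'   log1p expression.
#' @param time,event right-censored outcome (years, 0/1).
#' @param penalty a [penalty_config()].
#' @param seed RNG seed for fold assignment.
#' @return an object of classes `coxnet_cv`, `coxnet_fit`: list with
#'   `alpha`, `lambda` (path), `cv_mean`, `cv_se`, `lambda_min`,
#'   `lambda_1se`, `beta` (named coefficient vector at `lambda_1se`),
#'   `n_nonzero`, `is_null_model`, `breslow`, `path_truncated`
#'   (non-convergence record), training outcome and linear predictor.
#' @export
coxnet_cv <- function(x, time, event, penalty = penalty_config(), seed = NULL) {
  x <- check_survival_input(x, time, event)
  y <- survival::Surv(time, event)
  args <- list(x = x, y = y, family = "cox", alpha = penalty$alpha,
               nlambda = penalty$nlambda, standardize = penalty$standardize)
  if (!is.null(penalty$lambda_min_ratio))
    args$lambda.min.ratio <- penalty$lambda_min_ratio
  full <- do.call(glmnet::glmnet, args)
  path <- full$lambda
  truncated <- length(path) < penalty$nlambda

  k <- penalty$cv_folds
  folds <- stratified_folds(event, k, seed = seed)
  per_fold <- matrix(NA_real_, k, length(path))
  for (fk in seq_len(k)) {
    test <- folds == fk
    if (sum(event[!test]) < 2 || sum(event[test]) < 1) next
    fitk <- do.call(glmnet::glmnet,
                    utils::modifyList(args, list(x = x[!test, , drop = FALSE],
                                                 y = y[!test],
                                                 lambda = path)))
    eta <- stats::predict(fitk, newx = x, s = path, type = "link")
    d_test <- sum(event[test])
    for (j in seq_len(ncol(eta))) {
      d_all <- cox_deviance(eta[, j], time, event)
      d_tr <- cox_deviance(eta[!test, j], time[!test], event[!test])
      per_fold[fk, j] <- (d_all - d_tr) / d_test
    }
  }
  used <- rowSums(is.na(per_fold)) < length(path)
  if (sum(used) < 2) stopf("cross-validation failed: too few usable folds")
  cvm <- colMeans(per_fold[used, , drop = FALSE], na.rm = TRUE)
  cvse <- apply(per_fold[used, , drop = FALSE], 2,
                function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  lambda_1se <- select_lambda_1se(cvm, cvse, path)
  lambda_min <- path[which.min(cvm)]

  beta <- drop(as.matrix(stats::predict(full, type = "coefficients",
                                        s = lambda_1se)))
  names(beta) <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  eta_train <- drop(x %*% beta)
  structure(list(alpha = penalty$alpha, lambda = path, cv_mean = cvm,
                 cv_se = cvse, lambda_min = lambda_min,
                 lambda_1se = lambda_1se, beta = beta,
                 n_nonzero = sum(beta != 0),
                 is_null_model = all(beta == 0),
                 breslow = breslow_cumhaz(time, event, eta_train),
                 path_truncated = truncated,
                 penalty = penalty, folds = folds,
                 train = list(time = time, event = event, eta = eta_train),
                 nobs = nrow(x), nevents = sum(event)),
            class = c("coxnet_cv", "coxnet_fit"))
}

#' Refit a penalized Cox model at a fixed lambda
#'
#' Used by resampling validators under the `fixed_full_data` lambda policy:
#' the path is fitted on the resample down to the prescribed lambda (warm
#' starts along the given path) and coefficients are taken at that lambda.
#'
#' @param x,time,event training data.
#' @param penalty a [penalty_config()].
#' @param lambda the fixed penalty value.
#' @param lambda_path optional decreasing path to use for warm starts.
#' @return an object of class `coxnet_fit` (no CV fields).
#' @export
coxnet_refit <- function(x, time, event, penalty, lambda, lambda_path = NULL) {
  x <- check_survival_input(x, time, event)
  y <- survival::Surv(time, event)
  if (is.null(lambda_path)) {
    path <- NULL
  } else {
    path <- sort(unique(c(lambda_path[lambda_path >= lambda], lambda)),
                 decreasing = TRUE)
  }
  args <- list(x = x, y = y, family = "cox", alpha = penalty$alpha,
               standardize = penalty$standardize)
  if (is.null(path)) {
    # geometric warm-start path ending exactly at the requested lambda
    args$lambda <- lambda * 10^seq(3, 0, length.out = 25)
  } else {
    args$lambda <- path
  }
  fit <- do.call(glmnet::glmnet, args)
  beta <- drop(as.matrix(stats::predict(fit, type = "coefficients", s = lambda)))
  names(beta) <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  eta_train <- drop(x %*% beta)
  structure(list(alpha = penalty$alpha, lambda = fit$lambda,
                 lambda_1se = lambda, beta = beta,
                 n_nonzero = sum(beta != 0),
                 is_null_model = all(beta == 0),
                 breslow = breslow_cumhaz(time, event, eta_train),
                 penalty = penalty,
                 train = list(time = time, event = event, eta = eta_train),
                 nobs = nrow(x), nevents = sum(event)),
            class = "coxnet_fit")
}

check_feature_alignment <- function(object, newx) {
  if (!is.matrix(newx)) newx <- as.matrix(newx)
  if (ncol(newx) != length(object$beta))
    stopf("feature mismatch: model has %d features, newx has %d",
          length(object$beta), ncol(newx))
  if (!is.null(colnames(newx)) && !is.null(names(object$beta)) &&
      !identical(colnames(newx), names(object$beta)))
    stopf("feature columns do not match the training columns")
  newx
}

#' Predict from a fitted penalized Cox model
#'
#' `type = "lp"` returns the linear predictor (risk score) `beta' x`;
#' `type = "survival"` returns the matrix of survival probabilities
#' `S(t | x) = exp(-H0(t) exp(beta' x))` with H0 the training-data Breslow
#' baseline, one row per subject and one column per requested time.
#'
#' @param object a `coxnet_fit` / `coxnet_cv`.
#' @param newx feature matrix aligned with the training columns.
#' @param type `"lp"` or `"survival"`.
#' @param times nonnegative horizon times (years) for `type = "survival"`.
#' @param ... unused.
#' @return numeric vector (lp) or matrix (survival).
#' @export
predict.coxnet_fit <- function(object, newx, type = c("lp", "survival"),
                               times = NULL, ...) {
  type <- match.arg(type)
  newx <- check_feature_alignment(object, newx)
  lp <- drop(newx %*% object$beta)
  if (type == "lp") return(lp)
  if (is.null(times)) stopf("type = 'survival' requires times")
  if (any(times < 0)) stopf("times must be nonnegative")
  h0 <- breslow_eval(object$breslow, times)
  s <- exp(-outer(exp(lp), h0))
  dimnames(s) <- list(rownames(newx), paste0("t", times))
  s
}

#' @export
coef.coxnet_fit <- function(object, nonzero = FALSE, ...) {
  if (nonzero) object$beta[object$beta != 0] else object$beta
}

#' @export
print.coxnet_fit <- function(x, ...) {
  cat(sprintf("Penalized Cox model (alpha = %.2f)\n", x$alpha))
  cat(sprintf("  n = %d subjects, %d events, %d features\n",
              x$nobs, x$nevents, length(x$beta)))
  cat(sprintf("  lambda = %.5g, nonzero coefficients: %d%s\n",
              x$lambda_1se, x$n_nonzero,
              if (x$is_null_model) " (null model)" else ""))
  invisible(x)
}

#' @export
print.coxnet_cv <- function(x, ...) {
  cat(sprintf("Cross-validated penalized Cox model (alpha = %.2f)\n", x$alpha))
  cat(sprintf("  n = %d subjects, %d events, %d features\n",
              x$nobs, x$nevents, length(x$beta)))
  cat(sprintf("  %d-fold CV over %d lambdas%s\n", x$penalty$cv_folds,
              length(x$lambda),
              if (x$path_truncated) " (path truncated before convergence)" else ""))
  cat(sprintf("  lambda_min = %.5g, lambda_1se = %.5g\n",
              x$lambda_min, x$lambda_1se))
  cat(sprintf("  nonzero coefficients at lambda_1se: %d%s\n", x$n_nonzero,
              if (x$is_null_model) " (null model)" else ""))
  invisible(x)
}

#' @export
summary.coxnet_cv <- function(object, ...) {
  nz <- coef(object, nonzero = TRUE)
  out <- list(alpha = object$alpha, lambda_1se = object$lambda_1se,
              lambda_min = object$lambda_min, n_nonzero = object$n_nonzero,
              is_null_model = object$is_null_model,
              nonzero_coefficients = sort(nz),
              cv_table = data.frame(lambda = object$lambda,
                                    cv_mean = object$cv_mean,
                                    cv_se = object$cv_se))
  class(out) <- "summary.coxnet_cv"
  out
}

#' @export
print.summary.coxnet_cv <- function(x, ...) {
  cat(sprintf("alpha %.2f | lambda_1se %.5g (lambda_min %.5g) | %d nonzero\n",
              x$alpha, x$lambda_1se, x$lambda_min, x$n_nonzero))
  if (x$n_nonzero > 0 && x$n_nonzero <= 50) {
    cat("Nonzero coefficients:\n")
    print(round(x$nonzero_coefficients, 5))
  }
  invisible(x)
}

#' @export
plot.coxnet_cv <- function(x, ...) {
  ll <- log(x$lambda)
  graphics::plot(ll, x$cv_mean, type = "b", pch = 20,
                 xlab = "log(lambda)", ylab = "CV partial-likelihood deviance",
                 ylim = range(c(x$cv_mean - x$cv_se, x$cv_mean + x$cv_se)), ...)
  graphics::arrows(ll, x$cv_mean - x$cv_se, ll, x$cv_mean + x$cv_se,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  graphics::abline(v = log(c(x$lambda_min, x$lambda_1se)), lty = c(3, 2))
  invisible(x)
}

#' @export
residuals.coxnet_fit <- function(object, type = c("martingale"), ...) {
  type <- match.arg(type)
  tr <- object$train
  tr$event - breslow_eval(object$breslow, tr$time) * exp(tr$eta)
}

#' Serialize a fitted penalized Cox model to JSON
#'
#' Stores alpha, the lambda path, the selected lambda, the sparse nonzero
#' coefficient map and the Breslow baseline as (time, H0) pairs.
#'
#' @param model a `coxnet_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
coxnet_to_json <- function(model, path) {
  nz <- coef(model, nonzero = TRUE)
  obj <- list(alpha = model$alpha, lambda_path = model$lambda,
              lambda = model$lambda_1se,
              n_features = length(model$beta),
              feature_names = names(model$beta),
              coefficients = as.list(nz),
              breslow = list(time = model$breslow$time, H0 = model$breslow$H0),
              is_null_model = model$is_null_model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a penalized Cox model written by [coxnet_to_json()]
#'
#' @param path JSON file.
#' @return an object of class `coxnet_fit` (prediction-capable; no CV or
#'   training-residual fields).
#' @export
coxnet_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- stats::setNames(numeric(obj$n_features), obj$feature_names)
  if (length(obj$coefficients))
    beta[names(obj$coefficients)] <- unlist(obj$coefficients)
  structure(list(alpha = obj$alpha, lambda = obj$lambda_path,
                 lambda_1se = obj$lambda, beta = beta,
                 n_nonzero = sum(beta != 0), is_null_model = all(beta == 0),
                 breslow = structure(list(time = obj$breslow$time,
                                          hazard = diff(c(0, obj$breslow$H0)),
                                          H0 = obj$breslow$H0),
                                     class = "breslow_cumhaz"),
                 nobs = NA_integer_, nevents = NA_integer_),
            class = "coxnet_fit")
}
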