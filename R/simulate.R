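#' Fernandez-Steel skewed normal draws
#'
#' Draws from the two-piece (Fernandez-Steel) skewed normal with shape
#' parameter `xi`, re-located and re-scaled to the requested mean and
#' standard deviation.  `xi = 1` recovers the symmetric normal; `xi > 1`
#' skews to the right.  This is the "snorm" parameterization familiar from
#' the R time-series ecosystem; unlike the Azzalini skew-normal its shape
#' parameter is unbounded in effect, so a stated skewness parameter of 2 is
#' representable.
#'
#' @param n number of draws.
#' @param mean,sd target mean and standard deviation (recycled).
#' @param xi shape parameter (> 0).
#' @param seed optional RNG seed.
#' @return numeric vector of length `n`.
#' @export
rsnorm_fs <- function(n, mean = 0, sd = 1, xi = 2, seed = NULL) {
  stopifnot(xi > 0, all(sd >= 0))
  with_seed(seed, {
    m1 <- sqrt(2 / pi)
    mu_xi <- m1 * (xi - 1 / xi)
    sd_xi <- sqrt((xi^3 + 1 / xi^3) / (xi + 1 / xi) - mu_xi^2)
    pos <- stats::runif(n) < xi^2 / (1 + xi^2)
    absn <- abs(stats::rnorm(n))
    z <- ifelse(pos, xi * absn, -absn / xi)
    mean + sd * (z - mu_xi) / sd_xi
  })
}

#' Simulate clinical covariates
#'
#' Four independent covariates: age ~ Normal, sex and HPV ~ Bernoulli,
#' TNM stage ~ Categorical over 1-4.
#'
#' @param n number of subjects (>= 0).
#' @param params a [clinical_params()].
#' @param seed RNG seed.
#' @return data.frame with columns `age`, `sex`, `hpv`, `tnm`.
#' @export
simulate_clinical <- function(n, params = clinical_params(), seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 0) stopf("n must be a nonnegative count")
  n <- as.integer(n)
  with_seed(seed, {
    data.frame(
      age = stats::rnorm(n, params$age_mean, params$age_sd),
      sex = stats::rbinom(n, 1L, params$p_sex),
      hpv = stats::rbinom(n, 1L, params$p_hpv),
      tnm = if (n > 0) sample.int(4L, n, replace = TRUE, prob = params$tnm_probs)
            else integer(0)
    )
  })
}

#' Simulate transcript expression (four-step skewed count model)
#'
#' Step (i): per-transcript log-scale mean mu1 ~ Normal(mu0, sigma0).
#' Step (ii): per-transcript dispersion tau1 ~ LogNormal(mu_tau,
#' sigma_tau_log).  Step (iii): each sample value from a Fernandez-Steel
#' skewed normal with mean exp(mu1), shape `skewness`, and spread given by
#' the mean-variance relation selected by `dispersion_scale` (see
#' [transcript_params()]); values below `expression_floor` are truncated to
#' it.  Transcripts are simulated independently.
#'
#' @param n number of samples (>= 1).
#' @param params a [transcript_params()].
#' @param seed RNG seed.
#' @return list with `expression` (n x p matrix, TPM scale) and
#'   `transcript_params` (data.frame: `mu1`, `tau1`, `mean`, `sd` per
#'   transcript, for oracle use).
#' @export
simulate_expression <- function(n, params = transcript_params(), seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) stopf("n must be a positive count")
  n <- as.integer(n)
  p <- params$n_transcripts
  with_seed(seed, {
    mu1 <- stats::rnorm(p, params$mu0, params$sigma0)
    tau1 <- stats::rlnorm(p, meanlog = params$mu_tau, sdlog = params$sigma_tau_log)
    mu2 <- exp(mu1)
    sigma2 <- if (params$dispersion_scale == "variance") {
      sqrt(mu2 / params$scale_divisor * tau1)
    } else {
      mu2 / params$scale_divisor * tau1
    }
    z <- matrix(rsnorm_fs(n * p, mean = 0, sd = 1, xi = params$skewness), n, p)
    x <- sweep(z, 2L, sigma2, `*`)
    x <- sweep(x, 2L, mu2, `+`)
    x[x < params$expression_floor] <- params$expression_floor
    colnames(x) <- sprintf("tx%05d", seq_len(p))
    list(expression = x,
         transcript_params = data.frame(transcript = colnames(x), mu1 = mu1,
                                        tau1 = tau1, mean = mu2, sd = sigma2))
  })
}

#' Draw the true prognostic coefficient vector
#'
#' Selects `n_negative + n_positive` transcript positions uniformly at
#' random without replacement and assigns uniform log-hazard coefficients
#' from the negative and positive supports; all other transcript
#' coefficients are zero.  Clinical coefficients are fixed constants.
#' Transcript coefficients act on the log1p expression scale.
#'
#' @param spec a [coefficient_spec()].
#' @param n_transcripts total number of transcripts p.
#' @param seed RNG seed.
#' @return object of class `true_coefficients`: list with `clinical`
#'   (named length-4 vector), `transcript` (length-p vector),
#'   `prognostic_idx`, `negative_idx`, `positive_idx`.
#' @export
draw_true_coefficients <- function(spec = coefficient_spec(),
                                   n_transcripts = 15000, seed = NULL) {
  if (spec$n_prognostic > n_transcripts)
    stopf("n_prognostic (%d) exceeds n_transcripts (%d)",
          spec$n_prognostic, n_transcripts)
  with_seed(seed, {
    idx <- sample.int(n_transcripts, spec$n_prognostic)
    neg <- idx[seq_len(spec$n_negative)]
    pos <- idx[spec$n_negative + seq_len(spec$n_positive)]
    beta <- numeric(n_transcripts)
    beta[neg] <- stats::runif(spec$n_negative, spec$negative_range[1],
                              spec$negative_range[2])
    beta[pos] <- stats::runif(spec$n_positive, spec$positive_range[1],
                              spec$positive_range[2])
    structure(list(clinical = spec$beta_clinical, transcript = beta,
                   prognostic_idx = sort(idx), negative_idx = sort(neg),
                   positive_idx = sort(pos)),
              class = "true_coefficients")
  })
}

#' Simulate right-censored event times by inverse transform
#'
#' Latent event times follow the Cox model with baseline cumulative hazard
#' H0: `T = H0^{-1}(-log(U) * exp(-lp))` with U ~ Uniform(0,1).  Censoring
#' combines the administrative horizon with an optional independent
#' Exponential time.  Latent times beyond the range of a bounded table
#' baseline are administratively censored at the horizon.
#'
#' @param lp linear predictor (log-hazard) per subject, centered at the
#'   profile H0 refers to.
#' @param mech a [survival_mechanism()].
#' @param seed RNG seed.
#' @return data.frame with `time` (> 0, years), `event` (0/1) and
#'   `latent_time` (the uncensored event time; may be `Inf` for a bounded
#'   baseline).
#' @export
simulate_survival_times <- function(lp, mech = survival_mechanism(), seed = NULL) {
  n <- length(lp)
  with_seed(seed, {
    u <- stats::runif(n)
    h <- -log(u) * exp(-lp)
    tt <- baseline_cumhaz_inv(mech, h)
    cc <- rep(mech$horizon_years, n)
    if (mech$censor_rate > 0)
      cc <- pmin(cc, stats::rexp(n, mech$censor_rate))
    time <- pmin(tt, cc)
    event <- as.integer(tt <= cc)
    data.frame(time = pmax(time, .Machine$double.xmin), event = event,
               latent_time = tt)
  })
}

#' Calibrate the Exponential censoring rate to a target censoring fraction
#'
#' Simulates censoring-free latent event times under the mechanism and
#' solves for the Exponential rate that yields the target overall censoring
#' fraction in combination with the administrative horizon.  Used once to
#' fix the package default; exported so users can recalibrate after
#' changing generating parameters.
#'
#' @param gp a [generating_parameters()].
#' @param target target overall censoring fraction.
#' @param n Monte Carlo cohort size.
#' @param seed RNG seed.
#' @return calibrated rate (per year); 0 if administrative censoring alone
#'   already censors at least `target`.
#' @export
calibrate_censoring_rate <- function(gp, target = 0.5, n = 2000,
                                     seed = 20260102) {
  mech0 <- gp$mechanism
  mech0$censor_rate <- 0
  gp$mechanism <- mech0
  coh <- generate_cohort(n, gp, seed = seed)
  tt <- coh$latent_time
  horizon <- mech0$horizon_years
  cens_frac <- function(r) 1 - mean(ifelse(tt <= horizon, exp(-r * tt), 0))
  if (cens_frac(0) >= target) return(0)
  stats::uniroot(function(r) cens_frac(r) - target, c(1e-6, 50))$root
}

#' Generate one complete simulated cohort
#'
#' Composes the clinical, transcriptomic, coefficient and event-time
#' simulations into a `cox_cohort`.  The true coefficients are drawn from
#' `gp$coef_seed` and therefore shared by every cohort generated from the
#' same parameter bundle; `seed` governs the cohort draw itself.
#'
#' The true linear predictor is centered within cohort
#' (`true_lp = beta'x - mean(beta'x)`), so H0 is the cumulative hazard at
#' the cohort-average covariate profile; Cox fits and all rank-based
#' metrics are invariant to this shift.
#'
#' @param n cohort size (>= 1).
#' @param gp a [generating_parameters()].
#' @param seed RNG seed for this cohort.
#' @return object of class `cox_cohort`: list with `sample_ids`, `clinical`
#'   (data.frame), `expression` (n x p, TPM), `log_expression`
#'   (`log1p(expression)`), `time`, `event`, `latent_time`, `true_lp`,
#'   `coefficients` (`true_coefficients`), and the generating parameters.
#' @export
generate_cohort <- function(n, gp = generating_parameters(), seed = NULL) {
  stopifnot(inherits(gp, "generating_parameters"))
  if (length(n) != 1 || is.na(n) || n < 1) stopf("n must be a positive count")
  n <- as.integer(n)
  coefs <- draw_true_coefficients(gp$coefficients, gp$transcripts$n_transcripts,
                                  seed = gp$coef_seed)
  clinical <- simulate_clinical(n, gp$clinical, seed = derive_seed(seed, 1L))
  ex <- simulate_expression(n, gp$transcripts, seed = derive_seed(seed, 2L))
  expr <- ex$expression
  logx <- log1p(expr)
  clin_mat <- as.matrix(clinical[, c("age", "sex", "tnm", "hpv")])
  lp_raw <- drop(clin_mat %*% coefs$clinical[c("age", "sex", "tnm", "hpv")] +
                   logx %*% coefs$transcript)
  true_lp <- lp_raw - mean(lp_raw)
  surv <- simulate_survival_times(true_lp, gp$mechanism,
                                  seed = derive_seed(seed, 3L))
  structure(list(sample_ids = sprintf("S%05d", seq_len(n)),
                 clinical = clinical, expression = expr,
                 log_expression = logx, time = surv$time, event = surv$event,
                 latent_time = surv$latent_time, true_lp = true_lp,
                 coefficients = coefs, generating_parameters = gp,
                 transcript_params = ex$transcript_params, seed = seed),
            class = "cox_cohort")
}

#' Model feature matrix of a cohort
#'
#' Binds the four clinical covariates with the log1p expression matrix, in
#' the column order the true coefficient vector uses (age, sex, tnm, hpv,
#' transcripts).
#'
#' @param cohort a `cox_cohort` (simulated or user-supplied).
#' @return numeric matrix n x (4 + p), or n x p for expression-only cohorts.
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "cox_cohort"))
  if (!is.null(cohort$clinical) && ncol(cohort$clinical %||% data.frame()) > 0) {
    cbind(as.matrix(cohort$clinical[, c("age", "sex", "tnm", "hpv")]),
          cohort$log_expression)
  } else {
    cohort$log_expression
  }
}

#' @export
print.cox_cohort <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("Survival cohort: %d subjects, %d transcripts\n",
              n, ncol(x$expression)))
  cat(sprintf("  events: %d (%.1f%% censored)\n", sum(x$event),
              100 * mean(1 - x$event)))
  cat(sprintf("  follow-up: median %.2fy, max %.2fy\n",
              stats::median(x$time), max(x$time)))
  if (!is.null(x$true_lp))
    cat(sprintf("  true linear predictor: sd %.3f\n", stats::sd(x$true_lp)))
  invisible(x)
}
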