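#' Clinical covariate distribution parameters
#'
#' Distributional parameters for the four simulated clinical covariates:
#' age (Normal), sex and HPV status (Bernoulli), and TNM stage
#' (Categorical over stages I-IV, coded 1-4 and entered linearly in the
#' log hazard).
#'
#' @param age_mean mean age in years.
#' @param age_sd standard deviation of age in years (> 0).
#' @param p_sex probability of `sex == 1`.
#' @param p_hpv probability of HPV positivity.
#' @param tnm_probs length-4 probability vector over TNM stages I-IV.
#' @return an object of class `clinical_params`.
#' @export
clinical_params <- function(age_mean = 65, age_sd = 10,
                            p_sex = 0.3, p_hpv = 0.3,
                            tnm_probs = c(0.22, 0.13, 0.25, 0.40)) {
  stopifnot(age_sd > 0, length(tnm_probs) == 4)
  if (any(c(p_sex, p_hpv, tnm_probs) < 0) || any(c(p_sex, p_hpv, tnm_probs) > 1))
    stopf("probabilities must lie in [0, 1]")
  if (abs(sum(tnm_probs) - 1) > 1e-12)
    stopf("tnm_probs must sum to 1 (got %.15f)", sum(tnm_probs))
  structure(list(age_mean = age_mean, age_sd = age_sd, p_sex = p_sex,
                 p_hpv = p_hpv, tnm_probs = tnm_probs),
            class = "clinical_params")
}

#' Transcript expression model parameters
#'
#' Parameters of the four-step transcript simulation: per-transcript
#' log-scale mean mu1 ~ Normal(mu0, sigma0); per-transcript dispersion
#' tau1 ~ LogNormal(meanlog = mu_tau, sdlog = sigma_tau_log); sample values
#' from a Fernandez-Steel skewed normal with mean exp(mu1) and shape
#' `skewness`, truncated below at `expression_floor` (TPM scale).
#'
#' The dispersion enters through the mean-variance relation
#' `Var = (exp(mu1)/scale_divisor) * tau1` (`dispersion_scale =
#' "variance"`, the default): variance proportional to the mean, the
#' count-like relation seen in TPM data, giving realistic per-gene
#' log-expression spread (~0.9 sd at default parameters).  Setting
#' `dispersion_scale = "sd"` instead uses
#' `sd = (exp(mu1)/scale_divisor) * tau1`, a much more extreme model in
#' which the coefficient of variation itself is lognormal with median ~13.
#'
#' @param n_transcripts number of transcripts p.
#' @param mu0,sigma0 mean and sd of the per-transcript log-scale mean mu1.
#' @param mu_tau meanlog of the lognormal dispersion tau1.
#' @param sigma_tau_log sdlog of the lognormal dispersion tau1.
#' @param scale_divisor divisor in the mean-variance relation.
#' @param skewness Fernandez-Steel shape parameter xi (xi = 1 is symmetric).
#' @param expression_floor lower truncation bound for simulated expression
#'   (TPM); values below it are set to it.  Expression is nonnegative, and
#'   log expression is defined as log1p throughout the package.
#' @param dispersion_scale `"variance"` or `"sd"`; see Details.
#' @return an object of class `transcript_params`.
#' @export
transcript_params <- function(n_transcripts = 15000, mu0 = 2.3, sigma0 = 1.8,
                              mu_tau = 2.8, sigma_tau_log = 0.4,
                              scale_divisor = 1.3, skewness = 2,
                              expression_floor = 0,
                              dispersion_scale = c("variance", "sd")) {
  stopifnot(n_transcripts >= 1, sigma0 > 0, scale_divisor > 0,
            expression_floor >= 0, skewness > 0, sigma_tau_log >= 0)
  structure(list(n_transcripts = as.integer(n_transcripts), mu0 = mu0,
                 sigma0 = sigma0, mu_tau = mu_tau,
                 sigma_tau_log = sigma_tau_log,
                 scale_divisor = scale_divisor, skewness = skewness,
                 expression_floor = expression_floor,
                 dispersion_scale = match.arg(dispersion_scale)),
            class = "transcript_params")
}

#' True prognostic coefficient specification
#'
#' Of the p transcripts, `n_negative` carry log-hazard coefficients drawn
#' uniformly from `negative_range` and `n_positive` from `positive_range`;
#' positions are chosen uniformly at random without replacement.  Clinical
#' coefficients are fixed constants.  Transcript coefficients act on the
#' log1p expression scale; TNM enters linearly with one coefficient.
#'
#' @param n_negative,n_positive counts of negative / positive transcript
#'   coefficients.
#' @param negative_range,positive_range uniform supports on the log-hazard
#'   scale; both must exclude zero.
#' @param beta_age,beta_sex,beta_tnm,beta_hpv clinical log-hazard
#'   coefficients (age per year, TNM per stage).
#' @return an object of class `coefficient_spec`.
#' @export
coefficient_spec <- function(n_negative = 100, n_positive = 100,
                             negative_range = c(-0.1, -0.01),
                             positive_range = c(0.01, 0.1),
                             beta_age = 0.02, beta_sex = -0.8,
                             beta_tnm = 0.3, beta_hpv = -0.5) {
  stopifnot(n_negative >= 0, n_positive >= 0,
            length(negative_range) == 2, length(positive_range) == 2)
  if (n_negative > 0 && max(negative_range) >= 0)
    stopf("negative_range must exclude zero")
  if (n_positive > 0 && min(positive_range) <= 0)
    stopf("positive_range must exclude zero")
  structure(list(n_negative = as.integer(n_negative),
                 n_positive = as.integer(n_positive),
                 n_prognostic = as.integer(n_negative + n_positive),
                 negative_range = negative_range,
                 positive_range = positive_range,
                 beta_clinical = c(age = beta_age, sex = beta_sex,
                                   tnm = beta_tnm, hpv = beta_hpv)),
            class = "coefficient_spec")
}

#' Survival-time mechanism: baseline hazard and censoring
#'
#' The baseline cumulative hazard H0(t) is either parametric Weibull,
#' `H0(t) = (t/scale)^shape`, or a piecewise-linear table (columns
#' `time_years`, `cumulative_hazard`, e.g. a Breslow estimate exported from
#' a real cohort, see [read_baseline_table()]).  Event times are drawn by
#' inverse transform, `T = H0^{-1}(-log(U) * exp(-lp))`, where `lp` is the
#' linear predictor centered at the cohort-average covariate profile.
#' Censoring combines administrative censoring at `horizon_years` with an
#' optional independent Exponential censoring time with rate `censor_rate`
#' (per year; 0 disables it).
#'
#' Defaults: Weibull shape 1 with scale `3 / (-log 0.6)`, i.e. a subject at
#' the average covariate profile has a 40\% event probability by 3 years;
#' censoring rate 0.078/year, calibrated once by Monte Carlo (see
#' [calibrate_censoring_rate()]) to give ~50\% overall censoring under the
#' default generating parameters.
#'
#' @param baseline `"weibull"` or a two-column data.frame / matrix
#'   (time, cumulative hazard) for a piecewise-linear H0.
#' @param shape,scale Weibull parameters (ignored for a table baseline).
#' @param horizon_years administrative censoring horizon in years.
#' @param censor_rate rate of the independent Exponential censoring time.
#' @return an object of class `survival_mechanism`.
#' @export
survival_mechanism <- function(baseline = "weibull", shape = 1,
                               scale = 3 / (-log(0.6)),
                               horizon_years = 5,
                               censor_rate = 0.078) {
  stopifnot(horizon_years > 0, censor_rate >= 0)
  if (is.character(baseline)) {
    baseline <- match.arg(baseline, "weibull")
    stopifnot(shape > 0, scale > 0)
    b <- list(type = "weibull", shape = shape, scale = scale)
  } else {
    tab <- as.data.frame(baseline)
    if (ncol(tab) < 2) stopf("baseline table needs columns (time, cumulative_hazard)")
    tab <- tab[1:2]
    names(tab) <- c("time", "H0")
    if (is.unsorted(tab$time, strictly = TRUE) || is.unsorted(tab$H0))
      stopf("baseline table must have strictly increasing time and nondecreasing H0")
    if (tab$time[1] > 0) tab <- rbind(data.frame(time = 0, H0 = 0), tab)
    if (abs(tab$H0[1]) > 1e-12) stopf("H0(0) must be 0")
    b <- list(type = "table", table = tab)
  }
  structure(list(baseline = b, horizon_years = horizon_years,
                 censor_rate = censor_rate),
            class = "survival_mechanism")
}

#' Evaluate / invert the baseline cumulative hazard
#'
#' @param mech a [survival_mechanism()].
#' @param t nonnegative times (years).
#' @return `baseline_cumhaz`: H0(t).  `baseline_cumhaz_inv`: the smallest t
#'   with H0(t) >= h; `Inf` where `h` exceeds the range of a bounded table
#'   baseline (such draws are administratively censored downstream).
#' @export
baseline_cumhaz <- function(mech, t) {
  stopifnot(all(t >= 0))
  b <- mech$baseline
  if (b$type == "weibull") (t / b$scale)^b$shape
  else stats::approx(b$table$time, b$table$H0, xout = t, rule = 2)$y
}

#' @rdname baseline_cumhaz
#' @param h nonnegative cumulative-hazard values.
#' @export
baseline_cumhaz_inv <- function(mech, h) {
  stopifnot(all(h >= 0))
  b <- mech$baseline
  if (b$type == "weibull") {
    b$scale * h^(1 / b$shape)
  } else {
    out <- stats::approx(b$table$H0, b$table$time, xout = h, ties = "ordered")$y
    out[h > max(b$table$H0)] <- Inf
    out[h <= 0] <- 0
    out
  }
}

#' Full generating-parameter bundle
#'
#' Collects every constant of the data-generating mechanism.  `coef_seed`
#' fixes the realized true-coefficient draw, so all replicate cohorts
#' generated from one bundle -- and the independent validation cohort --
#' share the same prognostic transcripts and effect sizes, while the
#' per-transcript expression parameters and all sample-level draws are
#' governed by each cohort's own seed.
#'
#' @param clinical a [clinical_params()].
#' @param transcripts a [transcript_params()].
#' @param coefficients a [coefficient_spec()].
#' @param mechanism a [survival_mechanism()].
#' @param coef_seed integer seed fixing the true-coefficient draw.
#' @return an object of class `generating_parameters`.
#' @export
generating_parameters <- function(clinical = clinical_params(),
                                  transcripts = transcript_params(),
                                  coefficients = coefficient_spec(),
                                  mechanism = survival_mechanism(),
                                  coef_seed = 20260101) {
  stopifnot(inherits(clinical, "clinical_params"),
            inherits(transcripts, "transcript_params"),
            inherits(coefficients, "coefficient_spec"),
            inherits(mechanism, "survival_mechanism"))
  if (coefficients$n_prognostic > transcripts$n_transcripts)
    stopf("more prognostic transcripts (%d) than transcripts (%d)",
          coefficients$n_prognostic, transcripts$n_transcripts)
  structure(list(clinical = clinical, transcripts = transcripts,
                 coefficients = coefficients, mechanism = mechanism,
                 coef_seed = as.integer(coef_seed)),
            class = "generating_parameters")
}

#' @export
print.generating_parameters <- function(x, ...) {
  cat("Generating parameters\n")
  cat(sprintf("  transcripts: %d (%d prognostic), clinical covariates: 4\n",
              x$transcripts$n_transcripts, x$coefficients$n_prognostic))
  b <- x$mechanism$baseline
  if (b$type == "weibull")
    cat(sprintf("  baseline H0: Weibull(shape %.3g, scale %.3g)\n", b$shape, b$scale))
  else
    cat(sprintf("  baseline H0: piecewise table (%d knots)\n", nrow(b$table)))
  cat(sprintf("  censoring: administrative at %gy + Exp(rate %.3g)\n",
              x$mechanism$horizon_years, x$mechanism$censor_rate))
  invisible(x)
}
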