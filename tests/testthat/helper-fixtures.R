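# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small-p generating parameters: same mechanism, 300 transcripts of which 40
# are prognostic, so the signal-to-dimension ratio resembles the full-scale
# design while fits stay fast.
small_gp <- function(p = 300, n_neg = 20, n_pos = 20, coef_seed = 77,
                     censor_rate = survival_mechanism()$censor_rate) {
  generating_parameters(
    transcripts = transcript_params(n_transcripts = p),
    coefficients = coefficient_spec(n_negative = n_neg, n_positive = n_pos),
    mechanism = survival_mechanism(censor_rate = censor_rate),
    coef_seed = coef_seed)
}

# Strong-signal parameters: a handful of large-effect transcripts, so fitted
# lasso models discriminate almost perfectly.
strong_gp <- function(p = 60) {
  generating_parameters(
    transcripts = transcript_params(n_transcripts = p),
    coefficients = coefficient_spec(n_negative = 4, n_positive = 4,
                                    negative_range = c(-3, -2),
                                    positive_range = c(2, 3)),
    mechanism = survival_mechanism(censor_rate = 0.05),
    coef_seed = 99)
}

# Pure-noise parameters: no prognostic transcript, null clinical effects.
noise_gp <- function(p = 300) {
  generating_parameters(
    transcripts = transcript_params(n_transcripts = p),
    coefficients = coefficient_spec(n_negative = 0, n_positive = 0,
                                    beta_age = 0, beta_sex = 0,
                                    beta_tnm = 0, beta_hpv = 0),
    coef_seed = 5)
}

# Hand-built cohort wrapper around an explicit feature matrix; used for toy
# exact-value tests where the dgm would get in the way.
toy_cohort <- function(features, time, event) {
  colnames(features) <- colnames(features) %||%
    sprintf("f%02d", seq_len(ncol(features)))
  structure(list(sample_ids = sprintf("S%03d", seq_len(nrow(features))),
                 clinical = NULL, expression = exp(features) - 1,
                 log_expression = features, time = time,
                 event = as.integer(event), true_lp = NULL),
            class = "cox_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive-enumeration binary AUC of "event by t" vs risk; the independent
# oracle for auc_cd on uncensored data.
enum_auc <- function(risk, time, event, t) {
  cases <- which(time <= t & event == 1)
  controls <- which(time > t)
  if (!length(cases) || !length(controls)) return(NA_real_)
  s <- 0
  for (i in cases) for (j in controls)
    s <- s + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
  s / (length(cases) * length(controls))
}

# Exhaustive-enumeration Harrell C.
enum_c <- function(risk, time, event) {
  conc <- 0; ncomp <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[i] >= time[j]) next
      ncomp <- ncomp + 1
      conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  if (ncomp == 0) NA_real_ else conc / ncomp
}
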