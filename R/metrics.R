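#' Kaplan-Meier model of the censoring distribution
#'
#' Fits the Kaplan-Meier estimator to the censoring indicator (1 - event),
#' providing the censoring survival function G(t) and its left limit G(t-)
#' used for inverse-probability-of-censoring weights.  With no censored
#' subjects, G is identically 1 (all IPCW weights are 1).
#'
#' @param time positive follow-up times.
#' @param event event indicator (0/1); censoring indicator is `1 - event`.
#' @return object of class `censoring_km` with functions `G(t)` and
#'   `Gminus(t)`.
#' @export
censoring_km <- function(time, event) {
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  if (length(fit$time)) {
    G <- stats::stepfun(fit$time, c(1, fit$surv))
    Gminus <- stats::stepfun(fit$time, c(1, fit$surv), right = TRUE)
  } else {
    G <- Gminus <- function(t) rep(1, length(t))
  }
  structure(list(G = G, Gminus = Gminus, n = length(time),
                 n_censored = sum(1 - event)),
            class = "censoring_km")
}

#' @export
print.censoring_km <- function(x, ...) {
  cat(sprintf("Censoring Kaplan-Meier: %d subjects, %d censored\n",
              x$n, x$n_censored))
  invisible(x)
}

#' Cumulative/dynamic time-dependent AUC with IPCW
#'
#' At horizon t, cases are subjects with an observed event by t and
#' controls are subjects still event-free (under observation) beyond t.
#' Cases are weighted by the inverse probability of remaining uncensored,
#' `w_i = 1 / G(time_i-)`:
#' `AUC(t) = sum_ij w_i [1(r_i > r_j) + 0.5 * 1(r_i = r_j)] /
#' (sum_i w_i * #controls)`.  A constant risk vector scores 0.5 by the tie
#' rule.  With no cases or no controls the value is `NA` (undefined,
#' excluded from aggregation), not an error.
#'
#' @param risk risk scores (higher = higher risk).
#' @param time,event right-censored outcome.
#' @param t horizon time.
#' @param G a [censoring_km()] fitted on the evaluation data (computed
#'   internally if omitted).
#' @return AUC value in [0, 1] or `NA`, with attributes `n_cases`,
#'   `n_controls`, `n_excluded` (cases with zero censoring-survival
#'   weight, excluded).
#' @export
auc_cd <- function(risk, time, event, t, G = censoring_km(time, event)) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  cases <- which(time <= t & event == 1)
  controls <- which(time > t)
  out <- function(v, nexcl = 0L) structure(v, n_cases = length(cases),
                                           n_controls = length(controls),
                                           n_excluded = nexcl)
  if (!length(cases) || !length(controls)) return(out(NA_real_))
  w <- 1 / G$Gminus(time[cases])
  bad <- !is.finite(w)
  if (any(bad)) { cases <- cases[!bad]; w <- w[!bad] }
  if (!length(cases)) return(out(NA_real_, sum(bad)))
  rc <- sort(risk[controls])
  n_less <- findInterval(risk[cases], rc, left.open = TRUE)
  n_leq <- findInterval(risk[cases], rc)
  num <- sum(w * (n_less + 0.5 * (n_leq - n_less)))
  out(num / (sum(w) * length(controls)), sum(bad))
}

#' Time-dependent AUC curve over a horizon grid
#'
#' Maps [auc_cd()] over a grid of horizons (default 1 to 5 years in 0.1-year
#' steps); the 3-year AUC is the value at the grid point exactly 3.0.
#'
#' @inheritParams auc_cd
#' @param times horizon grid (strictly increasing).
#' @return data.frame with `time`, `auc`, `n_cases`, `n_controls`.
#' @export
auc_curve <- function(risk, time, event, times = seq(1, 5, by = 0.1),
                      G = censoring_km(time, event)) {
  stopifnot(!is.unsorted(times, strictly = TRUE))
  rows <- lapply(times, function(t) {
    a <- auc_cd(risk, time, event, t, G)
    data.frame(time = t, auc = as.numeric(a),
               n_cases = attr(a, "n_cases"), n_controls = attr(a, "n_controls"))
  })
  do.call(rbind, rows)
}

#' Harrell's concordance index
#'
#' Over comparable pairs (i usable against j when `event_i = 1` and
#' `time_i < time_j`): `C = (#concordant + 0.5 #risk-ties) / #comparable`.
#' Risk ties are credited one half; with no comparable pair the value is
#' `NA`.
#'
#' @inheritParams auc_cd
#' @return C-index in [0, 1] or `NA`, with attribute `n_comparable`.
#' @export
harrell_c <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  ev <- which(event == 1)
  conc <- 0; ties <- 0; ncomp <- 0
  for (i in ev) {
    j <- which(time > time[i])
    if (!length(j)) next
    ncomp <- ncomp + length(j)
    conc <- conc + sum(risk[i] > risk[j])
    ties <- ties + sum(risk[i] == risk[j])
  }
  if (ncomp == 0) return(structure(NA_real_, n_comparable = 0L))
  structure((conc + 0.5 * ties) / ncomp, n_comparable = ncomp)
}

#' IPCW Brier score at a fixed horizon
#'
#' `BS(t) = (1/n) sum_i [ S_i^2 1(time_i <= t, event_i = 1) / G(time_i-) +
#' (1 - S_i)^2 1(time_i > t) / G(t) ]` where `S_i` is the predicted
#' survival probability at t.  Subjects censored before t contribute 0;
#' subjects whose weight denominator is 0 are excluded (count recorded).
#'
#' @param surv_prob predicted survival probabilities at `t`, in [0, 1].
#' @inheritParams auc_cd
#' @return Brier score with attribute `n_excluded`.
#' @export
brier <- function(surv_prob, time, event, t, G = censoring_km(time, event)) {
  stopifnot(length(surv_prob) == length(time),
            all(surv_prob >= 0 & surv_prob <= 1))
  gi <- G$Gminus(time)
  gt <- G$G(t)
  case <- time <= t & event == 1
  ctrl <- time > t
  contrib <- numeric(length(time))
  excl <- (case & gi <= 0) | (ctrl & gt <= 0)
  contrib[case] <- surv_prob[case]^2 / gi[case]
  contrib[ctrl] <- (1 - surv_prob[ctrl])^2 / gt
  contrib[excl] <- 0
  structure(sum(contrib[!excl]) / sum(!excl), n_excluded = sum(excl))
}

#' Integrated Brier score by trapezoid rule
#'
#' `IBS = (1/t_max) * integral_0^t_max BS(t) dt`, the Brier score averaged
#' over the horizon window (default 0-3 years) on the supplied grid.
#'
#' @param surv_matrix matrix of predicted survival probabilities, one row
#'   per subject, one column per grid time.
#' @param times grid of evaluation times; must cover `[0, t_max]`.
#' @inheritParams auc_cd
#' @param t_max upper integration limit (years).
#' @return the integrated Brier score.
#' @export
ibs <- function(surv_matrix, time, event, times = seq(0, 3, by = 0.1),
                t_max = 3, G = censoring_km(time, event)) {
  surv_matrix <- as.matrix(surv_matrix)
  stopifnot(ncol(surv_matrix) == length(times), nrow(surv_matrix) == length(time))
  if (min(times) > 0 || max(times) < t_max)
    stopf("time grid must cover [0, %g]", t_max)
  keep <- times <= t_max + 1e-12
  tt <- times[keep]
  bs <- vapply(which(keep), function(j)
    as.numeric(brier(surv_matrix[, j], time, event, times[j], G)),
    numeric(1))
  sum(diff(tt) * (bs[-1] + bs[-length(bs)]) / 2) / t_max
}
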