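#' Write a cohort to plain-text files
#'
#' Emits the interchange formats: expression TSV (transcripts x samples,
#' TPM scale, first column `transcript`), clinical CSV (`id`, `age`,
#' `sex`, `hpv`, `tnm`), outcome CSV (`id`, `time_years`, `event`), and a
#' JSON sidecar recording the generating parameters and seed.
#'
#' @param cohort a `cox_cohort`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "cox_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  expr <- t(cohort$expression)
  colnames(expr) <- cohort$sample_ids
  utils::write.table(data.frame(transcript = rownames(expr), expr,
                                check.names = FALSE),
                     p("_expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(data.frame(id = cohort$sample_ids, cohort$clinical),
                   p("_clinical.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = cohort$sample_ids,
                              time_years = cohort$time, event = cohort$event),
                   p("_outcome.csv"), row.names = FALSE)
  gp <- cohort$generating_parameters
  side <- list(seed = cohort$seed,
               n = length(cohort$time),
               generating_parameters = if (!is.null(gp)) list(
                 clinical = unclass(gp$clinical),
                 transcripts = unclass(gp$transcripts),
                 coefficients = unclass(gp$coefficients)[
                   c("n_negative", "n_positive", "negative_range",
                     "positive_range", "beta_clinical")],
                 mechanism = list(baseline = gp$mechanism$baseline,
                                  horizon_years = gp$mechanism$horizon_years,
                                  censor_rate = gp$mechanism$censor_rate),
                 coef_seed = gp$coef_seed))
  jsonlite::write_json(side, p("_params.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(expression = p("_expression.tsv"), clinical = p("_clinical.csv"),
              outcome = p("_outcome.csv"), params = p("_params.json")))
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read an expression matrix with orientation auto-detection
#'
#' Accepts TSV/CSV, either transcripts x samples (first column transcript
#' ids, remaining column names sample ids) or samples x transcripts (first
#' column sample ids).  Orientation is resolved against the outcome ids:
#' whichever axis matches them is taken as samples.
#'
#' @param path expression file (TPM scale).
#' @param sample_ids ids from the outcome file.
#' @return numeric matrix samples x transcripts.
#' @export
read_expression <- function(path, sample_ids) {
  d <- read_delim_auto(path)
  if (ncol(d) < 2) stopf("expression file needs an id column plus data")
  first <- as.character(d[[1]])
  header <- colnames(d)[-1]
  m <- as.matrix(d[-1])
  if (!is.numeric(m)) {
    bad <- which(!vapply(d[-1], is.numeric, logical(1)))
    stopf("non-numeric expression columns: %s",
          paste(utils::head(colnames(d)[-1][bad], 5), collapse = ", "))
  }
  if (all(sample_ids %in% header)) {
    rownames(m) <- first
    out <- t(m[, sample_ids, drop = FALSE])
  } else if (all(sample_ids %in% first)) {
    rownames(m) <- first
    out <- m[sample_ids, , drop = FALSE]
  } else {
    missing <- setdiff(sample_ids, union(header, first))
    stopf("expression ids do not match outcome ids (e.g. %s)",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  if (any(is.na(out))) stopf("expression matrix contains missing values")
  out
}

#' Read an outcome file (id, time_years, event)
#'
#' @param path CSV/TSV with columns `id`, `time_years` (or `time`), `event`.
#' @return data.frame with `id`, `time_years`, `event`.
#' @export
read_outcome <- function(path) {
  d <- read_delim_auto(path)
  if (!"time_years" %in% names(d) && "time" %in% names(d))
    names(d)[names(d) == "time"] <- "time_years"
  need <- c("id", "time_years", "event")
  if (!all(need %in% names(d)))
    stopf("outcome file must have columns id, time_years, event")
  d <- d[need]
  if (any(is.na(d))) stopf("outcome file contains missing values")
  if (!all(d$event %in% c(0, 1))) stopf("event must be coded 0/1")
  if (any(d$time_years <= 0)) stopf("times must be positive")
  if (sum(d$event) == 0) stopf("all subjects censored: no events to model")
  d$id <- as.character(d$id)
  d
}

#' Assemble a cohort from user-supplied files
#'
#' Builds a `cox_cohort` (without true linear predictor) from an
#' expression file (TPM scale; log1p applied), an outcome file, and an
#' optional clinical file (`id`, `age`, `sex`, `hpv`, `tnm`).
#'
#' @param expr_file expression TSV/CSV.
#' @param outcome_file outcome CSV.
#' @param clinical_file optional clinical CSV.
#' @return a `cox_cohort`.
#' @export
read_cohort <- function(expr_file, outcome_file, clinical_file = NULL) {
  outcome <- read_outcome(outcome_file)
  expr <- read_expression(expr_file, outcome$id)
  clinical <- NULL
  if (!is.null(clinical_file)) {
    cd <- read_delim_auto(clinical_file)
    need <- c("id", "age", "sex", "hpv", "tnm")
    if (!all(need %in% names(cd)))
      stopf("clinical file must have columns id, age, sex, hpv, tnm")
    cd$id <- as.character(cd$id)
    if (!all(outcome$id %in% cd$id))
      stopf("clinical ids do not cover outcome ids")
    clinical <- cd[match(outcome$id, cd$id), c("age", "sex", "hpv", "tnm")]
    if (any(is.na(clinical))) stopf("clinical file contains missing values")
    rownames(clinical) <- NULL
  }
  if (any(expr < 0)) stopf("expression must be nonnegative (TPM scale)")
  structure(list(sample_ids = outcome$id, clinical = clinical,
                 expression = expr, log_expression = log1p(expr),
                 time = outcome$time_years, event = as.integer(outcome$event),
                 true_lp = NULL),
            class = "cox_cohort")
}

#' Read a piecewise baseline cumulative hazard table
#'
#' @param path CSV with columns (time_years, cumulative_hazard).
#' @param horizon_years,censor_rate censoring spec for the resulting
#'   mechanism.
#' @return a [survival_mechanism()] with a table baseline.
#' @export
read_baseline_table <- function(path, horizon_years = 5, censor_rate = 0) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stopf("baseline table needs 2 columns (time, H0)")
  survival_mechanism(baseline = d, horizon_years = horizon_years,
                     censor_rate = censor_rate)
}

#' Write a metric curve as CSV
#'
#' @param curve a data.frame as returned by [auc_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metric_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
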