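#' Apply the validation battery to user-supplied data
#'
#' Application mode: loads expression (TPM; log1p-transformed), outcome and
#' optional clinical files, fits the full-data elastic-net Cox model at
#' lambda-1SE, runs the requested internal-validation strategies, and
#' reports per-strategy AUC(t) curves, 3-year AUC, C-index and 3-year IBS
#' together with the nonzero-coefficient signature of the full model.
#'
#' @param expr_file,outcome_file,clinical_file input files (see
#'   [read_cohort()]); a `cox_cohort` may be passed directly as
#'   `expr_file`, in which case the other files are ignored.
#' @param alpha elastic-net mixing parameter.
#' @param strategies strategy names (see [run_strategy()]); the short
#'   aliases `tt`, `boot`, `boot632p`, `cv`, `ncv` are accepted.
#' @param penalty a [penalty_config()] (its alpha is overridden).
#' @param cfg a [strategy_config()].
#' @param seed RNG seed.
#' @param out_dir optional directory for JSON/CSV reports.
#' @return an object of class `validation_report`: list with `model`
#'   (`coxnet_cv`), `signature` (nonzero coefficients data.frame),
#'   `estimates` (named list of `validation_estimate`s), `ibs_table`.
#' @export
apply_validation <- function(expr_file, outcome_file = NULL,
                             clinical_file = NULL, alpha = 0.95,
                             strategies = c("tt", "boot", "boot632p", "cv", "ncv"),
                             penalty = penalty_config(),
                             cfg = strategy_config(), seed = 1,
                             out_dir = NULL) {
  cohort <- if (inherits(expr_file, "cox_cohort")) expr_file
            else read_cohort(expr_file, outcome_file, clinical_file)
  if (sum(cohort$event) < 2) stopf("need at least 2 events")
  strategies <- vapply(strategies, canonical_strategy, character(1))
  penalty$alpha <- alpha
  x <- cohort_features(cohort)
  full_fit <- coxnet_cv(x, cohort$time, cohort$event, penalty,
                        seed = derive_seed(seed, 20L))
  nz <- coef(full_fit, nonzero = TRUE)
  signature <- data.frame(feature = names(nz), coefficient = unname(nz))
  signature <- signature[order(-abs(signature$coefficient)), ]
  rownames(signature) <- NULL
  estimates <- lapply(strategies, function(st)
    run_strategy(st, cohort, penalty, cfg, seed = derive_seed(seed, 21L),
                 full_fit = full_fit))
  names(estimates) <- strategies
  ibs_table <- data.frame(strategy = strategies,
                          ibs_3y = vapply(estimates, `[[`, numeric(1), "ibs_3y"),
                          auc_3y = vapply(estimates, `[[`, numeric(1), "auc_3y"),
                          c_index = vapply(estimates, `[[`, numeric(1), "c_index"),
                          row.names = NULL)
  report <- structure(list(model = full_fit, signature = signature,
                           estimates = estimates, ibs_table = ibs_table,
                           alpha = alpha, seed = seed),
                      class = "validation_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(signature, file.path(out_dir, "signature.csv"),
                     row.names = FALSE)
    utils::write.csv(ibs_table, file.path(out_dir, "metrics_by_strategy.csv"),
                     row.names = FALSE)
    coxnet_to_json(full_fit, file.path(out_dir, "model.json"))
    for (st in strategies) {
      validation_to_json(estimates[[st]],
                         file.path(out_dir, paste0("validation_", st, ".json")),
                         seed = seed)
      if (!is.null(estimates[[st]]$auc_curve))
        write_metric_curve(estimates[[st]]$auc_curve,
                           file.path(out_dir, paste0("auc_curve_", st, ".csv")))
    }
  }
  report
}

canonical_strategy <- function(s) {
  switch(s,
         tt = , train_test = "train_test",
         boot = , bootstrap = "bootstrap",
         boot632p = , bootstrap_632plus = "bootstrap_632plus",
         cv = , kfold_cv = "kfold_cv",
         ncv = , nested_cv = "nested_cv",
         stopf("unknown strategy '%s'", s))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (alpha = %.2f)\n", x$alpha))
  cat(sprintf("  model: %d nonzero coefficients%s\n", x$model$n_nonzero,
              if (x$model$is_null_model) " (null model)" else ""))
  cat("\nMetrics by strategy:\n")
  print(transform(x$ibs_table, ibs_3y = round(ibs_3y, 4),
                  auc_3y = round(auc_3y, 3), c_index = round(c_index, 3)),
        row.names = FALSE)
  invisible(x)
}
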