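#' Oracle performance on an independent cohort
#'
#' Evaluates the generating model itself: the true (centered) linear
#' predictor is the risk score for the AUC curve and C-index, and the true
#' survival curves `S(t|x) = exp(-H0(t) exp(lp))` feed the integrated
#' Brier score.  The oracle is the benchmark no fitted model should beat
#' except by chance.
#'
#' @param independent a simulated `cox_cohort` carrying `true_lp`.
#' @param gp generating parameters (defaults to the cohort's own).
#' @return list with `auc_curve`, `auc_3y`, `c_index`, `ibs_3y`.
#' @export
oracle_performance <- function(independent,
                               gp = independent$generating_parameters) {
  if (is.null(independent$true_lp))
    stopf("oracle performance requires a simulated cohort with true_lp")
  lp <- independent$true_lp
  time <- independent$time; event <- independent$event
  G <- censoring_km(time, event)
  curve <- auc_curve(lp, time, event, auc_grid(), G)
  h0 <- baseline_cumhaz(gp$mechanism, ibs_grid())
  surv <- exp(-outer(exp(lp), h0))
  list(auc_curve = curve,
       auc_3y = curve$auc[abs(curve$time - 3) < 1e-9],
       c_index = as.numeric(harrell_c(lp, time, event)),
       ibs_3y = ibs(surv, time, event, ibs_grid(), 3, G))
}

#' Optimism bias of a validation strategy
#'
#' `bias = oracle_auc - mean(strategy_aucs)`; a negative bias means the
#' strategy reports performance beyond the oracle, i.e. is over-optimistic.
#'
#' @param oracle_auc the oracle reference value.
#' @param strategy_aucs replicate-level strategy estimates (NAs excluded).
#' @return the bias, or `NA` if no replicate is evaluable.
#' @export
optimism_bias <- function(oracle_auc, strategy_aucs) {
  v <- strategy_aucs[!is.na(strategy_aucs)]
  if (!length(v)) return(NA_real_)
  oracle_auc - mean(v)
}

#' Variance homogeneity across validation strategies
#'
#' Bartlett's test of equal variances across the per-strategy replicate
#' vectors; when it rejects at `alpha`, all pairwise two-sided F-tests of
#' variance ratios are run with Holm adjustment.  Groups with fewer than
#' two evaluable replicates are dropped; zero-variance pairs are flagged
#' `NA` rather than raising.
#'
#' @param groups named list of numeric replicate vectors (one per strategy).
#' @param alpha significance level gating the pairwise follow-up.
#' @return list with `bartlett_statistic`, `p_value`, `df`, `pairwise`
#'   (data.frame or NULL), `groups_used`.
#' @export
variance_homogeneity <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) < 2)
    stopf("need at least 2 groups with >= 2 evaluable replicates")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  vars <- vapply(groups, stats::var, numeric(1))
  if (all(vars == 0)) {
    bt <- list(statistic = c(`Bartlett's K-squared` = 0), p.value = 1,
               parameter = c(df = length(groups) - 1))
  } else {
    bt <- stats::bartlett.test(values, g)
  }
  pairwise <- NULL
  if (bt$p.value < alpha) {
    combs <- utils::combn(names(groups), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      a <- combs[1, j]; b <- combs[2, j]
      if (stats::var(groups[[a]]) == 0 || stats::var(groups[[b]]) == 0) {
        data.frame(group1 = a, group2 = b, f_statistic = NA_real_,
                   p_value = NA_real_, flagged = TRUE)
      } else {
        ft <- stats::var.test(groups[[a]], groups[[b]])
        data.frame(group1 = a, group2 = b,
                   f_statistic = unname(ft$statistic),
                   p_value = ft$p.value, flagged = FALSE)
      }
    }))
    pairwise$p_adjusted <- stats::p.adjust(pairwise$p_value, method = "holm")
  }
  list(bartlett_statistic = unname(bt$statistic), p_value = bt$p.value,
       df = unname(bt$parameter), pairwise = pairwise,
       groups_used = names(groups))
}

#' Benchmark scenario configuration
#'
#' @param sample_sizes training cohort sizes to benchmark.
#' @param n_replicates replicate cohorts per scenario (desk-scale default
#'   20; the full-scale design uses 100).
#' @param alphas elastic-net mixing values (ridge-like 0.05, elastic net
#'   0.5, lasso-like 0.95).
#' @param independent_n size of the shared independent validation cohort.
#' @param master_seed master seed; replicate b of scenario s uses
#'   `derive_seed(master_seed, s, b)`.
#' @param gp a [generating_parameters()].
#' @param penalty a [penalty_config()] template (alpha is overridden).
#' @param strategy a [strategy_config()].
#' @param strategies strategy names to run.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(sample_sizes = c(50, 75, 100, 500, 1000),
                            n_replicates = 20,
                            alphas = c(0.05, 0.5, 0.95),
                            independent_n = 1000,
                            master_seed = 1,
                            gp = generating_parameters(),
                            penalty = penalty_config(),
                            strategy = strategy_config(),
                            strategies = c("train_test", "bootstrap",
                                           "bootstrap_632plus", "kfold_cv",
                                           "nested_cv")) {
  stopifnot(all(sample_sizes >= 10), n_replicates >= 1, independent_n >= 10,
            all(alphas >= 0 & alphas <= 1))
  structure(list(sample_sizes = as.integer(sample_sizes),
                 n_replicates = as.integer(n_replicates),
                 alphas = alphas, independent_n = as.integer(independent_n),
                 master_seed = as.integer(master_seed), gp = gp,
                 penalty = penalty, strategy = strategy,
                 strategies = strategies),
            class = "scenario_config")
}

replicate_record <- function(n, alpha, replicate, strategy, est, full_fit) {
  data.frame(n = n, alpha = alpha, replicate = replicate, strategy = strategy,
             auc_3y = est$auc_3y, c_index = est$c_index, ibs_3y = est$ibs_3y,
             null_model = est$diagnostics$null_model_fraction %||% NA_real_,
             n_nonzero_full = full_fit$n_nonzero)
}

#' Run the full validation benchmark
#'
#' For each scenario (sample size) and replicate: generate a cohort; for
#' each alpha: fit the full-data lambda-1SE model, run every requested
#' internal-validation strategy, and validate the model on the shared
#' independent cohort.  The oracle is computed once on the independent
#' cohort.  Per-replicate records can be written to `out_dir` as JSON,
#' making the run resumable: existing records are loaded instead of
#' recomputed.
#'
#' @param cfg a [scenario_config()].
#' @param out_dir optional directory for per-replicate JSON records and
#'   aggregated CSV tables.
#' @return an object of class `benchmark_result`: list with `replicates`
#'   (long data.frame), `summary` (per n/alpha/strategy means and SDs),
#'   `tables` (wide, one per metric), `oracle`, `variance_tests`, `config`.
#' @export
run_benchmark <- function(cfg = scenario_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  independent <- generate_cohort(cfg$independent_n, cfg$gp,
                                 seed = derive_seed(cfg$master_seed, 0L, 0L))
  oracle <- oracle_performance(independent, cfg$gp)
  vs_log("oracle: 3y AUC %.3f, 3y IBS %.4f", oracle$auc_3y, oracle$ibs_3y)

  all_rows <- list()
  for (s in seq_along(cfg$sample_sizes)) {
    n <- cfg$sample_sizes[s]
    for (b in seq_len(cfg$n_replicates)) {
      rec_path <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("replicate_n%d_b%03d.json", n, b)) else NULL
      if (!is.null(rec_path) && file.exists(rec_path)) {
        rows <- jsonlite::read_json(rec_path, simplifyVector = TRUE)
        all_rows[[length(all_rows) + 1L]] <- as.data.frame(rows)
        next
      }
      seed_b <- derive_seed(cfg$master_seed, s, b)
      rows <- tryCatch({
        cohort <- generate_cohort(n, cfg$gp, seed = seed_b)
        rr <- list()
        for (alpha in cfg$alphas) {
          pen <- cfg$penalty
          pen$alpha <- alpha
          full_fit <- coxnet_cv(cohort_features(cohort), cohort$time,
                                cohort$event, pen,
                                seed = derive_seed(seed_b, 20L))
          for (st in cfg$strategies) {
            est <- run_strategy(st, cohort, pen, cfg$strategy,
                                seed = derive_seed(seed_b, 21L), full_fit = full_fit)
            rr[[length(rr) + 1L]] <- replicate_record(n, alpha, b, st, est, full_fit)
          }
          ind <- validate_independent(full_fit, independent)
          rr[[length(rr) + 1L]] <- replicate_record(n, alpha, b, "independent",
                                                    ind, full_fit)
        }
        do.call(rbind, rr)
      }, error = function(e) {
        vs_log("replicate n=%d b=%d failed: %s", n, b, conditionMessage(e))
        NULL
      })
      if (is.null(rows)) next
      if (!is.null(rec_path))
        jsonlite::write_json(rows, rec_path, auto_unbox = TRUE, digits = NA,
                             dataframe = "columns", na = "null")
      all_rows[[length(all_rows) + 1L]] <- rows
      vs_log("done n=%d replicate %d/%d", n, b, cfg$n_replicates)
    }
  }
  replicates <- do.call(rbind, all_rows)
  out <- structure(list(replicates = replicates,
                        summary = summarize_replicates(replicates),
                        tables = list(
                          auc_3y = aggregate_table(replicates, "auc_3y"),
                          ibs_3y = aggregate_table(replicates, "ibs_3y"),
                          c_index = aggregate_table(replicates, "c_index")),
                        oracle = oracle,
                        variance_tests = variance_tests(replicates),
                        independent_cohort_seed = derive_seed(cfg$master_seed, 0L, 0L),
                        config = cfg),
                   class = "benchmark_result")
  if (!is.null(out_dir)) {
    utils::write.csv(out$tables$auc_3y,
                     file.path(out_dir, "table_auc_3y.csv"), row.names = FALSE)
    utils::write.csv(out$tables$ibs_3y,
                     file.path(out_dir, "table_ibs_3y.csv"), row.names = FALSE)
    utils::write.csv(replicates,
                     file.path(out_dir, "replicates.csv"), row.names = FALSE)
    utils::write.csv(oracle$auc_curve,
                     file.path(out_dir, "oracle_auc_curve.csv"), row.names = FALSE)
  }
  out
}

summarize_replicates <- function(replicates) {
  agg <- function(v) c(mean = namean(v),
                       sd = if (sum(!is.na(v)) >= 2) stats::sd(v, na.rm = TRUE)
                            else NA_real_,
                       n_evaluable = sum(!is.na(v)))
  sp <- split(replicates,
              interaction(replicates$n, replicates$alpha, replicates$strategy,
                          drop = TRUE))
  do.call(rbind, lapply(sp, function(d) {
    data.frame(n = d$n[1], alpha = d$alpha[1], strategy = d$strategy[1],
               auc_3y_mean = agg(d$auc_3y)[["mean"]],
               auc_3y_sd = agg(d$auc_3y)[["sd"]],
               c_index_mean = agg(d$c_index)[["mean"]],
               c_index_sd = agg(d$c_index)[["sd"]],
               ibs_3y_mean = agg(d$ibs_3y)[["mean"]],
               ibs_3y_sd = agg(d$ibs_3y)[["sd"]],
               n_evaluable = agg(d$auc_3y)[["n_evaluable"]],
               row.names = NULL)
  }))
}

## Wide table: one row per (strategy, alpha), one "mean (sd)" column per n.
aggregate_table <- function(replicates, metric) {
  s <- summarize_replicates(replicates)
  mcol <- paste0(metric, "_mean"); scol <- paste0(metric, "_sd")
  s$cell <- sprintf("%.3f (%.3f)", s[[mcol]], s[[scol]])
  ns <- sort(unique(s$n))
  rows <- unique(s[c("strategy", "alpha")])
  rows <- rows[order(rows$strategy, rows$alpha), ]
  for (n in ns) {
    v <- s[s$n == n, ]
    rows[[paste0("n", n)]] <- v$cell[match(paste(rows$strategy, rows$alpha),
                                           paste(v$strategy, v$alpha))]
  }
  rownames(rows) <- NULL
  rows
}

variance_tests <- function(replicates) {
  internal <- setdiff(unique(replicates$strategy), "independent")
  sp <- split(replicates, interaction(replicates$n, replicates$alpha,
                                      drop = TRUE))
  res <- lapply(sp, function(d) {
    groups <- lapply(split(d[d$strategy %in% internal, "auc_3y"],
                           d[d$strategy %in% internal, "strategy"]),
                     as.numeric)
    groups <- groups[vapply(groups, function(v) sum(!is.na(v)) >= 2, logical(1))]
    if (length(groups) < 2) return(NULL)
    vt <- variance_homogeneity(groups)
    c(list(n = d$n[1], alpha = d$alpha[1]), vt)
  })
  res[!vapply(res, is.null, logical(1))]
}

#' @export
plot.benchmark_result <- function(x, metric = "auc_3y", alpha = NULL, ...) {
  s <- summarize_replicates(x$replicates)
  if (!is.null(alpha)) s <- s[abs(s$alpha - alpha) < 1e-9, ]
  mcol <- paste0(metric, "_mean")
  strategies <- unique(s$strategy)
  ns <- sort(unique(s$n))
  cols <- seq_along(strategies)
  graphics::plot(range(ns), range(s[[mcol]], na.rm = TRUE), type = "n",
                 log = "x", xlab = "training cohort size",
                 ylab = sprintf("mean %s", metric), ...)
  for (i in seq_along(strategies)) {
    d <- s[s$strategy == strategies[i], ]
    d <- d[order(d$n), ]
    graphics::lines(d$n, d[[mcol]], type = "b", pch = 20, col = cols[i])
  }
  if (metric == "auc_3y")
    graphics::abline(h = c(0.5, x$oracle$auc_3y), lty = c(3, 2), col = "grey40")
  graphics::legend("topleft", legend = strategies, col = cols, lty = 1,
                   pch = 20, bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("Validation-strategy benchmark\n")
  cat(sprintf("  oracle 3y AUC %.3f, 3y IBS %.4f\n",
              x$oracle$auc_3y, x$oracle$ibs_3y))
  cat(sprintf("  %d replicate records over n in {%s}, alpha in {%s}\n",
              nrow(x$replicates),
              paste(unique(x$replicates$n), collapse = ", "),
              paste(unique(x$replicates$alpha), collapse = ", ")))
  cat("\n3-year AUC, mean (sd):\n")
  print(x$tables$auc_3y, row.names = FALSE)
  invisible(x)
}
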