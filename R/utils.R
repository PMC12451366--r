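#' @keywords internal
"_PACKAGE"

## Seed handling: every stochastic operation takes an explicit `seed` and
## restores the caller's RNG state afterwards, so simulation results are pure
## functions of their arguments.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a replicate-level seed from a master seed
#'
#' Deterministic, collision-avoiding seed stream: replicate `b` of scenario
#' `s` always receives the same seed for a given `master`, independent of
#' evaluation order.  Values stay below 2^31 so they are valid R integer
#' seeds.
#'
#' @param master integer master seed.
#' @param ... one or more non-negative integer indices (scenario, replicate,
#'   repetition ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483629
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(h + 1)
}

## Fold assignment stratified by event status: events and censored subjects
## are spread as evenly as possible, which keeps eventless folds rare even at
## n = 50 with ~50% censoring.
stratified_folds <- function(event, k, seed = NULL) {
  with_seed(seed, {
    n <- length(event)
    fold <- integer(n)
    for (g in unique(event)) {
      idx <- which(event == g)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

vs_log <- function(..., verbose = getOption("coxvalsim.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
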