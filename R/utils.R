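# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so seeded package internals never perturb user-level
#' random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive a replicate seed from a base seed; kept below 2^31 - 1 so it is a
# valid R integer.  Base seed + index so extending a grid of replicates (or
# sizes) never changes the seeds of earlier replicates.
derive_seed <- function(base_seed, r) {
  as.integer((as.numeric(base_seed) + as.numeric(r)) %% 2147483647)
}

stop_ssnr <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "ssnr_error"),
                      call = sys.call(-1)))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_ssnr("'%s' must be a single integer >= %d", name, min,
              class = "ssnr_validation_error")
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop_ssnr("'%s' must be a single number strictly between 0 and 1", name,
              class = "ssnr_validation_error")
  }
  as.numeric(x)
}

# Row means and sample SDs (n - 1 denominator) of a genes x samples matrix,
# vectorised; returns list(mean, sd).
row_mean_sd <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1L))
  list(mean = m, sd = s)
}
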