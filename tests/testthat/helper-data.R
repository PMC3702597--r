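# Fixture builders shared across the test files.

# Small labelled dataset from an explicit matrix; labels class1/class2.
make_toy <- function(x, labels, log_scale = TRUE) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%d", seq_len(ncol(x)))
  labeled_dataset(expression_dataset(x, log_scale = log_scale),
                  factor(labels, levels = c("class1", "class2")))
}

# Random dataset with no class signal.
make_null_dataset <- function(n = 20, p = 30, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(p * n), nrow = p,
              dimnames = list(sprintf("g%03d", 1:p), sprintf("s%03d", 1:n)))
  make_toy(x, rep(c("class1", "class2"), length.out = n))
}

# Independent brute-force oracle for the per-gene SNR: explicit loop with
# mean() and sd(), floored denominator.
snr_oracle <- function(x, labels, sd_floor = 1e-8) {
  i1 <- labels == levels(labels)[1L]
  vapply(seq_len(nrow(x)), function(i) {
    (mean(x[i, i1]) - mean(x[i, !i1])) /
      max(sd(x[i, i1]) + sd(x[i, !i1]), sd_floor)
  }, numeric(1L))
}

# Independent direct evaluation of the MCC formula.
mcc_oracle <- function(tp, tn, fp, fn) {
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) return(0)
  (tp * tn - fp * fn) / sqrt(d)
}

# Build a learning_curve object from given summary statistics (to test the
# near-optimal rule against constructed fixtures).
fake_curve <- function(sizes, means, sds, nu = NULL, epsilon = 0.05) {
  evals <- Map(function(n, m, s) {
    structure(list(n_train = n, mcc_values = numeric(0), mean_mcc = m,
                   sd_mcc = s, p5 = m - s, p95 = m + s),
              class = "size_evaluation")
  }, sizes, means, sds)
  if (is.null(nu)) {
    nu <- vapply(seq_along(sizes)[-1L], function(i) {
      nu_index(means[i], means[i - 1L], sizes[i], sizes[i - 1L])
    }, numeric(1L))
  }
  structure(list(evaluations = evals, nu = nu, method = "ncentroid", seed = 1L,
                 config = curve_config(size_start = sizes[1L],
                                       size_step = diff(sizes)[1L],
                                       size_max = max(sizes),
                                       repetitions = 1, epsilon = epsilon)),
            class = "learning_curve")
}
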