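# SNR, SSNR, confusion counts, MCC and Pearson r.

test_that("class summaries match hand arithmetic and use the n-1 SD", {
  x <- rbind(g1 = c(1, 3, 0, 2), g2 = c(5, 5, 5, 5))
  colnames(x) <- paste0("s", 1:4)
  d <- make_toy(x, c("class1", "class1", "class2", "class2"))
  cs <- class_summaries(d)
  expect_equal(unname(cs$mu1), c(2, 5))
  expect_equal(unname(cs$mu2), c(1, 5))
  expect_equal(unname(cs$sd1), c(sqrt(2), 0))
  expect_equal(unname(cs$sd2), c(sqrt(2), 0))

  # a single-sample class cannot yield an SD
  d3 <- make_toy(x[, 1:3], c("class1", "class1", "class2"))
  expect_error(class_summaries(d3), class = "ssnr_class_size_error")
  # SNR requires log-scale data
  dl <- make_toy(x, c("class1", "class1", "class2", "class2"),
                 log_scale = FALSE)
  expect_error(class_summaries(dl), "log-scale",
               class = "ssnr_validation_error")
})

test_that("snr_vector follows (mu1-mu2)/(sd1+sd2) with floor and drop modes", {
  cs <- structure(list(mu1 = c(a = 2, b = 1, c = 4), mu2 = c(a = 1, b = 1, c = 4),
                       sd1 = c(a = 0.5, b = 1, c = 0), sd2 = c(a = 0.5, b = 2, c = 0),
                       n1 = 5L, n2 = 5L), class = "class_summary")
  a <- snr_vector(cs)
  expect_equal(unname(a), c(1, 0, 0))  # (2-1)/1; mu1=mu2 -> 0; 0/floor -> 0
  expect_true(all(is.finite(snr_vector(cs))))
  expect_equal(names(snr_vector(cs, zero_sd = "drop")), c("a", "b"))
})

test_that("snr_vector agrees with a brute-force per-gene oracle to 1e-12", {
  set.seed(42)
  for (rep in 1:100) {
    x <- matrix(rnorm(50 * 30), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:30)))
    lab <- factor(sample(rep(c("class1", "class2"), c(14, 16))),
                  levels = c("class1", "class2"))
    d <- labeled_dataset(expression_dataset(x), lab)
    a <- snr_vector(class_summaries(d))
    expect_equal(unname(a), snr_oracle(x, lab), tolerance = 1e-12)
  }
})

test_that("SNR is antisymmetric under class relabelling; SSNR invariant", {
  d <- make_null_dataset(n = 16, p = 25, seed = 7)
  a <- snr_vector(class_summaries(d))
  swapped <- labeled_dataset(d$dataset,
                             factor(d$labels, levels = rev(levels(d$labels))))
  a2 <- snr_vector(class_summaries(swapped))
  expect_equal(a2, -a)
  expect_equal(ssnr(a2), ssnr(a))
})

test_that("SSNR is the range, order-invariant, >= 0, shift/scale invariant", {
  expect_equal(ssnr(c(0.8, -0.4, 0.1)), 1.2)
  expect_equal(ssnr(rep(0, 5)), 0)
  expect_equal(ssnr(c(3)), 0)  # single gene: max = min
  set.seed(1)
  a <- rnorm(40)
  expect_equal(ssnr(sample(a)), ssnr(a))
  expect_gte(ssnr(a), 0)
  expect_error(ssnr(numeric(0)), class = "ssnr_validation_error")

  # per-gene shifts and common positive scaling of the log expression leave
  # SSNR unchanged (means and SDs transform consistently)
  d <- make_null_dataset(n = 12, p = 20, seed = 3)
  base <- snr_profile(d)$ssnr
  shifted <- d
  shifted$dataset$x <- d$dataset$x + rnorm(20)  # per-gene shift (recycled by row)
  expect_equal(snr_profile(shifted)$ssnr, base)
  scaled <- d
  scaled$dataset$x <- d$dataset$x * 3.7
  expect_equal(snr_profile(scaled)$ssnr, base)
})

test_that("confusion counts tally exactly", {
  cm <- confusion_counts(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]),
               c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cm <- confusion_counts(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]),
               c(TP = 0L, TN = 0L, FP = 2L, FN = 2L))
  cm <- confusion_counts(c(1, 2, 1, 2), c(1, 1, 2, 2))
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]),
               c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_error(confusion_counts(c(1, 2), c(1, 2, 1)),
               class = "ssnr_validation_error")
})

test_that("MCC matches direct evaluation of its formula", {
  expect_equal(mcc(structure(list(TP = 10, TN = 10, FP = 0, FN = 0),
                             class = "confusion_matrix")), 1)
  expect_equal(mcc(structure(list(TP = 0, TN = 0, FP = 10, FN = 10),
                             class = "confusion_matrix")), -1)
  expect_equal(mcc(structure(list(TP = 5, TN = 5, FP = 5, FN = 5),
                             class = "confusion_matrix")), 0)
  # frozen oracle value: (6*4 - 1*2)/sqrt(7*8*5*6)
  expect_equal(mcc(structure(list(TP = 6, TN = 4, FP = 1, FN = 2),
                             class = "confusion_matrix")),
               22 / sqrt(1680))
  # zero-marginal convention and empty-table error
  expect_equal(mcc(structure(list(TP = 0, TN = 3, FP = 0, FN = 2),
                             class = "confusion_matrix")), 0)
  expect_error(mcc(structure(list(TP = 0, TN = 0, FP = 0, FN = 0),
                             class = "confusion_matrix")),
               class = "ssnr_validation_error")
})

test_that("MCC is invariant under a simultaneous positive/negative swap", {
  set.seed(11)
  for (i in 1:20) {
    truth <- factor(sample(c("class1", "class2"), 30, replace = TRUE),
                    levels = c("class1", "class2"))
    pred <- sample(c("class1", "class2"), 30, replace = TRUE)
    if (nlevels(droplevels(truth)) < 2) next
    m1 <- mcc(confusion_counts(truth, pred))
    m2 <- mcc(confusion_counts(factor(truth, levels = rev(levels(truth))),
                               pred))
    expect_equal(m1, m2)
  }
})

test_that("pearson_r matches a brute-force covariance computation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2.2, 1.9, 3.5, 3.1, 4.8)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle)
  expect_error(pearson_r(c(1, 1, 1), y[1:3]), class = "ssnr_degenerate_error")
  expect_error(pearson_r(1:2, 1:2), class = "ssnr_validation_error")
})
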