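# Feature ranking, the three classifier backends, and cross-validated
# feature-count selection.

test_that("gene ranking orders by |SNR| with lexicographic ties", {
  x <- rbind(g1 = c(10, 10, 5, 5),    # a = large positive
             g2 = c(0, 0, 9, 9),      # a = large negative
             g3 = c(1.0, 1.2, 1.1, 0.9))
  x[1, ] <- x[1, ] + c(0.1, -0.1, 0.1, -0.1)  # non-zero SDs
  x[2, ] <- x[2, ] + c(0.1, -0.1, 0.1, -0.1)
  colnames(x) <- paste0("s", 1:4)
  d <- make_toy(x, c("class1", "class1", "class2", "class2"))
  r <- rank_genes_by_snr(d)
  expect_equal(r[3], "g3")
  expect_setequal(r[1:2], c("g1", "g2"))

  # exact |a| ties fall back to gene id order
  xt <- rbind(gB = c(1, 3, 0, 2), gA = c(0, 2, 1, 3), gC = c(5, 7, 4, 6))
  colnames(xt) <- paste0("s", 1:4)
  dt <- make_toy(xt, c("class1", "class1", "class2", "class2"))
  a <- snr_vector(class_summaries(dt))
  expect_true(length(unique(abs(a))) == 1L)
  expect_equal(rank_genes_by_snr(dt), c("gA", "gB", "gC"))
})

test_that("nearest centroid stores class means and predicts by distance", {
  set.seed(5)
  x <- cbind(matrix(rnorm(20, mean = 0), 4, 5), matrix(rnorm(20, mean = 4), 4, 5))
  dimnames(x) <- list(paste0("g", 1:4), paste0("s", 1:10))
  d <- make_toy(x, rep(c("class1", "class2"), each = 5))
  m <- train_classifier(d, paste0("g", 1:4), classifier_config("ncentroid"))
  expect_equal(m$fit$centroid1, rowMeans(x[, 1:5]))
  expect_equal(m$fit$centroid2, rowMeans(x[, 6:10]))

  # a sample exactly at the class-1 centroid is class 1; equidistant ties
  # also go to class 1
  q <- cbind(at1 = m$fit$centroid1,
             mid = (m$fit$centroid1 + m$fit$centroid2) / 2)
  expect_equal(as.character(predict(m, q)), c("class1", "class1"))

  # predictions match a brute-force nearest-mean loop on a random instance
  gen <- generate_dataset(16, 10, 3, 2, 0.5, seed = 9)
  tr <- subset_samples(gen$data, 1:10)
  te <- expr_matrix(gen$data)[, 11:16]
  mod <- train_classifier(tr, gene_ids(tr), classifier_config("ncentroid"))
  brute <- apply(te, 2, function(v) {
    d1 <- sum((v - mod$fit$centroid1)^2)
    d2 <- sum((v - mod$fit$centroid2)^2)
    if (d1 <= d2) "class1" else "class2"
  })
  expect_equal(as.character(predict(mod, te)), unname(brute))
})

test_that("kNN and SVM backends behave on separable toy data", {
  set.seed(8)
  x <- cbind(matrix(rnorm(30, 0, 0.3), 3, 10), matrix(rnorm(30, 5, 0.3), 3, 10))
  dimnames(x) <- list(paste0("g", 1:3), paste0("s", 1:20))
  d <- make_toy(x, rep(c("class1", "class2"), each = 10))

  for (method in c("knn", "svm")) {
    m <- train_classifier(d, paste0("g", 1:3), classifier_config(method))
    expect_equal(as.character(predict(m, x)), as.character(d$labels))
  }

  # kNN with an all-class1 neighbourhood predicts class1 for any query
  d3 <- make_toy(x[, c(1:3, 11)], c(rep("class1", 3), "class2"))
  mk <- train_classifier(subset_samples(d3, 1:4), paste0("g", 1:3),
                         classifier_config("knn"))
  mk$fit$x <- mk$fit$x[1:3, , drop = FALSE]  # keep only the class1 points
  mk$fit$y <- mk$fit$y[1:3]
  q <- matrix(rnorm(3), 3, 1, dimnames = list(paste0("g", 1:3), "q"))
  expect_equal(as.character(predict(mk, q)), "class1")
})

test_that("training validates inputs", {
  d <- make_null_dataset(n = 8, p = 5)
  expect_error(train_classifier(d, character(0)),
               class = "ssnr_validation_error")
  expect_error(train_classifier(d, "not_a_gene"),
               "absent", class = "ssnr_validation_error")
  m <- train_classifier(d, gene_ids(d)[1:2])
  q <- matrix(0, 1, 1, dimnames = list(gene_ids(d)[1], "q"))
  expect_error(predict(m, q), "absent", class = "ssnr_validation_error")
})

test_that("cross-validated selection prefers fewer features on ties and is deterministic", {
  gen <- generate_dataset(60, 40, 10, 4, 0.3, seed = 2)
  cfg <- classifier_config("ncentroid", feature_grid = c(5, 10, 20), seed = 3)
  m1 <- cross_validate_select(gen$data, cfg)
  m2 <- cross_validate_select(gen$data, cfg)
  expect_identical(m1[names(m1) != "config"], m2[names(m2) != "config"])
  # perfectly separable: every count scores 1, smallest count wins
  expect_equal(m1$cv_score, 1)
  expect_equal(length(m1$features), 5L)

  # a grid of one entry is selected regardless
  m3 <- cross_validate_select(gen$data,
                              classifier_config("ncentroid", feature_grid = 7,
                                                seed = 3))
  expect_equal(length(m3$features), 7L)
})

test_that("null labels give near-zero CV score on average", {
  scores <- vapply(1:50, function(s) {
    d <- make_null_dataset(n = 40, p = 30, seed = 100 + s)
    cross_validate_select(d, classifier_config("ncentroid",
                                               feature_grid = c(5, 10),
                                               seed = s))$cv_score
  }, numeric(1L))
  expect_lt(abs(mean(scores)), 0.1)
})

test_that("folds shrink with a warning when the minority class is small", {
  gen <- generate_dataset(24, 15, 3, 3, 0.5, prevalence = 1 / 8, seed = 6)
  expect_warning(
    m <- cross_validate_select(gen$data,
                               classifier_config("ncentroid",
                                                 feature_grid = c(3, 6))),
    "reducing folds")
  expect_equal(m$folds_used, 3L)
})

test_that("feature ranking inside CV cannot leak the held-out fold", {
  # gene 'leak' is informative ONLY in the samples of one fold; with
  # ranking done on fold-training data it cannot dominate that fold's model
  set.seed(21)
  n <- 25
  x <- matrix(rnorm(2 * n, sd = 0.1), nrow = 2,
              dimnames = list(c("g_mild", "leak"), sprintf("s%02d", 1:n)))
  lab <- factor(rep(c("class1", "class2"), length.out = n),
                levels = c("class1", "class2"))
  # g_mild carries a genuine class signal everywhere
  x["g_mild", ] <- x["g_mild", ] + ifelse(lab == "class1", 1, 0)
  cfg <- classifier_config("ncentroid", feature_grid = 1, folds = 5, seed = 2)
  fold <- ssnr:::make_folds(lab, 5L, cfg$seed)
  held <- which(fold == 1L)
  # 'leak' separates perfectly within the held-out fold only
  x["leak", held] <- ifelse(lab[held] == "class1", 10, -10)
  d <- labeled_dataset(expression_dataset(x), lab)
  tr <- subset_samples(d, which(fold != 1L))
  # ranked on fold-training data only, the leaky gene cannot enter the
  # fold's single-feature model
  expect_equal(rank_genes_by_snr(tr)[1], "g_mild")
  expect_equal(rank_genes_by_snr(tr)[2], "leak")
})
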