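# Dataset containers and the delimited-text readers/writers.

test_that("expression matrix read-back honours orientation and log transform", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(c(0, 1, 3, 7, 15, 31), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  writeLines(c("gene_id\ts1\ts2",
               paste(rownames(m), m[, 1], m[, 2], sep = "\t")), tmp)

  ds <- read_expression_matrix(tmp, log_scale = FALSE)
  expect_s3_class(ds, "expr_dataset")
  expect_equal(dim(ds$x), c(3L, 2L))
  expect_equal(ds$x["gB", "s2"], 15)

  # transposed orientation reads the same file as samples x genes
  dst <- read_expression_matrix(tmp, orientation = "samples_by_genes",
                                log_scale = FALSE)
  expect_equal(dim(dst$x), c(2L, 3L))
  expect_equal(dst$x, t(ds$x))

  # log2(v + 1) convenience: {0,1,3,7,15,31} -> {0,1,2,3,4,5}
  dsl <- read_expression_matrix(tmp, log_transform = "log2_with_offset")
  expect_equal(as.vector(dsl$x), 0:5)
  expect_true(dsl$log_scale)
})

test_that("GCT dialect is detected and its Description column dropped", {
  tmp <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t3",
               "Name\tDescription\ts1\ts2\ts3",
               "gA\tfoo\t1\t2\t3",
               "gB\tbar\t4\t5\t6"), tmp)
  ds <- read_expression_matrix(tmp)
  expect_equal(dim(ds$x), c(2L, 3L))
  expect_equal(ds$x["gB", "s3"], 6)
})

test_that("loader rejects malformed input with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\toops", "gB\t3\t4"), tmp)
  expect_error(read_expression_matrix(tmp), "non-numeric.*oops",
               class = "ssnr_parse_error")

  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), tmp)
  expect_error(read_expression_matrix(tmp), "duplicate gene ids",
               class = "ssnr_validation_error")

  writeLines(c("gene_id\ts1\ts2", "gA\t1\tNA", "gB\t3\t4"), tmp)
  expect_error(read_expression_matrix(tmp), "missing value",
               class = "ssnr_parse_error")
  imp <- read_expression_matrix(tmp, missing = "median")
  expect_equal(imp$x["gA", "s2"], 1)  # per-gene median of the observed value
})

test_that("label reading and attachment enforce the two-class contract", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("s1 A", "s2 A", "s3 B", "s4 B"), tmp)
  lab <- read_labels(tmp)
  expect_equal(lab, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))

  writeLines(c("s1 A", "s1 B"), tmp)
  expect_error(read_labels(tmp), "more than once",
               class = "ssnr_validation_error")
  writeLines(c("s1 A", "s2 A"), tmp)
  expect_error(read_labels(tmp), "single class",
               class = "ssnr_single_class_error")

  x <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  ds <- expression_dataset(x)
  ld <- attach_labels(ds, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"), "A")
  expect_equal(unname(class_counts(ld)), c(2L, 2L))
  expect_equal(levels(ld$labels)[1L], "A")  # positive token is class 1

  # prevalence 3:1 recorded through class counts
  ld31 <- attach_labels(ds, c(s1 = "A", s2 = "A", s3 = "A", s4 = "B"), "A")
  expect_equal(unname(class_counts(ld31)), c(3L, 1L))

  expect_error(attach_labels(ds, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"), "Z"),
               class = "ssnr_single_class_error")
  expect_error(attach_labels(ds, c(s1 = "A", s2 = "B"), "A"),
               "no label for sample", class = "ssnr_validation_error")
})

test_that("result tables round-trip with embedded metadata", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(n_train = c(20L, 40L), mean_mcc = c(0.21, 0.345))
  write_results(df, tmp, metadata = list(seed = 7L, method = "ncentroid"))
  lines <- readLines(tmp)
  expect_equal(length(lines), 2L + 1L + 2L)  # metadata + header + rows
  expect_match(lines[1L], "^# seed: 7$")
  back <- read_results(tmp)
  expect_equal(back, df)

  # empty table -> header-only payload
  write_results(df[0, ], tmp)
  expect_equal(readLines(tmp), "n_train\tmean_mcc")
})

test_that("dataset write/read round-trip preserves values and labels", {
  gen <- generate_dataset(10, 6, 2, 1, 0.5, seed = 4)
  tmpm <- withr::local_tempfile(fileext = ".tsv")
  tmpl <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(gen$data, tmpm, tmpl)
  ds <- read_expression_matrix(tmpm)
  lab <- read_labels(tmpl)
  ld <- attach_labels(ds, lab, "class1")
  expect_equal(expr_matrix(ld), expr_matrix(gen$data), tolerance = 1e-6)
  expect_equal(as.character(ld$labels), as.character(gen$data$labels))
})

test_that("split pairs demand disjoint samples on an identical gene panel", {
  d <- make_null_dataset(n = 10)
  a <- subset_samples(d, 1:6)
  b <- subset_samples(d, 7:10)
  expect_s3_class(split_pair(a, b), "split_pair")
  expect_error(split_pair(a, subset_samples(d, 5:10)),
               "share samples", class = "ssnr_validation_error")
})

test_that("container invariants reject degenerate inputs", {
  x <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expression_dataset(x[, 1, drop = FALSE]),
               class = "ssnr_validation_error")  # n >= 2
  xna <- x; xna[1, 1] <- NA
  expect_error(expression_dataset(xna), class = "ssnr_validation_error")
  expect_error(labeled_dataset(expression_dataset(x), c("A", "A")),
               class = "ssnr_single_class_error")
})
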