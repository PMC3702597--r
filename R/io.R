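# Readers and writers for the plain-text formats the package consumes:
# tab-delimited expression matrices (plus the GCT dialect), two-column label
# and covariate files, and delimited result tables.

#' Read an expression matrix from delimited text
#'
#' Reads a tab-delimited matrix with identifiers in the first row and column.
#' The GCT dialect (a `#1.2` preamble line, a dimensions line, and a
#' `Description` second column) is detected automatically and its extra
#' content skipped.  The matrix is stored internally as genes x samples
#' regardless of the file's orientation.
#'
#' @param path Path to the file.
#' @param orientation `"genes_by_samples"` (default) if rows are genes, or
#'   `"samples_by_genes"` if rows are samples.
#' @param log_transform `"none"` (values are already log scale) or
#'   `"log2_with_offset"` to apply `log2(v + offset)` to raw intensities.
#' @param offset Offset used by `log2_with_offset` (default 1).
#' @param log_scale Declared scale of the stored values when
#'   `log_transform = "none"`; defaults to `TRUE` (already log).
#' @param missing `"error"` to reject missing cells (default) or `"median"`
#'   to impute them with the per-gene median.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_by_samples",
                                                   "samples_by_genes"),
                                   log_transform = c("none", "log2_with_offset"),
                                   offset = 1,
                                   log_scale = TRUE,
                                   missing = c("error", "median")) {
  orientation <- match.arg(orientation)
  log_transform <- match.arg(log_transform)
  missing <- match.arg(missing)
  if (!file.exists(path)) {
    stop_ssnr("expression file not found: %s", path, class = "ssnr_io_error")
  }

  first <- readLines(path, n = 1L)
  gct <- length(first) == 1L && grepl("^#1\\.[0-9]", first)
  if (gct) {
    tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) >= 2L && tolower(names(tab)[2]) == "description") {
      tab <- tab[, -2L, drop = FALSE]
    }
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
  }
  if (ncol(tab) < 2L) {
    stop_ssnr("malformed header in %s: need an id column plus >= 1 data column",
              path, class = "ssnr_parse_error")
  }
  ids <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & trimws(v) != "" &
                     toupper(trimws(v)) != "NA")
      if (length(bad)) {
        stop_ssnr("non-numeric value '%s' at row %d, column '%s' of %s",
                  v[bad[1L]], bad[1L], names(vals)[j], path,
                  class = "ssnr_parse_error")
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids

  if (orientation == "samples_by_genes") m <- t(m)
  # now rows = genes, cols = samples

  if (anyNA(m)) {
    if (missing == "error") {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop_ssnr("missing value at gene '%s', sample '%s' in %s (set missing = 'median' to impute)",
                rownames(m)[bad[1L]], colnames(m)[bad[2L]], path,
                class = "ssnr_parse_error")
    }
    for (i in which(rowSums(is.na(m)) > 0L)) {
      med <- stats::median(m[i, ], na.rm = TRUE)
      if (is.na(med)) {
        stop_ssnr("gene '%s' is entirely missing; cannot impute", rownames(m)[i],
                  class = "ssnr_parse_error")
      }
      m[i, is.na(m[i, ])] <- med
    }
  }

  if (log_transform == "log2_with_offset") {
    if (any(m + offset <= 0)) {
      stop_ssnr("log2_with_offset requires v + offset > 0 for all values",
                class = "ssnr_validation_error")
    }
    m <- log2(m + offset)
    log_scale <- TRUE
  }
  expression_dataset(m, log_scale = log_scale)
}

#' Read a two-column sample/label file
#'
#' Whitespace- or tab-delimited, one sample per line: `sample_id  token`.
#' Tokens are preserved verbatim.
#'
#' @param path Path to the file.
#' @param require_two_classes Require >= 2 distinct tokens (default `TRUE`;
#'   set `FALSE` when reading a covariate that may have more levels).
#' @return Named character vector mapping sample id to token.
#' @export
read_labels <- function(path, require_two_classes = TRUE) {
  if (!file.exists(path)) {
    stop_ssnr("label file not found: %s", path, class = "ssnr_io_error")
  }
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample_id", "token"),
                           colClasses = "character")
  dup <- unique(tab$sample_id[duplicated(tab$sample_id)])
  if (length(dup)) {
    stop_ssnr("sample(s) listed more than once in %s: %s", path,
              paste(dup, collapse = ", "), class = "ssnr_validation_error")
  }
  if (require_two_classes && length(unique(tab$token)) < 2L) {
    stop_ssnr("label file %s contains a single class ('%s')", path,
              tab$token[1L], class = "ssnr_single_class_error")
  }
  structure(tab$token, names = tab$sample_id)
}

#' Attach endpoint labels to an expression dataset
#'
#' Samples whose token equals `positive_token` become class 1 (the positive
#' class); all other tokens collapse to class 2.
#'
#' @param dataset An [expression_dataset()].
#' @param labels Named character vector (sample id -> token), e.g. from
#'   [read_labels()].
#' @param positive_token Token designating class 1.
#' @return A [labeled_dataset()] with factor levels
#'   `c(positive_token, "<other>")`; when several tokens collapse into class 2
#'   the second level is named `"other"`.
#' @export
attach_labels <- function(dataset, labels, positive_token) {
  stopifnot(inherits(dataset, "expr_dataset"))
  ids <- colnames(dataset$x)
  missing <- setdiff(ids, names(labels))
  if (length(missing)) {
    stop_ssnr("no label for sample(s): %s", paste(missing, collapse = ", "),
              class = "ssnr_validation_error")
  }
  tok <- labels[ids]
  pos <- tok == positive_token
  if (!any(pos) || all(pos)) {
    stop_ssnr("positive token '%s' yields a single class (%d of %d samples positive)",
              positive_token, sum(pos), length(pos),
              class = "ssnr_single_class_error")
  }
  neg_tokens <- unique(tok[!pos])
  neg_name <- if (length(neg_tokens) == 1L) neg_tokens else "other"
  lab <- factor(ifelse(pos, positive_token, neg_name),
                levels = c(positive_token, neg_name))
  labeled_dataset(dataset, lab)
}

#' Attach a categorical covariate to a labelled dataset
#'
#' @param data A [labeled_dataset()].
#' @param name Covariate name.
#' @param values Named character vector (sample id -> level), e.g. from
#'   `read_labels(path, require_two_classes = FALSE)`.
#' @return The dataset with the covariate added.
#' @export
attach_covariate <- function(data, name, values) {
  stopifnot(inherits(data, "labeled_dataset"))
  ids <- sample_ids(data)
  missing <- setdiff(ids, names(values))
  if (length(missing)) {
    stop_ssnr("no '%s' value for sample(s): %s", name,
              paste(missing, collapse = ", "), class = "ssnr_validation_error")
  }
  cov <- data$covariates %||% data.frame(row.names = ids)
  cov[[name]] <- factor(values[ids])
  data$covariates <- cov
  data
}

#' Write a result table as tab-delimited text
#'
#' Writes a header line and one row per record.  Optional metadata (e.g. the
#' resolved configuration and seed of the run) is embedded as `# key: value`
#' comment lines above the header so every output is self-describing;
#' [read_results()] skips them.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @param metadata Optional named list written as comment lines.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path, metadata = NULL) {
  table <- as.data.frame(table)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) {
                    stop_ssnr("cannot write to %s: %s", path, conditionMessage(e),
                              class = "ssnr_io_error")
                  })
  on.exit(close(con))
  if (!is.null(metadata)) {
    for (k in names(metadata)) {
      writeLines(sprintf("# %s: %s", k,
                         paste(format(metadata[[k]]), collapse = " ")), con)
    }
  }
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a labelled dataset to matrix + label files
#'
#' @param data A [labeled_dataset()].
#' @param matrix_path,labels_path Output paths (tab-delimited).
#' @param metadata Optional named list embedded in the matrix file header.
#' @return Invisibly, a character vector of the files written.
#' @export
write_dataset <- function(data, matrix_path, labels_path, metadata = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  m <- expr_matrix(data)
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_results(tab, matrix_path, metadata = metadata)
  lab <- data.frame(sample_id = sample_ids(data),
                    label = as.character(data$labels))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(matrix_path, labels_path))
}
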