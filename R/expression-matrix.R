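#' Construct an expression matrix with per-sample class labels
#'
#' The package's basic container: a continuous genes-by-samples matrix plus a
#' class label for every sample. Labels are stored as a factor whose level
#' order (`class_set`) fixes the class order used downstream (contingency
#' tables, tie-breaks in prediction).
#'
#' @param values numeric matrix, rows = genes, columns = samples.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @param labels class label per sample (character or factor, length
#'   `ncol(values)`).
#' @param class_set optional ordered vector of distinct class labels; defaults
#'   to the labels' order of first appearance.
#' @return an object of class `"expression_matrix"`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `labels` (factor), `class_set`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values), labels,
                              class_set = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_fmt("expression values must be numeric")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop_fmt("gene_ids length (%d) != number of rows (%d)",
             length(gene_ids), nrow(values))
  if (length(sample_ids) != ncol(values))
    stop_fmt("sample_ids length (%d) != number of columns (%d)",
             length(sample_ids), ncol(values))
  if (anyDuplicated(gene_ids))
    stop_fmt("duplicate gene ids: %s",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_fmt("duplicate sample ids: %s",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_fmt("missing expression value at gene '%s', sample '%s'; impute before use",
             gene_ids[idx[1L]], sample_ids[idx[2L]])
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop_fmt("labels length (%d) != number of samples (%d)",
             length(labels), ncol(values))
  if (is.null(class_set)) class_set <- unique(labels)
  class_set <- as.character(class_set)
  if (!all(labels %in% class_set))
    stop_fmt("labels outside class_set: %s",
             paste(setdiff(labels, class_set), collapse = ", "))
  if (length(class_set) < 2L) stop_fmt("need at least 2 classes")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids,
                 labels = factor(labels, levels = class_set),
                 class_set = class_set),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat("classes:", paste(sprintf("%s (%d)", x$class_set, table(x$labels)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix and its label file
#'
#' The matrix file is delimited text with sample ids in the first row and gene
#' ids in the first column (genes as rows, the microarray convention). The
#' label file has two columns, sample id and class, with or without a header.
#' The delimiter is inferred from the file extension (`.csv` = comma,
#' otherwise tab) unless given explicitly.
#'
#' @param path matrix file.
#' @param labels_path two-column label file.
#' @param sep,labels_sep optional delimiter overrides.
#' @param transpose set `TRUE` if the file stores samples as rows; the matrix
#'   is never transposed silently.
#' @return an [expression_matrix].
#' @export
read_expression_matrix <- function(path, labels_path, sep = NULL,
                                   labels_sep = NULL, transpose = FALSE) {
  sep <- infer_sep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw),
           dimnames = dimnames(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_fmt("non-numeric cell '%s' at row '%s', column '%s' in %s",
             as.matrix(raw)[bad[1L], bad[2L]], rownames(raw)[bad[1L]],
             colnames(raw)[bad[2L]], path)
  }
  if (transpose) vals <- t(vals)
  lab_raw <- utils::read.table(labels_path, header = FALSE,
                               sep = infer_sep(labels_path, labels_sep),
                               colClasses = "character", comment.char = "")
  if (ncol(lab_raw) < 2L) stop_fmt("label file must have two columns")
  # tolerate a header row such as "sample_id<tab>class"
  if (identical(tolower(lab_raw[1L, 1L]), "sample_id"))
    lab_raw <- lab_raw[-1L, , drop = FALSE]
  lab_map <- stats::setNames(lab_raw[[2L]], lab_raw[[1L]])
  missing <- setdiff(colnames(vals), names(lab_map))
  if (length(missing))
    stop_fmt("samples present in matrix but absent from labels: %s",
             paste(missing, collapse = ", "))
  expression_matrix(vals, labels = unname(lab_map[colnames(vals)]))
}

#' Write an expression matrix and its label file
#'
#' @param x an [expression_matrix].
#' @param path matrix file to write.
#' @param labels_path optional label file to write (two columns, header
#'   `sample_id`, `class`).
#' @param sep optional delimiter override.
#' @export
write_expression_matrix <- function(x, path, labels_path = NULL, sep = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  sep <- infer_sep(path, sep)
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(sample_id = x$sample_ids, class = as.character(x$labels)),
      labels_path, sep = infer_sep(labels_path, sep), quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(x)
}

#' Write a gene ranking table to delimited text
#'
#' One row per gene with every score component (final ratio, impurity
#' reduction, splitting status, standard and weighted Gini indexes).
#'
#' @param ranking a data frame as returned by [rank_genes()].
#' @param path output file.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ranking)
}
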