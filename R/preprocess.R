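#' Construct an expression dataset
#'
#' Bundles a genes-by-samples expression matrix with per-sample subtype
#' labels. This is the universal input object of the package: every
#' downstream stage (network construction, module detection, featurization)
#' consumes it.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param labels named character vector mapping sample id to subtype name,
#'   or a two-column data.frame (sample_id, subtype).
#' @param log_transformed logical flag recording whether `values` are on the
#'   log2 scale.
#' @return an object of class `expression_dataset` with elements `values`,
#'   `labels` (named character vector aligned to columns) and
#'   `log_transformed`.
#' @export
expression_dataset <- function(values, labels, log_transformed = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (is.data.frame(labels)) {
    lab <- as.character(labels[[2L]])
    names(lab) <- as.character(labels[[1L]])
    labels <- lab
  }
  if (anyDuplicated(names(labels)))
    stop("duplicate sample ids in labels")
  missing_lab <- setdiff(colnames(values), names(labels))
  if (length(missing_lab))
    stop("samples without labels: ", paste(missing_lab, collapse = ", "))
  labels <- labels[colnames(values)]
  tab <- table(labels)
  if (any(tab < 2L))
    stop("every subtype needs at least 2 samples; too small: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  structure(
    list(values = values, labels = labels,
         log_transformed = isTRUE(log_transformed)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  tab <- table(x$labels)
  cat("subtypes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  cat("log2-transformed:", x$log_transformed, "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subtype names of a dataset
#' @param ds an `expression_dataset`.
#' @return character vector of subtype names in first-appearance order.
#' @export
subtypes <- function(ds) unique(unname(ds$labels))

#' Sample ids belonging to one subtype
#' @param ds an `expression_dataset`.
#' @param subtype subtype name.
#' @return character vector of sample ids.
#' @export
subtype_samples <- function(ds, subtype) {
  ids <- names(ds$labels)[ds$labels == subtype]
  if (!length(ids)) stop("unknown subtype: ", subtype)
  ids
}

#' Load expression data and labels from tab-separated files
#'
#' The expression file is a TSV with gene ids in the first column and a
#' header row of sample ids; the label file has two columns
#' (sample id, subtype), with an optional `#`-prefixed header. The dataset
#' is restricted to samples present in both files; matrix samples without a
#' label are dropped with a warning.
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the label TSV.
#' @param log_transform if `TRUE`, values are transformed to
#'   `log2(value + 1)` after loading.
#' @return an [expression_dataset()].
#' @export
load_expression <- function(matrix_path, labels_path, log_transform = FALSE) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  gene_ids <- as.character(raw[[1L]])
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids

  lab_raw <- utils::read.delim(labels_path, header = FALSE, sep = "\t",
                               comment.char = "#", stringsAsFactors = FALSE)
  labels <- as.character(lab_raw[[2L]])
  names(labels) <- as.character(lab_raw[[1L]])
  if (anyDuplicated(names(labels))) stop("duplicate sample ids in labels file")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in matrix file")

  keep <- intersect(colnames(values), names(labels))
  if (!length(keep))
    stop("no samples shared between expression matrix and labels")
  dropped <- setdiff(colnames(values), keep)
  if (length(dropped)) {
    warning(length(dropped), " sample(s) in matrix without a label dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  values <- values[, keep, drop = FALSE]
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (log_transform) values <- log2(values + 1)
  expression_dataset(values, labels[keep], log_transformed = log_transform)
}

#' Median absolute deviation without consistency scaling
#'
#' The plain statistic `median(|x - median(x)|)`, used to rank gene
#' variability. Unlike [stats::mad()] no Gaussian consistency constant
#' (1.4826) is applied.
#'
#' @param x numeric vector of length >= 1.
#' @return a non-negative scalar.
#' @export
gene_mad <- function(x) {
  if (!length(x)) stop("gene_mad: empty vector")
  stats::median(abs(x - stats::median(x)))
}

#' Filter genes by mean expression and variability
#'
#' Two-stage gene filter: genes whose mean raw-scale expression across all
#' samples falls below `min_mean` are removed first; of the survivors, the
#' `ceiling(keep_fraction * n)` genes with the largest [gene_mad()] of the
#' stored (possibly log2) values are kept. The mean filter always operates
#' on the raw scale: if the dataset is log2-transformed the values are
#' back-transformed (`2^v - 1`) for that step only.
#'
#' @param ds an [expression_dataset()].
#' @param min_mean minimum mean raw expression (default 10).
#' @param keep_fraction fraction of mean-filtered genes to keep by mad,
#'   in (0, 1] (default 0.9).
#' @return the filtered `expression_dataset`; input gene order is preserved.
#' @export
filter_genes <- function(ds, min_mean = 10, keep_fraction = 0.9) {
  stopifnot(inherits(ds, "expression_dataset"),
            keep_fraction > 0, keep_fraction <= 1)
  raw <- if (ds$log_transformed) 2^ds$values - 1 else ds$values
  mean_ok <- rowMeans(raw) >= min_mean
  if (!any(mean_ok)) stop("all genes removed by the mean-expression filter")
  vals <- ds$values[mean_ok, , drop = FALSE]
  n_keep <- ceiling(keep_fraction * nrow(vals))
  mads <- apply(vals, 1L, gene_mad)
  # ties at the keep boundary resolved by gene id so the result is stable
  ord <- order(-mads, rownames(vals), method = "radix")
  keep_ids <- rownames(vals)[sort(ord[seq_len(n_keep)])]
  expression_dataset(ds$values[keep_ids, , drop = FALSE], ds$labels,
                     log_transformed = ds$log_transformed)
}
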