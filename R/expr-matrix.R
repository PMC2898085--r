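#' Expression matrix with sample annotations
#'
#' Container used throughout the pipeline: a probes x samples numeric matrix
#' together with a sample sheet. Values may be raw intensities or log2
#' values; the `log2` flag records which, and downstream steps check it.
#'
#' @param values numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @param samples data.frame with columns `sample_id`, `drug`, `time_h`,
#'   `batch`, `arm`, `replicate`; one row per column of `values`.
#' @param log2 logical; `TRUE` if `values` are on the log2 scale.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples` and `log2`.
#' @export
expr_matrix <- function(values, samples, log2 = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyNA(rownames(values)))
    stopf("probe IDs (rownames) are required")
  if (is.null(colnames(values)) || anyNA(colnames(values)))
    stopf("sample IDs (colnames) are required")
  req <- c("sample_id", "drug", "time_h", "batch", "arm", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stopf("sample sheet lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stopf("sample sheet has %d rows but matrix has %d columns",
          nrow(samples), ncol(values))
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stopf("sample sheet order does not match matrix columns")
  key <- interaction(samples$drug, samples$time_h, samples$arm, samples$replicate)
  if (anyDuplicated(key))
    stopf("(drug, time_h, arm, replicate) combinations must be unique")
  if (!log2 && any(values <= 0))
    stopf("raw intensities must be positive")
  structure(list(values = values, samples = samples, log2 = log2),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2" else "intensity"))
  cat(sprintf("  drugs: %s\n", paste(unique(x$samples$drug), collapse = ", ")))
  cat(sprintf("  times (h): %s | batches: %d | arms: %s\n",
              paste(sort(unique(x$samples$time_h)), collapse = ", "),
              length(unique(x$samples$batch)),
              paste(unique(x$samples$arm), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by probes and/or samples
#'
#' @param x an [expr_matrix()].
#' @param probes probe IDs or indices (default all).
#' @param samples logical/integer vector over samples (default all).
#' @return an `expr_matrix`.
#' @export
subset_expr <- function(x, probes = NULL, samples = NULL) {
  v <- x$values
  s <- x$samples
  if (!is.null(probes)) v <- v[probes, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    s <- s[samples, , drop = FALSE]
  }
  expr_matrix(v, s, log2 = x$log2)
}
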