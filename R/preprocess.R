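#' Quantile normalization
#'
#' Forces every array (column) onto the same empirical distribution: the
#' reference distribution is the row mean of the column-sorted matrix, and
#' each value is replaced by the reference value at its within-column rank.
#' Ties within a column receive the mean of the reference values over the
#' tied rank span.
#'
#' @param x an [expr_matrix()] or a plain numeric matrix.
#' @return same type as the input, quantile-normalized.
#' @export
quantile_normalize <- function(x) {
  m <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (length(m) == 0) stopf("empty matrix")
  if (anyNA(m)) stopf("missing values are not supported")
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    v <- ref
    # average the reference over runs of tied input values
    v <- stats::ave(ref, match(m[o, j], unique(m[o, j])), FUN = mean)
    out[o, j] <- v
  }
  if (inherits(x, "expr_matrix")) {
    x$values <- out
    x
  } else out
}

#' Log2 transform
#'
#' @param x an [expr_matrix()] of raw intensities or a positive numeric
#'   matrix.
#' @return same type as input, elementwise log2; for an `expr_matrix` the
#'   `log2` flag is set.
#' @export
log2_transform <- function(x) {
  m <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (inherits(x, "expr_matrix") && x$log2)
    stopf("matrix is already on the log2 scale")
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("nonpositive value at probe '%s', sample '%s'",
          rownames(m)[bad[1, 1]] %||% bad[1, 1],
          colnames(m)[bad[1, 2]] %||% bad[1, 2])
  out <- log2(m)
  if (inherits(x, "expr_matrix")) {
    x$values <- out
    x$log2 <- TRUE
    x
  } else out
}

#' Z-score standardization to remove hybridization-batch effects
#'
#' Default mode standardizes each probe within each batch (subtract the
#' within-batch mean, divide by the within-batch standard deviation), which
#' removes per-batch location and scale while preserving contrasts between
#' treatment groups represented in every batch. `per_array` standardizes
#' each array over probes instead.
#'
#' @param x an [expr_matrix()] (log2 scale expected).
#' @param mode `"per_probe_within_batch"` (default) or `"per_array"`.
#' @return an `expr_matrix` of z-scores. Probes that are constant within a
#'   batch map to 0 and are counted in a warning.
#' @export
standardize <- function(x, mode = c("per_probe_within_batch", "per_array")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$values
  if (mode == "per_array") {
    mu <- colMeans(m)
    s <- apply(m, 2, stats::sd)
    x$values <- sweep(sweep(m, 2, mu), 2, s, "/")
    return(x)
  }
  batches <- unique(x$samples$batch)
  n_flagged <- 0L
  out <- m
  for (b in batches) {
    cols <- which(x$samples$batch == b)
    if (length(cols) < 2) stopf("batch '%s' has a single sample", b)
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1, stats::sd)
    z <- (sub - mu) / s
    const <- s == 0 | !is.finite(s)
    if (any(const)) {
      z[const, ] <- 0
      n_flagged <- n_flagged + sum(const)
    }
    out[, cols] <- z
  }
  if (n_flagged > 0)
    warnf("%d probe/batch combinations were constant and set to 0", n_flagged)
  x$values <- out
  x$log2 <- TRUE
  x
}

#' qPCR relative abundance (2^-Ct)
#'
#' Abundance from a threshold cycle: `2^-ct`; when a reference gene's cycle
#' is supplied, the reference-normalized ratio `2^-(ct - ct_reference)`.
#'
#' @param ct threshold cycle value(s).
#' @param ct_reference optional reference-gene threshold cycle(s).
#' @return numeric abundance or normalized ratio.
#' @seealso [qpcr_fold_change()]
#' @export
qpcr_relative_abundance <- function(ct, ct_reference = NULL) {
  if (any(!is.finite(ct))) stopf("cycle values must be finite")
  if (is.null(ct_reference)) return(2^(-ct))
  if (any(!is.finite(ct_reference))) stopf("cycle values must be finite")
  2^(-(ct - ct_reference))
}

#' qPCR fold change over control (delta-delta-Ct)
#'
#' @param ct_treated,ct_control threshold cycles of the gene of interest.
#' @param ct_ref_treated,ct_ref_control reference-gene threshold cycles.
#' @return fold change of treated over control, reference-normalized.
#' @export
qpcr_fold_change <- function(ct_treated, ct_control,
                             ct_ref_treated = 0, ct_ref_control = 0) {
  qpcr_relative_abundance(ct_treated, ct_ref_treated) /
    qpcr_relative_abundance(ct_control, ct_ref_control)
}
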