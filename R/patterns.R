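#' Saline-referenced standardized group-mean profiles
#'
#' Builds the genes x (drug x time) profile matrix that the clustering and
#' extension steps operate on: for each probe, the mean standardized value
#' of each drug x time group minus the mean of the time-matched saline
#' group. Naive samples are ignored.
#'
#' @param x a standardized [expr_matrix()] (see [standardize()]).
#' @param probes optional probe subset (IDs); default all probes.
#' @return numeric matrix, rows = probes, columns named `drug_T<h>h`, with
#'   attribute `col_design` (data.frame `drug`, `time_h`).
#' @export
profile_matrix <- function(x, probes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  s <- x$samples
  m <- x$values
  if (!is.null(probes)) m <- m[probes, , drop = FALSE]
  drugs <- setdiff(unique(s$drug), c("saline", "naive"))
  times <- sort(unique(s$time_h[s$drug %in% drugs]))
  cols <- expand.grid(drug = drugs, time_h = times, stringsAsFactors = FALSE)
  cols <- cols[order(match(cols$drug, drugs), cols$time_h), , drop = FALSE]
  prof <- matrix(NA_real_, nrow = nrow(m), ncol = nrow(cols),
                 dimnames = list(rownames(m),
                                 sprintf("%s_T%gh", cols$drug, cols$time_h)))
  for (i in seq_len(nrow(cols))) {
    g <- s$drug == cols$drug[i] & s$time_h == cols$time_h[i] & s$arm != "naive"
    ref <- s$drug == "saline" & s$time_h == cols$time_h[i]
    if (!any(g) || !any(ref))
      stopf("missing group or saline reference for (%s, %g h)",
            cols$drug[i], cols$time_h[i])
    prof[, i] <- rowMeans(m[, g, drop = FALSE]) - rowMeans(m[, ref, drop = FALSE])
  }
  attr(prof, "col_design") <- cols
  prof
}

#' Hierarchical clustering of expression profiles into patterns
#'
#' Agglomerative clustering with Euclidean distance and average linkage;
#' core clusters are the branches below the cut. The cut is specified either
#' by height `h` (the classical choice, scale-dependent) or by a number of
#' clusters `k`. Rows are canonically ordered by gene ID before clustering
#' so the result does not depend on input order; cluster labels `P1, P2, ...`
#' are assigned by decreasing cluster size (ties by first gene ID).
#'
#' @param profiles profile matrix from [profile_matrix()] (genes in rows).
#' @param h cut height (used when `k` is `NULL`).
#' @param k number of clusters (overrides `h` when given).
#' @param min_size drop core clusters smaller than this (singleton debris);
#'   default 1 keeps everything.
#' @return object of class `pattern_set`: list with `hclust`, `h`, `k`,
#'   `core` (named list label -> gene IDs), `centroids` (labels x columns
#'   matrix), `profiles`, and empty `extended` (see [extend_patterns()]).
#' @export
cluster_genes <- function(profiles, h = 13, k = NULL, min_size = 1) {
  if (nrow(profiles) < 2) stopf("need at least 2 genes to cluster")
  if (is.null(k) && h <= 0) stopf("cut height h must be > 0")
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = "average")
  cl <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  groups <- split(names(cl), cl)
  groups <- groups[order(-lengths(groups), vapply(groups, min, ""))]
  groups <- groups[lengths(groups) >= min_size]
  names(groups) <- sprintf("P%d", seq_along(groups))
  centroids <- do.call(rbind, lapply(groups, centroid, profiles = profiles))
  structure(list(hclust = hc, h = if (is.null(k)) h else NA_real_,
                 k = k %||% NA_integer_, core = groups,
                 centroids = centroids, profiles = profiles,
                 extended = list()),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: %d core clusters (cut %s) over %d genes\n",
              length(x$core),
              if (is.na(x$h)) sprintf("k = %d", x$k) else sprintf("h = %g", x$h),
              nrow(x$profiles)))
  for (nm in names(x$core)) {
    ext <- if (nm %in% names(x$extended)) nrow(x$extended[[nm]]) else NA
    cat(sprintf("  %s: %d core%s\n", nm, length(x$core[[nm]]),
                if (!is.na(ext)) sprintf(", %d extended", ext) else ""))
  }
  invisible(x)
}

#' Centroid (columnwise mean profile) of a gene cluster
#'
#' @param genes gene IDs of the cluster members.
#' @param profiles profile matrix containing those genes.
#' @return numeric vector, one value per profile column.
#' @export
centroid <- function(genes, profiles) {
  if (!length(genes)) stopf("empty cluster")
  colMeans(profiles[genes, , drop = FALSE])
}

#' Extend a pattern by correlation with its centroid
#'
#' Computes the Pearson correlation of every gene's profile with the
#' cluster centroid and keeps genes whose two-sided p-value (from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, n =
#' number of profile columns) is below `alpha`.
#'
#' @param centr centroid profile vector.
#' @param profiles profile matrix of all candidate genes.
#' @param alpha inclusion threshold on the correlation p-value.
#' @return data.frame (`gene`, `r`, `p`) sorted by `r` descending.
#' @export
extend_pattern <- function(centr, profiles, alpha = 1e-10) {
  n <- ncol(profiles)
  if (n < 4) stopf("profiles need at least 4 columns")
  sds <- apply(profiles, 1, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    warnf("%d zero-variance profiles excluded from extension", sum(zero))
  keep <- !zero
  r <- as.vector(stats::cor(t(profiles[keep, , drop = FALSE]), centr))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- data.frame(gene = rownames(profiles)[keep], r = r, p = p,
                    stringsAsFactors = FALSE)
  out <- out[out$p < alpha, , drop = FALSE]
  out[order(-out$r), , drop = FALSE]
}

#' Extend every core pattern of a pattern set
#'
#' @param ps a `pattern_set` from [cluster_genes()].
#' @param all_profiles profile matrix over the full candidate universe
#'   (default: the profiles the set was clustered on).
#' @param alpha inclusion threshold, see [extend_pattern()].
#' @return the `pattern_set` with `extended` filled in (label ->
#'   data.frame `gene`, `r`, `p`).
#' @export
extend_patterns <- function(ps, all_profiles = ps$profiles, alpha = 1e-10) {
  ps$extended <- lapply(names(ps$core), function(nm)
    extend_pattern(ps$centroids[nm, ], all_profiles, alpha = alpha))
  names(ps$extended) <- names(ps$core)
  ps
}

#' Overlap between two pattern gene lists
#'
#' Reports the intersection size and the overlap percentage relative to the
#' smaller list; the denominator convention is recorded in the output since
#' either list could serve as reference.
#'
#' @param a,b character vectors of gene IDs (nonempty).
#' @return list with `n_a`, `n_b`, `n_intersect`, `percent` and
#'   `denominator`.
#' @export
overlap_report <- function(a, b) {
  if (!length(a) || !length(b)) stopf("lists must be nonempty")
  k <- length(intersect(a, b))
  denom <- min(length(a), length(b))
  list(n_a = length(a), n_b = length(b), n_intersect = k,
       percent = 100 * k / denom, denominator = "smaller list")
}

#' Export a pattern-set dendrogram as Newick
#'
#' Branch lengths are the merge heights of the average-linkage dendrogram.
#'
#' @param ps a `pattern_set`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_dendrogram <- function(ps, file) {
  ape::write.tree(ape::as.phylo(ps$hclust), file = file)
  invisible(file)
}

#' Pattern membership table
#'
#' Long-format membership of a (possibly extended) pattern set.
#'
#' @param ps a `pattern_set`.
#' @return data.frame (`gene`, `pattern`, `membership` core/extended,
#'   `r`, `p`; core rows carry NA correlation unless extension was run).
#' @export
pattern_membership <- function(ps) {
  rows <- list()
  for (nm in names(ps$core)) {
    core <- data.frame(gene = ps$core[[nm]], pattern = nm,
                       membership = "core", r = NA_real_, p = NA_real_,
                       stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- core
    if (nm %in% names(ps$extended)) {
      ext <- ps$extended[[nm]]
      ext_only <- ext[!ext$gene %in% ps$core[[nm]], , drop = FALSE]
      core$r <- ext$r[match(core$gene, ext$gene)]
      core$p <- ext$p[match(core$gene, ext$gene)]
      rows[[length(rows)]] <- core
      if (nrow(ext_only))
        rows[[length(rows) + 1]] <- data.frame(
          gene = ext_only$gene, pattern = nm, membership = "extended",
          r = ext_only$r, p = ext_only$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
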