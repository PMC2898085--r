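#' Gene-set collection
#'
#' @param name collection name.
#' @param sets named list of character vectors (term -> gene IDs).
#' @param universe background gene IDs; sets are restricted to it.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(name, sets, universe) {
  if (!length(universe)) stopf("empty universe")
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  if (any(lengths(sets) == 0))
    stopf("every set must be nonempty after restriction to the universe")
  structure(list(name = name, sets = sets, universe = unique(universe)),
            class = "gene_set_collection")
}

#' Over-representation of one gene set in a query list
#'
#' One-sided Fisher / hypergeometric upper-tail test of the overlap between
#' a query gene list and a gene set, against a background universe, with
#' fold enrichment `(k/n) / (K/N)` (0 when the overlap k is 0).
#'
#' @param query character vector of gene IDs; genes outside the universe are
#'   dropped with a warning.
#' @param set character vector of gene IDs (the annotation term).
#' @param universe background gene IDs.
#' @return one-row data.frame (`k`, `n`, `K`, `N`, `fold`, `p`).
#' @export
ora <- function(query, set, universe) {
  if (!length(universe)) stopf("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe dropped", length(outside))
    query <- intersect(query, universe)
  }
  set <- intersect(unique(set), universe)
  k <- length(intersect(query, set))
  n <- length(query)
  K <- length(set)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (k == 0) 0 else (k / n) / (K / N)
  data.frame(k = k, n = n, K = K, N = N, fold = fold, p = p)
}

#' Screen a gene-set collection for over-represented terms
#'
#' Tests every set of the collection with [ora()], adjusts p-values across
#' the whole collection by Benjamini-Hochberg, retains terms with at least
#' `min_k` overlapping genes, and sorts by p ascending. The `significant`
#' flag uses the raw p-value against `alpha` (the screening convention for
#' annotation terms), with the BH q reported alongside.
#'
#' @param query character vector of gene IDs.
#' @param collection a [gene_set_collection()].
#' @param min_k minimum overlap to retain a term.
#' @param alpha raw-p significance level for the `significant` flag.
#' @return data.frame (`term`, `k`, `n`, `K`, `N`, `fold`, `p`, `q`,
#'   `significant`) sorted by `p`.
#' @export
screen_collection <- function(query, collection, min_k = 3, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- lapply(names(collection$sets), function(term) {
    res <- suppressWarnings(ora(query, collection$sets[[term]],
                                collection$universe))
    cbind(data.frame(term = term, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_bh(out$p)
  out <- out[out$k >= min_k, , drop = FALSE]
  out$significant <- out$p < alpha
  out[order(out$p), , drop = FALSE]
}

#' Cell-type labels for genes from a fold-enrichment table
#'
#' Labels each gene with every cell type whose expression fold enrichment
#' reaches the lowest threshold, and records the tier: the highest
#' threshold passed (thresholds inclusive).
#'
#' @param genes gene IDs to annotate.
#' @param enrichment_table data.frame (`gene`, `cell_type`, `fold`).
#' @param thresholds increasing fold tiers.
#' @return data.frame (`gene`, `cell_type`, `fold`, `tier`); genes absent
#'   from the table yield no rows.
#' @export
cell_type_annotate <- function(genes, enrichment_table,
                               thresholds = c(2, 5, 20)) {
  thresholds <- sort(thresholds)
  tab <- enrichment_table[enrichment_table$gene %in% genes, , drop = FALSE]
  tab <- tab[tab$fold >= thresholds[1], , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(gene = character(), cell_type = character(),
                      fold = numeric(), tier = numeric()))
  tab$tier <- vapply(tab$fold, function(f) max(thresholds[thresholds <= f]),
                     numeric(1))
  rownames(tab) <- NULL
  tab
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (term, description, tab-separated genes).
#' @return named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[`, "", 2)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
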