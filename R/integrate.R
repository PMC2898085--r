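#' Pattern activation scores from profiles
#'
#' Summarizes the mean standardized expression change of a pattern's genes,
#' either per drug x time point (for correlation with time-resolved
#' phenotypes such as locomotor activity) or summed over all time points per
#' drug (for correlation with one-score-per-drug phenotypes such as
#' conditioned place preference). The summed score per drug equals the sum
#' of its per-time scores.
#'
#' @param profiles profile matrix from [profile_matrix()].
#' @param genes pattern gene IDs.
#' @param mode `"per_time"` or `"summed"`.
#' @return data.frame (`drug`, `time_h`, `activation`) in per_time mode;
#'   (`drug`, `activation`) in summed mode.
#' @export
pattern_activation <- function(profiles, genes, mode = c("per_time", "summed")) {
  mode <- match.arg(mode)
  if (!length(genes)) stopf("pattern is empty")
  design <- attr(profiles, "col_design")
  if (is.null(design)) stopf("profiles lack a col_design attribute")
  v <- colMeans(profiles[genes, , drop = FALSE])
  per_time <- data.frame(drug = design$drug, time_h = design$time_h,
                         activation = unname(v), stringsAsFactors = FALSE)
  if (mode == "per_time") return(per_time)
  agg <- stats::aggregate(activation ~ drug, data = per_time, FUN = sum)
  agg[match(unique(design$drug), agg$drug), , drop = FALSE]
}

#' Correlation with significance
#'
#' @param x,y equal-length numeric vectors (length >= 3, nonzero variance).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n` and `method`. Pearson p-values use the
#'   t approximation; Spearman uses [stats::cor.test()]'s exact/AS89
#'   conventions.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("vectors must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in input vector")
  ct <- stats::cor.test(x, y, method = method, exact = NULL)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), method = method)
}

#' Assemble the regulatory network
#'
#' Builds a typed graph integrating the pipeline's evidence:
#' \itemize{
#'   \item coexpression edges between pattern genes whose profile Pearson
#'     correlation strictly exceeds `r_min`;
#'   \item `tfbs` edges from a transcription factor (matrix id) to every
#'     gene whose promoter carries a conserved binding site;
#'   \item `pharmacological` edges from a signaling element (the inhibitor's
#'     target) to the genes of each pattern whose dissection p-value is
#'     below `p_max`.
#' }
#' Gene nodes carry their pattern label.
#'
#' @param profiles profile matrix (genes in rows).
#' @param patterns a `pattern_set` (core membership supplies node labels
#'   and the gene universe of the graph).
#' @param tfbs_hits optional data.frame from [scan_promoter_set()]
#'   (columns `gene`, `matrix_id`).
#' @param dissection optional list of `dissection_result` objects, each
#'   with an `element` name attached (names of the list are the signaling
#'   elements).
#' @param r_min coexpression threshold (strict).
#' @param p_max pharmacological significance threshold (strict).
#' @return an [igraph::igraph] graph with vertex attributes `type`
#'   (gene / tf / signaling) and `pattern`, and edge attributes `type`,
#'   `r`, `matrix_id`, `p`.
#' @export
build_network <- function(profiles, patterns, tfbs_hits = NULL,
                          dissection = NULL, r_min = 0.6, p_max = 0.1) {
  genes <- unlist(patterns$core, use.names = FALSE)
  genes <- intersect(genes, rownames(profiles))
  lab <- rep(names(patterns$core), lengths(patterns$core))
  names(lab) <- unlist(patterns$core, use.names = FALSE)

  edges <- list()
  if (length(genes) >= 2) {
    cm <- stats::cor(t(profiles[genes, , drop = FALSE]))
    idx <- which(upper.tri(cm) & cm > r_min, arr.ind = TRUE)
    if (nrow(idx))
      edges$coexpr <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                                 type = "coexpression", r = cm[idx],
                                 matrix_id = NA_character_, p = NA_real_,
                                 stringsAsFactors = FALSE)
  }
  tf_nodes <- character()
  if (!is.null(tfbs_hits) && nrow(tfbs_hits)) {
    th <- unique(tfbs_hits[tfbs_hits$gene %in% genes, c("gene", "matrix_id")])
    if (nrow(th)) {
      tf_nodes <- unique(th$matrix_id)
      edges$tfbs <- data.frame(from = th$matrix_id, to = th$gene,
                               type = "tfbs", r = NA_real_,
                               matrix_id = th$matrix_id, p = NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  sig_nodes <- character()
  if (!is.null(dissection) && length(dissection)) {
    for (el in names(dissection)) {
      d <- dissection[[el]]
      if (is.na(d$p) || d$p >= p_max) next
      tgt <- intersect(patterns$core[[d$pattern]], genes)
      if (!length(tgt)) next
      sig_nodes <- union(sig_nodes, el)
      edges[[paste0("pharm_", el)]] <-
        data.frame(from = el, to = tgt, type = "pharmacological",
                   r = NA_real_, matrix_id = NA_character_, p = d$p,
                   stringsAsFactors = FALSE)
    }
  }
  nodes <- data.frame(
    name = c(genes, tf_nodes, sig_nodes),
    type = c(rep("gene", length(genes)), rep("tf", length(tf_nodes)),
             rep("signaling", length(sig_nodes))),
    pattern = c(unname(lab[genes]), rep(NA_character_,
                                        length(tf_nodes) + length(sig_nodes))),
    stringsAsFactors = FALSE)
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), type = character(),
               r = numeric(), matrix_id = character(), p = numeric())
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
}

#' Export a regulatory network
#'
#' GraphML preserves all node and edge attributes (lossless round trip via
#' [igraph::read_graph()]); SIF keeps only `from <edge type> to` triples.
#'
#' @param net an igraph graph from [build_network()].
#' @param file output path.
#' @param format `"graphml"` or `"sif"`.
#' @return `file`, invisibly.
#' @export
export_network <- function(net, file, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, file, format = "graphml")
  } else {
    if (igraph::ecount(net) == 0) {
      writeLines(character(), file)
    } else {
      e <- igraph::as_data_frame(net, what = "edges")
      writeLines(sprintf("%s\t%s\t%s", e$from, e$type, e$to), file)
    }
  }
  invisible(file)
}
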