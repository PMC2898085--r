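#' Position weight matrix constructor
#'
#' @param id matrix identifier (e.g. a JASPAR accession).
#' @param name transcription-factor name.
#' @param counts 4 x L numeric matrix of position base counts, rows
#'   A, C, G, T.
#' @return object of class `pwm`.
#' @export
new_pwm <- function(id, name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stopf("counts must have 4 rows (A, C, G, T)")
  rownames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (any(colSums(counts) == 0)) stopf("every column needs nonzero counts")
  structure(list(id = id, name = name, counts = counts), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), %d bp, consensus %s\n",
              x$id, x$name, ncol(x$counts), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm a `pwm` object.
#' @return character scalar; ties broken by A < C < G < T.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$counts)[apply(pwm$counts, 2, which.max)], collapse = "")
}

#' Log-odds scoring matrix of a PWM
#'
#' Converts position counts to log2 odds against a background base
#' composition, with an additive pseudocount distributed proportionally to
#' the background: `log2(((count + pc * bg) / (colsum + pc)) / bg)`, total
#' pseudocount mass `pc` per column. A fifth row for `N` scores 0 (the
#' background itself).
#'
#' @param pwm a `pwm` object.
#' @param background base frequencies (A, C, G, T), summing to 1.
#' @param pseudocount total pseudocount mass per column.
#' @return 5 x L numeric matrix (rows A, C, G, T, N) with attributes
#'   `min_score` and `max_score` (achievable raw score range).
#' @export
pwm_log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  if (abs(sum(background) - 1) > 1e-8) stopf("background must sum to 1")
  cs <- colSums(pwm$counts)
  freq <- sweep(pwm$counts + outer(background * pseudocount, rep(1, ncol(pwm$counts))),
                2, cs + pseudocount, "/")
  lo <- log2(freq / background)
  lo <- rbind(lo, N = 0)
  attr(lo, "min_score") <- sum(apply(lo[1:4, , drop = FALSE], 2, min))
  attr(lo, "max_score") <- sum(apply(lo[1:4, , drop = FALSE], 2, max))
  lo
}

# sequence string -> integer codes (A=1 C=2 G=3 T=4 N/other=5), gaps dropped
encode_seq <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  v <- v[v != "-"]
  code <- match(v, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

revcomp_codes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[codes])
}

#' Scan a sequence with a PWM
#'
#' Scores every offset (and optionally both strands) with the log-odds
#' matrix; positions containing `N` contribute 0. A hit is an offset whose
#' relative score, `(raw - min) / (max - min)` of the matrix's achievable
#' score range, reaches `min_relative_score`. Coordinates are 0-based
#' half-open over the ungapped input sequence; a minus-strand hit at
#' `start` covers the same footprint as the plus-strand window there.
#'
#' @param seq character scalar over A, C, G, T, N (gaps `-` are dropped).
#' @param pwm a `pwm` object.
#' @param min_relative_score hit threshold in `[0, 1]`.
#' @param both_strands also scan the reverse complement.
#' @param background,pseudocount passed to [pwm_log_odds()].
#' @return data.frame (`start`, `end`, `strand`, `score`, `rel_score`)
#'   sorted by position; empty when the sequence is shorter than the motif.
#' @export
scan_pwm <- function(seq, pwm, min_relative_score = 0.80,
                     both_strands = TRUE,
                     background = rep(0.25, 4), pseudocount = 0.8) {
  codes <- encode_seq(seq)
  lo <- pwm_log_odds(pwm, background, pseudocount)
  L <- ncol(lo)
  n <- length(codes)
  if (n < L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      rel_score = numeric()))
  strands <- if (both_strands) c("+", "-") else "+"
  smin <- attr(lo, "min_score"); smax <- attr(lo, "max_score")
  out <- list()
  for (st in strands) {
    cv <- if (st == "+") codes else revcomp_codes(codes)
    nw <- n - L + 1
    sc <- numeric(nw)
    for (j in seq_len(L)) sc <- sc + lo[cbind(cv[j:(j + nw - 1)], j)]
    rel <- (sc - smin) / (smax - smin)
    hit <- which(rel >= min_relative_score)
    if (length(hit)) {
      start <- if (st == "+") hit - 1L else n - (hit - 1L) - L
      out[[st]] <- data.frame(start = start, end = start + L,
                              strand = st, score = sc[hit],
                              rel_score = rel[hit],
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      rel_score = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Conservation mask from an aligned promoter pair
#'
#' Slides a window of `window_bp` alignment columns along the target /
#' ortholog alignment; a target position is conserved iff at least one
#' covering window has identity (matching non-gap bases / `window_bp`; gaps
#' and `N` count as mismatches) at or above `threshold`. The mask is
#' returned over ungapped target coordinates.
#'
#' @param target,ortholog aligned sequences of equal length (gaps `-`).
#' @param window_bp window size in alignment columns.
#' @param threshold identity threshold.
#' @return logical vector, one element per ungapped target base.
#' @export
conservation_mask <- function(target, ortholog, window_bp = 50,
                              threshold = 0.70) {
  t_v <- strsplit(toupper(target), "")[[1]]
  o_v <- strsplit(toupper(ortholog), "")[[1]]
  if (length(t_v) != length(o_v)) stopf("aligned lengths differ")
  L <- length(t_v)
  if (window_bp > L) stopf("window (%d) longer than alignment (%d)", window_bp, L)
  is_base <- t_v %in% c("A", "C", "G", "T") & o_v %in% c("A", "C", "G", "T")
  m <- as.numeric(is_base & t_v == o_v)
  wsum <- cumsum(m)
  wsum <- c(wsum[window_bp], diff(wsum, lag = window_bp))
  ok_start <- which(wsum / window_bp >= threshold)
  cov <- logical(L)
  if (length(ok_start)) {
    # union of qualifying windows via an increment/decrement sweep
    delta <- integer(L + 1)
    delta[ok_start] <- delta[ok_start] + 1L
    delta[ok_start + window_bp] <- delta[ok_start + window_bp] - 1L
    cov <- cumsum(delta[seq_len(L)]) > 0
  }
  cov[t_v != "-"]
}

#' Conserved TFBS hits in a promoter
#'
#' Scans the ungapped target sequence of an aligned promoter pair and keeps
#' hits whose full footprint lies inside the conservation mask. When more
#' than `cap` conserved hits remain, the top `cap` by raw score are retained
#' (ties broken by position, then strand). Hit coordinates are reported
#' relative to the TSS (0 = TSS, negative upstream, half-open).
#'
#' @param target,ortholog aligned promoter pair (equal length, gaps `-`).
#' @param pwm a `pwm` object.
#' @param tss_offset 1-based ungapped target position of the TSS.
#' @param mask optional precomputed [conservation_mask()]; computed when
#'   `NULL`.
#' @param cap retention cap on conserved hits (per promoter, per matrix).
#' @param ... passed to [scan_pwm()] and, when the mask is computed here,
#'   `window_bp` / `threshold` to [conservation_mask()].
#' @param window_bp,threshold conservation-mask parameters.
#' @param min_relative_score hit threshold, see [scan_pwm()].
#' @return data.frame (`start`, `end`, `strand`, `score`, `rel_score`,
#'   `conserved`) of retained conserved hits, `start`/`end` relative to
#'   the TSS.
#' @export
conserved_hits <- function(target, ortholog, pwm, tss_offset = 5001L,
                           mask = NULL, cap = 50,
                           window_bp = 50, threshold = 0.70,
                           min_relative_score = 0.80, ...) {
  if (is.null(mask))
    mask <- conservation_mask(target, ortholog, window_bp, threshold)
  ungapped <- gsub("-", "", target, fixed = TRUE)
  hits <- scan_pwm(ungapped, pwm, min_relative_score = min_relative_score, ...)
  if (!nrow(hits)) {
    hits$conserved <- logical(0)
    return(hits)
  }
  hits$conserved <- vapply(seq_len(nrow(hits)), function(i)
    all(mask[(hits$start[i] + 1):hits$end[i]]), logical(1))
  hits <- hits[hits$conserved, , drop = FALSE]
  if (nrow(hits) > cap) {
    o <- order(-hits$score, hits$start, hits$strand)
    hits <- hits[sort(o[seq_len(cap)]), , drop = FALSE]
  }
  hits$start <- hits$start - (tss_offset - 1L)
  hits$end <- hits$end - (tss_offset - 1L)
  rownames(hits) <- NULL
  hits
}

#' Conserved-TFBS over-representation between gene lists
#'
#' Computes the per-gene binary presence of at least one conserved hit of a
#' matrix, then contrasts the presence rate of the foreground genes against
#' the background universe: fold = (foreground rate)/(background rate), p =
#' one-sided hypergeometric (Fisher) tail of drawing the observed number of
#' present genes in the foreground.
#'
#' @param foreground,background gene ID vectors; `foreground` must be a
#'   subset of `background`.
#' @param promoters a `promoter_set` (see [simulate_promoters()] or
#'   [read_promoter_fasta()]).
#' @param pwm a `pwm` object.
#' @param ... passed to [conserved_hits()].
#' @return list with `fold` (Inf-flagged when the background rate is 0),
#'   `p`, `k_fg`, `n_fg`, `k_bg`, `n_bg`, and the per-gene `presence`
#'   vector.
#' @export
tfbs_enrichment <- function(foreground, background, promoters, pwm, ...) {
  if (!all(foreground %in% background))
    stopf("foreground must be a subset of the background universe")
  idx <- match(background, promoters$genes)
  if (anyNA(idx)) stopf("promoters missing for %d background gene(s)",
                        sum(is.na(idx)))
  presence <- vapply(idx, function(i) {
    nrow(conserved_hits(promoters$target[i], promoters$ortholog[i], pwm,
                        tss_offset = promoters$tss_offset, ...)) > 0
  }, logical(1))
  names(presence) <- background
  n_fg <- length(foreground); n_bg <- length(background)
  k_fg <- sum(presence[foreground])
  k_bg <- sum(presence)
  rate_bg <- k_bg / n_bg
  fold <- if (rate_bg == 0) Inf else (k_fg / n_fg) / rate_bg
  p <- stats::phyper(k_fg - 1, k_bg, n_bg - k_bg, n_fg, lower.tail = FALSE)
  list(fold = fold, p = p, k_fg = k_fg, n_fg = n_fg,
       k_bg = k_bg, n_bg = n_bg, presence = presence)
}

#' Conserved hits for every promoter of a set
#'
#' @param promoters a `promoter_set`.
#' @param pwm a `pwm` object.
#' @param genes optional subset of promoter genes.
#' @param ... passed to [conserved_hits()].
#' @return data.frame of hits with a leading `gene` column and a
#'   `matrix_id` column.
#' @export
scan_promoter_set <- function(promoters, pwm, genes = NULL, ...) {
  genes <- genes %||% promoters$genes
  idx <- match(genes, promoters$genes)
  if (anyNA(idx)) stopf("unknown gene(s): %s",
                        paste(genes[is.na(idx)], collapse = ", "))
  rows <- lapply(idx, function(i) {
    h <- conserved_hits(promoters$target[i], promoters$ortholog[i], pwm,
                        tss_offset = promoters$tss_offset, ...)
    if (!nrow(h)) return(NULL)
    cbind(data.frame(gene = promoters$genes[i], stringsAsFactors = FALSE),
          h, matrix_id = pwm$id)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(gene = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      rel_score = numeric(), conserved = logical(),
                      matrix_id = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
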