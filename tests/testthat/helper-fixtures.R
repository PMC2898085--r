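# Shared fixtures, all generated in code.

# small design for fast unit tests
small_config <- function(seed = 1L, ...) {
  sim_config(n_probes = 600, pattern_sizes = c(A = 10, B1 = 12, B2 = 8, B3 = 5),
             seed = seed, ...)
}

# a config with no planted effects (null model)
null_config <- function(seed = 1L, n_probes = 5000) {
  sim_config(n_probes = n_probes, seed = seed,
             effect_profile = default_effect_profile()[0, ],
             pattern_sizes = c(A = 0, B1 = 0, B2 = 0, B3 = 0))
}

# hand-built expression matrix: values by (drug, time) cell mean + noise
toy_expr <- function(cell_means, drugs, times, reps = 3, noise_sd = 0,
                     seed = 1, log2 = TRUE) {
  set.seed(seed)
  s <- expand.grid(drug = drugs, time_h = times, replicate = seq_len(reps),
                   stringsAsFactors = FALSE)
  s$arm <- "vehicle"
  s$batch <- 1L
  s$sample_id <- sprintf("%s_%gh_r%d", s$drug, s$time_h, s$replicate)
  s <- s[, c("sample_id", "drug", "time_h", "batch", "arm", "replicate")]
  n_probe <- nrow(cell_means)
  v <- matrix(0, n_probe, nrow(s),
              dimnames = list(rownames(cell_means), s$sample_id))
  for (j in seq_len(nrow(s))) {
    key <- paste(s$drug[j], s$time_h[j])
    v[, j] <- cell_means[, key] + rnorm(n_probe, 0, noise_sd)
  }
  expr_matrix(v, s, log2 = log2)
}

# dissection-experiment matrix with exact arm means on the log2 scale
arm_expr <- function(genes, log2_sv, log2_dv, log2_di, drug = "cocaine",
                     reps = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  s <- expand.grid(drug = c("saline", drug), arm = c("vehicle", "inhibitor"),
                   replicate = seq_len(reps), stringsAsFactors = FALSE)
  s$time_h <- 1
  s$batch <- 1L
  s$sample_id <- sprintf("%s_%s_r%d", s$drug, s$arm, s$replicate)
  s <- s[, c("sample_id", "drug", "time_h", "batch", "arm", "replicate")]
  v <- matrix(0, length(genes), nrow(s), dimnames = list(genes, s$sample_id))
  for (j in seq_len(nrow(s))) {
    mu <- if (s$drug[j] == "saline") log2_sv
    else if (s$arm[j] == "vehicle") log2_dv else log2_di
    v[, j] <- mu + rnorm(length(genes), 0, noise_sd)
  }
  expr_matrix(v, s, log2 = TRUE)
}

# naive O(n^3) average-linkage agglomeration: returns merge heights and the
# membership at a given cut height (independent oracle for hclust)
naive_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) {
        best_h <- h
        best <- c(i, j)
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

naive_cut <- function(d, h) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      hh <- mean(d[clusters[[i]], clusters[[j]]])
      if (hh < best_h) {
        best_h <- hh
        best <- c(i, j)
      }
    }
    if (best_h > h) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  membership
}

# brute-force PWM scoring of every window on both strands
brute_scan <- function(seq, pwm, min_rel = 0.8,
                       background = rep(0.25, 4), pseudocount = 0.8) {
  lo <- pwm_log_odds(pwm, background, pseudocount)
  smin <- attr(lo, "min_score"); smax <- attr(lo, "max_score")
  v <- strsplit(toupper(gsub("-", "", seq)), "")[[1]]
  L <- ncol(lo)
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_word <- function(word) {
    sum(vapply(seq_along(word), function(j) {
      b <- word[j]
      if (!b %in% c("A", "C", "G", "T")) b <- "N"
      lo[b, j]
    }, numeric(1)))
  }
  rows <- list()
  if (n >= L) for (i in 1:(n - L + 1)) {
    word <- v[i:(i + L - 1)]
    for (st in c("+", "-")) {
      w <- if (st == "+") word else rev(unname(comp[word]))
      sc <- score_word(w)
      rel <- (sc - smin) / (smax - smin)
      if (rel >= min_rel)
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1L, end = i - 1L + L, strand = st,
          score = sc, rel_score = rel, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      score = numeric(), rel_score = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random nucleotide string
random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# planted pattern genes of a truth object
planted_genes <- function(truth, pattern = NULL) {
  m <- truth$pattern_membership
  if (is.null(pattern)) names(m)[!is.na(m)]
  else names(m)[!is.na(m) & m == pattern]
}
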