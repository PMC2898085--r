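#' Per-probe two-way (drug x time) ANOVA
#'
#' Fits, for every probe, a two-way ANOVA with factors drug and time (and
#' their interaction by default). Naive samples are excluded from the model;
#' saline must be among the drug levels. Balanced designs (equal replication
#' in every drug x time cell) use classical sums of squares computed in a
#' vectorized pass over all probes; unbalanced designs fall back to
#' per-probe Type II partial sums of squares (requires the `car` package).
#'
#' @param x an [expr_matrix()] (typically standardized log2 values).
#' @param include_interaction include the drug:time interaction term.
#' @return object of class `anova_table`: a data.frame with one row per
#'   probe and columns `F_*`, `p_*`, `p_bonf_*`, `q_bh_*` for the factors
#'   `drug`, `time` and (if included) `interaction`, plus `degenerate`
#'   (zero residual variance; such probes carry p = 1). Degrees of freedom
#'   are attached as attribute `df`.
#' @export
fit_two_way_anova <- function(x, include_interaction = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  keep <- x$samples$arm != "naive" & x$samples$drug != "naive"
  s <- x$samples[keep, , drop = FALSE]
  m <- x$values[, keep, drop = FALSE]
  if (!"saline" %in% s$drug) stopf("design lacks saline samples")
  drug <- factor(s$drug)
  time <- factor(s$time_h)
  tab <- table(drug, time)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stopf("empty design cell(s): %s",
          paste(sprintf("(%s, %s h)", rownames(tab)[empty[, 1]],
                        colnames(tab)[empty[, 2]]), collapse = ", "))
  }
  if (any(tab < 2)) stopf("every (drug, time) cell needs >= 2 replicates")
  balanced <- length(unique(as.vector(tab))) == 1

  res <- if (balanced) {
    anova_balanced(m, drug, time, include_interaction)
  } else {
    anova_type2(m, drug, time, include_interaction)
  }
  factors <- c("drug", "time", if (include_interaction) "interaction")
  for (f in factors) {
    p <- res[[paste0("p_", f)]]
    res[[paste0("p_bonf_", f)]] <- adjust_bonferroni(p)
    res[[paste0("q_bh_", f)]] <- adjust_bh(p)
  }
  class(res) <- c("anova_table", "data.frame")
  res
}

# classical sums of squares, vectorized across probes (balanced designs)
anova_balanced <- function(m, drug, time, include_interaction) {
  a <- nlevels(drug); b <- nlevels(time)
  n <- ncol(m); r <- n / (a * b)
  cell <- interaction(drug, time, drop = TRUE)

  # group-mean operators: samples x groups indicators scaled by group size
  ind <- function(f) {
    M <- stats::model.matrix(~ f - 1)
    sweep(M, 2, colSums(M), "/")
  }
  Mc <- m %*% ind(cell)          # probes x (a*b) cell means
  Md <- m %*% ind(drug)          # probes x a
  Mt <- m %*% ind(time)          # probes x b
  gm <- rowMeans(m)

  ss_drug <- b * r * rowSums((Md - gm)^2)
  ss_time <- a * r * rowSums((Mt - gm)^2)
  # map each cell to its drug/time level for the interaction deviations
  cell_levels <- levels(cell)
  split_lv <- strsplit(cell_levels, ".", fixed = TRUE)
  d_of <- match(vapply(split_lv, `[`, "", 1), levels(drug))
  t_of <- match(vapply(split_lv, `[`, "", 2), levels(time))
  dev <- Mc - Md[, d_of, drop = FALSE] - Mt[, t_of, drop = FALSE] + gm
  ss_int <- r * rowSums(dev^2)
  ss_tot <- rowSums((m - gm)^2)

  if (include_interaction) {
    ss_res <- ss_tot - ss_drug - ss_time - ss_int
    df_res <- n - a * b
  } else {
    ss_res <- ss_tot - ss_drug - ss_time
    df_res <- n - a - b + 1
  }
  ss_res <- pmax(ss_res, 0)
  ms_res <- ss_res / df_res

  degenerate <- ms_res <= .Machine$double.eps * pmax(ss_tot, 1)
  safe_f <- function(ss, df) {
    f <- (ss / df) / ms_res
    f[degenerate] <- 0
    f
  }
  safe_p <- function(f, df) {
    p <- stats::pf(f, df, df_res, lower.tail = FALSE)
    p[degenerate] <- 1
    p
  }
  F_drug <- safe_f(ss_drug, a - 1); F_time <- safe_f(ss_time, b - 1)
  out <- data.frame(probe = rownames(m),
                    F_drug = F_drug, p_drug = safe_p(F_drug, a - 1),
                    F_time = F_time, p_time = safe_p(F_time, b - 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  df <- list(drug = a - 1, time = b - 1, residual = df_res)
  if (include_interaction) {
    F_int <- safe_f(ss_int, (a - 1) * (b - 1))
    out$F_interaction <- F_int
    out$p_interaction <- safe_p(F_int, (a - 1) * (b - 1))
    df$interaction <- (a - 1) * (b - 1)
  }
  out$degenerate <- degenerate
  attr(out, "df") <- df
  attr(out, "cell_means") <- Mc
  attr(out, "cell_levels") <- data.frame(drug = levels(drug)[d_of],
                                         time_h = levels(time)[t_of],
                                         stringsAsFactors = FALSE)
  attr(out, "cell_n") <- r
  attr(out, "ms_res") <- ms_res
  out
}

# Type II partial sums of squares per probe (unbalanced designs)
anova_type2 <- function(m, drug, time, include_interaction) {
  if (!requireNamespace("car", quietly = TRUE))
    stopf("unbalanced designs need the 'car' package for Type II sums of squares")
  fml <- if (include_interaction) y ~ drug * time else y ~ drug + time
  rows <- lapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    fit <- stats::lm(fml, data = data.frame(y = y, drug = drug, time = time))
    a2 <- car::Anova(fit, type = 2)
    degen <- !is.finite(a2[["F value"]][1]) || stats::sd(y) == 0
    grab <- function(term) {
      if (degen) return(c(0, 1))
      c(a2[term, "F value"], a2[term, "Pr(>F)"])
    }
    d <- grab("drug"); t <- grab("time")
    row <- data.frame(probe = rownames(m)[i],
                      F_drug = d[1], p_drug = d[2],
                      F_time = t[1], p_time = t[2],
                      stringsAsFactors = FALSE)
    if (include_interaction) {
      i2 <- grab("drug:time")
      row$F_interaction <- i2[1]; row$p_interaction <- i2[2]
    }
    row$degenerate <- degen
    row
  })
  do.call(rbind, rows)
}

#' Bonferroni adjustment
#'
#' @param p raw p-values.
#' @param m number of tests in the family (default `length(p)`).
#' @return `min(1, p * m)` per element.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  if (m <= 0) stopf("m must be positive")
  if (m < length(p)) stopf("m is smaller than the number of p-values")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Per-test Bonferroni threshold for a family-wise error level
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m <= 0) stopf("m must be positive")
  alpha / m
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p raw p-values (finite).
#' @return BH-adjusted values (q-values) in input order.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p))) stopf("p-values must be finite")
  stats::p.adjust(p, method = "BH")
}

#' True-positive versus FDR-level curve
#'
#' For a grid of FDR levels q (in percent), counts the discoveries
#' `N(q) = #\{BH q-values <= q/100\}` and estimates the true positives among
#' them as `TP(q) = round(N(q) * (1 - q/100))`. The level maximizing TP and
#' the q-range over which TP stays within `band` of that maximum are
#' attached; the plateau height sizes the responsive transcriptome without
#' committing to one significance threshold.
#'
#' @param q_values BH-adjusted p-values (one per probe, in `[0, 1]`).
#' @param grid FDR levels in percent.
#' @param band plateau band as a fraction of the maximum TP.
#' @return object of class `tp_curve`: data.frame (`q_percent`, `N`, `TP`)
#'   with attributes `argmax_q`, `max_tp` and `plateau_range`.
#' @export
tp_curve <- function(q_values,
                     grid = c(0.1, 0.5, 1, 2, 5, 10, 15, 20, 25, 29, 35,
                              40, 50, 60, 70),
                     band = 0.1) {
  if (!length(grid)) stopf("empty grid")
  if (any(q_values < 0 | q_values > 1)) stopf("q-values must lie in [0, 1]")
  grid <- sort(grid)
  N <- vapply(grid, function(q) sum(q_values <= q / 100), numeric(1))
  TP <- round(N * (1 - grid / 100))
  out <- data.frame(q_percent = grid, N = N, TP = TP)
  i_max <- which.max(TP)
  in_band <- TP >= (1 - band) * TP[i_max]
  attr(out, "argmax_q") <- grid[i_max]
  attr(out, "max_tp") <- TP[i_max]
  attr(out, "plateau_range") <- range(grid[in_band])
  # plateau height: the median TP across the grid is robust to single-level
  # sampling excursions and equals the flat level when the curve plateaus
  # (the max is biased upward for a flat curve measured with noise)
  attr(out, "plateau_tp") <- stats::median(TP)
  class(out) <- c("tp_curve", "data.frame")
  out
}

#' Tukey HSD contrasts of each drug against time-matched saline
#'
#' Runs Tukey's honest-significant-difference test over the family of all
#' drug x time cell means of a fitted ANOVA and reports only the contrasts
#' of each drug against saline at the same time point, with the sign of the
#' difference.
#'
#' @param fit an `anova_table` from [fit_two_way_anova()] on a balanced
#'   design.
#' @param alpha significance level.
#' @param probes optional probe subset (IDs).
#' @return data.frame (`probe`, `drug`, `time_h`, `diff`, `p_tukey`,
#'   `significant`, `direction`).
#' @export
tukey_drug_vs_saline <- function(fit, alpha = 0.05, probes = NULL) {
  Mc <- attr(fit, "cell_means")
  lv <- attr(fit, "cell_levels")
  r <- attr(fit, "cell_n")
  ms <- attr(fit, "ms_res")
  dfr <- attr(fit, "df")$residual
  if (is.null(Mc)) stopf("fit carries no cell means (unbalanced fits are not supported)")
  if (!"saline" %in% lv$drug) stopf("design lacks saline cells")
  sel <- seq_len(nrow(Mc))
  if (!is.null(probes)) sel <- match(probes, fit$probe)
  k <- nrow(lv)  # family: all cell means
  out <- list()
  for (t in unique(lv$time_h)) {
    j_sal <- which(lv$drug == "saline" & lv$time_h == t)
    for (d in setdiff(unique(lv$drug), "saline")) {
      j <- which(lv$drug == d & lv$time_h == t)
      diff <- Mc[sel, j] - Mc[sel, j_sal]
      se <- sqrt(ms[sel] / r)
      q_obs <- abs(diff) / se
      p <- stats::ptukey(q_obs, nmeans = k, df = dfr, lower.tail = FALSE)
      p[!is.finite(q_obs)] <- 1
      out[[length(out) + 1]] <- data.frame(
        probe = fit$probe[sel], drug = d, time_h = as.numeric(t),
        diff = diff, p_tukey = p, significant = p < alpha,
        direction = ifelse(diff > 0, "up", ifelse(diff < 0, "down", "none")),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}
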