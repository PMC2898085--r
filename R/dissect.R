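#' Percent inhibition of a drug-induced pattern response
#'
#' The pharmacological-dissection statistic. Per pattern gene, the
#' linear-scale fold change of the drug+vehicle and drug+inhibitor arms over
#' the saline+vehicle baseline is `FC = 2^(mean log2 arm - mean log2
#' saline+vehicle)`. Pattern activations are `a_d = mean(FC_drug) - 1` and
#' `a_i = mean(FC_inh) - 1`, and the percent inhibition is
#' `phi = (1 - a_i / a_d) * 100`: 0% means the inhibitor had no effect,
#' 100% complete block, above 100% reversal below the saline baseline
#' (e.g. 126% = 26% of the induction below basal level), below 0%
#' amplification.
#'
#' @param x an [expr_matrix()] on the log2 scale containing the arms
#'   `drug`+vehicle, saline+vehicle and `drug`+inhibitor (sample-sheet
#'   columns `drug` and `arm`).
#' @param pattern_genes probe IDs of the pattern.
#' @param drug drug label of the experiment.
#' @param pattern label recorded in the result.
#' @param activation_floor below this `|a_d|` the statistic is flagged
#'   unreliable (and `phi` is `NA` when `a_d` is exactly 0).
#' @return object of class `dissection_result`: list with `pattern`,
#'   `drug`, `a_d`, `a_i`, `phi`, `p` (paired test, see
#'   [dissection_test()]), `reliable`, `degenerate` and the per-gene `fc`
#'   data.frame (`gene`, `fc_drug`, `fc_inh`).
#' @export
percent_inhibition <- function(x, pattern_genes, drug,
                               pattern = "pattern", activation_floor = 0.1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!x$log2) stopf("expression must be on the log2 scale")
  if (!length(pattern_genes)) stopf("pattern is empty")
  missing_g <- setdiff(pattern_genes, rownames(x$values))
  if (length(missing_g))
    stopf("pattern gene(s) absent from matrix: %s",
          paste(utils::head(missing_g, 5), collapse = ", "))
  s <- x$samples
  arm_cols <- list(
    sv = s$drug == "saline" & s$arm == "vehicle",
    dv = s$drug == drug & s$arm == "vehicle",
    di = s$drug == drug & s$arm == "inhibitor")
  bad <- names(arm_cols)[vapply(arm_cols, sum, 0L) < 2]
  if (length(bad))
    stopf("arm(s) missing or with < 2 replicates: %s",
          paste(c(sv = "saline+vehicle", dv = "drug+vehicle",
                  di = "drug+inhibitor")[bad], collapse = ", "))
  m <- x$values[pattern_genes, , drop = FALSE]
  mean_arm <- function(sel) rowMeans(m[, sel, drop = FALSE])
  base <- mean_arm(arm_cols$sv)
  fc_drug <- 2^(mean_arm(arm_cols$dv) - base)
  fc_inh <- 2^(mean_arm(arm_cols$di) - base)
  a_d <- mean(fc_drug) - 1
  a_i <- mean(fc_inh) - 1
  phi <- if (a_d == 0) NA_real_ else (1 - a_i / a_d) * 100
  test <- dissection_test(fc_drug, fc_inh)
  structure(list(pattern = pattern, drug = drug,
                 a_d = a_d, a_i = a_i, phi = phi,
                 p = test$p, t = test$t, degenerate = test$degenerate,
                 reliable = is.finite(a_d) && abs(a_d) >= activation_floor,
                 fc = data.frame(gene = pattern_genes, fc_drug = fc_drug,
                                 fc_inh = fc_inh, row.names = NULL)),
            class = "dissection_result")
}

#' @export
print.dissection_result <- function(x, ...) {
  cat(sprintf("dissection of %s (%s): a_d = %.3f, a_i = %.3f, phi = %.1f%% (p = %.3g)%s\n",
              x$pattern, x$drug, x$a_d, x$a_i, x$phi, x$p,
              if (!x$reliable) " [unreliable: weak drug activation]" else ""))
  invisible(x)
}

#' Significance of a pharmacological-dissection effect
#'
#' Paired two-tailed t-test across pattern genes of the drug+inhibitor fold
#' changes against the drug+vehicle fold changes (both versus
#' saline+vehicle).
#'
#' @param fc_drug,fc_inh equal-length per-gene fold-change vectors over the
#'   same pattern genes.
#' @return list with `p`, `t`, `df` and `degenerate` (TRUE with p = 1 when
#'   all differences are zero).
#' @export
dissection_test <- function(fc_drug, fc_inh) {
  if (length(fc_drug) != length(fc_inh)) stopf("vectors must have equal length")
  if (length(fc_drug) < 2) stopf("need at least 2 genes")
  d <- fc_inh - fc_drug
  if (all(d == 0) || stats::sd(d) == 0)
    return(list(p = 1, t = 0, df = length(d) - 1, degenerate = TRUE))
  tt <- stats::t.test(fc_inh, fc_drug, paired = TRUE)
  list(p = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Per-gene regulation arrows between two arms
#'
#' Two-sample two-tailed t-test per gene between two arms; genes with
#' `p < alpha` get an up or down arrow by the sign of the mean difference
#' (arm_a minus arm_b).
#'
#' @param x an [expr_matrix()] on the log2 scale.
#' @param genes probe IDs to test.
#' @param arm_a,arm_b lists selecting the arms, e.g.
#'   `list(drug = "cocaine", arm = "inhibitor")`; each named element is
#'   matched against the sample sheet.
#' @param alpha significance level.
#' @return data.frame (`gene`, `diff`, `p`, `arrow` in up/down/none).
#' @export
per_gene_arrows <- function(x, genes, arm_a, arm_b, alpha = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  sel <- function(spec) {
    keep <- rep(TRUE, nrow(x$samples))
    for (nm in names(spec)) keep <- keep & x$samples[[nm]] == spec[[nm]]
    keep
  }
  ia <- sel(arm_a); ib <- sel(arm_b)
  if (sum(ia) < 2 || sum(ib) < 2) stopf("each arm needs >= 2 replicates")
  m <- x$values[genes, , drop = FALSE]
  res <- t(vapply(seq_along(genes), function(i) {
    a <- m[i, ia]; b <- m[i, ib]
    if (stats::sd(c(a, b)) == 0) return(c(0, 1))
    tt <- stats::t.test(a, b)
    c(mean(a) - mean(b), tt$p.value)
  }, numeric(2)))
  arrow <- ifelse(res[, 2] < alpha,
                  ifelse(res[, 1] > 0, "up", "down"), "none")
  data.frame(gene = genes, diff = res[, 1], p = res[, 2], arrow = arrow,
             stringsAsFactors = FALSE, row.names = NULL)
}
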