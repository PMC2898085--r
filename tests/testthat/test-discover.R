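test_that("two-way ANOVA matches aov on hand-set cell means", {
  drugs <- c("saline", "drugA")
  times <- c(1, 2)
  cm <- rbind(p1 = c(`saline 1` = 0, `drugA 1` = 2, `saline 2` = 0.5,
                     `drugA 2` = 1),
              p2 = c(`saline 1` = 1, `drugA 1` = 1, `saline 2` = 1,
                     `drugA 2` = 1))
  x <- toy_expr(cm, drugs, times, reps = 3, noise_sd = 0.5, seed = 4)
  fit <- fit_two_way_anova(x)
  for (i in 1:2) {
    y <- x$values[i, ]
    a <- anova(aov(y ~ factor(x$samples$drug) * factor(x$samples$time_h)))
    expect_equal(fit$F_drug[i], a$`F value`[1], tolerance = 1e-10)
    expect_equal(fit$F_time[i], a$`F value`[2], tolerance = 1e-10)
    expect_equal(fit$F_interaction[i], a$`F value`[3], tolerance = 1e-10)
    expect_equal(fit$p_drug[i], a$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("constant probes are degenerate with F = 0 and p = 1", {
  cm <- rbind(flat = c(`saline 1` = 3, `d 1` = 3, `saline 2` = 3, `d 2` = 3))
  x <- toy_expr(cm, c("saline", "d"), c(1, 2), reps = 3, noise_sd = 0)
  fit <- fit_two_way_anova(x)
  expect_true(fit$degenerate[1])
  expect_equal(fit$F_drug[1], 0)
  expect_equal(fit$p_drug[1], 1)
})

test_that("empty design cells are reported by name", {
  cfg <- small_config()
  sim <- simulate_expression(cfg)
  x <- log2_transform(sim$matrix)
  drop <- !(x$samples$drug == "cocaine" & x$samples$time_h == 1)
  expect_error(fit_two_way_anova(subset_expr(x, samples = drop)),
               "cocaine, 1 h")
})

test_that("Bonferroni adjustment clamps and reproduces the genome-wide threshold", {
  expect_equal(adjust_bonferroni(0), 0)
  expect_equal(adjust_bonferroni(0.5, m = 3), 1)       # min(1, 1.5)
  expect_equal(adjust_bonferroni(c(0.001, 0.2), m = 10), c(0.01, 1))
  expect_equal(signif(bonferroni_threshold(0.05, 48000), 1), 1e-6)
  expect_error(adjust_bonferroni(0.1, m = 0), "positive")
})

test_that("BH adjustment equals the step-up hand formula", {
  expect_equal(adjust_bh(0.37), 0.37)                   # single p unchanged
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(1, q_sorted)[order(o)]
  }
  for (s in 1:10) {
    set.seed(s)
    p <- runif(sample(5:200, 1))
    q <- adjust_bh(p)
    expect_equal(q, step_up(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))        # monotone in rank
  }
})

test_that("adjusted p-values dominate raw: bonferroni >= BH >= raw", {
  set.seed(3)
  p <- runif(500)^2
  expect_true(all(adjust_bonferroni(p) >= adjust_bh(p) - 1e-12))
  expect_true(all(adjust_bh(p) >= p - 1e-12))
})

test_that("TP curve implements N(q)(1 - q/100) with plateau reporting", {
  q <- c(rep(0, 10), rep(0.2, 20), rep(0.9, 70))
  curve <- tp_curve(q, grid = c(0, 29, 50, 95))
  expect_equal(curve$TP[curve$q_percent == 0], 10)       # TP(0) = N(0)
  expect_equal(curve$N[curve$q_percent == 29], 30)
  expect_equal(curve$TP[curve$q_percent == 29], round(30 * 0.71))
  # the printed-arithmetic case: 100 discoveries at 29% -> 71 true positives
  q100 <- rep(0.29, 100)
  expect_equal(tp_curve(q100, grid = 29)$TP, 71)
  expect_true(all(diff(curve$N) >= 0))
  expect_error(tp_curve(q, grid = numeric(0)), "empty grid")
})

test_that("Tukey p-values match TukeyHSD and the studentized-range lookup", {
  cm <- rbind(p1 = c(`saline 1` = 0, `d1 1` = 1.8, `d2 1` = 0.4,
                     `saline 2` = 0.2, `d1 2` = 0.5, `d2 2` = 1.1))
  x <- toy_expr(cm, c("saline", "d1", "d2"), c(1, 2), reps = 4,
                noise_sd = 0.6, seed = 8)
  fit <- fit_two_way_anova(x)
  tk <- tukey_drug_vs_saline(fit)
  # oracle: Tukey HSD over the 6 drug x time cell means
  y <- x$values[1, ]
  cell <- interaction(factor(x$samples$drug), factor(x$samples$time_h))
  th <- TukeyHSD(aov(y ~ cell))$cell
  for (i in seq_len(nrow(tk))) {
    nm <- grep(sprintf("^%s\\.%g-saline\\.%g$|^saline\\.%g-%s\\.%g$",
                       tk$drug[i], tk$time_h[i], tk$time_h[i],
                       tk$time_h[i], tk$drug[i], tk$time_h[i]),
               rownames(th))
    expect_equal(tk$p_tukey[i], unname(th[nm, "p adj"]), tolerance = 1e-8)
  }
  # the significance boundary is the studentized-range critical difference
  mse <- attr(fit, "ms_res")[1]
  dfr <- attr(fit, "df")$residual
  crit <- qtukey(0.95, nmeans = 6, df = dfr) * sqrt(mse / 4)
  expect_equal(tk$significant, abs(tk$diff) > crit)
})

test_that("identical group means yield no significant Tukey contrasts", {
  cm <- rbind(p1 = c(`saline 1` = 2, `d1 1` = 2, `d2 1` = 2,
                     `saline 2` = 2, `d1 2` = 2, `d2 2` = 2))
  x <- toy_expr(cm, c("saline", "d1", "d2"), c(1, 2), reps = 4,
                noise_sd = 0.3, seed = 12)
  fit <- fit_two_way_anova(x)
  tk <- tukey_drug_vs_saline(fit, alpha = 0.001)
  expect_false(any(tk$significant))
})

test_that("planted induction is called significant against time-matched saline", {
  hits <- vapply(1:10, function(s) {
    cfg <- small_config(seed = s)
    sim <- simulate_expression(cfg)
    norm <- standardize(log2_transform(quantile_normalize(sim$matrix)))
    fit <- fit_two_way_anova(norm)
    genes <- planted_genes(sim$truth, "A")
    tk <- tukey_drug_vs_saline(fit, probes = genes)
    sel <- tk$drug == "cocaine" & tk$time_h == 1
    mean(tk$significant[sel] & tk$direction[sel] == "up")
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})
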