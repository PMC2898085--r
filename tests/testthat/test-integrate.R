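profile_fixture <- function(values, drugs = c("d1", "d2"), times = c(1, 2)) {
  design <- expand.grid(drug = drugs, time_h = times, stringsAsFactors = FALSE)
  design <- design[order(match(design$drug, drugs), design$time_h), ]
  colnames(values) <- sprintf("%s_T%gh", design$drug, design$time_h)
  attr(values, "col_design") <- design
  values
}

test_that("pattern activation is additive over time points", {
  v <- profile_fixture(rbind(g1 = c(1, 2, 3, 4), g2 = c(3, 4, 5, 6)))
  per_time <- pattern_activation(v, c("g1", "g2"), mode = "per_time")
  summed <- pattern_activation(v, c("g1", "g2"), mode = "summed")
  for (d in c("d1", "d2"))
    expect_equal(summed$activation[summed$drug == d],
                 sum(per_time$activation[per_time$drug == d]))
  # all-zero profiles give zero activation
  z <- profile_fixture(rbind(g1 = rep(0, 4), g2 = rep(0, 4)))
  expect_true(all(pattern_activation(z, c("g1", "g2"))$activation == 0))
})

test_that("planted pattern-A activation separates psychostimulants from ethanol", {
  cfg <- small_config(seed = 16)
  sim <- simulate_expression(cfg)
  norm <- standardize(log2_transform(quantile_normalize(sim$matrix)))
  profiles <- profile_matrix(norm)
  act <- pattern_activation(profiles, planted_genes(sim$truth, "A"),
                            mode = "per_time")
  a1 <- function(d) act$activation[act$drug == d & act$time_h == 1]
  expect_gt(a1("cocaine"), a1("ethanol"))
})

test_that("correlate matches closed-form Pearson and rank-based Spearman", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  sp <- correlate(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "spearman")
  expect_equal(sp$r, cor(rank(c(1, 2, 3, 4)), rank(c(1, 3, 2, 4))))
  expect_equal(sp$r, 0.8)
  expect_error(correlate(x, rep(1, 5)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("simulated phenotype link is recovered by the correlation step", {
  cfg <- small_config(seed = 18)
  sim <- simulate_expression(cfg)
  ok <- vapply(1:40, function(s) {
    b <- simulate_behavior(sim$truth, cfg, seed = 3000 + s)
    correlate(b$truth_activation$cpp, b$cpp$score)$r >= 0.6
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # with zero noise the planted slope sign is always recovered
  tr <- sim$truth
  tr$phenotype_link$cpp$noise_sd <- 1e-9
  b0 <- simulate_behavior(tr, cfg)
  expect_gt(correlate(b0$truth_activation$cpp, b0$cpp$score)$r, 0.999)
})

test_that("network edges obey the strict correlation threshold", {
  # two probes correlated just below / above the threshold
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  make_pair <- function(r_target) {
    y <- r_target * scale(base)[, 1] +
      sqrt(1 - r_target^2) * scale(resid(lm(rnorm(8) ~ base)))[, 1]
    rbind(a = base, b = y)
  }
  set.seed(20)
  design <- expand.grid(drug = c("d1", "d2"), time_h = c(1, 2, 3, 4),
                        stringsAsFactors = FALSE)
  ps <- list(core = list(P1 = c("a", "b")))
  for (r_t in c(0.59, 0.61)) {
    prof <- make_pair(r_t)
    attr(prof, "col_design") <- design
    expect_equal(abs(cor(prof["a", ], prof["b", ]) - r_t) < 1e-8, TRUE)
    net <- build_network(prof, ps)
    expect_equal(igraph::ecount(net), as.integer(r_t > 0.6))
  }
})

test_that("network assembly equals brute-force thresholding on a toy", {
  set.seed(23)
  prof <- matrix(rnorm(5 * 8), nrow = 5,
                 dimnames = list(letters[1:5], NULL))
  attr(prof, "col_design") <- expand.grid(drug = c("x", "y"),
                                          time_h = c(1, 2, 3, 4))
  ps <- list(core = list(P1 = letters[1:3], P2 = letters[4:5]))
  net <- build_network(prof, ps, r_min = 0.3)
  cm <- cor(t(prof))
  want <- sum(cm[upper.tri(cm)] > 0.3)
  expect_equal(igraph::ecount(net), want)
  # raising r_min never adds edges
  for (r2 in c(0.5, 0.7, 0.9))
    expect_lte(igraph::ecount(build_network(prof, ps, r_min = r2)),
               igraph::ecount(net))
  # pattern labels ride on the vertices
  expect_equal(igraph::V(net)$pattern[match("a", igraph::V(net)$name)], "P1")
})

test_that("tfbs and pharmacological evidence become typed edges", {
  prof <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  prof <- prof + matrix(rnorm(12, 0, 0.01), nrow = 3)
  attr(prof, "col_design") <- expand.grid(drug = c("x", "y"),
                                          time_h = c(1, 2))
  ps <- list(core = list(P1 = c("a", "b", "c")))
  hits <- data.frame(gene = c("a", "b"), matrix_id = "SYN0001")
  diss <- list(D1R = structure(list(pattern = "P1", p = 0.01),
                               class = "dissection_result"),
               weak = structure(list(pattern = "P1", p = 0.5),
                                class = "dissection_result"))
  net <- build_network(prof, ps, tfbs_hits = hits, dissection = diss)
  types <- igraph::E(net)$type
  expect_equal(sum(types == "tfbs"), 2)
  expect_equal(sum(types == "pharmacological"), 3)  # p = 0.5 filtered out
  expect_false("weak" %in% igraph::V(net)$name)
  # empty evidence yields a pure coexpression graph
  pure <- build_network(prof, ps)
  expect_true(all(igraph::E(pure)$type == "coexpression"))
})

test_that("graphml round-trips losslessly and sif keeps the triples", {
  set.seed(2)
  prof <- matrix(rnorm(4 * 8), nrow = 4, dimnames = list(letters[1:4], NULL))
  attr(prof, "col_design") <- expand.grid(drug = c("x", "y"),
                                          time_h = c(1, 2, 3, 4))
  ps <- list(core = list(P1 = letters[1:4]))
  net <- build_network(prof, ps, r_min = -1.1)
  f <- tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net))
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_equal(sort(igraph::E(back)$r), sort(igraph::E(net)$r))
  fs <- tempfile(fileext = ".sif")
  export_network(net, fs, "sif")
  expect_equal(length(readLines(fs)), igraph::ecount(net))
  # empty network still writes valid documents
  empty <- build_network(prof[0, , drop = FALSE], list(core = list()))
  export_network(empty, f, "graphml")
  expect_silent(igraph::read_graph(f, format = "graphml"))
})
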