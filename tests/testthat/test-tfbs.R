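test_that("conservation mask matches direct window enumeration", {
  # identical sequences: fully conserved
  s <- random_seq(200, seed = 1)
  expect_true(all(conservation_mask(s, s)))
  # fully gapped ortholog: nothing conserved
  expect_false(any(conservation_mask(s, paste(rep("-", 200), collapse = ""))))
  # one 60-bp block at ~80% identity inside low-identity flanks
  set.seed(4)
  tgt <- strsplit(random_seq(300), "")[[1]]
  oth <- strsplit(random_seq(300), "")[[1]]          # ~25% chance identity
  block <- 121:180
  oth[block] <- tgt[block]
  flip <- sample(block, 12)                          # 48/60 = 80% identity
  oth[flip] <- chartr("ACGT", "TACG", tgt[flip])     # guaranteed mismatch
  mask <- conservation_mask(paste(tgt, collapse = ""),
                            paste(oth, collapse = ""),
                            window_bp = 50, threshold = 0.70)
  # oracle: enumerate all windows, mark covered positions
  m <- as.numeric(tgt == oth)
  expected <- logical(300)
  for (st in 1:(300 - 50 + 1))
    if (mean(m[st:(st + 49)]) >= 0.70)
      expected[st:(st + 49)] <- TRUE
  expect_equal(mask, expected)
  expect_true(any(mask[block]))
  expect_error(conservation_mask("ACGT", "ACGT", window_bp = 50), "longer")
})

test_that("PWM scanning equals brute-force window scoring", {
  pwm <- synthetic_pwm()
  # shorter than the motif: no hits
  expect_equal(nrow(scan_pwm("ACGTACGT", pwm)), 0)
  # the consensus scores relative 1.0 at its planted offset
  cons <- pwm_consensus(pwm)
  seq1 <- paste0(random_seq(20, seed = 3), cons, random_seq(20))
  hits <- scan_pwm(seq1, pwm)
  expect_true(any(hits$start == 20 & abs(hits$rel_score - 1) < 1e-12))
  # exhaustive equivalence on 200-bp random sequences, low cutoff
  for (s in 1:3) {
    seq200 <- random_seq(200, seed = 100 + s)
    got <- scan_pwm(seq200, pwm, min_relative_score = 0.51)
    want <- brute_scan(seq200, pwm, min_rel = 0.51)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # N bases score as background (0 log-odds contribution)
  lo <- pwm_log_odds(pwm)
  seqN <- paste0(substr(cons, 1, 13), "N")
  hN <- scan_pwm(seqN, pwm, min_relative_score = 0, both_strands = FALSE)
  expect_equal(hN$score[1],
               attr(lo, "max_score") - max(lo[1:4, 14]), tolerance = 1e-10)
})

test_that("scanning is strand-symmetric", {
  pwm <- synthetic_pwm()
  seq1 <- random_seq(150, seed = 9)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq1, "")[[1]]),
                                     collapse = ""))
  h1 <- scan_pwm(seq1, pwm, min_relative_score = 0.4)
  h2 <- scan_pwm(rc, pwm, min_relative_score = 0.4)
  # hits mirror: a + hit at s in seq1 is a - hit at n - s - L in the revcomp
  n <- 150; L <- ncol(pwm$counts)
  mirrored <- data.frame(start = n - h1$start - L,
                         strand = ifelse(h1$strand == "+", "-", "+"),
                         score = h1$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(h2$start, mirrored$start)
  expect_equal(h2$strand, mirrored$strand)
  expect_equal(h2$score, mirrored$score, tolerance = 1e-12)
})

test_that("reported hits respect the relative-score bounds", {
  pwm <- synthetic_pwm()
  hits <- scan_pwm(random_seq(3000, seed = 13), pwm, min_relative_score = 0.55)
  expect_true(all(hits$rel_score >= 0.55 & hits$rel_score <= 1))
})

test_that("conserved hits are capped at 50 per promoter and matrix", {
  pwm <- synthetic_pwm()
  cons <- pwm_consensus(pwm)
  # 60 planted consensus sites, fully conserved promoter
  spacer <- "AAAAAA"
  tgt <- paste0(paste(rep(paste0(cons, spacer), 60), collapse = ""),
                random_seq(100, seed = 2))
  hits <- conserved_hits(tgt, tgt, pwm, tss_offset = 1L, cap = 50)
  planted <- hits[abs(hits$rel_score - 1) < 1e-12, ]
  expect_equal(nrow(planted), 50)
  # retention equals brute-force filter + sort + truncate
  all_hits <- conserved_hits(tgt, tgt, pwm, tss_offset = 1L, cap = Inf)
  o <- order(-all_hits$score, all_hits$start, all_hits$strand)
  want <- all_hits[sort(o[1:50]), ]
  rownames(want) <- NULL
  expect_equal(hits, want)
  # an all-false mask yields nothing
  none <- conserved_hits(tgt, paste(rep("-", nchar(tgt)), collapse = ""),
                         pwm, tss_offset = 1L)
  expect_equal(nrow(none), 0)
})

test_that("hit coordinates are TSS-relative over the ungapped target", {
  pwm <- synthetic_pwm()
  cons <- pwm_consensus(pwm)
  tgt <- paste0(random_seq(30, seed = 5), cons, random_seq(30))
  h <- conserved_hits(tgt, tgt, pwm, tss_offset = 11L,
                      min_relative_score = 0.99)
  expect_true(any(h$start == 30 - 10))  # 0-based 30 in sequence, TSS at 10
})

test_that("tfbs enrichment reproduces fold and hypergeometric arithmetic", {
  # synthetic presence: 8/10 foreground vs 20/100 background overall
  pwm <- synthetic_pwm()
  cons <- pwm_consensus(pwm)
  with_site <- function() paste0(random_seq(40), cons, random_seq(40))
  without <- function() random_seq(94)
  set.seed(8)
  genes <- sprintf("g%03d", 1:100)
  present <- c(rep(TRUE, 8), rep(FALSE, 2),            # foreground 8/10
               rep(TRUE, 12), rep(FALSE, 78))          # rest of background
  seqs <- vapply(present, function(p) if (p) with_site() else without(),
                 character(1))
  prom <- structure(list(genes = genes, target = seqs, ortholog = seqs,
                         tss_offset = 1L), class = "promoter_set")
  enr <- tfbs_enrichment(genes[1:10], genes, prom, pwm)
  expect_equal(enr$k_fg, 8)
  expect_equal(enr$k_bg, 20)
  expect_equal(enr$fold, (8 / 10) / (20 / 100))
  expect_equal(enr$p, phyper(7, 20, 80, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  # equal presence rates give fold 1
  enr_all <- tfbs_enrichment(genes[11:20], genes[11:22], prom, pwm)
  expect_equal(enr_all$fold, 1)
})

test_that("label-shuffled foregrounds are calibrated", {
  cfg <- small_config(seed = 19)
  sim <- simulate_expression(cfg)
  prom <- simulate_promoters(cfg, sim$truth, n_background = 120)
  pwm <- prom$pwm
  # presence computed once; shuffle foreground labels
  enr0 <- tfbs_enrichment(prom$genes[prom$foreground], prom$genes, prom, pwm)
  presence <- enr0$presence
  n_fg <- sum(prom$foreground)
  set.seed(99)
  p_shuffle <- vapply(1:100, function(i) {
    fg <- sample(prom$genes, n_fg)
    k <- sum(presence[fg])
    phyper(k - 1, enr0$k_bg, enr0$n_bg - enr0$k_bg, n_fg, lower.tail = FALSE)
  }, numeric(1))
  expect_lte(mean(p_shuffle < 0.05), 0.07)
})

test_that("JASPAR text matrices round-trip", {
  pwms <- list(synthetic_pwm(), synthetic_pwm("SYN0002", "OTHER"))
  f <- tempfile(fileext = ".jaspar")
  write_jaspar(pwms, f)
  back <- read_jaspar(f)
  expect_equal(names(back), c("SYN0001", "SYN0002"))
  expect_equal(unname(back$SYN0001$counts), unname(pwms[[1]]$counts))
  expect_equal(back$SYN0002$name, "OTHER")
})
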