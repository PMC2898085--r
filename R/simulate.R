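#' Default log2 effect-size table for the planted expression patterns
#'
#' Encodes the timing of the four drug-induced transcriptional modules:
#' pattern A (immediate early genes) peaks 1-2 h after psychostimulants
#' (cocaine, methamphetamine) and 4 h after opioids (morphine, heroin);
#' B1 is induced 1-2 h after every drug, to a degree that differs between
#' drugs; B2 2-4 h after ethanol, morphine, heroin and methamphetamine;
#' B3 at 4 h after ethanol, morphine and heroin. Effect sizes are log2
#' fold changes over time-matched saline, capped at 1.5.
#'
#' @return data.frame with columns `pattern`, `drug`, `time_h`, `log2fc`.
#' @export
default_effect_profile <- function() {
  e <- rbind(
    # pattern A: fast psychostimulant response, delayed opioid response
    c("A", "cocaine",         1, 1.5), c("A", "cocaine",         2, 1.3),
    c("A", "methamphetamine", 1, 1.5), c("A", "methamphetamine", 2, 1.2),
    c("A", "morphine",        4, 1.4), c("A", "heroin",          4, 1.3),
    # pattern B1: all drugs at 1-2 h, graded magnitude
    c("B1", "cocaine",         1, 1.2), c("B1", "cocaine",         2, 1.4),
    c("B1", "methamphetamine", 1, 1.1), c("B1", "methamphetamine", 2, 1.3),
    c("B1", "morphine",        1, 1.3), c("B1", "morphine",        2, 1.5),
    c("B1", "heroin",          1, 1.2), c("B1", "heroin",          2, 1.5),
    c("B1", "ethanol",         1, 0.9), c("B1", "ethanol",         2, 1.1),
    c("B1", "nicotine",        1, 0.5), c("B1", "nicotine",        2, 0.7),
    # pattern B2: 2-4 h, no cocaine/nicotine
    c("B2", "ethanol",         2, 1.2), c("B2", "ethanol",         4, 1.4),
    c("B2", "morphine",        2, 1.2), c("B2", "morphine",        4, 1.5),
    c("B2", "heroin",          2, 1.1), c("B2", "heroin",          4, 1.4),
    c("B2", "methamphetamine", 2, 0.9), c("B2", "methamphetamine", 4, 1.1),
    # pattern B3: late wave, 4 h only
    c("B3", "ethanol",  4, 1.4), c("B3", "morphine", 4, 1.5),
    c("B3", "heroin",   4, 1.4)
  )
  data.frame(pattern = e[, 1], drug = e[, 2],
             time_h = as.numeric(e[, 3]), log2fc = as.numeric(e[, 4]),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Describes the design of the emulated expression-profiling experiment:
#' six drugs of abuse plus saline and naive controls, four post-injection
#' time points, three replicate arrays per group split over two
#' hybridization batches, and ~100-130 drug-responsive probes organized
#' into four temporal patterns against a large diurnal background.
#'
#' @param n_probes number of probes on the simulated array.
#' @param drugs drug labels (controls `saline` and `naive` are added
#'   automatically to the design).
#' @param time_points post-injection sampling times in hours.
#' @param replicates_per_group replicate arrays per (drug, time) group.
#' @param batches number of hybridization batches; groups are split evenly
#'   across batches.
#' @param pattern_sizes named integer vector: planted probes per pattern.
#' @param effect_profile data.frame (`pattern`, `drug`, `time_h`, `log2fc`)
#'   of planted log2 effects versus time-matched saline; see
#'   [default_effect_profile()].
#' @param diurnal_fraction proportion of probes carrying a diurnal
#'   (24 h sinusoidal) time trend.
#' @param diurnal_amplitude_range log2 amplitude range of diurnal trends.
#' @param noise_sd log2-scale residual standard deviation per array.
#' @param batch_shift_sd standard deviation of per-probe log2 shifts
#'   between hybridization batches.
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution.
#' @param seed integer seed; identical (config, seed) reproduces all
#'   outputs exactly.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_probes = 5000,
                       drugs = c("cocaine", "methamphetamine", "morphine",
                                 "heroin", "ethanol", "nicotine"),
                       time_points = c(1, 2, 4, 8),
                       replicates_per_group = 3,
                       batches = 2,
                       pattern_sizes = c(A = 38, B1 = 45, B2 = 31, B3 = 18),
                       effect_profile = default_effect_profile(),
                       diurnal_fraction = 0.3,
                       diurnal_amplitude_range = c(0.3, 1.0),
                       noise_sd = 0.2,
                       batch_shift_sd = 0.1,
                       baseline_mean = 7,
                       baseline_sd = 1.5,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), drugs = drugs,
              time_points = time_points,
              replicates_per_group = as.integer(replicates_per_group),
              batches = as.integer(batches),
              pattern_sizes = pattern_sizes,
              effect_profile = effect_profile,
              diurnal_fraction = diurnal_fraction,
              diurnal_amplitude_range = diurnal_amplitude_range,
              noise_sd = noise_sd, batch_shift_sd = batch_shift_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_probes < 1 || cfg$replicates_per_group < 1 || cfg$batches < 1)
    stopf("all counts must be positive")
  if (any(cfg$pattern_sizes < 0)) stopf("pattern sizes must be nonnegative")
  if (sum(cfg$pattern_sizes) > cfg$n_probes)
    stopf("pattern sizes (%d) exceed n_probes (%d)",
          sum(cfg$pattern_sizes), cfg$n_probes)
  if (cfg$noise_sd <= 0) stopf("noise_sd must be > 0")
  ep <- cfg$effect_profile
  bad <- setdiff(unique(ep$drug), cfg$drugs)
  if (length(bad))
    stopf("effect_profile refers to unknown drug label(s): %s",
          paste(bad, collapse = ", "))
  bad_t <- setdiff(unique(ep$time_h), cfg$time_points)
  if (length(bad_t))
    stopf("effect_profile refers to time point(s) not in the design: %s",
          paste(bad_t, collapse = ", "))
  invisible(cfg)
}

# (pattern, drug, time) -> log2 effect, 0 where unplanted
effect_lookup <- function(effect_profile) {
  key <- paste(effect_profile$pattern, effect_profile$drug,
               effect_profile$time_h, sep = "\r")
  stats::setNames(effect_profile$log2fc, key)
}

#' Simulate a drug x time expression experiment with planted ground truth
#'
#' Generates a raw-intensity probes x samples matrix following the design in
#' the supplied configuration: per-probe log2 baseline, planted pattern
#' effects versus time-matched saline, a sinusoidal 24 h diurnal trend on a
#' fraction of probes (affecting all treatment groups equally, including
#' naive and saline), per-probe hybridization-batch shifts, and Gaussian
#' log2 noise. Returned intensities are `2^log2`.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{matrix}{an [expr_matrix()] of raw intensities,}
#'     \item{truth}{a `ground_truth` list: `pattern_membership` (named
#'       character vector, `NA` for background probes), `diurnal_probes`,
#'       the effect profile, default planted-motif and phenotype-link
#'       parameters used by the companion generators.}
#'   }
#' @export
simulate_expression <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_probes
    probes <- sprintf("probe_%05d", seq_len(n))

    # planted pattern membership
    membership <- rep(NA_character_, n)
    names(membership) <- probes
    idx <- sample.int(n, sum(config$pattern_sizes))
    membership[idx] <- rep(names(config$pattern_sizes), config$pattern_sizes)

    # diurnal probes: random subset, may overlap with pattern probes
    n_diurnal <- floor(config$diurnal_fraction * n)
    diurnal_idx <- sample.int(n, n_diurnal)
    amp <- stats::runif(n_diurnal, config$diurnal_amplitude_range[1],
                        config$diurnal_amplitude_range[2])
    phase <- stats::runif(n_diurnal, 0, 24)

    samples <- build_sample_sheet(config)
    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    batch_shift <- matrix(stats::rnorm(n * config$batches, 0, config$batch_shift_sd),
                          nrow = n)

    eff <- effect_lookup(config$effect_profile)
    m <- matrix(baseline, nrow = n, ncol = nrow(samples))
    rownames(m) <- probes
    colnames(m) <- samples$sample_id
    for (j in seq_len(nrow(samples))) {
      dj <- samples$drug[j]; tj <- samples$time_h[j]
      if (!dj %in% c("saline", "naive")) {
        key <- paste(membership[idx], dj, tj, sep = "\r")
        e <- eff[key]
        e[is.na(e)] <- 0
        m[idx, j] <- m[idx, j] + e
      }
      m[diurnal_idx, j] <- m[diurnal_idx, j] +
        amp * sin(2 * pi * (tj + phase) / 24)
      m[, j] <- m[, j] + batch_shift[, samples$batch[j]]
    }
    m <- m + matrix(stats::rnorm(length(m), 0, config$noise_sd), nrow = n)

    truth <- structure(list(
      pattern_membership = membership,
      diurnal_probes = probes[diurnal_idx],
      effect_profile = config$effect_profile,
      planted_motifs = data.frame(pattern = "A", pwm_id = "SYN0001",
                                  fg_rate = 0.6, bg_rate = 0.1,
                                  stringsAsFactors = FALSE),
      planted_inhibition = list(),
      phenotype_link = list(
        cpp = list(pattern = "B1", slope = 1, noise_sd = 0.15),
        locomotion = list(pattern = "A", slope = 1, noise_sd = 0.15)
      )
    ), class = "ground_truth")

    list(matrix = expr_matrix(2^m, samples, log2 = FALSE), truth = truth)
  })
}

build_sample_sheet <- function(config) {
  groups <- expand.grid(drug = c(config$drugs, "saline", "naive"),
                        time_h = config$time_points,
                        replicate = seq_len(config$replicates_per_group),
                        stringsAsFactors = FALSE)
  groups$arm <- ifelse(groups$drug == "naive", "naive", "vehicle")
  # every group is represented in every batch, and the odd replicate
  # alternates across groups so total batch sizes stay balanced
  grp_id <- as.integer(interaction(groups$drug, groups$time_h, drop = TRUE))
  groups$batch <- ((groups$replicate - 1L + grp_id) %% config$batches) + 1L
  groups$sample_id <- sprintf("%s_%gh_r%d", groups$drug, groups$time_h,
                              groups$replicate)
  groups[, c("sample_id", "drug", "time_h", "batch", "arm", "replicate")]
}

#' Simulate aligned promoter pairs with planted, conserved motif instances
#'
#' For each gene, draws a target promoter of 6001 bp (positions -5000..+1000
#' around the TSS) and an aligned ortholog copy. A set of conserved windows
#' is designated per promoter; outside them the ortholog is mutated (and
#' occasionally gapped) at a high rate, inside them at a low rate, so that
#' a sliding-window identity mask recovers the windows. Consensus instances
#' of the planted motif are inserted into a conserved window of both
#' sequences with probability `fg_rate` for genes of the motif's pattern and
#' `bg_rate` otherwise (rates from `truth$planted_motifs`).
#'
#' @param config a [sim_config()] (supplies the seed).
#' @param truth `ground_truth` from [simulate_expression()].
#' @param n_background number of non-pattern genes given promoters, in
#'   addition to all planted pattern genes.
#' @param mutation_rate per-base ortholog substitution rate outside
#'   conserved windows.
#' @param conserved_mutation_rate substitution rate inside conserved windows.
#' @param gap_rate per-base deletion ('-') rate in the ortholog outside
#'   conserved windows.
#' @param n_windows,window_len number and length (bp) of conserved windows.
#' @param pwm optional PWM to plant; default [synthetic_pwm()].
#' @param seed optional seed overriding `config$seed + 1`.
#' @return object of class `promoter_set`: list with `genes`, `target` and
#'   `ortholog` (aligned character vectors, equal lengths), `tss_offset`
#'   (alignment position of the TSS, here 5001), `windows` (list of
#'   start/end pairs), `pwm`, and `planted` (logical, motif planted).
#' @export
simulate_promoters <- function(config, truth, n_background = 400,
                               mutation_rate = 0.55,
                               conserved_mutation_rate = 0.05,
                               gap_rate = 0.01,
                               n_windows = 8, window_len = 120,
                               pwm = synthetic_pwm(), seed = NULL) {
  if (is.null(truth$planted_motifs) || !nrow(truth$planted_motifs))
    stopf("truth carries no planted_motifs")
  pm <- truth$planted_motifs[1, ]
  L <- ncol(pwm$counts)
  if (L > window_len) stopf("motif (%d bp) longer than conserved window (%d bp)", L, window_len)
  with_seed(seed %||% (config$seed + 1L), {
    fg <- names(truth$pattern_membership)[
      !is.na(truth$pattern_membership) & truth$pattern_membership == pm$pattern]
    bg_pool <- names(truth$pattern_membership)[is.na(truth$pattern_membership)]
    bg <- sample(bg_pool, min(n_background, length(bg_pool)))
    genes <- c(fg, bg)
    is_fg <- c(rep(TRUE, length(fg)), rep(FALSE, length(bg)))
    len <- 6001L
    bases <- c("A", "C", "G", "T")
    consensus <- pwm_consensus(pwm)

    target <- character(length(genes))
    ortholog <- character(length(genes))
    windows <- vector("list", length(genes))
    planted <- logical(length(genes))
    for (i in seq_along(genes)) {
      tgt <- sample(bases, len, replace = TRUE)
      # non-overlapping conserved windows on a regular raster, jittered
      slots <- floor(len / (n_windows + 1))
      starts <- pmin(len - window_len,
                     (seq_len(n_windows) - 1) * slots + 1 +
                       sample.int(max(1, slots - window_len), n_windows, replace = TRUE))
      starts <- sort(starts)
      in_window <- rep(FALSE, len)
      for (s in starts) in_window[s:(s + window_len - 1)] <- TRUE

      rate <- pm$bg_rate
      if (is_fg[i]) rate <- pm$fg_rate
      planted[i] <- stats::runif(1) < rate
      if (planted[i]) {
        w <- sample(starts, 1)
        off <- w + sample.int(window_len - L + 1, 1) - 1
        tgt[off:(off + L - 1)] <- strsplit(consensus, "")[[1]]
      }

      orth <- tgt
      p_mut <- ifelse(in_window, conserved_mutation_rate, mutation_rate)
      mut <- stats::runif(len) < p_mut
      if (any(mut)) {
        # substitute uniformly among the three other bases
        codes <- match(orth[mut], bases)
        shift <- sample.int(3, sum(mut), replace = TRUE)
        orth[mut] <- bases[((codes - 1L + shift) %% 4L) + 1L]
      }
      gap <- !in_window & stats::runif(len) < gap_rate
      orth[gap] <- "-"
      # keep the planted instance intact in the ortholog (conserved site)
      if (planted[i]) orth[off:(off + L - 1)] <- tgt[off:(off + L - 1)]

      target[i] <- paste(tgt, collapse = "")
      ortholog[i] <- paste(orth, collapse = "")
      windows[[i]] <- data.frame(start = starts, end = starts + window_len - 1)
    }
    structure(list(genes = genes, target = target, ortholog = ortholog,
                   tss_offset = 5001L, window = c(-5000L, 1000L),
                   windows = windows, pwm = pwm, planted = planted,
                   foreground = is_fg),
              class = "promoter_set")
  })
}

#' A synthetic position frequency matrix used for motif planting
#'
#' A sharply informative 14-bp matrix over the consensus `TGACGTCATGACGT`
#' (a CRE-like direct repeat), 100 sites per column with 91/3/3/3 splits.
#' The length keeps chance occurrences of near-consensus sites rare at the
#' default relative-score cutoff, so planted-motif recovery is driven by the
#' planting rates rather than by background hits. Synthetic: not taken from
#' any motif database.
#'
#' @param id,name identifiers embedded in the matrix object.
#' @return a `pwm` object (list with `id`, `name`, `counts` 4 x L matrix).
#' @export
synthetic_pwm <- function(id = "SYN0001", name = "SYNCRE") {
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A",
                 "T", "G", "A", "C", "G", "T")
  counts <- matrix(3, nrow = 4, ncol = length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 91
  new_pwm(id, name, counts)
}

#' Simulate behavioral phenotypes linked to pattern activation
#'
#' Conditioned place preference (CPP) per drug is generated as
#' `slope * (summed planted activation of the linked pattern over all time
#' points) + noise`; locomotor activity per drug x time as
#' `slope * (planted activation of its linked pattern at that time) + noise`.
#' Links, slopes and noise come from `truth$phenotype_link`.
#'
#' @param truth `ground_truth` from [simulate_expression()].
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed + 2`.
#' @return object of class `phenotype_table`: list with data.frames
#'   `cpp` (drug, score) and `locomotion` (drug, time_h, activity).
#' @export
simulate_behavior <- function(truth, config, seed = NULL) {
  if (is.null(truth$phenotype_link)) stopf("truth carries no phenotype_link")
  eff <- effect_lookup(truth$effect_profile)
  act <- function(pattern, drug, time_h) {
    e <- eff[paste(pattern, drug, time_h, sep = "\r")]
    ifelse(is.na(e), 0, e)
  }
  with_seed(seed %||% (config$seed + 2L), {
    lk <- truth$phenotype_link
    cpp_act <- vapply(config$drugs, function(d)
      sum(vapply(config$time_points, function(t) act(lk$cpp$pattern, d, t),
                 numeric(1))), numeric(1))
    cpp <- data.frame(drug = config$drugs,
                      score = lk$cpp$slope * cpp_act +
                        stats::rnorm(length(config$drugs), 0, lk$cpp$noise_sd))
    grid <- expand.grid(drug = config$drugs, time_h = config$time_points,
                        stringsAsFactors = FALSE)
    loco_act <- mapply(function(d, t) act(lk$locomotion$pattern, d, t),
                       grid$drug, grid$time_h)
    loco <- data.frame(drug = grid$drug, time_h = grid$time_h,
                       activity = lk$locomotion$slope * loco_act +
                         stats::rnorm(nrow(grid), 0, lk$locomotion$noise_sd))
    structure(list(cpp = cpp, locomotion = loco,
                   truth_activation = list(cpp = cpp_act, locomotion = loco_act)),
              class = "phenotype_table")
  })
}

#' Simulate a pharmacological-dissection (inhibitor) experiment
#'
#' Generates the four arms of a dissection experiment at one drug and time
#' point: saline+vehicle, drug+vehicle, saline+inhibitor and drug+inhibitor.
#' For each pattern named in `phi`, the drug+inhibitor linear-scale
#' activation (mean fold change - 1) of its probes is
#' `(1 - phi/100)` times the drug+vehicle activation; `phi` may be below 0
#' (amplification) or above 100 (reversal below the saline baseline).
#'
#' @param truth `ground_truth` from [simulate_expression()].
#' @param phi named numeric vector, percent inhibition per pattern label.
#' @param config a [sim_config()].
#' @param drug,time_h the drug and time point of the experiment.
#' @param inhibitor label recorded in the sample sheet.
#' @param seed optional seed overriding `config$seed + 3`.
#' @return an [expr_matrix()] of raw intensities whose sample sheet has
#'   `drug` in (drug, saline) and `arm` in (vehicle, inhibitor).
#' @export
simulate_inhibitor_experiment <- function(truth, phi, config,
                                          drug = "cocaine", time_h = 1,
                                          inhibitor = "inhibitor",
                                          seed = NULL) {
  bad <- setdiff(names(phi), unique(stats::na.omit(truth$pattern_membership)))
  if (length(bad)) stopf("unknown pattern key(s): %s", paste(bad, collapse = ", "))
  if (any(!is.finite(phi))) stopf("phi values must be finite")
  eff <- effect_lookup(truth$effect_profile)
  with_seed(seed %||% (config$seed + 3L), {
    probes <- names(truth$pattern_membership)
    n <- length(probes)
    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)

    arms <- expand.grid(drug = c("saline", drug), arm = c("vehicle", "inhibitor"),
                        replicate = seq_len(config$replicates_per_group),
                        stringsAsFactors = FALSE)
    arms$time_h <- time_h
    arms$batch <- 1L
    arms$sample_id <- sprintf("%s_%s_r%d", arms$drug, arms$arm, arms$replicate)
    arms <- arms[, c("sample_id", "drug", "time_h", "batch", "arm", "replicate")]

    # planted log2 shift per probe for the drug arms
    key <- paste(truth$pattern_membership, drug, time_h, sep = "\r")
    e_vehicle <- eff[key]
    e_vehicle[is.na(e_vehicle)] <- 0
    e_inhib <- e_vehicle
    for (p in names(phi)) {
      sel <- !is.na(truth$pattern_membership) & truth$pattern_membership == p
      fc_inh <- 1 + (1 - phi[[p]] / 100) * (2^e_vehicle[sel] - 1)
      if (any(fc_inh <= 0))
        stopf("phi = %g drives the fold change of pattern %s non-positive", phi[[p]], p)
      e_inhib[sel] <- log2(fc_inh)
    }

    m <- matrix(baseline, nrow = n, ncol = nrow(arms),
                dimnames = list(probes, arms$sample_id))
    for (j in seq_len(nrow(arms))) {
      if (arms$drug[j] == drug)
        m[, j] <- m[, j] + if (arms$arm[j] == "inhibitor") e_inhib else e_vehicle
    }
    m <- m + matrix(stats::rnorm(length(m), 0, config$noise_sd), nrow = n)
    expr_matrix(2^m, arms, log2 = FALSE)
  })
}
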