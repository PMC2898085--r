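#' Run the full module-discovery and dissection pipeline
#'
#' End-to-end driver over simulated data: generates an expression experiment
#' with planted ground truth, normalizes (quantile + log2 + batch z-score),
#' discovers drug-responsive probes by two-way ANOVA with Bonferroni/BH
#' adjustment and a true-positive/FDR curve, clusters their profiles into
#' patterns and extends them by centroid correlation, screens a gene-set
#' collection for over-representation, scans simulated promoter alignments
#' for conserved binding sites of the planted motif and tests their
#' enrichment, runs a simulated inhibitor experiment through the
#' percent-inhibition statistic, correlates pattern activation with
#' simulated behavior, and assembles the regulatory network. When `outdir`
#' is given, every declared file format is written there.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @param bonferroni_alpha family-wise level for the discovery gene list.
#' @param k number of pattern clusters to cut (see [cluster_genes()]; the
#'   height-based `h` cut is available through that function directly).
#' @param extension_alpha centroid-correlation inclusion threshold.
#' @param phi planted percent inhibition (named by pattern) for the
#'   dissection experiment.
#' @param r_min,p_max network thresholds, see [build_network()].
#' @return list with all intermediate objects (`sim`, `norm`, `anova`,
#'   `tp`, `tukey`, `patterns`, `enrichment`, `promoters`, `tfbs_hits`,
#'   `tfbs_enrichment`, `dissection`, `behavior`, `correlations`,
#'   `network`, `files`).
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         bonferroni_alpha = 0.05, k = 4,
                         extension_alpha = 1e-10,
                         phi = c(A = 100), r_min = 0.6, p_max = 0.1) {
  sim <- simulate_expression(config)
  norm <- standardize(log2_transform(quantile_normalize(sim$matrix)))
  fit <- fit_two_way_anova(norm)
  tp <- tp_curve(fit$q_bh_drug)
  discovered <- fit$probe[fit$p_bonf_drug < bonferroni_alpha]
  tukey <- tukey_drug_vs_saline(fit, probes = discovered)

  profiles <- profile_matrix(norm)
  ps <- cluster_genes(profiles[discovered, , drop = FALSE], k = k)
  ps <- extend_patterns(ps, profiles, alpha = extension_alpha)

  universe <- fit$probe
  collection <- truth_collection(sim$truth, universe, seed = config$seed + 4L)
  enrichment <- lapply(ps$core, screen_collection, collection = collection)

  promoters <- simulate_promoters(config, sim$truth)
  pwm <- promoters$pwm
  fg <- names(sim$truth$pattern_membership)[
    !is.na(sim$truth$pattern_membership) &
      sim$truth$pattern_membership == sim$truth$planted_motifs$pattern[1]]
  tf_enr <- tfbs_enrichment(intersect(fg, promoters$genes), promoters$genes,
                            promoters, pwm)
  hits <- scan_promoter_set(promoters, pwm,
                            genes = intersect(unlist(ps$core), promoters$genes))

  inh <- simulate_inhibitor_experiment(sim$truth, phi, config)
  inh_norm <- log2_transform(quantile_normalize(inh))
  dres <- lapply(names(phi), function(p) {
    genes <- names(sim$truth$pattern_membership)[
      !is.na(sim$truth$pattern_membership) & sim$truth$pattern_membership == p]
    percent_inhibition(inh_norm, genes, drug = "cocaine", pattern = p)
  })
  names(dres) <- paste0("inhibitor_", names(phi))

  behavior <- simulate_behavior(sim$truth, config)
  core_label <- label_clusters_by_truth(ps, sim$truth)
  correlations <- phenotype_correlations(profiles, ps, core_label, behavior,
                                         config)
  # network over core genes, using truth labels where dissection applies
  net_dissect <- dres
  for (i in seq_along(net_dissect)) {
    cl <- names(ps$core)[match(names(phi)[i], core_label)]
    if (!is.na(cl)) net_dissect[[i]]$pattern <- cl
  }
  net <- build_network(profiles, ps, tfbs_hits = hits,
                       dissection = net_dissect, r_min = r_min, p_max = p_max)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(...) file.path(outdir, ...)
    write_expression(sim$matrix, fp("expression.tsv"), fp("samples.csv"))
    write_truth_yaml(sim$truth, fp("truth.yaml"))
    write_expression(norm, fp("normalized.tsv"))
    write_anova_tsv(fit, fp("anova.tsv"))
    utils::write.table(as.data.frame(tp), fp("tp_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tukey, fp("tukey.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(pattern_membership(ps), fp("patterns.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    export_dendrogram(ps, fp("dendrogram.nwk"))
    write_gmt(collection$sets, fp("gene_sets.gmt"))
    enr_all <- do.call(rbind, lapply(names(enrichment), function(nm)
      cbind(pattern = nm, enrichment[[nm]])))
    utils::write.table(enr_all, fp("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_promoter_fasta(promoters, fp("promoters.fa"))
    write_jaspar(pwm, fp("pwms.jaspar"))
    write_tfbs_bed(hits, fp("tfbs_hits.bed"))
    utils::write.table(
      data.frame(matrix_id = pwm$id, fold = tf_enr$fold, p = tf_enr$p,
                 k_fg = tf_enr$k_fg, n_fg = tf_enr$n_fg,
                 k_bg = tf_enr$k_bg, n_bg = tf_enr$n_bg),
      fp("tfbs_enrichment.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    diss_df <- do.call(rbind, lapply(names(dres), function(nm) {
      d <- dres[[nm]]
      data.frame(experiment = nm, pattern = d$pattern, drug = d$drug,
                 a_d = d$a_d, a_i = d$a_i, phi = d$phi, p = d$p,
                 reliable = d$reliable)
    }))
    utils::write.table(diss_df, fp("dissection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_phenotypes(behavior, fp("phenotype_cpp.csv"),
                     fp("phenotype_locomotion.csv"))
    utils::write.table(correlations, fp("correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    export_network(net, fp("network.graphml"), "graphml")
    export_network(net, fp("network.sif"), "sif")
    files <- list.files(outdir, full.names = TRUE)
  }
  list(sim = sim, norm = norm, anova = fit, tp = tp, tukey = tukey,
       discovered = discovered, patterns = ps, core_label = core_label,
       collection = collection, enrichment = enrichment,
       promoters = promoters, tfbs_hits = hits, tfbs_enrichment = tf_enr,
       dissection = dres, behavior = behavior, correlations = correlations,
       network = net, files = files)
}

# serialize an anova_table (drops matrix attributes)
write_anova_tsv <- function(fit, path) {
  utils::write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# map recovered cluster labels (P1..) to planted pattern labels by majority
label_clusters_by_truth <- function(ps, truth) {
  vapply(ps$core, function(g) {
    lab <- truth$pattern_membership[g]
    lab <- lab[!is.na(lab)]
    if (!length(lab)) return(NA_character_)
    names(which.max(table(lab)))
  }, character(1))
}

# gene-set collection built from planted pattern membership plus random sets
truth_collection <- function(truth, universe, n_random = 30,
                             random_size = c(20, 80), seed = 1L) {
  planted <- truth$pattern_membership[!is.na(truth$pattern_membership)]
  sets <- split(names(planted), unname(planted))
  names(sets) <- paste0("planted_pattern_", names(sets))
  sets <- lapply(sets, intersect, y = universe)
  with_seed(seed, {
    for (i in seq_len(n_random)) {
      sz <- sample(random_size[1]:random_size[2], 1)
      sets[[sprintf("random_set_%02d", i)]] <- sample(universe, sz)
    }
  })
  gene_set_collection("synthetic_truth_collection", sets, universe)
}

# pattern activation vs simulated phenotypes (CPP summed, locomotion per time)
phenotype_correlations <- function(profiles, ps, core_label, behavior,
                                   config) {
  rows <- list()
  cpp_pat <- "B1"; loco_pat <- "A"
  cl_cpp <- names(core_label)[match(cpp_pat, core_label)]
  cl_loco <- names(core_label)[match(loco_pat, core_label)]
  if (!is.na(cl_cpp)) {
    act <- pattern_activation(profiles, ps$core[[cl_cpp]], mode = "summed")
    m <- match(behavior$cpp$drug, act$drug)
    ct <- correlate(act$activation[m], behavior$cpp$score)
    rows[[1]] <- data.frame(phenotype = "cpp", pattern = cpp_pat,
                            mode = "summed", r = ct$r, p = ct$p, n = ct$n)
  }
  if (!is.na(cl_loco)) {
    act <- pattern_activation(profiles, ps$core[[cl_loco]], mode = "per_time")
    key <- paste(act$drug, act$time_h)
    m <- match(paste(behavior$locomotion$drug, behavior$locomotion$time_h), key)
    ct <- correlate(act$activation[m], behavior$locomotion$activity)
    rows[[2]] <- data.frame(phenotype = "locomotion", pattern = loco_pat,
                            mode = "per_time", r = ct$r, p = ct$p, n = ct$n)
  }
  do.call(rbind, rows)
}
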