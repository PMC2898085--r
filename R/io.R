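#' Write / read an expression matrix as TSV plus sample sheet CSV
#'
#' The TSV has probes in rows (first column `probe_id`) and sample IDs as
#' column names; the sample sheet CSV has columns `sample_id`, `drug`,
#' `time_h`, `batch`, `arm`, `replicate`.
#'
#' @param x an [expr_matrix()].
#' @param tsv,csv output paths.
#' @return paths, invisibly.
#' @export
write_expression <- function(x, tsv, csv = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(csv))
    utils::write.csv(x$samples, csv, row.names = FALSE, quote = FALSE)
  invisible(c(tsv, csv))
}

#' @rdname write_expression
#' @param log2 whether the stored values are log2 (recorded on the object).
#' @return for `read_expression`, an [expr_matrix()].
#' @export
read_expression <- function(tsv, csv, log2 = FALSE) {
  df <- utils::read.delim(tsv, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  samples <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expr_matrix(m, samples, log2 = log2)
}

#' Write / read aligned promoter pairs as multi-FASTA
#'
#' Two records per gene, `<gene>|target` and `<gene>|ortholog`, of equal
#' aligned length with gaps as `-`.
#'
#' @param promoters a `promoter_set`.
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  seqs <- as.vector(rbind(promoters$target, promoters$ortholog))
  names(seqs) <- as.vector(rbind(paste0(promoters$genes, "|target"),
                                 paste0(promoters$genes, "|ortholog")))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_promoter_fasta
#' @param tss_offset 1-based ungapped target position of the TSS.
#' @return for `read_promoter_fasta`, a `promoter_set`.
#' @export
read_promoter_fasta <- function(path, tss_offset = 5001L) {
  ss <- Biostrings::readBStringSet(path)
  nm <- names(ss)
  gene <- sub("\\|(target|ortholog)$", "", nm)
  role <- sub("^.*\\|", "", nm)
  genes <- unique(gene)
  tgt <- as.character(ss[match(paste0(genes, "|target"), nm)])
  ort <- as.character(ss[match(paste0(genes, "|ortholog"), nm)])
  if (anyNA(tgt) || anyNA(ort))
    stopf("each gene needs one target and one ortholog record")
  if (any(nchar(tgt) != nchar(ort)))
    stopf("target/ortholog aligned lengths differ")
  structure(list(genes = genes, target = unname(tgt), ortholog = unname(ort),
                 tss_offset = as.integer(tss_offset),
                 window = c(-(tss_offset - 1L),
                            nchar(tgt[1]) - tss_offset),
                 windows = NULL, pwm = NULL, planted = NULL,
                 foreground = NULL),
            class = "promoter_set")
}

#' Write / read PWMs in JASPAR text format
#'
#' The 2016-style flat format: a `>ID NAME` header followed by four lines
#' `A [ 4 19 0 ... ]` etc.
#'
#' @param pwms a `pwm` or list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_jaspar
#' @return for `read_jaspar`, a named list of `pwm` objects (names = IDs).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stopf("no matrices found in '%s'", path)
  out <- lapply(heads, function(h) {
    hdr <- sub("^>", "", lines[h])
    toks <- strsplit(hdr, "[ \t]+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else id
    rows <- lines[(h + 1):(h + 4)]
    counts <- do.call(rbind, lapply(rows, function(r) {
      nums <- sub("^[ACGTacgt]", "", r)
      as.numeric(regmatches(nums, gregexpr("[0-9]+\\.?[0-9]*", nums))[[1]])
    }))
    new_pwm(id, name, counts)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write TFBS hits as BED6
#'
#' One line per hit: chrom = gene ID, start/end in promoter-window
#' coordinates (0-based, TSS at 5000 for the standard -5000..+1000 window),
#' name = matrix ID, score = round(1000 * relative score), strand. A header
#' comment records the coordinate convention.
#'
#' @param hits data.frame from [scan_promoter_set()] (TSS-relative
#'   coordinates).
#' @param path output path.
#' @param tss_offset 1-based TSS position used to shift back to window
#'   coordinates.
#' @return `path`, invisibly.
#' @export
write_tfbs_bed <- function(hits, path, tss_offset = 5001L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coordinates: 0-based half-open within the promoter window; TSS at %d",
                     tss_offset - 1L), con)
  if (nrow(hits))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                       hits$gene,
                       hits$start + tss_offset - 1L,
                       hits$end + tss_offset - 1L,
                       hits$matrix_id,
                       round(1000 * hits$rel_score),
                       hits$strand), con)
  invisible(path)
}

#' Write the simulation ground truth as YAML
#'
#' @param truth a `ground_truth` list from [simulate_expression()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  membership <- truth$pattern_membership
  planted <- membership[!is.na(membership)]
  obj <- list(
    pattern_membership = split(names(planted), unname(planted)),
    diurnal_probes = truth$diurnal_probes,
    effect_profile = truth$effect_profile,
    planted_motifs = truth$planted_motifs,
    planted_inhibition = truth$planted_inhibition,
    phenotype_link = truth$phenotype_link)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Write behavioral phenotype tables as CSV
#'
#' @param phenotypes a `phenotype_table` from [simulate_behavior()].
#' @param cpp_csv,locomotion_csv output paths.
#' @return paths, invisibly.
#' @export
write_phenotypes <- function(phenotypes, cpp_csv, locomotion_csv) {
  utils::write.csv(phenotypes$cpp, cpp_csv, row.names = FALSE, quote = FALSE)
  utils::write.csv(phenotypes$locomotion, locomotion_csv,
                   row.names = FALSE, quote = FALSE)
  invisible(c(cpp_csv, locomotion_csv))
}
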