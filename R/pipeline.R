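## Pipeline orchestration: a single validated config drives
## simulate -> demux -> align -> exons -> transcripts -> quantify ->
## junctions -> proteome, with stage outputs and a summary JSON.

#' Default pipeline configuration
#'
#' Returns the full nested parameter list; callers override individual
#' entries.  Unknown keys are rejected by [run_pipeline()].
#'
#' @param mode `"pacbio"` or `"ont"`.
#' @param seed Integer master seed.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(mode = "pacbio", seed = 1) {
  structure(list(
    mode = mode,
    seed = seed,
    simulate = list(
      n_exons = 14L, alt3ss_exons = 7L, n_isoforms = 12L,
      n_samples = 4L, reads_per_sample = 500L,
      error_rates = c(sub = 0.01, ins = 0.0025, del = 0.0025),
      truncation_prob = 0, alpha = 2,
      short_read_length = 100L, short_reads_per_sample = 2000L),
    demux = list(max_mismatch = 2L, window = 100L),
    align = list(k = 13L, min_intron = 20L, band = 16L,
                 reject_identity = 0.66, refine_window = 10L),
    exons = list(tol = 3L, min_support = NULL, dominance = 0.05),
    transcripts = list(match = 1, mismatch = -2, gap_open = -2,
                       gap_extend = -1, min_cov = 0.8, min_ident = 0.85,
                       qc_min_identity = 0.85, min_cluster_reads = NULL,
                       require_terminal_exons = NULL),
    junctions = list(overhang_5p = 9L, overhang_3p = 6L, min_overlap = 15L,
                     max_mismatch = 0L),
    proteome = list(min_orf_nt = 300L,
                    start_codons = c("ATG", "CTG", "GTG", "TTG"),
                    policy = "longest_per_stop", protease = "trypsin",
                    missed_cleavages = 2L, len_range = c(7L, 30L))),
    class = "pipeline_config")
}

## Recursively check a user config against the defaults: unknown keys are
## rejected before any compute.
validate_config <- function(config, template = default_config()) {
  check <- function(cfg, tpl, path = "") {
    unknown <- setdiff(names(cfg), names(tpl))
    if (length(unknown) > 0)
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (nm in names(cfg)) {
      if (is.list(tpl[[nm]]) && !is.null(names(tpl[[nm]])) &&
          is.list(cfg[[nm]]))
        check(cfg[[nm]], tpl[[nm]], paste0(path, nm, "$"))
    }
  }
  check(config, template)
  ## merge user values over defaults
  merge <- function(tpl, cfg) {
    for (nm in names(cfg)) {
      tpl[[nm]] <- if (is.list(tpl[[nm]]) && !is.null(names(tpl[[nm]])) &&
                       is.list(cfg[[nm]]))
        merge(tpl[[nm]], cfg[[nm]]) else cfg[[nm]]
    }
    tpl
  }
  out <- merge(unclass(template), unclass(config))
  class(out) <- "pipeline_config"
  out
}

#' Read a pipeline config from YAML or JSON
#'
#' @param path Config file; keys mirror [default_config()].
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_config(cfg)
}

#' Run the full pipeline
#'
#' Simulates (or loads) the inputs, then runs demultiplexing, spliced
#' alignment, exon discovery, architecture clustering, quantification,
#' junction analysis and proteome prediction.  Stage outputs are written
#' under stage-named subdirectories of `out_dir` (when given) together
#' with a machine-readable `summary.json`; the result list carries every
#' intermediate object.  Deterministic given config + seed.
#'
#' @param config A `pipeline_config` (or partial list; validated and
#'   merged over defaults).
#' @param out_dir Optional output directory.
#' @return A list with `gene`, `sim`, `demux`, `alignments`, `catalog`,
#'   `clusters`, `matrix`, `junctions`, `proteome`, `summary`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  stage_dir <- function(stage) {
    if (is.null(out_dir)) return(NULL)
    d <- file.path(out_dir, stage)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }

  ## -- simulate ------------------------------------------------------------
  sc <- config$simulate
  gene <- build_toy_gene(n_exons = sc$n_exons, alt3ss_exons = sc$alt3ss_exons,
                         n_isoforms = sc$n_isoforms, seed = config$seed)
  sheet <- make_sample_sheet(sc$n_samples, seed = config$seed + 1L)
  scenario <- sim_scenario(n_samples = sc$n_samples,
                           reads_per_sample = sc$reads_per_sample,
                           alpha = sc$alpha, error_rates = sc$error_rates,
                           truncation_prob = sc$truncation_prob,
                           short_read_length = sc$short_read_length,
                           short_reads_per_sample = sc$short_reads_per_sample,
                           seed = config$seed + 2L)
  sim <- simulate_long_reads(gene, scenario, sheet)
  short <- simulate_short_reads(gene, scenario, sheet)
  if (!is.null(d <- stage_dir("simulate"))) {
    write_reads(sim$reads, file.path(d, "long_reads.fastq"))
    write_reads(short$reads, file.path(d, "short_reads.fastq"))
    utils::write.table(sim$manifest, file.path(d, "long_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_sample_sheet(sheet, file.path(d, "sample_sheet.tsv"))
    write_locus_fasta(gene$locus, file.path(d, "locus.fasta"))
  }

  ## -- demux ---------------------------------------------------------------
  dm <- demultiplex(sim$reads, sheet, config$demux$max_mismatch,
                    config$demux$window)
  oriented <- orient_reads(dm$reads)
  if (!is.null(d <- stage_dir("demux")))
    utils::write.table(dm$report, file.path(d, "demux_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- align ---------------------------------------------------------------
  al <- align_reads(oriented, gene$locus, k = config$align$k,
                    min_intron = config$align$min_intron,
                    band = config$align$band,
                    reject_identity = config$align$reject_identity,
                    window = config$align$refine_window)
  if (!is.null(d <- stage_dir("align"))) {
    write_alignments_bed12(al$alignments, gene$locus,
                           file.path(d, "alignments.bed12"))
    utils::write.table(al$rejected, file.path(d, "rejected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## -- exons ---------------------------------------------------------------
  ## default exon support: 0.5% of aligned reads, at least 2 -- boundary
  ## noise is per-read, so no erroneous position recurs at this rate
  min_support <- config$exons$min_support %||%
    max(2L, round(0.005 * length(al$alignments)))
  ex <- discover_exons(al$alignments, gene$locus, tol = config$exons$tol,
                       min_support = min_support,
                       dominance = config$exons$dominance)
  exon_seqs <- exon_sequences(ex$catalog, gene$locus)
  if (!is.null(d <- stage_dir("exons"))) {
    write_exons_bed(ex$catalog, file.path(d, "exons.bed"),
                    chrom = gene$locus$name)
    utils::write.table(ex$excluded, file.path(d, "excluded.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## -- transcripts ---------------------------------------------------------
  tp <- config$transcripts
  params <- annotation_params(match = tp$match, mismatch = tp$mismatch,
                              gap_open = tp$gap_open,
                              gap_extend = tp$gap_extend,
                              min_cov = tp$min_cov, min_ident = tp$min_ident,
                              qc_min_identity = tp$qc_min_identity,
                              mode = config$mode,
                              min_cluster_reads = tp$min_cluster_reads,
                              require_terminal_exons = tp$require_terminal_exons)
  aligned_reads <- oriented[oriented$read_id %in% names(al$alignments), ,
                            drop = FALSE]
  ann <- annotate_exons(aligned_reads, exon_seqs, ex$catalog, params,
                        alignments = al$alignments)
  qc <- qc_against_theoretical(aligned_reads, ann$barcodes, exon_seqs, params,
                               alignments = al$alignments)
  clusters <- cluster_and_name(qc, ex$catalog, exon_seqs, params,
                               sample_ids = sheet$sample_id)
  if (!is.null(d <- stage_dir("transcripts"))) {
    write_transcripts_bed12(clusters, gene$locus, ex$catalog,
                            file.path(d, "transcripts.bed12"))
    utils::write.table(clusters$clusters, file.path(d, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## -- quantify ------------------------------------------------------------
  mx <- build_matrix(clusters, sample_ids = sheet$sample_id)
  usage <- exon_usage(mx, ex$catalog)
  if (!is.null(d <- stage_dir("quantify"))) {
    write_counts_tsv(mx$counts, file.path(d, "counts.tsv"))
    utils::write.table(data.frame(exon = rownames(usage), usage),
                       file.path(d, "exon_usage.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## -- junctions -----------------------------------------------------------
  jx <- enumerate_junctions(clusters)
  ov <- min_unique_overhangs(jx, exon_seqs)
  o5 <- max(config$junctions$overhang_5p, ov$global["A"], na.rm = TRUE)
  o3 <- max(config$junctions$overhang_3p, ov$global["B"], na.rm = TRUE)
  jref <- build_junction_reference(jx, exon_seqs, o5, o3)
  jcounts <- count_short_read_support(
    short$reads, jref, min_overlap = config$junctions$min_overlap,
    min_overhang_5p = config$junctions$overhang_5p,
    min_overhang_3p = config$junctions$overhang_3p,
    max_mismatch = config$junctions$max_mismatch)
  jx$short_read_count <- jcounts$short_read_count[
    match(jx$junction_id, jcounts$junction_id)]
  jx$min_overhang_5p <- ov$per_junction$a[
    match(jx$junction_id, ov$per_junction$junction_id)]
  jx$min_overhang_3p <- ov$per_junction$b[
    match(jx$junction_id, ov$per_junction$junction_id)]
  if (!is.null(d <- stage_dir("junctions"))) {
    utils::write.table(jx, file.path(d, "junctions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    build_junction_reference(jx, exon_seqs, o5, o3,
                             path = file.path(d, "junction_reference.fasta"))
  }

  ## -- proteome ------------------------------------------------------------
  pr <- config$proteome
  prot <- predict_proteome(clusters, ex$catalog,
                           validated_tis = gene$validated_tis,
                           start_codons = pr$start_codons,
                           min_orf_nt = pr$min_orf_nt, policy = pr$policy)
  peptides <- if (nrow(prot$isoforms) > 0)
    digest_and_map(prot$isoforms, protease = pr$protease,
                   missed_cleavages = pr$missed_cleavages,
                   len_range = pr$len_range, orfs = prot$orfs,
                   clusters = clusters, catalog = ex$catalog)
  else list(peptides = data.frame())
  if (!is.null(d <- stage_dir("proteome"))) {
    utils::write.table(prot$isoforms[, setdiff(names(prot$isoforms), "protein")],
                       file.path(d, "isoforms.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(prot$isoforms) > 0) {
      s <- Biostrings::AAStringSet(prot$isoforms$protein)
      names(s) <- prot$isoforms$isoform_id
      Biostrings::writeXStringSet(s, file.path(d, "isoforms.fasta"))
      utils::write.table(peptides$peptides, file.path(d, "peptides.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## -- summary -------------------------------------------------------------
  summary <- list(
    mode = config$mode, seed = config$seed,
    reads_total = nrow(sim$reads),
    reads_assigned = sum(!is.na(dm$reads$sample_id)),
    reads_aligned = length(al$alignments),
    reads_qc_pass = sum(qc$keep),
    n_exons = nrow(ex$catalog),
    n_transcripts = nrow(clusters$clusters),
    n_junctions = nrow(jx),
    proteome = as.list(prot$counts))
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(list(package_version =
                                as.character(utils::packageVersion("ampliso")),
                              config = unclass(config)),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(gene = gene, sheet = sheet, sim = sim, short = short, demux = dm,
       alignments = al, catalog = ex$catalog, exon_seqs = exon_seqs,
       excluded_exons = ex$excluded, annotation = ann, qc = qc,
       clusters = clusters, matrix = mx, exon_usage = usage,
       junctions = jx, junction_ref = jref, overhangs = ov,
       proteome = prot, peptides = peptides, summary = summary)
}
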