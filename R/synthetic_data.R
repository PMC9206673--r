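## Synthetic data: toy loci, isoform repertoires, abundances and
## error-bearing long/short reads with a ground-truth manifest.
##
## The generator emulates a targeted amplicon design: every molecule is
## barcode + primer + full-length isoform cDNA + primer + barcode, so the
## locus itself carries no flanking sequence beyond the first/last exon.

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                  DNA_BASES, paste0)),
  c("TAA", "TAG", "TGA"))

#' Build a toy multi-exon gene with ground truth
#'
#' Constructs a single-gene locus whose structure exercises every downstream
#' stage: `n_exons` exons separated by GT..AG introns, optional alternative
#' 3' splice-site (acceptor) variants, and an isoform repertoire in which
#' internal exons are skipped.  A protein-coding frame is embedded in the
#' full-length isoform (ATG near the 5' end, stop codon inside the last
#' exon, no premature in-frame stop), so that exon skipping naturally
#' produces both frame-preserving isoforms and frameshifted ones carrying
#' premature termination codons.
#'
#' @param n_exons Number of exons (>= 3).
#' @param alt3ss_exons Integer indices of internal exons that get an
#'   alternative acceptor variant (two variants sharing their donor,
#'   starts differing by 6-24 nt).
#' @param n_isoforms Number of distinct isoforms to generate; all include
#'   the first and last exon and are strictly increasing in genomic order.
#' @param seed Integer seed; the same seed reproduces the gene byte for byte.
#' @param exon_len_range,intron_len_range Length ranges (nt); introns are
#'   always >= 20 nt.
#' @param utr5,utr3 Untranslated lengths flanking the embedded CDS within
#'   the full-length transcript.
#' @param gc_donor_exons Integer indices of exons whose downstream intron
#'   starts `GC` instead of the canonical `GT` (their truth `donor_ok` is
#'   FALSE); used to exercise the splice-site filter.
#' @param locus_name Name used for the locus record.
#' @return An object of class `simulated_gene`: `locus`, `exons` (truth
#'   `exon_catalog`), `isoforms` (named list of exon-name vectors),
#'   `isoform_seqs`, `intron_lengths`, `primers`, `validated_tis` (genomic
#'   coordinate of the active ATG), `alt3ss` (variant table).
#' @export
build_toy_gene <- function(n_exons = 14, alt3ss_exons = integer(0),
                           n_isoforms = 12, seed = 1,
                           exon_len_range = c(80, 200),
                           intron_len_range = c(40, 150),
                           utr5 = 30, utr3 = 60,
                           gc_donor_exons = integer(0),
                           locus_name = "toylocus") {
  stopifnot(n_exons >= 3, all(alt3ss_exons > 1 & alt3ss_exons < n_exons),
            all(gc_donor_exons >= 1 & gc_donor_exons < n_exons),
            intron_len_range[1] >= 20)
  with_seed(seed, {
    exon_lens <- sample(seq(exon_len_range[1], exon_len_range[2]),
                        n_exons, replace = TRUE)
    total <- sum(exon_lens)
    ## embed a CDS in the full-length transcript: ATG at utr5 (0-based),
    ## sense codons, stop inside the last exon
    last_start_tx <- total - exon_lens[n_exons]
    stop_min <- last_start_tx + 5
    stop_max <- total - utr3 - 3
    stopifnot(stop_max > stop_min)
    stop_tx <- stop_max - ((stop_max - utr5) %% 3)
    if (stop_tx < stop_min) stop("last exon too short to host the stop codon")
    n_sense <- (stop_tx - utr5 - 3) / 3
    stopifnot(utr5 >= 3)
    ## a stop immediately 5' of the ATG terminates any upstream reading
    ## frame, so the ATG is the reported TIS under longest-per-stop
    tx <- paste0(random_dna(utr5 - 3L), "TAA", "ATG",
                 paste(sample(SENSE_CODONS, n_sense, replace = TRUE),
                       collapse = ""),
                 sample(c("TAA", "TAG", "TGA"), 1),
                 random_dna(total - stop_tx - 3))
    ends_tx <- cumsum(exon_lens)
    starts_tx <- c(0L, ends_tx[-n_exons])
    exon_seqs <- substring(tx, starts_tx + 1L, ends_tx)

    ## alternative acceptor variants: force AG inside the exon so the
    ## variant start is a canonical 3' splice site; reject deltas that
    ## would introduce a premature in-frame stop into the full transcript
    alt <- data.frame(exon = integer(0), delta = integer(0))
    for (i in alt3ss_exons) {
      placed <- FALSE
      for (delta in sample(6:24)) {
        if (exon_lens[i] - delta < 30) next
        cand <- exon_seqs[i]
        substr(cand, delta - 1L, delta) <- "AG"
        tmp <- exon_seqs; tmp[i] <- cand
        full <- paste(tmp, collapse = "")
        cods <- substring(full, seq(utr5 + 1L, stop_tx - 2L, 3L),
                          seq(utr5 + 3L, stop_tx, 3L))
        if (any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA"))) next
        exon_seqs[i] <- cand
        alt <- rbind(alt, data.frame(exon = i, delta = delta))
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place an alternative acceptor in exon ", i)
    }

    ## introns: GT .. AG, length >= 20
    intron_lens <- sample(seq(intron_len_range[1], intron_len_range[2]),
                          n_exons - 1, replace = TRUE)
    introns <- vapply(seq_along(intron_lens), function(j)
      paste0(if (j %in% gc_donor_exons) "GC" else "GT",
             random_dna(intron_lens[j] - 4L), "AG"), character(1))
    pieces <- character(2 * n_exons - 1)
    pieces[seq(1, by = 2, length.out = n_exons)] <- exon_seqs
    pieces[seq(2, by = 2, length.out = n_exons - 1)] <- introns
    locus_seq <- paste(pieces, collapse = "")
    g_starts <- cumsum(c(0L, exon_lens[-n_exons] + intron_lens))
    g_ends <- g_starts + exon_lens

    ## truth catalog in discovery naming: E<k>, variants E<k>a / E<k>b
    rows <- list()
    for (i in seq_len(n_exons)) {
      is_alt <- i %in% alt$exon
      base <- sprintf("E%d", i)
      if (is_alt) {
        d <- alt$delta[alt$exon == i]
        rows[[length(rows) + 1]] <- data.frame(
          name = c(paste0(base, "a"), paste0(base, "b")),
          start = c(g_starts[i], g_starts[i] + d),
          end = g_ends[i], group = base, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          name = base, start = g_starts[i], end = g_ends[i],
          group = base, stringsAsFactors = FALSE)
      }
    }
    cat_df <- do.call(rbind, rows)
    cat_df$acceptor_ok <- TRUE
    cat_df$donor_ok <- !(match(cat_df$group, sprintf("E%d", seq_len(n_exons)))
                         %in% gc_donor_exons)
    cat_df$acceptor_ok[1] <- NA
    cat_df$donor_ok[cat_df$end == max(cat_df$end) &
                    cat_df$group == sprintf("E%d", n_exons)] <- NA
    cat_df$support <- 0L
    truth <- new_exon_catalog(cat_df[, c("name", "start", "end",
                                         "acceptor_ok", "donor_ok",
                                         "support", "group")])

    ## primers: 20-mers sharing no 13-mer with the locus
    kmers <- substring(locus_seq, seq_len(nchar(locus_seq) - 12L),
                       seq(13L, nchar(locus_seq)))
    fresh_primer <- function() {
      repeat {
        p <- random_dna(20L)
        pk <- substring(p, 1:8, 13:20)
        if (!any(pk %in% kmers) && !any(revcomp(pk) %in% kmers)) return(p)
      }
    }
    primers <- list(fwd = fresh_primer(), rev = fresh_primer())

    ## isoform repertoire: full-length first, then a b-variant swap per alt
    ## group, then random internal skips / variant choices
    base_chain <- vapply(seq_len(n_exons), function(i)
      if (i %in% alt$exon) sprintf("E%da", i) else sprintf("E%d", i),
      character(1))
    isoforms <- list(base_chain)
    for (i in alt$exon) {
      ch <- base_chain
      ch[i] <- sprintf("E%db", i)
      isoforms[[length(isoforms) + 1]] <- ch
    }
    keys <- vapply(isoforms, paste, character(1), collapse = "|")
    tries <- 0
    while (length(isoforms) < n_isoforms && tries < 10000) {
      tries <- tries + 1
      drop <- sample(2:(n_exons - 1), sample(1:min(3, n_exons - 2), 1))
      ch <- base_chain
      for (i in alt$exon) if (stats::runif(1) < 0.5) ch[i] <- sprintf("E%db", i)
      ch <- ch[-drop]
      key <- paste(ch, collapse = "|")
      if (!key %in% keys) {
        isoforms[[length(isoforms) + 1]] <- ch
        keys <- c(keys, key)
      }
    }
    if (length(isoforms) < n_isoforms)
      stop("could not generate ", n_isoforms, " distinct isoforms")
    isoforms <- isoforms[seq_len(n_isoforms)]
    names(isoforms) <- sprintf("ISO-%d", seq_len(n_isoforms))
    iso_seqs <- vapply(isoforms, function(ch) {
      m <- match(ch, truth$name)
      paste(substring(locus_seq, truth$start[m] + 1L, truth$end[m]),
            collapse = "")
    }, character(1))
    if (anyDuplicated(iso_seqs))
      stop("isoform sequences collide; use a different seed")

    structure(list(
      locus = gene_locus(locus_name, locus_seq),
      exons = truth,
      isoforms = isoforms,
      isoform_seqs = iso_seqs,
      intron_lengths = intron_lens,
      primers = primers,
      validated_tis = g_starts[1] + utr5,
      cds = list(atg_tx = utr5, stop_tx = stop_tx),
      alt3ss = alt,
      seed = seed), class = "simulated_gene")
  })
}

#' @export
print.simulated_gene <- function(x, ...) {
  cat(sprintf("<simulated_gene> %d exons (%d acceptor variants), %d isoforms, locus %d nt\n",
              length(x$intron_lengths) + 1, nrow(x$alt3ss),
              length(x$isoforms), nchar(x$locus$sequence)))
  invisible(x)
}

#' Simulation scenario
#'
#' Bundles sample sizes, the abundance model and the read error model.
#' Abundances are per-sample isoform proportions: explicit via
#' `proportions`/`exact_counts`, otherwise drawn from a symmetric Dirichlet
#' with concentration `alpha`.
#'
#' @param n_samples Number of barcoded samples.
#' @param reads_per_sample Long reads per sample.
#' @param alpha Dirichlet concentration (scalar or per-isoform vector).
#' @param proportions Optional n_samples x n_isoforms matrix of proportions
#'   (rows sum to 1).
#' @param exact_counts Optional n_samples x n_isoforms integer matrix of
#'   exact per-isoform read counts (overrides proportions).
#' @param error_rates Named vector `c(sub=, ins=, del=)` of per-base
#'   probabilities, each in \[0, 0.2\].
#' @param truncation_prob Probability that a long read is truncated from one
#'   end (emulating degraded ONT libraries); 0 keeps all reads full-length.
#' @param short_read_length,short_reads_per_sample Short-read simulation.
#' @param seed Integer seed recorded in the manifest.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_samples = 4, reads_per_sample = 500, alpha = 2,
                         proportions = NULL, exact_counts = NULL,
                         error_rates = c(sub = 0.01, ins = 0.0025, del = 0.0025),
                         truncation_prob = 0,
                         short_read_length = 100,
                         short_reads_per_sample = 2000,
                         seed = 1) {
  er <- error_rates[c("sub", "ins", "del")]
  stopifnot(!anyNA(er), all(er >= 0 & er <= 0.2),
            truncation_prob >= 0, truncation_prob <= 1)
  if (!is.null(proportions)) {
    stopifnot(all(abs(rowSums(proportions) - 1) < 1e-9))
  }
  structure(list(n_samples = n_samples, reads_per_sample = reads_per_sample,
                 alpha = alpha, proportions = proportions,
                 exact_counts = exact_counts, error_rates = er,
                 truncation_prob = truncation_prob,
                 short_read_length = short_read_length,
                 short_reads_per_sample = short_reads_per_sample,
                 seed = seed), class = "sim_scenario")
}

## Per-sample isoform proportions, shared between long- and short-read
## simulation so the two agree for a given scenario seed.
scenario_proportions <- function(gene, scenario) {
  n_iso <- length(gene$isoforms)
  if (!is.null(scenario$exact_counts)) {
    cm <- scenario$exact_counts
    stopifnot(ncol(cm) == n_iso)
    return(sweep(cm, 1, rowSums(cm), "/"))
  }
  if (!is.null(scenario$proportions)) {
    stopifnot(ncol(scenario$proportions) == n_iso)
    return(scenario$proportions)
  }
  alpha <- rep(scenario$alpha, length.out = n_iso)
  with_seed(scenario$seed + 7919L, {
    g <- matrix(stats::rgamma(scenario$n_samples * n_iso, shape = alpha),
                nrow = scenario$n_samples, byrow = TRUE)
    sweep(g, 1, rowSums(g), "/")
  })
}

## i.i.d. per-base error model: substitution to a uniform other base,
## single-base insertions/deletions.
apply_errors <- function(seq, sub, ins, del) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  del_mask <- stats::runif(n) < del
  sub_mask <- stats::runif(n) < sub & !del_mask
  if (any(sub_mask)) {
    idx <- match(ch[sub_mask], DNA_BASES)
    shift <- sample(1:3, sum(sub_mask), replace = TRUE)
    ch[sub_mask] <- DNA_BASES[(idx + shift - 1L) %% 4L + 1L]
  }
  ch <- ch[!del_mask]
  ins_mask <- stats::runif(length(ch) + 1L) < ins
  n_ins <- sum(ins_mask)
  if (n_ins > 0) {
    pos <- which(ins_mask) - 1L          # insert after this many kept bases
    newch <- character(length(ch) + n_ins)
    take <- rep(TRUE, length(newch))
    at <- pos + seq_along(pos)           # positions of inserted bases
    take[at] <- FALSE
    newch[at] <- sample(DNA_BASES, n_ins, replace = TRUE)
    newch[take] <- ch
    ch <- newch
  }
  list(seq = paste(ch, collapse = ""),
       n_sub = sum(sub_mask), n_ins = n_ins, n_del = sum(del_mask))
}

#' Simulate barcoded full-length long reads
#'
#' Each molecule is `barcode_fwd + primer_fwd + isoform cDNA +
#' rc(primer_rev) + rc(barcode_rev)`, mutated by the i.i.d. error model,
#' optionally truncated, and emitted in random orientation with constant
#' quality.  Realised per-sample isoform counts are multinomial draws from
#' the scenario proportions (or the exact counts, when supplied).
#'
#' @param gene A `simulated_gene`.
#' @param scenario A `sim_scenario`.
#' @param sheet A `sample_sheet` with at least `n_samples` rows.
#' @return A list: `reads` (`read_set`, sample/orientation left for the
#'   demultiplexer to recover), `manifest` (read_id, sample, isoform,
#'   n_sub, n_ins, n_del, orientation, truncated), `proportions`, `counts`.
#' @export
simulate_long_reads <- function(gene, scenario, sheet) {
  stopifnot(nrow(sheet) >= scenario$n_samples)
  sheet <- sheet[seq_len(scenario$n_samples), , drop = FALSE]
  props <- scenario_proportions(gene, scenario)
  n_iso <- length(gene$isoforms)
  with_seed(scenario$seed, {
    counts <- if (!is.null(scenario$exact_counts)) {
      scenario$exact_counts
    } else {
      t(vapply(seq_len(scenario$n_samples), function(s)
        as.integer(stats::rmultinom(1, scenario$reads_per_sample, props[s, ])),
        integer(n_iso)))
    }
    rownames(counts) <- sheet$sample_id
    colnames(counts) <- names(gene$isoforms)
    er <- scenario$error_rates
    recs <- vector("list", sum(counts))
    man <- vector("list", sum(counts))
    k <- 0L
    for (s in seq_len(nrow(counts))) {
      rc_tail <- revcomp(paste0(sheet$barcode_rev[s],
                                gene$primers$rev))
      for (i in seq_len(n_iso)) {
        if (counts[s, i] == 0) next
        molecule <- paste0(sheet$barcode_fwd[s], gene$primers$fwd,
                           gene$isoform_seqs[[i]], rc_tail)
        for (r in seq_len(counts[s, i])) {
          k <- k + 1L
          e <- apply_errors(molecule, er["sub"], er["ins"], er["del"])
          sq <- e$seq
          truncated <- FALSE
          if (scenario$truncation_prob > 0 &&
              stats::runif(1) < scenario$truncation_prob) {
            truncated <- TRUE
            cut <- ceiling(stats::runif(1, 0.1, 0.6) * nchar(sq))
            sq <- if (stats::runif(1) < 0.5) substr(sq, cut + 1L, nchar(sq))
                  else substr(sq, 1L, nchar(sq) - cut)
          }
          orient <- if (stats::runif(1) < 0.5) "forward" else "reverse"
          if (orient == "reverse") sq <- revcomp(sq)
          recs[[k]] <- sq
          man[[k]] <- data.frame(
            read_id = "", sample = sheet$sample_id[s],
            isoform = names(gene$isoforms)[i],
            n_sub = e$n_sub, n_ins = e$n_ins, n_del = e$n_del,
            orientation = orient, truncated = truncated,
            stringsAsFactors = FALSE)
        }
      }
    }
    manifest <- do.call(rbind, man)
    manifest$read_id <- sprintf("R%06d", seq_len(k))
    reads <- read_set(manifest$read_id, unlist(recs),
                      qualities = strrep("I", nchar(unlist(recs))))
    list(reads = reads, manifest = manifest, proportions = props,
         counts = counts)
  })
}

#' Simulate short reads from the isoform repertoire
#'
#' Reads are drawn uniformly along isoforms chosen with the scenario's
#' per-sample abundances; the manifest records, for every read, which
#' exon-exon junctions it truly spans and with what overhangs.
#'
#' @inheritParams simulate_long_reads
#' @return A list: `reads` (`read_set` with `sample_id` filled),
#'   `manifest` (one row per read), `junction_spans` (one row per read x
#'   spanned junction: donor/acceptor exon names, genomic boundary
#'   coordinates, 5'/3' overhang lengths).
#' @export
simulate_short_reads <- function(gene, scenario, sheet = NULL) {
  L <- scenario$short_read_length
  iso_lens <- nchar(gene$isoform_seqs)
  stopifnot(L <= min(iso_lens))
  props <- scenario_proportions(gene, scenario)
  n_iso <- length(gene$isoforms)
  sample_ids <- if (!is.null(sheet)) sheet$sample_id[seq_len(scenario$n_samples)]
                else sprintf("S%d", seq_len(scenario$n_samples))
  ## per-isoform junction tables (tx boundary, exon names, genomic coords)
  jt <- lapply(gene$isoforms, function(ch) {
    m <- match(ch, gene$exons$name)
    lens <- gene$exons$end[m] - gene$exons$start[m]
    if (length(ch) < 2) return(NULL)
    data.frame(tx_boundary = cumsum(lens)[-length(lens)],
               donor_exon = ch[-length(ch)], acceptor_exon = ch[-1],
               donor_end = gene$exons$end[m][-length(ch)],
               acceptor_start = gene$exons$start[m][-1],
               stringsAsFactors = FALSE)
  })
  er <- scenario$error_rates
  with_seed(scenario$seed + 104729L, {
    reads <- list(); man <- list(); spans <- list()
    k <- 0L
    for (s in seq_len(scenario$n_samples)) {
      n <- scenario$short_reads_per_sample
      iso <- sample.int(n_iso, n, replace = TRUE, prob = props[s, ])
      pos <- floor(stats::runif(n) * (iso_lens[iso] - L + 1))
      for (r in seq_len(n)) {
        k <- k + 1L
        id <- sprintf("SR%06d", k)
        sq <- substr(gene$isoform_seqs[[iso[r]]], pos[r] + 1L, pos[r] + L)
        e <- apply_errors(sq, er["sub"], er["ins"], er["del"])
        reads[[k]] <- read_set(id, e$seq,
                               qualities = strrep("I", nchar(e$seq)),
                               sample_id = sample_ids[s],
                               orientation = "forward")
        man[[k]] <- data.frame(read_id = id, sample = sample_ids[s],
                               isoform = names(gene$isoforms)[iso[r]],
                               start = pos[r], n_sub = e$n_sub,
                               n_ins = e$n_ins, n_del = e$n_del,
                               stringsAsFactors = FALSE)
        j <- jt[[iso[r]]]
        if (!is.null(j)) {
          hit <- j$tx_boundary > pos[r] & j$tx_boundary < pos[r] + L
          if (any(hit)) {
            jj <- j[hit, , drop = FALSE]
            spans[[length(spans) + 1]] <- data.frame(
              read_id = id, sample = sample_ids[s],
              donor_exon = jj$donor_exon, acceptor_exon = jj$acceptor_exon,
              donor_end = jj$donor_end, acceptor_start = jj$acceptor_start,
              overhang_5p = jj$tx_boundary - pos[r],
              overhang_3p = pos[r] + L - jj$tx_boundary,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(reads = do.call(rbind, reads), manifest = do.call(rbind, man),
         junction_spans = if (length(spans)) do.call(rbind, spans)
                          else data.frame())
  })
}
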