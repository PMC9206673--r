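## Theoretical proteome prediction: ORF enumeration per transcript,
## TIS-evidence filtering, deduplication, PTC removal, molecular weights,
## in-silico digestion and isoform-discriminating peptide mapping.

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Monoisotopic and average residue masses (Da); water added per chain.
AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
             V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
             I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
             K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
             F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
AA_AVG <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
            V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
            I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
            K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
            F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MONO <- 18.010565
WATER_AVG <- 18.01528

#' Enumerate open reading frames in a transcript sequence
#'
#' Scans all three forward frames.  An ORF runs from a start codon to the
#' first in-frame stop; the stop codon is included in `length_nt` and in
#' the 300-nt default minimum.  Under the default `longest_per_stop`
#' policy only the most upstream qualifying start is kept per (frame,
#' stop); `all_starts` reports every qualifying start.  Unterminated
#' reading frames (no in-frame stop) are not reported.
#'
#' @param sequence Transcript DNA string.
#' @param start_codons Start codon set; the default adds the near-cognate
#'   trio CTG/GTG/TTG to ATG.
#' @param min_orf_nt Minimum ORF length in nt, stop codon included.
#' @param policy `"longest_per_stop"` or `"all_starts"`.
#' @return Data frame: `frame` (0-2), `start_codon`, `tx_start`, `tx_end`
#'   (0-based half-open, stop included), `length_nt`, `protein` (initiator
#'   written as M regardless of the start codon).
#' @export
find_orfs <- function(sequence, start_codons = c("ATG", "CTG", "GTG", "TTG"),
                      min_orf_nt = 300,
                      policy = c("longest_per_stop", "all_starts")) {
  policy <- match.arg(policy)
  len <- nchar(sequence)
  out <- list()
  for (f in 0:2) {
    pos <- seq(f, len - 3L, by = 3L)         # 0-based codon starts
    if (length(pos) == 0) next
    cod <- substring(sequence, pos + 1L, pos + 3L)
    is_stop <- cod %in% STOP_CODONS
    is_start <- cod %in% start_codons
    prev_stop <- 0L                           # codon index bound (exclusive)
    for (s in which(is_stop)) {
      starts <- which(is_start[seq_len(s - 1L)])
      starts <- starts[starts > prev_stop]
      lens <- (s - starts + 1L) * 3L
      ok <- lens >= min_orf_nt
      starts <- starts[ok]
      if (length(starts) > 0) {
        if (policy == "longest_per_stop") starts <- starts[1]
        for (a in starts) {
          tx_start <- pos[a]
          tx_end <- pos[s] + 3L
          orf_seq <- substring(sequence, tx_start + 1L, tx_end - 3L)
          prot <- as.character(Biostrings::translate(
            Biostrings::DNAString(orf_seq), no.init.codon = TRUE))
          substr(prot, 1L, 1L) <- "M"        # initiator is Met
          out[[length(out) + 1]] <- data.frame(
            frame = f, start_codon = cod[a], tx_start = tx_start,
            tx_end = tx_end, length_nt = tx_end - tx_start,
            protein = prot, stringsAsFactors = FALSE)
        }
      }
      prev_stop <- s
    }
  }
  if (length(out) == 0)
    return(data.frame(frame = integer(0), start_codon = character(0),
                      tx_start = integer(0), tx_end = integer(0),
                      length_nt = integer(0), protein = character(0)))
  res <- do.call(rbind, out)
  res[order(res$tx_start, res$tx_end, res$frame), , drop = FALSE]
}

## Map a transcript coordinate (0-based) to locus coordinate and exon name
## through a transcript's exon chain.
tx_to_genomic <- function(txpos, chain, catalog) {
  m <- match(chain, catalog$name)
  lens <- catalog$end[m] - catalog$start[m]
  ends <- cumsum(lens)
  i <- findInterval(txpos, c(0L, ends), rightmost.closed = FALSE)
  stopifnot(i >= 1, i <= length(chain), txpos < ends[length(ends)])
  offset <- txpos - c(0L, ends)[i]
  list(genomic = catalog$start[m[i]] + offset, exon = chain[i])
}

#' Predict ORFs for every transcript cluster
#'
#' Runs [find_orfs()] on each theoretical transcript sequence and maps the
#' translation initiation site and the stop codon back to locus
#' coordinates through the transcript's exon chain.  A stop codon spanning
#' an exon-exon junction is assigned to the exon containing its first
#' base.
#'
#' @param clusters A `transcript_clusters` object.
#' @param catalog The `exon_catalog`.
#' @inheritParams find_orfs
#' @return Data frame of ORF records with `transcript`, `genomic_tis` and
#'   `stop_exon` columns added.
#' @export
predict_orfs <- function(clusters, catalog,
                         start_codons = c("ATG", "CTG", "GTG", "TTG"),
                         min_orf_nt = 300,
                         policy = c("longest_per_stop", "all_starts")) {
  policy <- match.arg(policy)
  out <- lapply(clusters$clusters$name, function(tx) {
    chain <- strsplit(clusters$clusters$barcode[
      clusters$clusters$name == tx], "|", fixed = TRUE)[[1]]
    orfs <- find_orfs(clusters$sequences[[tx]], start_codons, min_orf_nt,
                      policy)
    if (nrow(orfs) == 0) return(NULL)
    orfs$transcript <- tx
    orfs$genomic_tis <- vapply(orfs$tx_start, function(p)
      tx_to_genomic(p, chain, catalog)$genomic, numeric(1))
    orfs$stop_exon <- vapply(orfs$tx_end - 3L, function(p)
      tx_to_genomic(p, chain, catalog)$exon, character(1))
    orfs
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), start_codon = character(0),
                      tx_start = integer(0), tx_end = integer(0),
                      length_nt = integer(0), protein = character(0),
                      transcript = character(0), genomic_tis = numeric(0),
                      stop_exon = character(0))
  out
}

#' Filter ORFs by validated translation initiation sites
#'
#' Keeps ORFs whose genomic TIS is in the validated set (e.g. from
#' ribosome profiling).  An empty validated set drops everything and warns
#' loudly, to distinguish "no evidence supplied" from "none validated".
#'
#' @param orfs Data frame from [predict_orfs()].
#' @param validated_tis Numeric vector of validated genomic TIS
#'   coordinates (0-based).
#' @return A list: `orfs` (filtered) and `report` (TIS tally).
#' @export
filter_by_tis <- function(orfs, validated_tis) {
  observed <- unique(orfs$genomic_tis)
  if (length(validated_tis) == 0)
    warning("empty validated-TIS set: all ORFs dropped; supply TIS evidence ",
            "or skip this filter")
  keep <- orfs$genomic_tis %in% validated_tis
  list(orfs = orfs[keep, , drop = FALSE],
       report = data.frame(n_tis_observed = length(observed),
                           n_tis_validated = sum(observed %in% validated_tis),
                           n_orfs_in = nrow(orfs),
                           n_orfs_kept = sum(keep)))
}

#' Collapse duplicate ORFs and remove PTC-bearing ones
#'
#' Identical protein sequences collapse into one isoform carrying all
#' source transcripts.  An isoform is flagged as carrying a premature
#' termination codon (PTC) — and removed — unless at least one of its
#' source ORFs places the stop codon in the catalog's last exon (any
#' member of the terminal variant group); such transcripts are the
#' presumptive nonsense-mediated-decay substrates.
#'
#' @param orfs Data frame from [predict_orfs()] (possibly TIS-filtered).
#' @param catalog The `exon_catalog`.
#' @return A list: `isoforms` (data frame `isoform_id`, `protein`,
#'   `source_transcripts`, `tis`, `n_sources`), `removed` (PTC removal
#'   log), `n_deduplicated` (isoform count before PTC removal).
#' @export
drop_duplicates_and_ptc <- function(orfs, catalog) {
  if (nrow(orfs) == 0)
    return(list(isoforms = data.frame(), removed = data.frame(),
                n_deduplicated = 0L))
  last_group <- catalog$group[nrow(catalog)]
  last_names <- catalog$name[catalog$group == last_group]
  orfs$ptc <- !(orfs$stop_exon %in% last_names)
  sp <- split(orfs, orfs$protein)
  rows <- lapply(sp, function(g) {
    data.frame(protein = g$protein[1],
               source_transcripts = paste(sort(unique(g$transcript)),
                                          collapse = ","),
               n_sources = length(unique(g$transcript)),
               tis = g$genomic_tis[1],
               ptc = all(g$ptc), stringsAsFactors = FALSE)
  })
  dedup <- do.call(rbind, rows)
  dedup <- dedup[order(-nchar(dedup$protein), dedup$protein), , drop = FALSE]
  removed <- dedup[dedup$ptc, c("protein", "source_transcripts"), drop = FALSE]
  if (nrow(removed) > 0) removed$reason <- "PTC"
  iso <- dedup[!dedup$ptc, , drop = FALSE]
  rownames(iso) <- NULL
  if (nrow(iso) > 0) {
    iso$isoform_id <- sprintf("P-%d", seq_len(nrow(iso)))
    iso <- iso[, c("isoform_id", "protein", "source_transcripts",
                   "n_sources", "tis")]
  } else {
    iso <- data.frame(isoform_id = character(0), protein = character(0),
                      source_transcripts = character(0),
                      n_sources = integer(0), tis = numeric(0))
  }
  list(isoforms = iso, removed = removed, n_deduplicated = nrow(dedup))
}

#' Protein molecular weights
#'
#' Average and monoisotopic masses as the sum of residue masses plus one
#' water.
#'
#' @param proteins Character vector of one-letter protein sequences
#'   (standard 20 residues).
#' @return Data frame `mw_average_da`, `mw_mono_da`.
#' @export
molecular_weights <- function(proteins) {
  res <- vapply(proteins, function(p) {
    aa <- strsplit(p, "")[[1]]
    bad <- which(!aa %in% names(AA_MONO))
    if (length(bad) > 0)
      stop("non-standard residue '", aa[bad[1]], "' at position ", bad[1])
    c(avg = sum(AA_AVG[aa]) + WATER_AVG,
      mono = sum(AA_MONO[aa]) + WATER_MONO)
  }, numeric(2))
  data.frame(mw_average_da = res["avg", ], mw_mono_da = res["mono", ],
             row.names = NULL)
}

PROTEASE_RULES <- list(
  trypsin = list(side = "after", residues = c("K", "R"), except_before = "P",
                 rule = "after K/R, not before P"),
  elastase = list(side = "after", residues = c("A", "V", "S", "G", "L", "I"),
                  except_before = NULL,
                  rule = "after A/V/S/G/L/I (simplified specificity)"),
  thermolysin = list(side = "before",
                     residues = c("I", "L", "V", "A", "M", "F"),
                     except_before = NULL,
                     rule = "before I/L/V/A/M/F (simplified specificity)"),
  papain = list(side = "after", residues = c("K", "R", "H"),
                except_before = "P",
                rule = "after K/R/H, not before P (simplified specificity)"))

#' In-silico proteolytic digestion of one protein
#'
#' @param protein One-letter protein string.
#' @param protease One of `"trypsin"`, `"elastase"`, `"thermolysin"`,
#'   `"papain"`.
#' @param missed_cleavages Maximum missed cleavages per peptide.
#' @param len_range Length range retained, or NULL for no filter.
#' @return Data frame `peptide`, `aa_start`, `aa_end` (1-based inclusive),
#'   `n_missed`.
#' @export
digest_protein <- function(protein, protease = "trypsin",
                           missed_cleavages = 2, len_range = c(7, 30)) {
  if (!protease %in% names(PROTEASE_RULES)) {
    rules <- vapply(PROTEASE_RULES, `[[`, character(1), "rule")
    stop("unsupported protease '", protease, "'; supported: ",
         paste(sprintf("%s (%s)", names(rules), rules), collapse = "; "))
  }
  rule <- PROTEASE_RULES[[protease]]
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n == 0) return(data.frame())
  between <- seq_len(n - 1L)                 # cut between i and i+1
  cut <- if (rule$side == "after") aa[between] %in% rule$residues
         else aa[between + 1L] %in% rule$residues
  if (!is.null(rule$except_before))
    cut <- cut & aa[between + 1L] != rule$except_before
  bounds <- c(0L, which(cut), n)             # fragment boundaries
  nf <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nf)) {
    for (m in 0:min(missed_cleavages, nf - i)) {
      a <- bounds[i] + 1L
      b <- bounds[i + 1L + m]
      out[[length(out) + 1]] <- data.frame(
        peptide = paste(aa[a:b], collapse = ""),
        aa_start = a, aa_end = b, n_missed = m, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(len_range)) {
    w <- res$aa_end - res$aa_start + 1L
    res <- res[w >= len_range[1] & w <= len_range[2], , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Digest the proteome and classify peptides by isoform specificity
#'
#' Digests every isoform and classifies each distinct peptide as
#' `isoform-unique` (appears in the digest of exactly one isoform),
#' `group-discriminating` (a proper subset) or `shared` (all isoforms).
#' When ORF and cluster information is supplied, peptides whose coding
#' span crosses an exon-exon junction of their source transcript are
#' flagged junction-spanning.  An observed-peptide list restricts a
#' summary of which isoforms gain unique support.
#'
#' @param isoforms Data frame from [drop_duplicates_and_ptc()].
#' @param protease,missed_cleavages,len_range See [digest_protein()].
#' @param orfs Optional ORF table ([predict_orfs()]) for junction flags.
#' @param clusters,catalog Optional, required with `orfs`.
#' @param observed Optional character vector of observed peptide sequences.
#' @return A list: `peptides` (peptide, class, isoforms, junction_spanning),
#'   `observed_support` (isoform_id, n_unique_observed) when `observed`
#'   is given.
#' @export
digest_and_map <- function(isoforms, protease = "trypsin",
                           missed_cleavages = 2, len_range = c(7, 30),
                           orfs = NULL, clusters = NULL, catalog = NULL,
                           observed = NULL) {
  stopifnot(nrow(isoforms) > 0)
  digs <- lapply(seq_len(nrow(isoforms)), function(i)
    digest_protein(isoforms$protein[i], protease, missed_cleavages,
                   len_range))
  names(digs) <- isoforms$isoform_id
  pep2iso <- list()
  for (i in seq_along(digs)) {
    for (p in unique(digs[[i]]$peptide)) {
      pep2iso[[p]] <- c(pep2iso[[p]], isoforms$isoform_id[i])
    }
  }
  n_iso <- nrow(isoforms)
  classes <- vapply(pep2iso, function(z) {
    k <- length(unique(z))
    if (k == 1L && n_iso > 1L) "isoform-unique"
    else if (k == n_iso) "shared"
    else if (n_iso == 1L) "isoform-unique"
    else "group-discriminating"
  }, character(1))
  peptides <- data.frame(peptide = names(pep2iso), class = unname(classes),
                         isoforms = vapply(pep2iso, paste, character(1),
                                           collapse = ","),
                         stringsAsFactors = FALSE)
  rownames(peptides) <- NULL
  if (!is.null(orfs) && !is.null(clusters) && !is.null(catalog)) {
    peptides$junction_spanning <- vapply(seq_len(nrow(peptides)), function(i) {
      iso_id <- strsplit(peptides$isoforms[i], ",")[[1]][1]
      iso <- isoforms[isoforms$isoform_id == iso_id, ]
      tx <- strsplit(iso$source_transcripts, ",")[[1]][1]
      o <- orfs[orfs$transcript == tx & orfs$protein == iso$protein, ][1, ]
      d <- digs[[iso_id]]
      hit <- d[d$peptide == peptides$peptide[i], ][1, ]
      nt_start <- o$tx_start + 3L * (hit$aa_start - 1L)
      nt_end <- o$tx_start + 3L * hit$aa_end
      chain <- strsplit(clusters$clusters$barcode[
        clusters$clusters$name == tx], "|", fixed = TRUE)[[1]]
      m <- match(chain, catalog$name)
      boundaries <- cumsum(catalog$end[m] - catalog$start[m])
      any(boundaries > nt_start & boundaries < nt_end)
    }, logical(1))
  }
  res <- list(peptides = peptides)
  if (!is.null(observed)) {
    obs <- peptides[peptides$peptide %in% observed &
                    peptides$class == "isoform-unique", , drop = FALSE]
    sup <- table(obs$isoforms)
    res$observed_support <- data.frame(
      isoform_id = names(sup), n_unique_observed = as.integer(sup),
      stringsAsFactors = FALSE)
  }
  res
}

#' Run the full proteome-prediction filter chain
#'
#' ORF enumeration, TIS filtering, deduplication, PTC removal and
#' molecular weights, with the per-step counts the pipeline reports.
#'
#' @inheritParams predict_orfs
#' @param validated_tis Validated genomic TIS set (see [filter_by_tis()]);
#'   NULL skips the filter.
#' @return A list: `isoforms` (with molecular weights), `orfs`,
#'   `counts` (named vector of the per-step cardinalities), `tis_report`,
#'   `removed`.
#' @export
predict_proteome <- function(clusters, catalog, validated_tis = NULL,
                             start_codons = c("ATG", "CTG", "GTG", "TTG"),
                             min_orf_nt = 300,
                             policy = "longest_per_stop") {
  orfs <- predict_orfs(clusters, catalog, start_codons, min_orf_nt, policy)
  n_orfs <- nrow(orfs)
  tis_report <- NULL
  if (!is.null(validated_tis)) {
    fl <- filter_by_tis(orfs, validated_tis)
    orfs_f <- fl$orfs
    tis_report <- fl$report
  } else orfs_f <- orfs
  dd <- drop_duplicates_and_ptc(orfs_f, catalog)
  iso <- dd$isoforms
  if (nrow(iso) > 0) iso <- cbind(iso, molecular_weights(iso$protein))
  list(isoforms = iso, orfs = orfs,
       counts = c(n_orfs = n_orfs, n_tis_filtered = nrow(orfs_f),
                  n_deduplicated = dd$n_deduplicated,
                  n_isoforms = nrow(iso)),
       tis_report = tis_report, removed = dd$removed)
}
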