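## Exon-architecture barcoding: per-read exon presence/absence by
## thresholded local alignment, QC against the theoretical transcript by
## ends-free global alignment, and clustering of identical barcodes into
## named transcripts.

#' Annotation and clustering parameters
#'
#' Alignment scores follow the +1 match / -2 mismatch scheme; gap scores
#' are the total for a length-1 gap (`gap_open`) and the increment per
#' additional gapped base (`gap_extend`).
#'
#' @param match,mismatch,gap_open,gap_extend Local/global alignment scores.
#' @param min_cov Minimum fraction of the exon length aligned for a
#'   presence call.
#' @param min_ident Minimum identity within the aligned span.
#' @param qc_min_identity Minimum global identity of a read against its
#'   theoretical transcript.
#' @param min_cluster_reads Minimum reads per retained transcript cluster
#'   (PacBio mode 1, ONT mode 10).
#' @param require_terminal_exons Drop reads whose barcode lacks the
#'   catalog's first or last exon before counting (ONT mode).
#' @param mode `"pacbio"` or `"ont"`; sets the last two defaults.
#' @return An `annotation_params` list.
#' @export
annotation_params <- function(match = 1, mismatch = -2, gap_open = -2,
                              gap_extend = -1, min_cov = 0.8,
                              min_ident = 0.85, qc_min_identity = 0.85,
                              mode = c("pacbio", "ont"),
                              min_cluster_reads = NULL,
                              require_terminal_exons = NULL) {
  mode <- match.arg(mode)
  stopifnot(mismatch < 0, match > 0, gap_open < 0, gap_extend < 0,
            min_cov > 0, min_cov <= 1, min_ident > 0, min_ident <= 1)
  structure(list(
    match = match, mismatch = mismatch,
    gap_open = gap_open, gap_extend = gap_extend,
    min_cov = min_cov, min_ident = min_ident,
    qc_min_identity = qc_min_identity,
    mode = mode,
    min_cluster_reads = min_cluster_reads %||% if (mode == "ont") 10L else 1L,
    require_terminal_exons = require_terminal_exons %||% (mode == "ont")),
    class = "annotation_params")
}

## Biostrings gap parameters for our gap_open/gap_extend convention:
## a gap of length L costs gapOpening + L * gapExtension.
gap_params <- function(params) {
  list(opening = -(params$gap_open - params$gap_extend),
       extension = -params$gap_extend)
}

#' Annotate reads for exon presence and build architecture barcodes
#'
#' Every exon is locally aligned against every read; an exon is present
#' iff its best hit covers at least `min_cov` of the exon at identity at
#' least `min_ident`.  Among acceptor-variant group members matching the
#' same read, a longer variant is preferred over its shorter sibling (of
#' which it is a superstring) only when its score advantage is at least
#' half the length difference — reads carrying only the shorter form gain
#' just chance matches for the extra bases, so a bare best-score rule
#' would mis-call them.  Reads whose exon order along the read disagrees
#' with genomic order are excluded as non-colinear; reads with no exon at
#' all are excluded as `no_architecture`.
#'
#' @param reads A forward-oriented `read_set`.
#' @param exon_seqs Named exon sequences ([exon_sequences()]).
#' @param catalog The `exon_catalog` (for genomic order and variant groups).
#' @param params An [annotation_params()].
#' @param alignments Optional named list of `read_alignment` for these
#'   reads.  When supplied, each exon is aligned only against the read
#'   window its spliced alignment maps the exon interval to (plus
#'   `window_pad` nt); exons outside the aligned span are called absent
#'   without alignment.  Without it every exon is aligned against the
#'   whole read.
#' @param window_pad Window padding in nt.
#' @return A list: `barcodes` (named character, NA for excluded reads),
#'   `hits` (long per-read/per-exon table with score, coverage, identity),
#'   `excluded` (read_id, reason).
#' @export
annotate_exons <- function(reads, exon_seqs, catalog,
                           params = annotation_params(),
                           alignments = NULL, window_pad = 20) {
  stopifnot(nrow(reads) > 0, length(exon_seqs) > 0)
  mat <- nuc_matrix(params$match, params$mismatch)
  gp <- gap_params(params)
  hits <- vector("list", length(exon_seqs))
  for (e in seq_along(exon_seqs)) {
    ex <- exon_seqs[[e]]
    if (is.null(alignments)) {
      use <- seq_len(nrow(reads))
      win_start <- rep(0L, nrow(reads))
      pat <- Biostrings::DNAStringSet(reads$sequence)
    } else {
      w <- exon_read_windows(reads, alignments,
                             catalog$start[match(names(exon_seqs)[e],
                                                 catalog$name)],
                             catalog$end[match(names(exon_seqs)[e],
                                               catalog$name)], window_pad)
      use <- w$use
      if (length(use) == 0) next
      win_start <- w$start
      pat <- Biostrings::DNAStringSet(substr(reads$sequence[use],
                                             w$start + 1L, w$end))
    }
    pa <- Biostrings::pairwiseAlignment(
      pat, Biostrings::DNAString(ex), type = "local",
      substitutionMatrix = mat, gapOpening = gp$opening,
      gapExtension = gp$extension)
    span <- BiocGenerics::end(Biostrings::subject(pa)) -
      BiocGenerics::start(Biostrings::subject(pa)) + 1L
    hits[[e]] <- data.frame(
      read_id = reads$read_id[use],
      exon = names(exon_seqs)[e],
      score = Biostrings::score(pa),
      coverage = span / nchar(ex),
      identity = Biostrings::nmatch(pa) / Biostrings::nchar(pa),
      read_start = win_start[seq_along(use)] +
        BiocGenerics::start(Biostrings::pattern(pa)),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hits)
  hits$present <- hits$coverage >= params$min_cov &
    hits$identity >= params$min_ident
  hits$group <- catalog$group[match(hits$exon, catalog$name)]
  barcodes <- rep(NA_character_, nrow(reads))
  names(barcodes) <- reads$read_id
  excl <- list()
  sp <- split(seq_len(nrow(hits)), hits$read_id)
  for (rid in reads$read_id) {
    h <- hits[sp[[rid]], , drop = FALSE]
    h <- h[h$present, , drop = FALSE]
    if (nrow(h) == 0) {
      excl[[length(excl) + 1]] <- data.frame(read_id = rid,
                                             reason = "no_architecture")
      next
    }
    ## variant-group resolution by score margin: a longer variant is
    ## preferred over a shorter sibling (its suffix) only when its score
    ## advantage is at least half the length difference -- true extra
    ## bases match almost fully (+1 each), chance matches in a read that
    ## only contains the shorter form gain far less
    if (anyDuplicated(h$group)) {
      len <- nchar(exon_seqs)[h$exon]
      keep_rows <- unlist(lapply(split(seq_len(nrow(h)), h$group),
                                 function(ii) {
        if (length(ii) == 1) return(ii)
        ii <- ii[order(-len[ii])]
        best <- ii[length(ii)]                 # start from the shortest
        for (j in rev(seq_len(length(ii) - 1))) {
          margin <- (len[ii[j]] - len[best]) * params$match / 2
          if (h$score[ii[j]] - h$score[best] >= margin) best <- ii[j]
        }
        best
      }), use.names = FALSE)
      h <- h[sort(keep_rows), , drop = FALSE]
    }
    ## colinearity: order along the read must equal genomic order
    h <- h[order(h$read_start), , drop = FALSE]
    ranks <- match(h$exon, catalog$name)
    if (is.unsorted(ranks, strictly = TRUE)) {
      excl[[length(excl) + 1]] <- data.frame(read_id = rid,
                                             reason = "non_colinear")
      next
    }
    barcodes[rid] <- paste(h$exon, collapse = "|")
  }
  list(barcodes = barcodes, hits = hits,
       excluded = if (length(excl)) do.call(rbind, excl)
                  else data.frame(read_id = character(0), reason = character(0)))
}

## Read windows the spliced alignment maps a locus interval to, per read.
## Returns 0-based window starts and 1-based (inclusive) ends for substr().
exon_read_windows <- function(reads, alignments, ex_start, ex_end, pad) {
  n <- nrow(reads)
  use <- integer(0); ws <- integer(0); we <- integer(0)
  for (i in seq_len(n)) {
    aln <- alignments[[reads$read_id[i]]]
    if (is.null(aln)) next
    b <- aln$blocks
    ov <- which(b$locus_start < ex_end & b$locus_end > ex_start)
    if (length(ov) == 0) next
    f <- ov[1]; l <- ov[length(ov)]
    rs <- b$read_start[f] + max(0L, ex_start - b$locus_start[f])
    rs <- min(rs, b$read_end[f])
    re <- b$read_start[l] + (min(ex_end, b$locus_end[l]) - b$locus_start[l])
    re <- min(re, b$read_end[l])
    rs <- max(0L, rs - pad)
    re <- min(nchar(reads$sequence[i]), re + pad)
    if (re - rs < 5) next
    use <- c(use, i); ws <- c(ws, rs); we <- c(we, re)
  }
  list(use = use, start = ws, end = we)
}

#' Theoretical transcript sequence of a barcode
#'
#' @param barcode Canonical barcode string (`"E1|E2|..."`).
#' @param exon_seqs Named exon sequences.
#' @return The concatenated DNA string.
#' @export
theoretical_sequence <- function(barcode, exon_seqs) {
  ex <- strsplit(barcode, "|", fixed = TRUE)[[1]]
  missing <- setdiff(ex, names(exon_seqs))
  if (length(missing) > 0)
    stop("unknown exon(s) in barcode: ", paste(missing, collapse = ", "))
  paste(exon_seqs[ex], collapse = "")
}

#' QC reads against their theoretical transcripts
#'
#' Each read is aligned end-to-end (with free end gaps, so primer/barcode
#' remnants cost nothing) against the concatenation of its barcode's exon
#' sequences; identity is matches over alignment columns excluding end
#' gaps.  Reads below `qc_min_identity` are dropped.
#'
#' @param reads A forward-oriented `read_set`.
#' @param barcodes Named barcode vector from [annotate_exons()].
#' @param exon_seqs Named exon sequences.
#' @param params An [annotation_params()].
#' @param alignments Optional named list of `read_alignment`.  When
#'   supplied, each read is trimmed to its aligned span (dropping
#'   barcode/primer tails) and the identity is computed with the banded
#'   aligner ([banded_align()]); otherwise a full ends-free alignment is
#'   used.  Both give identity as matches over alignment columns
#'   excluding end gaps.
#' @return Data frame `read_id`, `sample_id`, `barcode`, `identity`, `keep`.
#' @export
qc_against_theoretical <- function(reads, barcodes, exon_seqs,
                                   params = annotation_params(),
                                   alignments = NULL) {
  barcodes <- barcodes[reads$read_id]
  ok <- !is.na(barcodes)
  reads <- reads[ok, , drop = FALSE]
  barcodes <- barcodes[ok]
  mat <- nuc_matrix(params$match, params$mismatch)
  gp <- gap_params(params)
  out <- vector("list", length(unique(barcodes)))
  i <- 0L
  for (bc in unique(barcodes)) {
    i <- i + 1L
    theo <- theoretical_sequence(bc, exon_seqs)
    member <- which(barcodes == bc)
    if (!is.null(alignments)) {
      ident <- vapply(member, function(r) {
        aln <- alignments[[reads$read_id[r]]]
        insert <- if (is.null(aln)) reads$sequence[r]
          else substr(reads$sequence[r], min(aln$blocks$read_start) + 1L,
                      max(aln$blocks$read_end))
        st <- banded_align(insert, theo, params$match, params$mismatch,
                           params$gap_open, params$gap_extend,
                           band = abs(nchar(insert) - nchar(theo)) + 50L)
        if (st$columns == 0) 0 else st$matches / st$columns
      }, numeric(1))
    } else {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(reads$sequence[member]),
        Biostrings::DNAString(theo), type = "overlap",
        substitutionMatrix = mat, gapOpening = gp$opening,
        gapExtension = gp$extension)
      ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    }
    out[[i]] <- data.frame(read_id = reads$read_id[member],
                           sample_id = reads$sample_id[member],
                           barcode = bc, identity = ident,
                           keep = ident >= params$qc_min_identity,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cluster identical architecture barcodes into transcripts
#'
#' Clusters are exact equality classes of the canonical barcode string.
#' In ONT mode, reads whose barcode lacks the catalog's first or last exon
#' (any member of the terminal variant groups) are dropped before
#' counting, and clusters below `min_cluster_reads` (default 10) are
#' discarded; PacBio mode keeps every cluster.  Clusters are sorted by
#' total count (ties lexicographically by barcode) and named `T-1..T-N`.
#'
#' @param qc Data frame from [qc_against_theoretical()] (only `keep` rows
#'   are used).
#' @param catalog The `exon_catalog`.
#' @param exon_seqs Named exon sequences.
#' @param params An [annotation_params()]; `params$mode` selects the
#'   filtering behaviour.
#' @param sample_ids Optional full sample set for the count matrix columns.
#' @return A `transcript_clusters` object: `clusters` (name, barcode,
#'   total_count), `counts` (transcript x sample matrix), `members`,
#'   `sequences`, `excluded_reads`.
#' @export
cluster_and_name <- function(qc, catalog, exon_seqs,
                             params = annotation_params(),
                             sample_ids = NULL) {
  qc <- qc[qc$keep, , drop = FALSE]
  excl <- data.frame(read_id = character(0), reason = character(0))
  if (params$require_terminal_exons) {
    first_grp <- catalog$group[1]
    last_grp <- catalog$group[nrow(catalog)]
    first_names <- catalog$name[catalog$group == first_grp]
    last_names <- catalog$name[catalog$group == last_grp]
    has_terms <- vapply(strsplit(qc$barcode, "|", fixed = TRUE), function(ex)
      any(ex %in% first_names) && any(ex %in% last_names), logical(1))
    excl <- data.frame(read_id = qc$read_id[!has_terms],
                       reason = rep("missing_terminal_exon", sum(!has_terms)))
    qc <- qc[has_terms, , drop = FALSE]
  }
  if (nrow(qc) == 0) stop("no reads left to cluster")
  sample_ids <- sample_ids %||% sort(unique(qc$sample_id))
  tab <- table(qc$barcode)
  keep_bc <- names(tab)[tab >= params$min_cluster_reads]
  dropped <- qc[!qc$barcode %in% keep_bc, , drop = FALSE]
  if (nrow(dropped) > 0)
    excl <- rbind(excl, data.frame(read_id = dropped$read_id,
                                   reason = "below_min_cluster_reads"))
  qc <- qc[qc$barcode %in% keep_bc, , drop = FALSE]
  tab <- tab[keep_bc]
  ord <- order(-as.integer(tab), names(tab))
  bcs <- names(tab)[ord]
  counts <- matrix(0L, length(bcs), length(sample_ids),
                   dimnames = list(sprintf("T-%d", seq_along(bcs)), sample_ids))
  xt <- table(factor(qc$barcode, levels = bcs),
              factor(qc$sample_id, levels = sample_ids))
  counts[] <- as.integer(xt)
  clusters <- data.frame(name = sprintf("T-%d", seq_along(bcs)),
                         barcode = bcs,
                         total_count = as.integer(rowSums(counts)),
                         stringsAsFactors = FALSE)
  members <- split(qc$read_id, factor(qc$barcode, levels = bcs))
  names(members) <- clusters$name
  seqs <- vapply(bcs, theoretical_sequence, character(1),
                 exon_seqs = exon_seqs)
  names(seqs) <- clusters$name
  structure(list(clusters = clusters, counts = counts, members = members,
                 sequences = seqs, excluded_reads = excl,
                 params = params),
            class = "transcript_clusters")
}

#' @export
print.transcript_clusters <- function(x, ...) {
  cat(sprintf("<transcript_clusters> %d transcripts, %d reads, %d samples\n",
              nrow(x$clusters), sum(x$clusters$total_count), ncol(x$counts)))
  print(utils::head(x$clusters, 10))
  if (nrow(x$clusters) > 10) cat("...\n")
  invisible(x)
}
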