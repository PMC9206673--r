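## Spliced alignment of long reads to the locus: exact k-mer seeding,
## colinear chaining with intron-aware gap costs, block building, boundary
## assignment and GT-AG splice-boundary refinement.

#' Build a k-mer index of the locus
#'
#' @param locus A `gene_locus`.
#' @param k Seed length.
#' @return A `locus_index` used by [align_read()].
#' @export
locus_index <- function(locus, k = 13) {
  seq <- locus$sequence
  n <- nchar(seq) - k + 1L
  stopifnot(n >= 1)
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  structure(list(k = k, tbl = split(0:(n - 1L), kmers),
                 seq = seq, chars = strsplit(seq, "")[[1]],
                 locus = locus), class = "locus_index")
}

## Merged exact-match anchors for one read orientation (0-based coords).
seed_anchors <- function(read_seq, idx) {
  k <- idx$k
  L <- nchar(read_seq)
  if (L < 2 * k) return(NULL)
  rk <- substring(read_seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  hits <- idx$tbl[rk]
  nh <- lengths(hits)
  if (sum(nh) == 0) return(NULL)
  rpos <- rep.int(0:(L - k), nh)
  lpos <- unlist(hits, use.names = FALSE)
  d <- lpos - rpos
  o <- order(d, rpos)
  rpos <- rpos[o]; lpos <- lpos[o]; d <- d[o]
  ## merge runs of consecutive k-mers on the same diagonal
  brk <- c(TRUE, diff(d) != 0L | diff(rpos) != 1L)
  grp <- cumsum(brk)
  rstart <- tapply(rpos, grp, min)
  lstart <- tapply(lpos, grp, min)
  len <- tapply(rpos, grp, function(z) max(z) - min(z) + k)
  a <- data.frame(rstart = as.integer(rstart), lstart = as.integer(lstart),
                  len = as.integer(len))
  a[order(a$rstart, a$lstart), , drop = FALSE]
}

## Colinear chaining: maximise anchored length; gaps that look like introns
## (net locus gap >= min_intron, unanchored read flank <= read_slack) are
## free, anything else costs the gap-length difference.  The read flank
## allowance covers the up-to-2(k-1) nt next to a splice junction that
## cannot carry a k-mer anchor when sequencing errors sit nearby.
chain_anchors <- function(a, min_intron, max_intron, band, read_slack) {
  n <- nrow(a)
  score <- a$len
  prev <- rep(NA_integer_, n)
  rend <- a$rstart + a$len          # exclusive
  lend <- a$lstart + a$len
  for (j in seq_len(n)[-1]) {
    for (i in seq_len(j - 1L)) {
      if (a$rstart[i] >= a$rstart[j] || a$lstart[i] >= a$lstart[j]) next
      trim <- max(0L, rend[i] - a$rstart[j], lend[i] - a$lstart[j])
      eff <- a$len[j] - trim
      if (eff <= 0) next
      dr <- a$rstart[j] - rend[i]
      dl <- a$lstart[j] - lend[i]
      cost <- if (dl - dr >= min_intron && dl <= max_intron &&
                  dr <= read_slack) 0
              else abs(dl - dr)
      s <- score[i] + eff - cost
      if (s > score[j]) { score[j] <- s; prev[j] <- i }
    }
  }
  best <- which.max(score)
  chain <- best
  while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
  list(anchors = a[chain, , drop = FALSE], score = score[best])
}

count_matches <- function(rch, lch) sum(rch == lch)

## X-drop ungapped extension; returns number of extended positions and matches.
xdrop_extend <- function(rch, lch, x = 8L) {
  n <- min(length(rch), length(lch))
  if (n == 0) return(c(len = 0L, matches = 0L))
  sc <- cumsum(ifelse(rch[seq_len(n)] == lch[seq_len(n)], 1L, -2L))
  run <- cummax(sc)
  stop_at <- which(run - sc >= x)[1]
  lim <- if (is.na(stop_at)) n else stop_at
  best <- which.max(sc[seq_len(lim)])
  if (sc[best] <= 0) return(c(len = 0L, matches = 0L))
  c(len = best, matches = sum(rch[seq_len(best)] == lch[seq_len(best)]))
}

#' Align one read to the locus as a chain of exonic blocks
#'
#' Both orientations are seeded with exact k-mer anchors and chained; the
#' orientation with the higher chain score is kept (ties break toward
#' forward).  Chained anchors merge into blocks; gaps on the locus of at
#' least `min_intron` nt co-occurring with read gaps of at most `band` nt
#' become introns.  Unanchored read bases between blocks are assigned to
#' the flanking blocks at the split maximising matches; terminal read ends
#' extend by X-drop.  The result is rejected when nothing seeds or when the
#' matched fraction of the read falls below `reject_identity`.
#'
#' @param read_seq A DNA string (one read, any orientation).
#' @param idx A [locus_index()].
#' @param min_intron,max_intron Allowed intron length range.
#' @param band Maximum read-gap length across an intron.
#' @param reject_identity Minimum matched fraction of the read length.
#' @return A `read_alignment` (list with `blocks`, `introns`, `orientation`,
#'   `identity`, `score`) or `NULL` with attribute `reason` on rejection.
#' @export
align_read <- function(read_seq, idx, min_intron = 20, max_intron = Inf,
                       band = 16, reject_identity = 0.66) {
  L <- nchar(read_seq)
  read_slack <- band + 2L * (idx$k - 1L)
  cand <- list(forward = read_seq, reverse = revcomp(read_seq))
  chains <- lapply(cand, function(s) {
    a <- seed_anchors(s, idx)
    if (is.null(a)) NULL
    else chain_anchors(a, min_intron, max_intron, band, read_slack)
  })
  sc <- vapply(chains, function(z) if (is.null(z)) -Inf else z$score, numeric(1))
  if (all(!is.finite(sc)))
    return(structure(list(), class = "alignment_rejection", reason = "unmappable"))
  orient <- if (sc["forward"] >= sc["reverse"]) "forward" else "reverse"
  seq_used <- cand[[orient]]
  ch <- chains[[orient]]
  rch <- strsplit(seq_used, "")[[1]]
  lch <- idx$chars

  ## anchors -> blocks; trim chain overlaps first
  a <- ch$anchors
  if (nrow(a) > 1) {
    for (j in 2:nrow(a)) {
      trim <- max(0L, a$rstart[j - 1] + a$len[j - 1] - a$rstart[j],
                  a$lstart[j - 1] + a$len[j - 1] - a$lstart[j])
      if (trim > 0) {
        a$rstart[j] <- a$rstart[j] + trim
        a$lstart[j] <- a$lstart[j] + trim
        a$len[j] <- a$len[j] - trim
      }
    }
    a <- a[a$len > 0, , drop = FALSE]
  }
  blocks <- data.frame(read_start = a$rstart[1],
                       read_end = a$rstart[1] + a$len[1],
                       locus_start = a$lstart[1],
                       locus_end = a$lstart[1] + a$len[1],
                       matches = a$len[1])
  if (nrow(a) > 1) for (j in 2:nrow(a)) {
    i <- nrow(blocks)
    dr <- a$rstart[j] - blocks$read_end[i]
    dl <- a$lstart[j] - blocks$locus_end[i]
    if (dl - dr >= min_intron && dl <= max_intron && dr <= read_slack) {
      ## intron: split the unanchored read segment between the two blocks,
      ## scoring +1/-2 so repeats do not drag the boundary sideways
      m <- dr
      t_best <- 0L; best <- -Inf; gt_best <- FALSE
      ml_best <- 0L; mr_best <- 0L
      le <- blocks$locus_end[i]; ls <- a$lstart[j]
      r0 <- blocks$read_end[i]
      nL <- length(lch)
      for (t in 0:m) {
        ml <- if (t > 0) count_matches(rch[(r0 + 1):(r0 + t)],
                                       lch[(le + 1):(le + t)]) else 0L
        mr <- if (t < m) count_matches(rch[(r0 + t + 1):(r0 + m)],
                                       lch[(ls - (m - t) + 1):ls]) else 0L
        sc <- ml + mr
        ## equal splits (sequence repeats around the junction) break
        ## toward the placement framed by canonical GT..AG
        don <- le + t; acc <- ls - (m - t)
        gt <- don + 2 <= nL && acc - 2 >= 0 &&
          lch[don + 1L] == "G" && lch[don + 2L] == "T" &&
          lch[acc - 1L] == "A" && lch[acc] == "G"
        if (sc > best || (sc == best && gt && !gt_best)) {
          best <- sc; t_best <- t; gt_best <- gt
          ml_best <- ml; mr_best <- mr
        }
      }
      blocks$read_end[i] <- blocks$read_end[i] + t_best
      blocks$locus_end[i] <- blocks$locus_end[i] + t_best
      blocks$matches[i] <- blocks$matches[i] + ml_best
      blocks <- rbind(blocks, data.frame(
        read_start = a$rstart[j] - (dr - t_best),
        read_end = a$rstart[j] + a$len[j],
        locus_start = a$lstart[j] - (dr - t_best),
        locus_end = a$lstart[j] + a$len[j],
        matches = a$len[j] + mr_best))
    } else {
      ## same block: small indel / unanchored stretch
      blocks$read_end[i] <- a$rstart[j] + a$len[j]
      blocks$locus_end[i] <- a$lstart[j] + a$len[j]
      blocks$matches[i] <- blocks$matches[i] + a$len[j]
    }
  }

  ## terminal extensions (adapters/barcodes simply stop extending)
  b1 <- 1L; bn <- nrow(blocks)
  nl <- if (blocks$read_start[b1] > 0 && blocks$locus_start[b1] > 0) {
    xdrop_extend(rev(rch[seq_len(blocks$read_start[b1])]),
                 rev(lch[seq_len(blocks$locus_start[b1])]))
  } else c(len = 0L, matches = 0L)
  blocks$read_start[b1] <- blocks$read_start[b1] - nl["len"]
  blocks$locus_start[b1] <- blocks$locus_start[b1] - nl["len"]
  blocks$matches[b1] <- blocks$matches[b1] + nl["matches"]
  nr <- if (blocks$read_end[bn] < L && blocks$locus_end[bn] < length(lch)) {
    xdrop_extend(rch[(blocks$read_end[bn] + 1):L],
                 lch[(blocks$locus_end[bn] + 1):length(lch)])
  } else c(len = 0L, matches = 0L)
  blocks$read_end[bn] <- blocks$read_end[bn] + nr["len"]
  blocks$locus_end[bn] <- blocks$locus_end[bn] + nr["len"]
  blocks$matches[bn] <- blocks$matches[bn] + nr["matches"]

  identity <- sum(blocks$matches) / L
  if (identity < reject_identity)
    return(structure(list(), class = "alignment_rejection",
                     reason = sprintf("low_identity:%.3f", identity)))
  aln <- structure(list(read_id = NA_character_, orientation = orient,
                        blocks = blocks, identity = identity,
                        score = ch$score, read_seq = seq_used),
                   class = "read_alignment")
  aln$introns <- intron_dinucleotides(aln, idx$locus)
  aln
}

intron_dinucleotides <- function(aln, locus) {
  b <- aln$blocks
  if (nrow(b) < 2) {
    return(data.frame(donor = character(0), acceptor = character(0)))
  }
  don <- substring(locus$sequence, b$locus_end[-nrow(b)] + 1L,
                   b$locus_end[-nrow(b)] + 2L)
  acc <- substring(locus$sequence, b$locus_start[-1] - 1L, b$locus_start[-1])
  data.frame(donor = don, acceptor = acc, stringsAsFactors = FALSE)
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("<read_alignment> %s: %d block(s), identity %.3f, %s\n",
              x$read_id %||% "?", nrow(x$blocks), x$identity, x$orientation))
  invisible(x)
}

#' Align a whole read set
#'
#' @param reads A `read_set` (oriented forward or not; both orientations are
#'   tried per read).
#' @param locus A `gene_locus` or a prebuilt [locus_index()].
#' @param k Seed length.
#' @inheritParams align_read
#' @param refine Refine splice boundaries toward GT-AG (see
#'   [refine_splice_boundaries()]).
#' @return A list: `alignments` (named list of `read_alignment`) and
#'   `rejected` (data frame read_id, reason).
#' @export
align_reads <- function(reads, locus, k = 13, min_intron = 20,
                        max_intron = Inf, band = 16, reject_identity = 0.66,
                        refine = TRUE, window = 10) {
  idx <- if (inherits(locus, "locus_index")) locus else locus_index(locus, k)
  out <- vector("list", nrow(reads))
  rej <- list()
  for (i in seq_len(nrow(reads))) {
    a <- align_read(reads$sequence[i], idx, min_intron, max_intron, band,
                    reject_identity)
    if (inherits(a, "alignment_rejection")) {
      rej[[length(rej) + 1]] <- data.frame(read_id = reads$read_id[i],
                                           reason = attr(a, "reason"))
    } else {
      a$read_id <- reads$read_id[i]
      if (refine && nrow(a$blocks) > 1)
        a <- refine_splice_boundaries(a, idx$locus, window = window)
      out[[i]] <- a
    }
  }
  keep <- !vapply(out, is.null, logical(1))
  alignments <- out[keep]
  names(alignments) <- vapply(alignments, `[[`, character(1), "read_id")
  list(alignments = alignments,
       rejected = if (length(rej)) do.call(rbind, rej)
                  else data.frame(read_id = character(0), reason = character(0)))
}

#' Refine splice boundaries toward canonical GT-AG
#'
#' Each intron's donor/acceptor pair is re-placed by scoring every joint
#' shift `t` within `+/-window` nt combined with a small intron-length
#' adjustment `d` in `+/-2` nt (which absorbs a single-base indel sitting
#' next to the junction, the situation in which a sequence repeat
#' otherwise pins the boundary at the wrong copy).  The placement
#' maximises matches over the surrounding window; equal scores break
#' toward the GT..AG-restoring placement, then the smaller length
#' adjustment, then leftmost.  When no placement restores GT..AG the
#' boundary keeps the best-scoring position and the dinucleotides are
#' recorded as found.
#'
#' @param aln A `read_alignment` with at least one intron.
#' @param locus The `gene_locus` it was aligned to.
#' @param window Maximum shift in nt.
#' @return The refined `read_alignment`.
#' @export
refine_splice_boundaries <- function(aln, locus, window = 10) {
  b <- aln$blocks
  if (nrow(b) < 2) return(aln)
  rch <- strsplit(aln$read_seq, "")[[1]]
  lch <- strsplit(locus$sequence, "")[[1]]
  nL <- length(lch)
  K <- window + 6L
  for (i in seq_len(nrow(b) - 1L)) {
    r <- b$read_end[i]          # read split (0-based exclusive end of donor)
    le <- b$locus_end[i]
    ls <- b$locus_start[i + 1]
    tmax <- min(window, b$read_end[i + 1] - 1L - r)
    tmin <- -min(window, r - b$read_start[i] - 1L)
    if (tmax < tmin) next
    u <- (r - K + 1L):(r + K)   # 1-based read positions around the split
    u <- u[u >= 1 & u <= length(rch)]
    don_lp <- le + u - r        # 1-based locus position on the donor side
    don_ok <- don_lp >= 1 & don_lp <= nL
    don_match <- don_ok & (rch[u] == lch[pmax(don_lp, 1L)])
    best <- NULL
    for (d in -2:2) {
      acc_lp <- ls + d + u - r
      acc_ok <- acc_lp >= 1 & acc_lp <= nL
      acc_match <- acc_ok & (rch[u] == lch[pmax(acc_lp, 1L)])
      cum_don <- cumsum(don_match)
      cum_acc_tail <- rev(cumsum(rev(acc_match)))
      for (t in tmin:tmax) {
        split_idx <- match(r + t, u)       # last donor-side position
        if (is.na(split_idx) && r + t < u[1]) split_idx <- 0L
        if (is.na(split_idx)) next
        sc <- (if (split_idx > 0) cum_don[split_idx] else 0L) +
          (if (split_idx < length(u)) cum_acc_tail[split_idx + 1L] else 0L)
        le2 <- le + t
        ls2 <- ls + t + d
        if (ls2 - le2 < 1 || le2 + 2 > nL || ls2 - 2 < 0) next
        gt <- lch[le2 + 1L] == "G" && lch[le2 + 2L] == "T" &&
          lch[ls2 - 1L] == "A" && lch[ls2] == "G"
        cand <- c(sc = sc, gt = gt, d = d, t = t)
        ## ties: GT-AG-restoring first, then the smallest intron-length
        ## adjustment, then the smallest movement, then leftmost
        if (is.null(best) ||
            sc > best["sc"] ||
            (sc == best["sc"] && gt && !best["gt"]) ||
            (sc == best["sc"] && gt == best["gt"] &&
             abs(d) < abs(best["d"])) ||
            (sc == best["sc"] && gt == best["gt"] &&
             abs(d) == abs(best["d"]) && abs(t) < abs(best["t"])) ||
            (sc == best["sc"] && gt == best["gt"] &&
             abs(d) == abs(best["d"]) && abs(t) == abs(best["t"]) &&
             t < best["t"]))
          best <- cand
      }
    }
    if (!is.null(best) && (best["t"] != 0 || best["d"] != 0)) {
      t <- best[["t"]]; d <- best[["d"]]
      b$read_end[i] <- r + t
      b$locus_end[i] <- le + t
      b$read_start[i + 1] <- r + t
      b$locus_start[i + 1] <- ls + t + d
    }
  }
  aln$blocks <- b
  aln$introns <- intron_dinucleotides(aln, locus)
  aln
}

#' Export alignments to BED12
#'
#' @param alignments List of `read_alignment` (as from [align_reads()]).
#' @param locus The `gene_locus`.
#' @param path Output file.
#' @export
write_alignments_bed12 <- function(alignments, locus, path) {
  rows <- lapply(alignments, function(a) {
    b <- a$blocks
    cs <- min(b$locus_start); ce <- max(b$locus_end)
    data.frame(chrom = locus$name, start = cs, end = ce, name = a$read_id,
               score = 0L, strand = if (a$orientation == "forward") "+" else "-",
               thickStart = cs, thickEnd = ce, rgb = "0",
               blockCount = nrow(b),
               blockSizes = paste0(paste(b$locus_end - b$locus_start,
                                         collapse = ","), ","),
               blockStarts = paste0(paste(b$locus_start - cs, collapse = ","), ","))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import externally produced spliced alignments from BED12
#'
#' Blocks are taken verbatim; identities are recomputed by ends-free global
#' alignment of each read against its spliced block reference.
#'
#' @param path BED12 file whose names match read ids.
#' @param reads The `read_set` the names refer to.
#' @param locus The `gene_locus`.
#' @return A named list of `read_alignment`.
#' @export
import_alignments <- function(path, reads, locus) {
  recs <- read_bed12_blocks(path)
  ids <- vapply(recs, `[[`, character(1), "name")
  missing <- setdiff(ids, reads$read_id)
  if (length(missing) > 0)
    stop("unknown read id(s) in ", path, ": ", paste(missing, collapse = ", "))
  mat <- nuc_matrix()
  out <- lapply(recs, function(rec) {
    b <- rec$blocks
    blocks <- data.frame(read_start = NA_integer_, read_end = NA_integer_,
                         locus_start = b$locus_start, locus_end = b$locus_end,
                         matches = NA_integer_)
    ref <- paste(substring(locus$sequence, b$locus_start + 1L, b$locus_end),
                 collapse = "")
    rseq <- reads$sequence[match(rec$name, reads$read_id)]
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(rseq), Biostrings::DNAString(ref),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = 1, gapExtension = 1)
    aln <- structure(list(read_id = rec$name, orientation = "forward",
                          blocks = blocks,
                          identity = Biostrings::nmatch(pa) / nchar(rseq),
                          score = Biostrings::score(pa), read_seq = rseq),
                     class = "read_alignment")
    aln$introns <- intron_dinucleotides(aln, locus)
    aln
  })
  names(out) <- ids
  out
}
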