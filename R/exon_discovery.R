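## Exon catalog construction from the union of read alignments: boundary
## clustering with modal consensus, alternative-acceptor-aware candidate
## splitting, GT-AG validation and genomic-order naming.

new_exon_catalog <- function(df) {
  stopifnot(all(c("name", "start", "end") %in% names(df)))
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$name)) stop("exon names must be unique")
  class(df) <- c("exon_catalog", "data.frame")
  df
}

#' @export
print.exon_catalog <- function(x, ...) {
  cat(sprintf("<exon_catalog> %d exons in %d groups\n",
              nrow(x), length(unique(x$group))))
  print(as.data.frame(x))
  invisible(x)
}

#' Collect candidate exon intervals from alignments
#'
#' Block edges are clustered (single linkage; a new cluster starts when the
#' gap between successive distinct edge values exceeds `tol`) and each
#' cluster is replaced by its modal value (ties toward the smaller
#' coordinate).  A candidate exon is a (consensus start, consensus end)
#' pair observed jointly in at least `min_support` reads.  Candidates
#' sharing a donor (end) but differing in acceptor (start) by more than
#' `tol` remain separate — this is what distinguishes alternative 3'
#' splice-site variants from boundary noise.
#'
#' @param alignments List of `read_alignment`.
#' @param tol Boundary clustering tolerance (nt).
#' @param min_support Minimum reads jointly supporting a candidate.  When
#'   `locus` is supplied the threshold applies to *confident* support:
#'   blocks whose first and last `conf_width` bases match the locus
#'   exactly.  Sequencing errors sitting next to a junction are exactly
#'   what displaces a boundary, so displaced-boundary artifacts have
#'   near-zero confident support while genuinely rare exon variants keep
#'   most of theirs.
#' @param locus Optional `gene_locus` enabling confident-support counting.
#' @param conf_width Bases checked on each side for confident support.
#' @return Data frame with `start`, `end`, `support`, `conf_support`.
#' @export
collect_boundaries <- function(alignments, tol = 3, min_support = 1,
                               locus = NULL, conf_width = 8) {
  stopifnot(length(alignments) >= 1)
  lch <- if (!is.null(locus)) strsplit(locus$sequence, "")[[1]]
  blocks <- do.call(rbind, lapply(alignments, function(a) {
    b <- a$blocks
    if (is.null(locus) || is.null(a$read_seq) ||
        anyNA(b$read_start)) {
      b$clean <- TRUE
      return(b[, c("locus_start", "locus_end", "clean")])
    }
    rch <- strsplit(a$read_seq, "")[[1]]
    b$clean <- vapply(seq_len(nrow(b)), function(i) {
      w <- min(conf_width, b$read_end[i] - b$read_start[i])
      rs <- b$read_start[i]; ls0 <- b$locus_start[i]
      re <- b$read_end[i]; le <- b$locus_end[i]
      if (ls0 + w > length(lch) || le > length(lch)) return(FALSE)
      all(rch[(rs + 1):(rs + w)] == lch[(ls0 + 1):(ls0 + w)]) &&
        all(rch[(re - w + 1):re] == lch[(le - w + 1):le])
    }, logical(1))
    b[, c("locus_start", "locus_end", "clean")]
  }))
  starts <- blocks$locus_start
  ends <- blocks$locus_end
  cs <- cluster_consensus(starts, tol)
  ce <- cluster_consensus(ends, tol)
  key <- paste(cs[as.character(starts)], ce[as.character(ends)])
  tab <- table(key)
  conf <- tapply(blocks$clean, key, sum)[names(tab)]
  parts <- do.call(rbind, strsplit(names(tab), " "))
  cand <- data.frame(start = as.integer(parts[, 1]),
                     end = as.integer(parts[, 2]),
                     support = as.integer(tab),
                     conf_support = as.integer(conf))
  basis <- if (is.null(locus)) cand$support else cand$conf_support
  cand <- cand[basis >= min_support, , drop = FALSE]
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

## Map each observed edge value to its cluster's modal consensus.
## Peak claiming rather than single linkage: the strongest remaining value
## (ties toward the smaller coordinate) claims everything within +/- tol,
## so two true boundaries further than tol apart can never chain-merge
## through noisy intermediate values.
cluster_consensus <- function(values, tol) {
  tab <- table(values)
  v <- as.integer(names(tab))
  n <- as.integer(tab)
  out <- integer(length(v))
  names(out) <- as.character(v)
  remaining <- rep(TRUE, length(v))
  while (any(remaining)) {
    ii <- which(remaining)
    peak <- ii[order(-n[ii], v[ii])][1]
    claim <- ii[abs(v[ii] - v[peak]) <= tol]
    out[claim] <- v[peak]
    remaining[claim] <- FALSE
  }
  out
}

#' Validate candidate exons at their splice sites
#'
#' Internal candidates are retained iff the two locus bases immediately
#' upstream read `AG` (acceptor) and the two immediately downstream read
#' `GT` (donor) on the transcribed strand.  The first exon (minimal start)
#' is checked only on its donor side, the last (maximal end) only on its
#' acceptor side; the unchecked flags are NA.  Retained exons are named
#' `E1..En` in genomic order; acceptor variants sharing a donor get
#' suffixes `a`, `b`, ... by increasing start.
#'
#' @param candidates Data frame from [collect_boundaries()].
#' @param locus The `gene_locus`.
#' @param dominance Relative-support floor for boundary variants: a
#'   candidate sharing its start (or end) with another candidate of at
#'   least `1/dominance` times its support is excluded as boundary noise
#'   (`minor_boundary_variant`) before splice-site checking.  Sequencing
#'   errors next to a junction scatter a few percent of reads onto
#'   alternative GT/AG positions, so boundary variants below `dominance`
#'   of their strongest sibling cannot be told apart from that noise at
#'   the error rates this pipeline targets; the default 0.05 is the
#'   resulting identifiability floor.  Set to 0 to keep everything.
#' @return A list: `catalog` (`exon_catalog`) and `excluded` (data frame
#'   with a `reason` per dropped candidate).
#' @export
validate_splice_sites <- function(candidates, locus, dominance = 0.05) {
  n_locus <- nchar(locus$sequence)
  cand <- candidates[order(candidates$start, candidates$end), , drop = FALSE]
  if (dominance > 0 && nrow(cand) > 1) {
    ## compare confident supports when available: reads that displace a
    ## boundary carry errors there and lose confidence, genuine variant
    ## reads keep it, so the ratio sharpens in the direction that matters
    sup <- if ("conf_support" %in% names(cand) && !anyNA(cand$conf_support))
      cand$conf_support else cand$support
    max_by_start <- tapply(sup, cand$start, max)[as.character(cand$start)]
    max_by_end <- tapply(sup, cand$end, max)[as.character(cand$end)]
    minor <- sup < dominance * pmax(max_by_start, max_by_end)
    dropped <- cbind(cand[minor, , drop = FALSE],
                     reason = rep("minor_boundary_variant", sum(minor)))
    cand <- cand[!minor, , drop = FALSE]
  } else {
    dropped <- cbind(cand[integer(0), , drop = FALSE], reason = character(0))
  }
  first_start <- min(cand$start)
  last_end <- max(cand$end)
  acc <- substring(locus$sequence, cand$start - 1L, cand$start)
  don <- substring(locus$sequence, cand$end + 1L, cand$end + 2L)
  keep <- rep(TRUE, nrow(cand))
  reason <- rep(NA_character_, nrow(cand))
  acceptor_ok <- acc == "AG"
  donor_ok <- don == "GT"
  is_first <- cand$start == first_start
  is_last <- cand$end == last_end
  out_of_bounds <- cand$start < 0 | cand$end > n_locus
  acceptor_ok[is_first] <- NA
  donor_ok[is_last] <- NA
  for (i in seq_len(nrow(cand))) {
    if (out_of_bounds[i]) {
      keep[i] <- FALSE; reason[i] <- "out_of_bounds"
    } else if (isFALSE(acceptor_ok[i]) && isFALSE(donor_ok[i])) {
      keep[i] <- FALSE; reason[i] <- "acceptor_fail+donor_fail"
    } else if (isFALSE(acceptor_ok[i])) {
      keep[i] <- FALSE; reason[i] <- "acceptor_fail"
    } else if (isFALSE(donor_ok[i])) {
      keep[i] <- FALSE; reason[i] <- "donor_fail"
    }
  }
  excluded <- rbind(dropped,
                    cbind(cand[!keep, , drop = FALSE],
                          reason = reason[!keep]))
  ret <- cand[keep, , drop = FALSE]
  if (nrow(ret) == 0) stop("no candidate exon passed splice-site validation")
  ret$acceptor_ok <- acceptor_ok[keep]
  ret$donor_ok <- donor_ok[keep]
  ## group by shared donor coordinate; number groups in genomic order
  grp_of_end <- integer(0)
  grp_ids <- character(nrow(ret))
  next_id <- 0L
  ends_seen <- integer(0)
  for (i in seq_len(nrow(ret))) {
    hit <- match(ret$end[i], ends_seen)
    if (is.na(hit)) {
      next_id <- next_id + 1L
      ends_seen <- c(ends_seen, ret$end[i])
      grp_of_end <- c(grp_of_end, next_id)
      grp_ids[i] <- sprintf("E%d", next_id)
    } else {
      grp_ids[i] <- sprintf("E%d", grp_of_end[hit])
    }
  }
  ret$group <- grp_ids
  name <- grp_ids
  for (g in unique(grp_ids)) {
    ii <- which(grp_ids == g)
    if (length(ii) > 1) {
      ii <- ii[order(ret$start[ii])]
      name[ii] <- paste0(g, letters[seq_along(ii)])
    }
  }
  ret$name <- name
  list(catalog = new_exon_catalog(
         ret[, c("name", "start", "end", "acceptor_ok", "donor_ok",
                 "support", "group")]),
       excluded = excluded)
}

#' Extract exon sequences from the locus
#'
#' @param catalog An `exon_catalog`.
#' @param locus The `gene_locus`.
#' @return Named character vector, one DNA string per exon.
#' @export
exon_sequences <- function(catalog, locus) {
  out <- substring(locus$sequence, catalog$start + 1L, catalog$end)
  names(out) <- catalog$name
  out
}

#' Discover the exon catalog from aligned reads
#'
#' Convenience wrapper: [collect_boundaries()] then
#' [validate_splice_sites()].
#'
#' @inheritParams collect_boundaries
#' @inheritParams validate_splice_sites
#' @export
discover_exons <- function(alignments, locus, tol = 3, min_support = 1,
                           dominance = 0.05) {
  cand <- collect_boundaries(alignments, tol, min_support, locus = locus)
  validate_splice_sites(cand, locus, dominance)
}
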