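## Exon-exon junctions: enumeration from transcript barcodes, minimal
## uniqueness overhangs, the artificial junction reference, and short-read
## support counting.

#' Enumerate exon-exon junctions from transcript clusters
#'
#' One junction per ordered adjacent exon pair occurring in at least one
#' transcript barcode; `long_read_count` sums the counts of the supporting
#' transcripts.
#'
#' @param clusters A `transcript_clusters` object.
#' @return Data frame: `junction_id` (`"Ei-Ej"`), `donor_exon`,
#'   `acceptor_exon`, `supporting_transcripts` (comma-joined),
#'   `n_transcripts`, `long_read_count`.
#' @export
enumerate_junctions <- function(clusters) {
  cl <- clusters$clusters
  stopifnot(nrow(cl) > 0)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cl))) {
    ex <- strsplit(cl$barcode[i], "|", fixed = TRUE)[[1]]
    if (length(ex) < 2) next
    for (j in seq_len(length(ex) - 1L)) {
      id <- paste0(ex[j], "-", ex[j + 1])
      cur <- if (!is.null(acc[[id]])) acc[[id]] else
        list(donor = ex[j], acceptor = ex[j + 1],
             transcripts = character(0), count = 0L)
      cur$transcripts <- c(cur$transcripts, cl$name[i])
      cur$count <- cur$count + cl$total_count[i]
      acc[[id]] <- cur
    }
  }
  ids <- ls(acc)
  out <- do.call(rbind, lapply(ids, function(id) {
    x <- acc[[id]]
    data.frame(junction_id = id, donor_exon = x$donor,
               acceptor_exon = x$acceptor,
               supporting_transcripts = paste(x$transcripts, collapse = ","),
               n_transcripts = length(x$transcripts),
               long_read_count = x$count, stringsAsFactors = FALSE)
  }))
  out[order(out$junction_id), , drop = FALSE]
}

#' Minimal uniqueness overhangs per junction
#'
#' For each junction, the smallest overhang pair `(a, b)` (by sum, then by
#' `a`) such that `suffix_a(donor exon) + prefix_b(acceptor exon)` occurs
#' exactly once across the junction context set — each junction's flanking
#' string taken with `a+b` nt of context on both sides, so occurrences
#' straddling any junction at any offset are caught — and never occurs
#' inside any single exon sequence.  The global pair `(A, B)` is the
#' elementwise maximum over junctions.
#'
#' @param junctions Data frame from [enumerate_junctions()].
#' @param exon_seqs Named exon sequences.
#' @param max_overhang Search bound per side.
#' @return A list: `per_junction` (junction_id, a, b, discriminable) and
#'   `global` (`c(A, B)`, NA if any junction is non-discriminable).
#' @export
min_unique_overhangs <- function(junctions, exon_seqs, max_overhang = 30) {
  ctx <- function(i, m) {
    d <- exon_seqs[[junctions$donor_exon[i]]]
    a <- exon_seqs[[junctions$acceptor_exon[i]]]
    paste0(substring(d, max(1L, nchar(d) - m + 1L), nchar(d)),
           substring(a, 1L, min(m, nchar(a))))
  }
  n <- nrow(junctions)
  res <- data.frame(junction_id = junctions$junction_id,
                    a = NA_integer_, b = NA_integer_,
                    discriminable = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    don <- exon_seqs[[junctions$donor_exon[i]]]
    acp <- exon_seqs[[junctions$acceptor_exon[i]]]
    found <- FALSE
    for (s in 2:(2 * max_overhang)) {
      contexts <- vapply(seq_len(n), ctx, character(1), m = s)
      for (a in seq_len(s - 1L)) {
        b <- s - a
        if (a > nchar(don) || b > nchar(acp) ||
            a > max_overhang || b > max_overhang) next
        probe <- paste0(substring(don, nchar(don) - a + 1L, nchar(don)),
                        substring(acp, 1L, b))
        n_occ <- sum(vapply(contexts, count_occurrences, integer(1),
                            probe = probe))
        in_exon <- any(vapply(exon_seqs, function(e)
          count_occurrences(e, probe) > 0, logical(1)))
        if (n_occ == 1L && !in_exon) {
          res$a[i] <- a; res$b[i] <- b; res$discriminable[i] <- TRUE
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  glob <- if (all(res$discriminable))
    c(A = max(res$a), B = max(res$b)) else c(A = NA_integer_, B = NA_integer_)
  list(per_junction = res, global = glob)
}

## Overlapping occurrence count of probe in subject (plain strings).
count_occurrences <- function(subject, probe) {
  if (nchar(probe) > nchar(subject)) return(0L)
  n <- 0L
  from <- 1L
  repeat {
    hit <- regexpr(probe, substring(subject, from), fixed = TRUE)
    if (hit == -1L) break
    n <- n + 1L
    from <- from + hit  # advance one past the match start: overlapping
  }
  n
}

#' Build the artificial junction reference
#'
#' One FASTA-style record per junction: `suffix_{o5}(donor) +
#' prefix_{o3}(acceptor)`.  Records whose flanking exon is shorter than the
#' requested overhang are truncated and flagged.
#'
#' @param junctions Data frame from [enumerate_junctions()].
#' @param exon_seqs Named exon sequences.
#' @param overhang_5p,overhang_3p Overhang lengths (defaults 9 and 6 nt).
#' @param path Optional FASTA output path.
#' @return Data frame `junction_id`, `sequence`, `junction_point` (nt of
#'   donor sequence in the record), `truncated`.
#' @export
build_junction_reference <- function(junctions, exon_seqs,
                                     overhang_5p = 9, overhang_3p = 6,
                                     path = NULL) {
  recs <- do.call(rbind, lapply(seq_len(nrow(junctions)), function(i) {
    d <- exon_seqs[[junctions$donor_exon[i]]]
    a <- exon_seqs[[junctions$acceptor_exon[i]]]
    o5 <- min(overhang_5p, nchar(d))
    o3 <- min(overhang_3p, nchar(a))
    data.frame(junction_id = junctions$junction_id[i],
               sequence = paste0(substring(d, nchar(d) - o5 + 1L, nchar(d)),
                                 substring(a, 1L, o3)),
               junction_point = o5,
               truncated = o5 < overhang_5p || o3 < overhang_3p,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    s <- Biostrings::DNAStringSet(recs$sequence)
    names(s) <- recs$junction_id
    Biostrings::writeXStringSet(s, path)
  }
  recs
}

#' Count short-read support per junction
#'
#' A read supports a junction iff it contains a contiguous match to the
#' junction record covering the junction point with at least
#' `min_overhang_5p` / `min_overhang_3p` nt on either side and total
#' matched length at least `min_overlap`.  Each read counts at most once
#' per junction; junctions without support are reported with zero.
#'
#' @param short_reads A `read_set` of short reads.
#' @param junction_ref Data frame from [build_junction_reference()].
#' @param min_overlap Minimum total matched length (default 15).
#' @param min_overhang_5p,min_overhang_3p Per-side minima (defaults 9, 6).
#' @param max_mismatch Mismatches allowed in the core match (default 0).
#' @return Data frame `junction_id`, `short_read_count`.
#' @export
count_short_read_support <- function(short_reads, junction_ref,
                                     min_overlap = 15,
                                     min_overhang_5p = 9,
                                     min_overhang_3p = 6,
                                     max_mismatch = 0) {
  reads <- Biostrings::DNAStringSet(short_reads$sequence)
  counts <- integer(nrow(junction_ref))
  for (i in seq_len(nrow(junction_ref))) {
    rec <- junction_ref$sequence[i]
    jp <- junction_ref$junction_point[i]
    o5 <- min(min_overhang_5p, jp)
    o3 <- min(min_overhang_3p, nchar(rec) - jp)
    core <- substring(rec, jp - o5 + 1L, jp + o3)
    if (nchar(core) < min_overlap) {
      need <- min_overlap - nchar(core)
      ## grow symmetrically within the record to reach min_overlap
      ext5 <- min(jp - o5, ceiling(need / 2))
      ext3 <- min(nchar(rec) - jp - o3, need - ext5)
      ext5 <- min(jp - o5, need - ext3)
      core <- substring(rec, jp - o5 - ext5 + 1L, jp + o3 + ext3)
      if (nchar(core) < min_overlap) { counts[i] <- 0L; next }
    }
    hits <- Biostrings::vcountPattern(core, reads,
                                      max.mismatch = max_mismatch,
                                      fixed = TRUE)
    counts[i] <- sum(hits > 0)
  }
  data.frame(junction_id = junction_ref$junction_id,
             short_read_count = counts, stringsAsFactors = FALSE)
}

#' Report on a queried list of exon pairs
#'
#' Screens given exon pairs (e.g. candidate pathological junctions)
#' against the discovered junction set: presence, supporting transcripts,
#' and the percentage of total expression carried by those transcripts.
#'
#' @param pairs Data frame with columns `donor_exon`, `acceptor_exon`.
#' @param junctions Data frame from [enumerate_junctions()].
#' @param clusters The `transcript_clusters` the junctions came from.
#' @return Data frame with presence, transcript count and expression share.
#' @export
query_junctions <- function(pairs, junctions, clusters) {
  total <- sum(clusters$clusters$total_count)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    id <- paste0(pairs$donor_exon[i], "-", pairs$acceptor_exon[i])
    j <- junctions[junctions$junction_id == id, , drop = FALSE]
    if (nrow(j) == 0) {
      data.frame(junction_id = id, present = FALSE, n_transcripts = 0L,
                 long_read_count = 0L, pct_expression = 0,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(junction_id = id, present = TRUE,
                 n_transcripts = j$n_transcripts,
                 long_read_count = j$long_read_count,
                 pct_expression = 100 * j$long_read_count / total,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
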