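## Readers/writers for on-disk artifacts plus barcode demultiplexing.
##
## Conventions: all coordinates are 0-based half-open internally and in BED
## output; sequences are uppercase A/C/G/T/N on the transcribed strand.

#' Construct a gene locus
#'
#' A single genomic locus holding the reference sequence the pipeline aligns
#' to.  The stored sequence is the transcribed strand of the amplicon, so
#' splice sites read GT..AG directly off it.
#'
#' @param name Locus name (used as the BED chromosome field).
#' @param sequence DNA string; lowercase and U are normalised.
#' @param strand `"+"` or `"-"`: strand of the stored sequence relative to
#'   the reference genome it was taken from (bookkeeping only; all
#'   coordinates are on the stored sequence).
#' @return An object of class `gene_locus`.
#' @export
gene_locus <- function(name, sequence, strand = "+") {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0, strand %in% c("+", "-"))
  sequence <- normalize_seq(sequence)
  check_alphabet(sequence, "locus sequence")
  structure(list(name = name, sequence = sequence, strand = strand,
                 coordinate_system = "0-based, half-open"),
            class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s: %d nt, strand %s (%s)\n",
              x$name, nchar(x$sequence), x$strand, x$coordinate_system))
  invisible(x)
}

#' Read a locus from a FASTA file
#'
#' @param path FASTA file with a single record.
#' @param strand Strand of the stored sequence (see [gene_locus()]).
#' @return A `gene_locus`.
#' @export
read_locus_fasta <- function(path, strand = "+") {
  s <- Biostrings::readBStringSet(path)
  if (length(s) != 1L)
    stop("locus FASTA must contain exactly one record, found ", length(s))
  gene_locus(sub("\\s.*$", "", names(s)[1]), as.character(s[[1]]), strand)
}

#' @rdname read_locus_fasta
#' @param locus A `gene_locus` to write.
#' @export
write_locus_fasta <- function(locus, path) {
  s <- Biostrings::DNAStringSet(locus$sequence)
  names(s) <- locus$name
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read long or short reads from FASTA/FASTQ
#'
#' The format is auto-detected from the first record delimiter (`>` FASTA,
#' `@` FASTQ).  Sequences are uppercased and U is converted to T.  Qualities
#' are kept as Phred+33 strings and are present iff the input is FASTQ.
#'
#' @param path Input file.
#' @return A data frame of class `read_set` with columns `read_id`,
#'   `sequence`, `qualities` (NA for FASTA), `sample_id`, `orientation`.
#' @export
read_fasta_or_fastq <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("cannot detect format of ", path,
                   ": first line starts with neither '>' nor '@'")
  s <- Biostrings::readBStringSet(path, format = fmt,
                                  with.qualities = (fmt == "fastq"))
  seqs <- normalize_seq(as.character(s))
  ids <- sub("\\s.*$", "", names(s))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0)
    stop("format error at record ", empty[1], ": id without sequence")
  check_alphabet(seqs, "read record")
  quals <- rep(NA_character_, length(s))
  if (fmt == "fastq") {
    quals <- tryCatch(as.character(S4Vectors::mcols(s)$qualities),
                      error = function(e) diagnose_fastq(path))
    bad <- which(nchar(quals) != nchar(seqs))
    if (length(bad) > 0) diagnose_fastq(path)
  }
  read_set(ids, seqs, quals)
}

## Locate the first malformed FASTQ record for an informative error.
diagnose_fastq <- function(path) {
  lines <- readLines(path)
  n_rec <- length(lines) %/% 4
  for (i in seq_len(n_rec)) {
    sq <- lines[4 * i - 2]
    qu <- lines[4 * i]
    if (nchar(sq) != nchar(qu))
      stop(sprintf(
        "format error at record %d: sequence length %d != quality length %d",
        i, nchar(sq), nchar(qu)))
  }
  stop("malformed FASTQ file: ", path)
}

read_set <- function(read_id, sequence, qualities = NA_character_,
                     sample_id = NA_character_, orientation = "unknown") {
  df <- data.frame(read_id = read_id, sequence = sequence,
                   qualities = qualities, sample_id = sample_id,
                   orientation = orientation, stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

#' Write reads to FASTQ or FASTA
#'
#' FASTQ is written when all records carry qualities, FASTA otherwise.
#'
#' @param reads A `read_set` data frame.
#' @param path Output file.
#' @export
write_reads <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- reads$read_id
  if (all(!is.na(reads$qualities))) {
    Biostrings::writeXStringSet(s, path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$qualities))
  } else {
    Biostrings::writeXStringSet(s, path)
  }
  invisible(path)
}

## ---- sample sheet ---------------------------------------------------------

#' Read or write a sample sheet
#'
#' TSV with header `sample_id`, `barcode_fwd`, `barcode_rev`, `metadata`;
#' metadata is a `key=value;key=value` string.
#'
#' @param path TSV file.
#' @return A data frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "barcode_fwd", "barcode_rev")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  if (!"metadata" %in% names(df)) df$metadata <- ""
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet A `sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("sample_ids must be unique")
  if (anyDuplicated(df$barcode_fwd) || anyDuplicated(df$barcode_rev))
    stop("barcodes must be unique within each side")
  bc <- c(df$barcode_fwd, df$barcode_rev)
  bc <- normalize_seq(bc)
  if (any(nchar(bc) < 6)) stop("barcodes must be at least 6 nt")
  check_alphabet(bc, "barcode", allow_n = FALSE)
  df$barcode_fwd <- normalize_seq(df$barcode_fwd)
  df$barcode_rev <- normalize_seq(df$barcode_rev)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Generate a multiplexing sample sheet
#'
#' Barcodes are drawn randomly with a minimum pairwise Hamming distance of
#' `min_dist` across all barcodes of both sides, so that demultiplexing at
#' the default mismatch tolerance is unambiguous.
#'
#' @param n_samples Number of samples.
#' @param barcode_len Barcode length (default 16, as in common long-read
#'   barcoding kits).
#' @param min_dist Minimum pairwise Hamming distance between barcodes.
#' @param seed Integer seed.
#' @param metadata Optional character vector (one `key=value;...` string per
#'   sample).
#' @return A `sample_sheet`.
#' @export
make_sample_sheet <- function(n_samples, barcode_len = 16, min_dist = 6,
                              seed = 1, metadata = NULL) {
  stopifnot(n_samples >= 1, barcode_len >= 6)
  with_seed(seed, {
    pool <- character(0)
    while (length(pool) < 2 * n_samples) {
      cand <- random_dna(barcode_len)
      ok <- all(vapply(pool, function(b) hamming(b, cand) >= min_dist, logical(1)))
      if (ok) pool <- c(pool, cand)
    }
    df <- data.frame(
      sample_id = sprintf("S%d", seq_len(n_samples)),
      barcode_fwd = pool[seq_len(n_samples)],
      barcode_rev = pool[n_samples + seq_len(n_samples)],
      metadata = metadata %||% "",
      stringsAsFactors = FALSE)
    validate_sample_sheet(df)
  })
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## ---- demultiplexing -------------------------------------------------------

#' Demultiplex reads by terminal barcodes
#'
#' Each read is scanned over its first and last `window` bases.  A forward
#' barcode at the 5' end or a reverse-complemented reverse barcode at the
#' 3' end indicates forward orientation; a reverse barcode at the 5' end
#' or a reverse-complemented forward barcode at the 3' end indicates
#' reverse orientation (the library layout is `bc_fwd + primer + cDNA +
#' rc(primer) + rc(bc_rev)`).  Matching tolerates `max_mismatch` edits
#' (substitutions or indels); N never counts as a match.  A read is
#' assigned when exactly one sample matches; reads matching two or more
#' samples are flagged `ambiguous`, reads matching none `unassigned`.
#'
#' @param reads A `read_set`.
#' @param sheet A `sample_sheet`.
#' @param max_mismatch Maximum Hamming mismatches allowed in a barcode hit.
#' @param window Number of bases at the read 5' end searched.
#' @return A list with `reads` (the input with `sample_id` and `orientation`
#'   filled; unassigned/ambiguous reads keep `sample_id` NA) and `report`
#'   (per-sample counts plus `ambiguous` and `unassigned` rows).
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 2, window = 100) {
  stopifnot(max_mismatch >= 0)
  n <- nrow(reads)
  len <- nchar(reads$sequence)
  prefix <- Biostrings::DNAStringSet(substr(reads$sequence, 1,
                                            pmin(len, window)))
  suffix <- Biostrings::DNAStringSet(substr(reads$sequence,
                                            pmax(1, len - window + 1), len))
  scan <- function(pattern, subjects) {
    Biostrings::vcountPattern(pattern, subjects,
                              max.mismatch = max_mismatch,
                              with.indels = TRUE, fixed = TRUE) > 0
  }
  hit_f <- matrix(FALSE, n, nrow(sheet))
  hit_r <- matrix(FALSE, n, nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    hit_f[, i] <- scan(sheet$barcode_fwd[i], prefix) |
      scan(revcomp(sheet$barcode_rev[i]), suffix)
    hit_r[, i] <- scan(sheet$barcode_rev[i], prefix) |
      scan(revcomp(sheet$barcode_fwd[i]), suffix)
  }
  any_hit <- hit_f | hit_r
  n_samples_hit <- rowSums(any_hit)
  status <- ifelse(n_samples_hit == 0, "unassigned",
                   ifelse(n_samples_hit > 1, "ambiguous", "assigned"))
  idx <- apply(any_hit, 1, function(z) if (sum(z) == 1) which(z) else NA_integer_)
  reads$sample_id <- ifelse(status == "assigned", sheet$sample_id[idx], NA_character_)
  ## ties between orientations of the same sample break toward forward
  reads$orientation <- ifelse(status != "assigned", "unknown",
                              ifelse(hit_f[cbind(seq_len(n), idx)],
                                     "forward", "reverse"))
  counts <- table(factor(reads$sample_id, levels = sheet$sample_id))
  report <- data.frame(
    category = c(sheet$sample_id, "ambiguous", "unassigned"),
    count = c(as.integer(counts), sum(status == "ambiguous"),
              sum(status == "unassigned")),
    stringsAsFactors = FALSE)
  list(reads = reads, report = report,
       status = status)
}

#' Orient demultiplexed reads to the forward strand
#'
#' Reverse-orientation reads are reverse-complemented (and their quality
#' strings reversed) so that downstream stages see all reads 5'->3' on the
#' transcribed strand.  Unassigned reads are dropped.
#'
#' @param reads A demultiplexed `read_set`.
#' @return A `read_set` with all orientations `"forward"`.
#' @export
orient_reads <- function(reads) {
  keep <- !is.na(reads$sample_id)
  reads <- reads[keep, , drop = FALSE]
  rev <- reads$orientation == "reverse"
  if (any(rev)) {
    reads$sequence[rev] <- revcomp(reads$sequence[rev])
    reads$qualities[rev] <- vapply(reads$qualities[rev], function(q) {
      if (is.na(q)) NA_character_
      else paste(rev(strsplit(q, "")[[1]]), collapse = "")
    }, character(1))
    reads$orientation[rev] <- "forward"
  }
  reads
}

## ---- BED / TSV writers ----------------------------------------------------

#' Write an exon catalog to BED
#'
#' BED4 (chrom, start, end, name), 0-based half-open.  Validation flags and
#' support are not representable in BED4; [read_exons_bed()] round-trips the
#' name and coordinates.
#'
#' @param catalog An `exon_catalog`.
#' @param path Output BED file.
#' @param chrom Chromosome/locus name for column 1.
#' @export
write_exons_bed <- function(catalog, path, chrom = "locus") {
  df <- as.data.frame(catalog)
  if (!identical(order(df$start, df$end), seq_len(nrow(df))))
    stop("exon catalog is not sorted by (start, end); refusing to write")
  out <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    name = df$name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_exons_bed
#' @return `read_exons_bed` returns a minimal `exon_catalog` (name, start,
#'   end; flags NA).
#' @export
read_exons_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  new_exon_catalog(data.frame(
    name = gr$name,
    start = BiocGenerics::start(gr) - 1L,  # back to 0-based
    end = BiocGenerics::end(gr),
    acceptor_ok = NA, donor_ok = NA, support = NA_integer_,
    group = NA_character_, stringsAsFactors = FALSE))
}

#' Write transcript models to BED12
#'
#' Each transcript cluster becomes one BED12 line whose blocks are its exon
#' chain on the locus; blockStarts/blockSizes reconstruct the chain exactly.
#'
#' @param clusters A `transcript_clusters` object.
#' @param locus The `gene_locus` (names column 1 and bounds the blocks).
#' @param path Output file.
#' @param catalog The `exon_catalog` that the cluster barcodes refer to.
#' @export
write_transcripts_bed12 <- function(clusters, locus, catalog, path) {
  rows <- lapply(seq_len(nrow(clusters$clusters)), function(i) {
    exons <- strsplit(clusters$clusters$barcode[i], "|", fixed = TRUE)[[1]]
    m <- catalog[match(exons, catalog$name), ]
    chromStart <- min(m$start)
    chromEnd <- max(m$end)
    data.frame(chrom = locus$name, start = chromStart, end = chromEnd,
               name = clusters$clusters$name[i],
               score = min(clusters$clusters$total_count[i], 1000L),
               strand = locus$strand,
               thickStart = chromStart, thickEnd = chromEnd, rgb = "0",
               blockCount = nrow(m),
               blockSizes = paste0(paste(m$end - m$start, collapse = ","), ","),
               blockStarts = paste0(paste(m$start - chromStart, collapse = ","), ","))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Parse a BED12 file into a list of block tables (0-based half-open).
read_bed12_blocks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    chromStart <- BiocGenerics::start(gr)[i] - 1L
    st <- chromStart + BiocGenerics::start(b) - 1L
    en <- chromStart + BiocGenerics::end(b)
    if (is.unsorted(st, strictly = TRUE))
      stop("format error in ", path, ": blockStarts not increasing for record ",
           gr$name[i])
    list(name = gr$name[i],
         blocks = data.frame(locus_start = st, locus_end = en))
  })
}

#' Write or read a transcript-by-sample count matrix
#'
#' TSV with transcripts as rows and samples as columns; integer cells.
#' The pair round-trips losslessly.
#'
#' @param counts Integer matrix with transcript rownames and sample colnames.
#' @param path TSV file.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(transcript = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
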