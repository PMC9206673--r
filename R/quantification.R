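## Per-sample transcript matrices, percentages, common-core/specific
## partitioning and per-exon usage normalised by total gene expression.

#' Build the transcript-by-sample count matrix
#'
#' @param clusters A `transcript_clusters` object.
#' @param sample_ids Optional sample ordering (defaults to the cluster
#'   count columns).
#' @return A `count_matrix` object: `counts` (integer matrix, transcripts
#'   ordered by global abundance), `percentages` (per-sample percent of
#'   total; NA with a warning for empty samples), `barcodes`.
#' @export
build_matrix <- function(clusters, sample_ids = NULL) {
  counts <- clusters$counts
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(counts))
    if (length(missing) > 0) {
      add <- matrix(0L, nrow(counts), length(missing),
                    dimnames = list(rownames(counts), missing))
      counts <- cbind(counts, add)
    }
    counts <- counts[, sample_ids, drop = FALSE]
  }
  counts <- counts[order(-rowSums(counts), rownames(counts)), , drop = FALSE]
  totals <- colSums(counts)
  if (any(totals == 0))
    warning("sample(s) with zero reads: ",
            paste(colnames(counts)[totals == 0], collapse = ", "),
            "; percentages reported as NA")
  pct <- sweep(counts, 2, totals, "/") * 100
  pct[, totals == 0] <- NA_real_
  bc <- clusters$clusters$barcode[match(rownames(counts),
                                        clusters$clusters$name)]
  names(bc) <- rownames(counts)
  structure(list(counts = counts, percentages = pct, barcodes = bc),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(utils::head(x$counts))
  invisible(x)
}

#' Partition transcripts into common core, tissue-specific and shared-partial
#'
#' A transcript is *core* when detected (count >= `min_count`) in every
#' tissue, *specific* to tissue t when detected only in t, and
#' *shared-partial* otherwise; the three classes partition the transcript
#' set.
#'
#' @param matrix A `count_matrix`.
#' @param grouping Named character vector mapping sample ids to tissues.
#' @param min_count Detection threshold.
#' @return A list: `core` (names), `specific` (named list per tissue),
#'   `shared_partial` (names).
#' @export
core_and_specific <- function(matrix, grouping, min_count = 1) {
  counts <- matrix$counts
  tissues <- unique(unname(grouping[colnames(counts)]))
  stopifnot(length(tissues) >= 2)
  by_tissue <- vapply(tissues, function(t) {
    cols <- colnames(counts)[grouping[colnames(counts)] == t]
    rowSums(counts[, cols, drop = FALSE] >= min_count) > 0
  }, logical(nrow(counts)))
  n_detected <- rowSums(by_tissue)
  core <- rownames(counts)[n_detected == length(tissues)]
  specific <- lapply(tissues, function(t)
    rownames(counts)[n_detected == 1 & by_tissue[, t]])
  names(specific) <- tissues
  shared_partial <- rownames(counts)[n_detected > 1 &
                                     n_detected < length(tissues)]
  ## transcripts detected nowhere end up shared_partial = no; keep them out
  undetected <- rownames(counts)[n_detected == 0]
  list(core = core, specific = specific, shared_partial = shared_partial,
       undetected = undetected)
}

#' Per-exon usage normalised by total gene expression
#'
#' `usage(e, s)` is the fraction of sample `s`'s reads whose transcript
#' contains exon `e`; values lie in \[0, 1\].
#'
#' @param matrix A `count_matrix`.
#' @param catalog The `exon_catalog` (row order of the result).
#' @return Exon-by-sample numeric matrix.
#' @export
exon_usage <- function(matrix, catalog) {
  counts <- matrix$counts
  totals <- colSums(counts)
  membership <- vapply(catalog$name, function(e) {
    vapply(strsplit(matrix$barcodes[rownames(counts)], "|", fixed = TRUE),
           function(ex) e %in% ex, logical(1))
  }, logical(nrow(counts)))
  usage <- t(membership) %*% counts
  usage <- sweep(usage, 2, pmax(totals, 1L), "/")
  usage[, totals == 0] <- NA_real_
  rownames(usage) <- catalog$name
  usage
}
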