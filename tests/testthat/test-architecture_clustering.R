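small_annotation <- function(run = small_run()) {
  if (is.null(.fixture_cache$small_ann)) {
    ex <- discover_exons(run$al$alignments, run$gene$locus)
    es <- exon_sequences(ex$catalog, run$gene$locus)
    p <- annotation_params()
    ar <- run$oriented[run$oriented$read_id %in% names(run$al$alignments), ]
    ann <- annotate_exons(ar, es, ex$catalog, p, alignments = run$al$alignments)
    qc <- qc_against_theoretical(ar, ann$barcodes, es, p,
                                 alignments = run$al$alignments)
    .fixture_cache$small_ann <- list(ex = ex, es = es, p = p, ar = ar,
                                     ann = ann, qc = qc)
  }
  .fixture_cache$small_ann
}

test_that("zero-noise reads get their exact architecture barcode, including skipping", {
  run <- small_run()
  fx <- small_annotation(run)
  truth <- truth_barcodes(run$gene)
  m <- run$sim$manifest
  got <- fx$ann$barcodes[m$read_id]
  expect_true(all(!is.na(got)))
  expect_equal(unname(got), unname(truth[m$isoform]))
  ## skipping isoforms present by construction
  expect_true(any(lengths(strsplit(got, "|", fixed = TRUE)) <
                    nrow(run$gene$exons) - 1))
})

test_that("suffix acceptor variants resolve to the correct member", {
  run <- small_run()
  fx <- small_annotation(run)
  m <- run$sim$manifest
  truth <- truth_barcodes(run$gene)
  for (iso in names(run$gene$isoforms)) {
    ids <- m$read_id[m$isoform == iso]
    vars <- grep("^E3", run$gene$isoforms[[iso]], value = TRUE)
    if (length(vars) == 0) next
    in_bc <- vapply(strsplit(fx$ann$barcodes[ids], "|", fixed = TRUE),
                    function(e) grep("^E3", e, value = TRUE)[1], character(1))
    expect_true(all(in_bc == vars))
  }
  ## hit table: both variants score, the longer full variant scores higher
  ## on a read that truly contains it (Smith-Waterman oracle check)
  a_read <- m$read_id[m$isoform == names(which(vapply(
    run$gene$isoforms, function(ch) "E3a" %in% ch, logical(1))))[1]][1]
  seqs <- run$oriented$sequence[run$oriented$read_id == a_read]
  sa <- oracle_local_score(seqs, fx$es[["E3a"]])
  sb <- oracle_local_score(seqs, fx$es[["E3b"]])
  expect_gt(sa, sb)
  h <- fx$ann$hits
  expect_equal(h$score[h$read_id == a_read & h$exon == "E3a"], sa)
  expect_equal(h$score[h$read_id == a_read & h$exon == "E3b"], sb)
})

test_that("local alignment scores equal the brute-force oracle on random pairs", {
  set.seed(41)
  p <- annotation_params()
  for (i in 1:25) {
    ex <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), TRUE),
                collapse = "")
    rd <- paste(sample(c("A", "C", "G", "T"), sample(40:150, 1), TRUE),
                collapse = "")
    if (runif(1) < 0.5) {  # embed a mutated copy half the time
      pos <- sample(nchar(rd) - nchar(ex), 1)
      sub <- strsplit(ex, "")[[1]]
      flip <- runif(length(sub)) < 0.05
      sub[flip] <- vapply(sub[flip], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      rd <- paste0(substr(rd, 1, pos), paste(sub, collapse = ""),
                   substr(rd, pos + 1, nchar(rd)))
    }
    reads <- ampliso:::read_set("r", rd)
    catalog <- ampliso:::new_exon_catalog(data.frame(
      name = "X", start = 0L, end = nchar(ex), acceptor_ok = NA,
      donor_ok = NA, support = 1L, group = "X"))
    ann <- annotate_exons(reads, c(X = ex), catalog, p)
    expect_equal(ann$hits$score, oracle_local_score(rd, ex),
                 label = sprintf("case %d", i))
  }
})

test_that("non-colinear reads are excluded and exon-free reads are flagged", {
  run <- small_run()
  fx <- small_annotation(run)
  es <- fx$es
  ## scrambled exon order: E2 after E4
  scrambled <- paste0(es[["E1"]], es[["E4"]], es[["E2"]])
  reads <- ampliso:::read_set("scr", scrambled)
  ann <- annotate_exons(reads, es, fx$ex$catalog, fx$p)
  expect_equal(ann$excluded$reason, "non_colinear")
  expect_true(is.na(ann$barcodes["scr"]))
  set.seed(4)
  junk <- ampliso:::read_set("junk", paste(
    sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))
  ann2 <- annotate_exons(junk, es, fx$ex$catalog, fx$p)
  expect_equal(ann2$excluded$reason, "no_architecture")
})

test_that("QC identity matches the ends-free oracle and applies the threshold", {
  run <- small_run()
  fx <- small_annotation(run)
  ## exact read: identity 1, kept
  theo <- theoretical_sequence("E1|E2|E4", fx$es)
  reads <- ampliso:::read_set("t", theo)
  qc <- qc_against_theoretical(reads, c(t = "E1|E2|E4"), fx$es, fx$p)
  expect_equal(qc$identity, 1.0)
  expect_true(qc$keep)
  ## adapter tails cost nothing under free end gaps
  set.seed(8)
  tails <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  padded <- ampliso:::read_set("pad", paste0(tails, theo, revcomp(tails)))
  qc2 <- qc_against_theoretical(padded, c(pad = "E1|E2|E4"), fx$es, fx$p)
  expect_equal(qc2$identity, 1.0)
  ## scrambled interior drops below threshold; oracle agrees closely
  ch <- strsplit(theo, "")[[1]]
  mid <- (length(ch) %/% 4):(3 * length(ch) %/% 4)
  ch[mid] <- sample(ch[mid])
  bad <- paste(ch, collapse = "")
  qc3 <- qc_against_theoretical(ampliso:::read_set("bad", bad),
                                c(bad = "E1|E2|E4"), fx$es, fx$p)
  expect_false(qc3$keep)
  o <- oracle_overlap(bad, theo)
  expect_lt(abs(qc3$identity - o$matches / o$columns), 0.05)
  ## fast (banded) and exact engines agree on real noisy reads
  noisy <- small_run(seed = 5, reads_per_sample = 20,
                     error_rates = c(sub = 0.01, ins = 0.0025, del = 0.0025))
  ar <- noisy$oriented[noisy$oriented$read_id %in%
                         names(noisy$al$alignments), ][1:15, ]
  ann <- annotate_exons(ar, fx$es, fx$ex$catalog, fx$p,
                        alignments = noisy$al$alignments)
  q_fast <- qc_against_theoretical(ar, ann$barcodes, fx$es, fx$p,
                                   alignments = noisy$al$alignments)
  q_slow <- qc_against_theoretical(ar, ann$barcodes, fx$es, fx$p)
  m <- match(q_fast$read_id, q_slow$read_id)
  expect_true(all(abs(q_fast$identity - q_slow$identity[m]) < 0.02))
})

test_that("clustering modes: pacbio keeps all, ont applies the >=10 and terminal-exon rules", {
  ## synthetic QC table: barcodes A|B|C x12, A|C x9, B|C x50 (no first exon)
  catalog <- ampliso:::new_exon_catalog(data.frame(
    name = c("A", "B", "C"), start = c(0L, 20L, 40L), end = c(10L, 30L, 50L),
    acceptor_ok = NA, donor_ok = NA, support = 1L,
    group = c("A", "B", "C")))
  es <- c(A = strrep("A", 10), B = strrep("C", 10), C = strrep("G", 10))
  qc <- data.frame(
    read_id = sprintf("r%d", 1:71),
    sample_id = "S1",
    barcode = c(rep("A|B|C", 12), rep("A|C", 9), rep("B|C", 50)),
    identity = 1, keep = TRUE, stringsAsFactors = FALSE)
  ont <- cluster_and_name(qc, catalog, es, annotation_params(mode = "ont"))
  expect_equal(ont$clusters$barcode, "A|B|C")   # A|C < 10, B|C lacks A
  expect_equal(sum(ont$excluded_reads$reason == "missing_terminal_exon"), 50)
  pb <- cluster_and_name(qc, catalog, es, annotation_params(mode = "pacbio"))
  expect_equal(pb$clusters$barcode, c("B|C", "A|B|C", "A|C"))
  expect_equal(pb$clusters$name, c("T-1", "T-2", "T-3"))
  ## cluster counts partition the QC-passing reads
  expect_equal(sum(pb$clusters$total_count), nrow(qc))
  expect_equal(sum(ont$clusters$total_count) + nrow(ont$excluded_reads),
               nrow(qc))
  ## determinism and tie-break: equal counts order lexicographically
  qc2 <- qc[c(1:12, 22:33), ]
  qc2$barcode[13:24] <- "A|B"
  cl2 <- cluster_and_name(qc2, catalog, es, annotation_params())
  expect_equal(cl2$clusters$barcode[1:2], c("A|B", "A|B|C"))
  expect_identical(cluster_and_name(qc2, catalog, es, annotation_params()),
                   cl2)
})

test_that("theoretical sequences concatenate exon sequences in barcode order", {
  es <- c(E1 = "AAAA", E2 = "CCCC", E3 = "GGGG")
  expect_equal(theoretical_sequence("E1|E3", es), "AAAAGGGG")
  expect_error(theoretical_sequence("E1|E9", es), "unknown exon")
})
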