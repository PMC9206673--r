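test_that("zero-noise reads recover the true block structure exactly", {
  for (seed in c(5, 9)) {
    g <- build_toy_gene(n_exons = 6, alt3ss_exons = 3, n_isoforms = 4,
                        seed = seed)
    idx <- locus_index(g$locus)
    for (iso in names(g$isoforms)) {
      a <- align_read(g$isoform_seqs[[iso]], idx)
      expect_s3_class(a, "read_alignment")
      ## raw chaining may sit one base off at a repeat-ambiguous junction;
      ## GT-AG placement is the refinement step's contract
      a <- refine_splice_boundaries(a, g$locus)
      m <- g$exons[match(g$isoforms[[iso]], g$exons$name), ]
      expect_equal(a$blocks$locus_start, m$start)
      expect_equal(a$blocks$locus_end, m$end)
      expect_equal(a$identity, 1.0)
      ## every intron canonical
      expect_true(all(a$introns$donor == "GT" & a$introns$acceptor == "AG"))
    }
  }
})

test_that("single-exon reads give one block and chain score is strand-invariant", {
  g <- small_gene()
  idx <- locus_index(g$locus)
  ex1 <- exon_sequences(g$exons, g$locus)[["E2"]]
  a <- align_read(ex1, idx)
  expect_equal(nrow(a$blocks), 1L)
  expect_equal(nrow(a$introns), 0L)
  ## reverse-complementing the read flips orientation, same score/blocks
  iso <- g$isoform_seqs[[1]]
  af <- align_read(iso, idx)
  ar <- align_read(revcomp(iso), idx)
  expect_equal(ar$score, af$score)
  expect_equal(ar$orientation, "reverse")
  expect_equal(ar$blocks$locus_start, af$blocks$locus_start)
})

test_that("alignment rejects unmappable reads with a reason", {
  g <- small_gene()
  idx <- locus_index(g$locus)
  set.seed(2)
  junk <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  res <- align_reads(ampliso:::read_set("junk", junk), g$locus)
  expect_equal(nrow(res$rejected), 1L)
  expect_match(res$rejected$reason, "unmappable|low_identity")
})

test_that("substitution noise preserves block structure; oracle DP agrees on small instances", {
  g <- build_toy_gene(n_exons = 4, n_isoforms = 3, seed = 17,
                      exon_len_range = c(50, 80),
                      intron_len_range = c(40, 60), utr3 = 20)
  idx <- locus_index(g$locus)
  set.seed(99)
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    k <- rbinom(1, length(ch), rate)
    if (k > 0) {
      pos <- sample(length(ch), k)
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    paste(ch, collapse = "")
  }
  for (rep in 1:12) {
    iso <- sample(names(g$isoforms), 1)
    clean <- g$isoform_seqs[[iso]]
    truth <- refine_splice_boundaries(align_read(clean, idx), g$locus)
    noisy <- mutate(clean, 0.02)
    a <- refine_splice_boundaries(align_read(noisy, idx), g$locus)
    expect_equal(nrow(a$blocks), nrow(truth$blocks))
    expect_true(all(abs(a$blocks$locus_start - truth$blocks$locus_start) <= 2))
    expect_true(all(abs(a$blocks$locus_end - truth$blocks$locus_end) <= 2))
    ## brute-force free-intron DP on the clean read (with errors the free
    ## jump is degenerate: it can dodge any mismatch) agrees with the
    ## implementation's block structure up to splice-ambiguity ties
    o <- oracle_spliced(clean, g$locus$sequence, min_intron = 20)
    expect_equal(nrow(o$blocks), nrow(truth$blocks))
    expect_true(all(abs(o$blocks$locus_start - truth$blocks$locus_start) <= 3))
    expect_true(all(abs(o$blocks$locus_end - truth$blocks$locus_end) <= 3))
  }
})

test_that("splice-boundary refinement restores GT-AG and is a fixed point on clean input", {
  g <- small_gene()
  idx <- locus_index(g$locus)
  a <- refine_splice_boundaries(align_read(g$isoform_seqs[[1]], idx),
                                g$locus)
  refined <- refine_splice_boundaries(a, g$locus)
  expect_equal(refined$blocks, a$blocks)    # refinement is idempotent
  ## perturb one boundary by 2 nt: donor-side bases moved to acceptor side
  b <- a$blocks
  shift_at <- 1
  b$read_end[shift_at] <- b$read_end[shift_at] - 2L
  b$locus_end[shift_at] <- b$locus_end[shift_at] - 2L
  b$read_start[shift_at + 1] <- b$read_start[shift_at + 1] - 2L
  b$locus_start[shift_at + 1] <- b$locus_start[shift_at + 1] - 2L
  pert <- a; pert$blocks <- b
  fixed <- refine_splice_boundaries(pert, g$locus)
  expect_equal(fixed$blocks$locus_end[shift_at], a$blocks$locus_end[shift_at])
  expect_equal(fixed$blocks$locus_start[shift_at + 1],
               a$blocks$locus_start[shift_at + 1])
  ## enumerate all shifts: no shift beats the refined placement
  rch <- strsplit(a$read_seq, "")[[1]]
  lch <- strsplit(g$locus$sequence, "")[[1]]
  r <- fixed$blocks$read_end[shift_at]
  le <- fixed$blocks$locus_end[shift_at]
  ls <- fixed$blocks$locus_start[shift_at + 1]
  for (s in -5:5) {
    if (s == 0) next
    seg <- if (s > 0) rch[(r + 1):(r + s)] else rch[(r + s + 1):r]
    gain <- if (s > 0)
      sum(seg == lch[(le + 1):(le + s)]) - sum(seg == lch[(ls + 1):(ls + s)])
    else
      sum(seg == lch[(ls + s + 1):ls]) - sum(seg == lch[(le + s + 1):le])
    expect_lte(gain, 0)
  }
})

test_that("a boundary with no canonical site in the window is left as found", {
  g <- build_toy_gene(n_exons = 4, n_isoforms = 2, seed = 11,
                      gc_donor_exons = 2)
  idx <- locus_index(g$locus)
  a <- align_read(g$isoform_seqs[[1]], idx)
  refined <- refine_splice_boundaries(a, g$locus)
  expect_equal(refined$blocks$locus_end[2], g$exons$end[2])
  expect_equal(refined$introns$donor[2], "GC")   # recorded verbatim
  expect_equal(refined$introns$acceptor[2], "AG")
})

test_that("BED12 export/import round-trips blocks and flags unknown ids", {
  run <- small_run()
  tf <- withr::local_tempfile(fileext = ".bed")
  some <- run$al$alignments[1:10]
  write_alignments_bed12(some, run$gene$locus, tf)
  back <- import_alignments(tf, run$oriented, run$gene$locus)
  for (id in names(some)) {
    expect_equal(back[[id]]$blocks$locus_start, some[[id]]$blocks$locus_start)
    expect_equal(back[[id]]$blocks$locus_end, some[[id]]$blocks$locus_end)
    expect_gte(back[[id]]$identity, 0.9)  # recomputed against the locus
  }
  strangers <- run$oriented[!run$oriented$read_id %in% names(some), ]
  expect_error(import_alignments(tf, strangers[1:3, ], run$gene$locus),
               "unknown read id")
})

test_that("banded aligner equals Biostrings pairwiseAlignment on random pairs", {
  set.seed(7)
  mat <- ampliso:::nuc_matrix()
  for (i in 1:40) {
    n1 <- sample(10:70, 1); n2 <- sample(10:70, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n1, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), n2, TRUE), collapse = "")
    st <- banded_align(a, b, band = 100, free_ends = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 1, gapExtension = 1)
    expect_equal(st$score, Biostrings::score(pa))
  }
})
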