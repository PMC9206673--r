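mini_clusters <- function(barcodes, counts) {
  cl <- data.frame(name = sprintf("T-%d", seq_along(barcodes)),
                   barcode = barcodes, total_count = counts,
                   stringsAsFactors = FALSE)
  structure(list(clusters = cl, counts = NULL, members = list(),
                 sequences = character(0)), class = "transcript_clusters")
}

test_that("junction enumeration lists adjacent pairs with complete support", {
  cl <- mini_clusters(c("A|B|C", "A|C"), c(12L, 25L))
  jx <- enumerate_junctions(cl)
  expect_setequal(jx$junction_id, c("A-B", "B-C", "A-C"))
  expect_equal(jx$long_read_count[jx$junction_id == "A-C"], 25L)
  expect_equal(jx$supporting_transcripts[jx$junction_id == "A-C"], "T-2")
  expect_equal(jx$n_transcripts[jx$junction_id == "A-B"], 1L)
  ## a junction in many barcodes counts each supporting transcript
  many <- mini_clusters(sprintf("A|B|X%d", 1:7), rep(1L, 7))
  jm <- enumerate_junctions(many)
  expect_equal(jm$n_transcripts[jm$junction_id == "A-B"], 7L)
})

test_that("minimal uniqueness overhangs are verified by transcript-scan oracle", {
  set.seed(23)
  for (rep in 1:8) {
    g <- build_toy_gene(n_exons = 5, n_isoforms = 4, seed = 100 + rep,
                        exon_len_range = c(60, 90),
                        intron_len_range = c(40, 60), utr3 = 20)
    es <- exon_sequences(g$exons, g$locus)
    cl <- mini_clusters(vapply(g$isoforms, paste, character(1),
                               collapse = "|"),
                        rep(1L, length(g$isoforms)))
    jx <- enumerate_junctions(cl)
    ov <- min_unique_overhangs(jx, es)
    pj <- ov$per_junction
    for (i in seq_len(nrow(pj))) {
      if (!pj$discriminable[i]) next
      don <- es[[jx$donor_exon[i]]]; acp <- es[[jx$acceptor_exon[i]]]
      probe <- paste0(substring(don, nchar(don) - pj$a[i] + 1),
                      substring(acp, 1, pj$b[i]))
      ## oracle: in every theoretical transcript, occurrences of the probe
      ## sit exactly at this junction's boundary, and nowhere else
      n_hits <- 0L
      for (iso in names(g$isoforms)) {
        ch <- g$isoforms[[iso]]
        lens <- nchar(es[ch])
        tx <- paste(es[ch], collapse = "")
        pos <- oracle_find_all(tx, probe)
        k <- match(jx$donor_exon[i], ch)
        has_j <- !is.na(k) && k < length(ch) && ch[k + 1] == jx$acceptor_exon[i]
        if (has_j) {
          bnd <- cumsum(lens)[k]
          expect_equal(pos, unname(bnd) - pj$a[i] + 1,
                       label = sprintf("junction %s in %s",
                                       jx$junction_id[i], iso))
          n_hits <- n_hits + length(pos)
        } else {
          expect_equal(length(pos), 0L)
        }
      }
      expect_gt(n_hits, 0L)
    }
    ## global pair is the elementwise maximum
    if (all(pj$discriminable)) {
      expect_equal(unname(ov$global), c(max(pj$a), max(pj$b)))
    }
  }
})

test_that("junctions sharing a donor-side variant are flagged non-discriminable", {
  ## E2b a suffix of E2a: junctions E2a-X and E2b-X have identical flanks
  run <- small_run()
  es <- exon_sequences(run$gene$exons, run$gene$locus)
  cl <- mini_clusters(c("E1|E3a|E4", "E1|E3b|E4"), c(5L, 5L))
  jx <- enumerate_junctions(cl)
  ov <- min_unique_overhangs(jx, es)
  pj <- ov$per_junction
  expect_false(pj$discriminable[pj$junction_id == "E3a-E4"])
  expect_false(pj$discriminable[pj$junction_id == "E3b-E4"])
  ## the acceptor-side junctions remain discriminable
  expect_true(pj$discriminable[pj$junction_id == "E1-E3a"])
})

test_that("junction reference records have the requested overhangs", {
  es <- c(A = strrep("ACGT", 10), B = strrep("GGCA", 10))
  jx <- data.frame(junction_id = "A-B", donor_exon = "A", acceptor_exon = "B",
                   stringsAsFactors = FALSE)
  ref <- build_junction_reference(jx, es, 9, 6)
  expect_equal(nchar(ref$sequence), 15L)
  expect_equal(ref$junction_point, 9L)
  expect_equal(ref$sequence, paste0(substring(es[["A"]], 32, 40),
                                    substring(es[["B"]], 1, 6)))
  ## short exon: truncated and flagged
  es2 <- c(A = "ACGTA", B = strrep("G", 10))
  ref2 <- build_junction_reference(
    data.frame(junction_id = "A-B", donor_exon = "A", acceptor_exon = "B"),
    es2, 9, 6)
  expect_true(ref2$truncated)
  expect_equal(ref2$junction_point, 5L)
  ## FASTA emission round-trips
  tf <- withr::local_tempfile(fileext = ".fasta")
  build_junction_reference(jx, es, 9, 6, path = tf)
  back <- Biostrings::readDNAStringSet(tf)
  expect_equal(names(back), "A-B")
})

test_that("short-read support equals manifest spanning counts on zero-error data", {
  g <- small_gene()
  sheet <- make_sample_sheet(1, seed = 3)
  sc <- sim_scenario(n_samples = 1, short_reads_per_sample = 1500,
                     error_rates = c(sub = 0, ins = 0, del = 0), seed = 31)
  sh <- simulate_short_reads(g, sc, sheet)
  es <- exon_sequences(g$exons, g$locus)
  cl <- mini_clusters(truth_barcodes(g), rep(1L, length(g$isoforms)))
  jx <- enumerate_junctions(cl)
  ov <- min_unique_overhangs(jx, es)
  o5 <- max(9, ov$global["A"], na.rm = TRUE)
  o3 <- max(6, ov$global["B"], na.rm = TRUE)
  ref <- build_junction_reference(jx, es, o5, o3)
  counts <- count_short_read_support(sh$reads, ref, min_overlap = 15,
                                     min_overhang_5p = 9, min_overhang_3p = 6)
  js <- sh$junction_spans
  js$junction_id <- paste0(js$donor_exon, "-", js$acceptor_exon)
  disc <- ov$per_junction$junction_id[ov$per_junction$discriminable]
  for (j in jx$junction_id) {
    if (!j %in% disc) next
    expected <- sum(js$junction_id == j & js$overhang_5p >= 9 &
                      js$overhang_3p >= 6 &
                      js$overhang_5p + js$overhang_3p >= 15)
    expect_equal(counts$short_read_count[counts$junction_id == j], expected,
                 label = j)
  }
  ## a read with a 3-nt acceptor overhang is never counted
  short_ov <- js[js$overhang_3p < 6, ]
  if (nrow(short_ov) > 0) {
    one <- sh$reads[sh$reads$read_id == short_ov$read_id[1], , drop = FALSE]
    cnt1 <- count_short_read_support(one, ref)
    jid <- paste0(short_ov$donor_exon[1], "-", short_ov$acceptor_exon[1])
    spans_ok <- js[js$read_id == one$read_id & js$junction_id == jid &
                     js$overhang_5p >= 9 & js$overhang_3p >= 6, ]
    expect_equal(cnt1$short_read_count[cnt1$junction_id == jid],
                 nrow(spans_ok))
  }
})

test_that("query reports presence and expression share for exon pairs", {
  cl <- mini_clusters(c("A|B|C", "A|C"), c(75L, 25L))
  jx <- enumerate_junctions(cl)
  rep <- query_junctions(data.frame(donor_exon = c("A", "B"),
                                    acceptor_exon = c("C", "A")), jx, cl)
  expect_true(rep$present[1])
  expect_equal(rep$pct_expression[1], 25)
  expect_false(rep$present[2])
})
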