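test_that("ORF detection handles the minimum-length boundary exactly", {
  ## ATG + 99 lysine codons + TAA = 303 nt
  s303 <- paste0("ATG", strrep("AAA", 99), "TAA")
  orfs <- find_orfs(s303)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$length_nt, 303L)
  expect_equal(orfs$protein, paste0("M", strrep("K", 99)))
  ## exactly 300 nt (98 codons) retained; 297 rejected
  s300 <- paste0("ATG", strrep("AAA", 98), "TAA")
  expect_equal(find_orfs(s300)$length_nt, 300L)
  s297 <- paste0("ATG", strrep("AAA", 97), "TAA")
  expect_equal(nrow(find_orfs(s297)), 0L)
})

test_that("ORF enumeration equals brute force on random sequences, both policies", {
  set.seed(53)
  for (rep in 1:12) {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    for (pol in c("longest_per_stop", "all_starts")) {
      got <- find_orfs(s, min_orf_nt = 120, policy = pol)
      want <- oracle_orfs(s, min_orf_nt = 120, policy = pol)
      expect_equal(got[, c("frame", "tx_start", "tx_end", "length_nt")],
                   want, ignore_attr = TRUE,
                   label = sprintf("rep %d policy %s", rep, pol))
    }
    ## ATG-only mode is a subset
    atg <- find_orfs(s, start_codons = "ATG", min_orf_nt = 120)
    expect_true(all(atg$start_codon == "ATG"))
  }
})

test_that("TIS filtering keeps only evidence-backed starts and warns on empty evidence", {
  run <- small_run()
  fx <- list()
  ex <- discover_exons(run$al$alignments, run$gene$locus)
  es <- exon_sequences(ex$catalog, run$gene$locus)
  p <- annotation_params()
  ar <- run$oriented[run$oriented$read_id %in% names(run$al$alignments), ]
  ann <- annotate_exons(ar, es, ex$catalog, p, alignments = run$al$alignments)
  qc <- qc_against_theoretical(ar, ann$barcodes, es, p,
                               alignments = run$al$alignments)
  cl <- cluster_and_name(qc, ex$catalog, es, p,
                         sample_ids = run$sheet$sample_id)
  orfs <- predict_orfs(cl, ex$catalog)
  expect_gt(nrow(orfs), 0)
  fl <- filter_by_tis(orfs, run$gene$validated_tis)
  expect_true(all(fl$orfs$genomic_tis == run$gene$validated_tis))
  ## identity filter
  all_tis <- unique(orfs$genomic_tis)
  expect_equal(nrow(filter_by_tis(orfs, all_tis)$orfs), nrow(orfs))
  expect_warning(empty <- filter_by_tis(orfs, numeric(0)), "empty")
  expect_equal(nrow(empty$orfs), 0L)
  ## alternative acceptor shifts the same transcript-relative ATG to a
  ## distinct genomic TIS only if it lies downstream of the variant; the
  ## canonical ATG in exon 1 maps identically through all chains
  expect_equal(length(unique(fl$orfs$genomic_tis)), 1L)
  .fixture_cache$proteome <- list(cl = cl, ex = ex, orfs = orfs, fl = fl)
})

test_that("duplicate ORFs collapse and PTC-bearing ORFs are removed", {
  fxp <- .fixture_cache$proteome
  dd <- drop_duplicates_and_ptc(fxp$fl$orfs, fxp$ex$catalog)
  iso <- dd$isoforms
  ## dedup: protein sequences unique; sources preserved
  expect_false(anyDuplicated(iso$protein) > 0)
  expect_equal(sum(iso$n_sources) + 0, length(unique(unlist(
    strsplit(iso$source_transcripts, ",")))))
  ## every retained isoform's stop codon maps into the last exon
  last_names <- fxp$ex$catalog$name[fxp$ex$catalog$group ==
                                      fxp$ex$catalog$group[nrow(fxp$ex$catalog)]]
  kept <- fxp$fl$orfs[fxp$fl$orfs$protein %in% iso$protein, ]
  expect_true(any(kept$stop_exon %in% last_names))
  ## removal log names PTC
  if (nrow(dd$removed) > 0) expect_true(all(dd$removed$reason == "PTC"))
  ## monotone filter chain
  expect_gte(nrow(fxp$orfs), nrow(fxp$fl$orfs))
  expect_gte(nrow(fxp$fl$orfs), dd$n_deduplicated)
  expect_gte(dd$n_deduplicated, nrow(iso))
  ## hand-built PTC case: stop in penultimate exon removed, in last kept
  catalog <- ampliso:::new_exon_catalog(data.frame(
    name = c("E1", "E2", "E3"), start = c(0L, 100L, 200L),
    end = c(50L, 150L, 250L), acceptor_ok = NA, donor_ok = NA,
    support = 1L, group = c("E1", "E2", "E3")))
  orfs <- data.frame(protein = c("MAAA", "MCCC"), transcript = c("T-1", "T-1"),
                     genomic_tis = 0, stop_exon = c("E2", "E3"),
                     stringsAsFactors = FALSE)
  dd2 <- drop_duplicates_and_ptc(orfs, catalog)
  expect_equal(dd2$isoforms$protein, "MCCC")
  expect_equal(dd2$removed$protein, "MAAA")
})

test_that("molecular weights follow residue additivity and the composition oracle", {
  g <- molecular_weights("G")
  expect_equal(g$mw_average_da, 57.0519 + 18.01528, tolerance = 1e-6)
  ## additivity: mass(AB) = mass(A) + mass(B) - water
  ab <- molecular_weights(c("MKWV", "TYDE", "MKWVTYDE"))
  expect_equal(ab$mw_mono_da[3],
               ab$mw_mono_da[1] + ab$mw_mono_da[2] - 18.010565,
               tolerance = 1e-6)
  ## elemental-composition oracle on random proteins
  set.seed(71)
  aas <- names(ampliso:::AA_MONO)
  for (i in 1:40) {
    p <- paste(sample(aas, sample(5:60, 1), TRUE), collapse = "")
    mw <- molecular_weights(p)
    o <- oracle_mw(p)
    expect_lt(abs(mw$mw_mono_da - o["mono"]), 0.005 + 1e-4 * nchar(p))
    ## average masses are convention-dependent at ~1e-3 Da per residue
    expect_lt(abs(mw$mw_average_da - o["avg"]), 0.01 + 2e-3 * nchar(p))
  }
  expect_error(molecular_weights("MKXW"), "position 3")
})

test_that("digestion follows protease rules and matches the substring-scan oracle", {
  ## trypsin before length filtering: MK | R | AAAK
  d <- digest_protein("MKRAAAK", "trypsin", missed_cleavages = 0,
                      len_range = NULL)
  expect_equal(d$peptide, c("MK", "R", "AAAK"))
  ## proline blocks cleavage
  dp <- digest_protein("MKPAAAK", "trypsin", missed_cleavages = 0,
                       len_range = NULL)
  expect_equal(dp$peptide, c("MKPAAAK"))
  ## oracle scan over random proteins with missed cleavages + length filter
  set.seed(83)
  aas <- names(ampliso:::AA_MONO)
  for (i in 1:15) {
    p <- paste(sample(aas, sample(30:80, 1), TRUE), collapse = "")
    got <- sort(unique(digest_protein(p, "trypsin", 2, c(7, 30))$peptide))
    expect_equal(got, oracle_tryptic_peptides(p, 2, c(7, 30)),
                 label = sprintf("protein %d", i))
  }
  expect_error(digest_protein("MK", "pepsin"), "trypsin")
})

test_that("peptide classes partition and respond to isoform structure", {
  iso <- data.frame(
    isoform_id = c("P-1", "P-2"),
    protein = c("MKAAAAAAAKWWWWWWWWK", "MKAAAAAAAKVVVVVVVVK"),
    source_transcripts = c("T-1", "T-2"), n_sources = 1, tis = 0,
    stringsAsFactors = FALSE)
  dm <- digest_and_map(iso, len_range = c(5, 30))
  peps <- dm$peptides
  expect_setequal(unique(peps$class),
                  intersect(c("isoform-unique", "group-discriminating",
                              "shared"), peps$class))
  ## shared N-terminal peptide, unique C-terminal peptides
  expect_true(any(peps$class == "shared"))
  uq <- peps[peps$class == "isoform-unique", ]
  expect_true(any(grepl("W", uq$peptide)) && any(grepl("V", uq$peptide)))
  ## identical isoforms: pigeonhole, nothing is unique
  iso2 <- iso; iso2$protein[2] <- iso2$protein[1]
  dm2 <- digest_and_map(iso2, len_range = c(5, 30))
  expect_false(any(dm2$peptides$class == "isoform-unique"))
  ## observed peptides report unique support
  obs <- uq$peptide[1]
  dm3 <- digest_and_map(iso, len_range = c(5, 30), observed = obs)
  expect_equal(nrow(dm3$observed_support), 1L)
})

test_that("end-to-end proteome prediction flags junction-spanning peptides", {
  fxp <- .fixture_cache$proteome
  run <- small_run()
  pr <- predict_proteome(fxp$cl, fxp$ex$catalog,
                         validated_tis = run$gene$validated_tis)
  expect_equal(unname(pr$counts["n_orfs"]), nrow(pr$orfs))
  expect_true(all(diff(unname(pr$counts)) <= 0))  # monotone chain
  if (nrow(pr$isoforms) > 0) {
    dm <- digest_and_map(pr$isoforms, orfs = pr$orfs, clusters = fxp$cl,
                         catalog = fxp$ex$catalog)
    expect_true(any(dm$peptides$junction_spanning))
    expect_true(all(pr$isoforms$mw_mono_da > 0))
  }
})
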