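## Shared fixtures.  The full-scale default-scenario pipeline run is
## expensive, so it is computed once per session on first use and cached.

.fixture_cache <- new.env(parent = emptyenv())

## Full default scenario: 14 exons, one alternative-acceptor group,
## 12 isoforms, 4 samples x 500 reads, 1% substitutions / 0.5% indels.
default_run <- function() {
  if (is.null(.fixture_cache$res))
    .fixture_cache$res <- run_pipeline(default_config(seed = 1))
  .fixture_cache$res
}

## Small gene + zero-noise reads, enough for most module tests.
small_gene <- function(seed = 5) {
  build_toy_gene(n_exons = 6, alt3ss_exons = 3, n_isoforms = 4, seed = seed)
}

small_run <- function(seed = 5, reads_per_sample = 60,
                      error_rates = c(sub = 0, ins = 0, del = 0), ...) {
  key <- paste("sr", seed, reads_per_sample, paste(error_rates, collapse = ","))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  g <- small_gene(seed)
  sheet <- make_sample_sheet(2, seed = seed + 1)
  sc <- sim_scenario(n_samples = 2, reads_per_sample = reads_per_sample,
                     error_rates = error_rates, seed = seed + 2, ...)
  sim <- simulate_long_reads(g, sc, sheet)
  dm <- demultiplex(sim$reads, sheet)
  o <- orient_reads(dm$reads)
  al <- align_reads(o, g$locus)
  out <- list(gene = g, sheet = sheet, scenario = sc, sim = sim, demux = dm,
              oriented = o, al = al)
  .fixture_cache[[key]] <- out
  out
}

truth_barcodes <- function(gene) {
  vapply(gene$isoforms, paste, character(1), collapse = "|")
}
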