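---
title: "Targeted long-read isoform discovery with ampliso: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted long-read isoform discovery with ampliso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliso)
```

## The problem

A single gene can express hundreds of splice isoforms.  Targeted
full-length cDNA sequencing — amplifying one locus between primers in its
first and last exons, barcoding per sample, and sequencing the amplicons
with a long-read platform — captures each isoform end to end, so a single
read determines a complete exon architecture.  `ampliso` turns such reads
into four linked results:

1. an **exon catalog**: the set of genomic intervals used as exons,
   including alternative 3' splice-site (acceptor) variants, each
   validated at canonical GT..AG splice sites;
2. a set of **transcripts**: clusters of reads with identical
   exon-architecture barcodes, with per-sample counts and percentages;
3. an **exon–exon junction table** with minimal uniqueness overhangs, an
   artificial junction reference, and short-read support counts;
4. a **theoretical proteome**: ORFs per transcript filtered by
   translation-initiation evidence and premature-termination-codon (PTC)
   removal, with molecular weights and an in-silico digest that classifies
   peptides by how specifically they identify protein isoforms.

All coordinates are 0-based half-open on the stored locus sequence, which
is the transcribed strand, so a donor site reads `GT` immediately after an
exon and an acceptor reads `AG` immediately before one.

## The synthetic-data generator

Real data for this design are multi-gigabyte sequencing runs; the package
instead ships a generator (`build_toy_gene()`, `simulate_long_reads()`,
`simulate_short_reads()`) whose defaults define the conditions every test
runs under:

* a 14-exon locus, exon lengths 80–200 nt, introns 40–150 nt (always
  GT..AG, at least 20 nt), one internal exon carrying an alternative
  acceptor variant 6–24 nt downstream (an `AG` is written into the exon so
  the variant is itself canonical);
* a protein-coding frame embedded in the full-length isoform: ATG at
  transcript position 30 (preceded immediately by a stop codon, so the
  ATG is the reported start under a longest-per-stop ORF policy), sense
  codons to a stop inside the last exon.  Exon skipping then naturally
  yields frame-preserving isoforms and frameshifted ones whose early stop
  exercises the PTC filter;
* 12 distinct isoforms, all containing the first and last exon (the
  amplicon primers sit there), internal exons skipped at random;
* 4 barcoded samples × 500 long reads; per-sample isoform proportions
  drawn from a symmetric Dirichlet with concentration 2 (several isoforms
  per sample at comparable abundance plus a tail of rare ones, which is
  what targeted profiles of one gene look like); realised counts are
  multinomial draws, recorded per read in a manifest;
* read errors i.i.d. per base: 1% substitution, 0.25% insertion, 0.25%
  deletion (a post-consensus long-read error profile).  Molecules are
  `barcode + primer + cDNA + rc(primer) + rc(barcode)` with 16-nt sample
  barcodes (pairwise Hamming distance at least 6) and 20-nt primers
  sharing no 13-mer with the locus; orientation is random;
* optionally truncated reads (`truncation_prob`) emulating degraded ONT
  libraries, used to exercise the terminal-exon filter;
* short reads: 100-nt substrings drawn uniformly along isoforms with the
  same abundances; the manifest records every junction a read spans and
  with what overhangs.

The generator does **not** emulate homopolymer-dependent errors, quality
score variation (a constant Q40 is written), chimeric molecules,
truncation hotspots, or inter-gene mapping ambiguity.  Passing tests
therefore demonstrate the correctness of the pipeline's logic under a
realistic error budget, not robustness to every artifact of real runs.

The ground truth for recovery statements is the manifest — the realised
per-sample read composition — rather than the Dirichlet parameter vector:
with 12 isoforms at 500 reads per sample, several true proportions differ
by less than multinomial noise, so agreement with the unrealised
parameters is capped by the generator's own sampling, not by pipeline
error.

## Spliced alignment

`align_read()` is a seed–chain–extend spliced aligner specialised for one
locus: exact 13-mer anchors (both orientations; ties toward forward) are
merged along diagonals and chained with a gap cost that is zero for an
intron-like gap — net locus gap of at least `min_intron` (20 nt) with at
most `band + 2(k-1)` unanchored read bases — and proportional to the gap
mismatch otherwise.  The unanchored read bases at a junction are assigned
to the flanking exons at the split maximising matches, with ties broken
toward a GT..AG-framed placement.  Terminal read ends (barcodes, primers)
extend by X-drop and simply stop matching; reads with less than
`reject_identity` (0.66) of their length matched are rejected with a
logged reason.

`refine_splice_boundaries()` then re-places every junction by exhaustive
search over joint shifts `t` in ±10 nt combined with an intron-length
adjustment `d` in ±2 nt; the latter absorbs a single-base indel sitting
at the junction, which otherwise pins a boundary on the wrong copy of a
local sequence repeat.  Ties break toward GT..AG, then minimal `|d|`,
then minimal `|t|`, then leftmost.  Minimal movement (rather than plain
leftmost) matters: reads carrying an error near a junction produce flat
tie landscapes, and a systematic directional tie-break would pile them
all onto the same wrong position, manufacturing a recurrent false
boundary.

For read-vs-transcript comparisons the package uses a banded
Gotoh aligner with free end gaps (`banded_align()`, C++), exact within
its band and verified score-identical to `Biostrings::pairwiseAlignment`
in the tests.

## Exon discovery

Block edges from all alignments are clustered by **modal peak claiming**:
the most frequent remaining edge value (ties toward the smaller
coordinate) claims everything within ±`tol` (3 nt).  Unlike single
linkage, two true boundaries more than `tol` apart can never chain-merge
through intermediate noisy values — essential when acceptor variants sit
17 nt apart with ±2 nt of boundary scatter in between.

A candidate exon is a (consensus start, consensus end) pair.  Support is
counted twice: all blocks, and *confident* blocks whose first and last
8 bases match the locus exactly under the final mapping.  The pipeline's
default support threshold — `max(2, 0.5%)` of aligned reads — applies to
confident support, because the reads that displace a boundary are
precisely those with errors at the boundary.

Validation retains internal candidates iff their flanks read
`AG..exon..GT`; the first exon is checked only on its donor side and the
last only on its acceptor side (`NA` flags).  Only GT-AG is accepted by
default, matching the targeted design this models; the exclusion log
records every rejected candidate with its reason.  Finally, a *dominance*
filter removes candidates sharing a start or end with a sibling at least
20× stronger (`dominance = 0.05`): sequencing errors adjacent to a
junction scatter a few percent of reads onto alternative GT/AG positions
that are otherwise indistinguishable from genuine minor variants.  Under
the generator's conditions genuine acceptor variants carry at least ~10%
of their sibling's support, so 5% is an identifiability floor — variants
rarer than that require deeper coverage or manual curation, which is how
such catalogs have historically been resolved.

Retained exons are named `E1..En` in genomic order; acceptor variants
sharing a donor become `E7a`, `E7b`, … by increasing start.

## Architecture barcoding, QC and clustering

Each exon is aligned locally (match +1, mismatch −2, gap −2 to open and
−1 to extend, the `blastn-short`-style scheme) against each read; an exon
is present iff its best hit covers ≥ 80% of the exon at ≥ 85% identity.
When spliced alignments are available the search is restricted to the
read window the alignment maps the exon interval to (±20 nt) — a pure
speed measure that the tests compare against whole-read alignment.
Acceptor-variant groups are resolved by score margin: the longer variant
wins over a shorter sibling (its suffix) only when its local-alignment
score exceeds the sibling's by at least half the length difference.  A
read that truly carries the longer form matches essentially all of its
extra bases (+1 each); a read carrying only the shorter form gains just
the ~25% chance matches of unrelated sequence, so plain best-score
selection — where a single chance match breaks the tie — would
systematically call the longer variant on short-variant reads.

The ordered presences form the read's architecture barcode
(`E1|E2|E4|...`).  Reads whose exon order disagrees with genomic order
are excluded as non-colinear (amplicon chimeras); reads with no exon are
excluded as `no_architecture`.  Each read is then QC'd by an ends-free
global alignment against its barcode's theoretical transcript (the
concatenated exon sequences); identity is matches over alignment columns
excluding end gaps, and reads below 0.85 are dropped.  The 0.85 default
is recorded in the pipeline provenance; at the default error rates true
reads sit near 0.98, so the threshold only removes structural outliers.

Identical barcodes form transcript clusters.  PacBio mode keeps every
cluster (single-read transcripts are legitimate in deep targeted data);
ONT mode first drops reads lacking the catalog's first or last exon and
then clusters with fewer than 10 reads, counted across the pooled
samples (a per-sample variant is a parameter away).  Clusters are sorted
by total count (ties lexicographically) and named `T-1..T-N`.

## Quantification

`build_matrix()` derives per-sample percentages (`NA` with a warning for
empty samples).  `core_and_specific()` partitions transcripts into the
common core (detected in every tissue at `min_count ≥ 1`),
tissue-specific, shared-partial and undetected classes.  `exon_usage()`
reports, per exon and sample, the fraction of reads whose transcript
contains that exon — normalisation by total gene expression, so values
are comparable across samples of very different depth.

## Junctions

Junctions are the ordered adjacent exon pairs across all transcript
barcodes.  For each, `min_unique_overhangs()` finds the smallest
`(a, b)` (by sum, then by `a`) such that `suffix_a(donor) +
prefix_b(acceptor)` occurs exactly once across all junction contexts
(each junction flanked with `a+b` nt on both sides, so occurrences
straddling any junction at any offset are caught) and never inside a
single exon.  Junctions downstream of an acceptor-variant pair share
their donor-side sequence entirely and are flagged non-discriminable —
no overhang can separate `E7a–E8` from `E7b–E8` because the variant is a
suffix of its sibling.  The artificial junction reference uses the
larger of the computed global minima and the conventional 9 nt (5') /
6 nt (3') overhangs.  A short read supports a junction iff it contains a
contiguous match to the junction record covering the junction point with
at least the per-side minimum overhangs and ≥ 15 nt total — so support
counting is conservative: with errors it can undercount, never
overcount.

## Theoretical proteome

Per transcript, `find_orfs()` scans the three forward frames for ORFs
from a start codon (ATG plus the near-cognate trio CTG/GTG/TTG by
default) to the first in-frame stop, keeping the most upstream start per
(frame, stop) (`longest_per_stop`; `all_starts` is available) and
requiring ≥ 300 nt including the stop codon.  The stop-inclusive reading
of the threshold is a documented convention, tested at the boundary.
The genomic TIS of each ORF is mapped back through the exon chain and
filtered against the validated-TIS set (ribosome-profiling evidence in
real use; the generator's active ATG in the tests).  An empty validated
set drops everything with a loud warning, to distinguish "no evidence
supplied" from "none validated".

Identical proteins collapse into one isoform carrying all source
transcripts.  An isoform is removed as a PTC/NMD candidate unless some
source ORF places its stop codon (first base, for stops spanning a
junction) in the catalog's last exon — the generalisation of the
classical "stop upstream of the last exon" rule, without a 50-nt
refinement.  Near-cognate initiators are written as M in the protein.
Molecular weights are residue-mass sums plus water (average and
monoisotopic).  `digest_protein()` implements trypsin (after K/R, not
before P) exactly and simplified specificity sets for elastase,
thermolysin and papain; peptides with up to 2 missed cleavages and 7–30
residues are classified as isoform-unique, group-discriminating or
shared, and flagged when their coding span crosses an exon–exon
junction.

## Numerical and degenerate-input choices

* Alignment scores: +1/−2 with gap open −2 / extend −1 throughout; a gap
  of length L costs `2 + (L−1)`.  The banded aligner treats N as a
  mismatch everywhere; barcodes may not contain N.
* Orientation ties break toward forward; clustering ties break
  lexicographically; boundary ties as described above.  All stages are
  deterministic given the seed, and reruns are byte-identical.
* Empty inputs: an empty validated-TIS set warns loudly; a sample with
  zero reads yields NA percentages with a warning; a catalog that cannot
  be sorted is refused by the BED writer; an unknown config key aborts
  before any compute.
* Problem sizes in the test-suite: the full default scenario (2,000 long
  reads, 8,000 short reads) is run once and reused across acceptance
  checks; module tests use 5–9-exon genes with 40–120 reads, chosen so
  the whole suite exercises every path at interactive turnaround.

## Known limitations

* Acceptor variants rarer than ~5% of their sibling are excluded as
  error noise (see exon discovery); donor-side (alternative 5') variants
  are not modelled at all, mirroring the targeted design this package
  reimplements.
* The aligner is single-locus; reads from paralogs or other genes are
  rejected by identity, not assigned elsewhere.
* Junction support counting is exact-match (configurable to 1 mismatch)
  and therefore conservative under high short-read error rates.
* The proteome stage predicts; it does not interpret mass spectra.  An
  observed-peptide list can be supplied to `digest_and_map()` to report
  which isoforms gain unique support.
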