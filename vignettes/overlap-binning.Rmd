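---
title: "Overlap-graph read binning with an automated MAD degree filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-graph read binning with an automated MAD degree filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overbin)
```

## The model

overbin groups shotgun metagenomic reads into bins intended to contain reads
from a single source molecule, before any assembly. The object at the core is
the *read-overlap graph*: reads are nodes and an undirected edge connects two
reads whenever they share an ungapped alignment of at least *b* bases
(the *b-parameter*, the minimum alignment length accepted) on either strand.
Candidate bins are the connected components of this graph.

The usual failure mode of overlap binning is the *promiscuous read*: a read
from a region shared across molecules — a ribosomal gene, a repeat — connects
components that should stay apart, and also shows an unusually large number
of edges. In a bin drawn from one molecule at roughly uniform coverage, the
number-of-edges-per-node histogram is expected to be unimodal and
normal-like; departures signal reads touching shared or repetitive sequence.
overbin automates the edge-count threshold (the *e-parameter* that CLAME-style
workflows ask the user to pick by eye) with a robust spread rule:

* `MAD = median(|d_i − median(d)|)` over the member degrees `d_i`,
* `sigma_hat = 1.4826 × MAD`, the usual consistency factor
  (`1/Φ⁻¹(3/4)` to four decimals) that makes the MAD estimate a normal
  standard deviation,
* a read is an outlier when `|d_i − median(d)| > 3 × sigma_hat`.

Outliers are removed, connectivity is recomputed (a component may split),
and every remaining sub-component with at least `min_bin_size` reads is
reported as a bin. Removed reads return to the pool.

Binning iterates over a strictly descending *b* schedule — 70 bp first,
then 50 and 30 bp by default. Reads captured at a stricter *b* are withdrawn;
smaller values re-examine only the remaining pool. Lowering *b* increases
sensitivity but also the chance of joining reads from different molecules,
which is why the schedule starts strict.

## Stages around the core

* **Quality control** (`trim_reads`): the maximal run of bases with phred
  quality below `min_quality` (default 30) is removed from each end of a
  read — interior bases are never touched, which makes the operation
  idempotent — and reads shorter than `min_length` (default 60 bp) are
  dropped. A sliding-window trimmer is deliberately not implemented; the
  end-run rule is the simplest one consistent with "trim both ends".
* **Paired-end preparation** (`prepare_binning_input`): mates are merged
  into single fragments for binning only. A true overlap merge is attempted
  first (longest suffix/prefix agreement of at least `min_overlap` bases,
  mismatch fraction at most `max_mismatch_rate`, consensus by higher base
  quality with ties to the first mate). When no such overlap exists the pair
  is *force-merged*: first mate, then exactly three `N` characters, then the
  reverse complement of the second mate (`ATCGT` + `NNN` + `TTATC` in the
  worked example). The spacer keeps the two mates in one binnable fragment
  while the `N`s — which never participate in alignments — prevent spurious
  overlaps across the junction. Binning runs on merged fragments; reported
  bins are mapped back to the original reads through the provenance table.
* **16S screening** (`partition_rrna`): reads are mapped against a
  user-supplied ribosomal reference with a built-in seed-and-extend ungapped
  mapper (seed k-mer 21, alignment of ≥ 50 bases at ≥ 90% identity). Reads
  that hit are set aside before binning, because near-identical ribosomal
  regions are exactly the conserved sequence that falsely connects genomes.
  The mapper is intentionally small; users who prefer an external aligner can
  pass its read-id list instead. Taxonomic classification of the ribosomal
  fraction is out of scope — those reads are written to their own FASTA.
* **Evaluation** (`evaluate_bins`): on synthetic data with a truth table,
  per-bin purity (fraction of reads from the plurality genome) and per-genome
  completeness (fraction of a genome's reads captured by its best bin) are
  computed at read level. This replaces marker-gene completeness estimates,
  which are database-bound; with known truth the read-level score is exact.

## Overlap detection: exactness by construction

The alignment model is deliberately exact by default: an "alignment" is a
maximal common substring (`max_mismatches = 0`), on either strand, and `N`
never matches. Two detectors implement it:

* `find_overlaps_bruteforce` — all read pairs, longest-common-substring
  dynamic programming. Quadratic, used as the reference.
* `find_overlaps_indexed` — a canonical b-mer index proposes candidate
  (pair, strand, diagonal) triples, each verified by a windowed diagonal
  scan. A shared substring of length ≥ *b* necessarily contains a shared
  b-mer *on its own diagonal*, so the candidate set is complete and the two
  detectors provably return the same edge set; the test suite asserts this
  equality on randomized instances, and against an independent pure-R
  oracle at small size.

A mismatch-tolerant mode exists (ungapped windows with at most
`max_mismatches` mismatches). Its seeds have length
`floor((b − m)/(m + 1))` for `m` mismatches: a length-*b* window with `m`
mismatches is cut into `m + 1` exact runs whose longest has at least that
length, so completeness is preserved (a ceiling-based seed would not
guarantee it). `N` is treated as a hard window break in both modes, so the
forced-merge spacer can never support an alignment.

One edge is kept per read pair — the maximal alignment length and its
strand — because the degree histogram counts distinct partners. All
iteration orders are fixed by sorted read ids, making every output
deterministic.

## Degenerate and numerical choices

* **MAD = 0**: a perfectly uniform degree histogram is the signature of a
  clean single-molecule bin; any symmetric rule would then remove arbitrary
  reads, so removal is disabled and the bin is flagged `mad_degenerate`.
* **"3 MAD" reading**: the removal distance is `3 × 1.4826 × MAD`, because
  `sigma_hat = 1.4826 × MAD` is introduced as the standard-deviation
  estimator immediately before the rule; the raw-MAD reading
  (`3 × MAD`) is available via `mad_outlier_filter(..., raw_mad = TRUE)`.
* **Medians** use the midpoint convention for even counts.
* **Bin diagnostics after splits**: a reported bin's degree histogram covers
  its members plus its parent component's removed outliers (pre-filter
  degrees), so histogram counts always sum to bin size plus outlier count.
* **Ties**: plurality ties in evaluation break toward the lexicographically
  smallest genome label; equal-quality consensus ties toward the first mate;
  equal-length strand ties report `same`.

## Block-wise processing

Very large inputs are processed in consecutive blocks of `block_size` reads
(default 2×10⁷), each binned independently, followed by a merge pass: bins
from different blocks are unioned when some cross-bin read pair overlaps by
at least the stricter of the two bins' `b` values, and a merged bin keeps
that stricter value. With one block the merge pass vanishes and the result
is identical to the plain iterative path. The merge pass can be viewed as a
superset of running blocks fully independently; disable it by binning blocks
yourself if strict independence is wanted.

## The pipeline and its backends

`run_pipeline` executes the stages as a dependency-driven task graph:
trim → merge → screen → binning form a chain, then one task per reported
bin (original-read export and per-bin reports) fans out, then a single
report task. The executor supports a serial backend and a local-parallel
backend (forked workers for the fan-out tasks). All tasks are
deterministic and results are collected in task-id order, so the two
backends produce byte-identical outputs — parallelism changes time, never
results — and the test suite compares the emitted files byte for byte.
Fan-out tasks declare their input and output files; a re-run skips tasks
whose outputs exist and are newer than their inputs. The final report
contains no timestamps, so regenerating it is also byte-identical.

The configuration is a flat `key = value` text file. The minimum viable
configuration names only `input_path`, `input_format` and `output_dir`;
every other key has the documented default, unknown keys are rejected with
the list of valid keys, and missing mandatory keys are reported by name.

## What the synthetic generator does and does not emulate

`simulate_community` / `simulate_reads` generate uniform random genomes
with controlled relative abundances, an optional conserved segment copied
verbatim into every genome (the 16S stand-in; it overwrites a slice so
genome length is preserved), uniform read starts on both strands, optional
paired-end geometry with a normal insert-size model, and i.i.d. per-base
substitution errors. The total read count is
`coverage × Σ genome_length / read_length`, allocated to genomes in
proportion to `abundance × length`, so under equal abundances each genome
receives exactly `coverage`-fold coverage.

The generator intentionally omits indels (the default overlap model is
exact-match, and indels would conflate error-model and aligner testing),
platform-specific error profiles, real genomic repeat structure, GC bias
and circular elements. Passing tests therefore demonstrate the algorithmic
contracts — completeness of the indexed search, exactness of the
partition, determinism, the conserved-segment rescue — on idealized reads;
they do not predict binning quality on real instrument data, where repeats
and indel errors will lower both purity and completeness.

## Test and default problem sizes

The community-scale checks use three 20 kb genomes at 20× coverage of
150-base error-free single-end reads (about 8,000 reads), with
`min_bin_size` scaled to 50; randomized oracle-equivalence checks use up to
200 reads per instance at b ∈ {30, 50, 70}. These sizes were chosen so the
whole suite exercises every stage end-to-end in well under an hour on a
laptop while keeping every premise (e.g., "no cross-genome 30-mer")
verifiable by brute force. The shipped `min_bin_size` default of 2000 reads
reflects a realistic reporting threshold for single-machine runs; published
large-scale workflows have used 100,000 (high-coverage simulated
benchmarks) or 5,000, and these are one-line config changes.

## Known limitations

* The 3-MAD rule is symmetric: it removes low-degree reads at local
  coverage dips as readily as high-degree promiscuous reads. On thin or
  uneven coverage this can split a genome's component into several pure
  bins, which halves read-level completeness while leaving purity at 1.0.
  The spread of per-genome completeness across simulation seeds in the
  acceptance script shows exactly this effect.
* Exact-match overlaps mean sequencing errors shorten effective alignments;
  at realistic error rates users should either enable the mismatch-tolerant
  mode or trim aggressively first.
* The screening mapper is ungapped; a reference diverged by indels from the
  sampled community will be missed. Any FASTA can be supplied, so a real
  aligner's output can substitute through the id-list adapter.
* External assemblers and annotators are not invoked; the pipeline exports
  per-bin FASTA files of the original reads as the hand-off point.
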