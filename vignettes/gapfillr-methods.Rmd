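---
title: "Mining unmapped reads for novel sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining unmapped reads for novel sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapfillr)
```

## The problem

A short-read resequencing experiment maps its read pairs to a reference
genome and, typically, discards whatever fails to align. When the reference
is incomplete — unfinished assembly gaps left as N-runs, or sequence present
in the sequenced population but absent from the individual the reference was
built from — those unmapped pairs are not noise: they are the only direct
evidence of the missing sequence. gapfillr implements a pseudo-de novo
strategy for recovering it:

1. **Triage.** Reads are quality-trimmed and pairs classified as concordantly
   mapped, one-end-anchored (OEA: exactly one mate aligns), or unaligned.
   Unaligned pairs (including, by default, discordantly mapped pairs) form
   the assembly pool; OEA pairs are set aside as placement evidence.
2. **Two-tier assembly.** The pool is assembled per sample (primary), then
   all samples' primary contigs are pooled per group and re-assembled
   (secondary). A secondary contig supported by a single primary contig is a
   singlet and excluded as debris — sequence seen in only one sample, at one
   tier, is not trusted.
3. **QC.** Per-contig GC content, DUST and entropy complexity scores,
   exact-duplicate removal, and an optional contaminant k-mer screen.
4. **Novelty screen.** Contigs found verbatim in the reference (100%
   identity, 100% coverage, either orientation) are not novel and are
   removed; near-matches are reported with their best identity and coverage
   but retained.
5. **OEA placement.** Each OEA pair whose anchored mate maps uniquely to the
   genome and whose free mate maps uniquely to a contig (mapping quality at
   least 30 on both sides) votes, via fragment-length arithmetic, for where
   the contig belongs. Votes are clustered, contigs classified by locus
   multiplicity (single / two / more), and single-locus predictions verified
   by local realignment against the predicted window.
6. **Gap accounting.** Placed contigs are intersected with the reference's
   N-run gaps and with gene models: gaps hit, gaps closed (fully covered by
   the union of contig intervals), bases filled, genic-gap classes (exon,
   splice site, UTR5/UTR3, intron, ncRNA), and gap contigs without BAC-insert
   support.

## Anchor geometry

The placement arithmetic is the package's methodological core, so it is
stated exactly. Coordinates are 0-based half-open throughout. For an OEA
pair with anchored genome mate at leftmost position $g$ and expected insert
$\mu$:

* anchored mate on `+`: the fragment extends right; the free mate's expected
  leftmost genome position is $m = g + \mu - \ell_c$, with $\ell_c$ the free
  mate's length;
* anchored mate on `-`: $m = g + \ell_g - \mu$, with $\ell_g$ the anchored
  mate's aligned length.

The free mate's expected genome strand is the opposite of the anchored
mate's. If the free mate maps to the contig at position $c$ on strand equal
to that expectation, the contig is genome-forward and its predicted start is
$m - c$; otherwise it is flipped and the start is $m + c + \ell_c - L$ for a
contig of length $L$. A brute-force round-trip test over all four strand
configurations (simulate one pair from a known placement, invert) pins the
formulas down: only self-consistent geometry passes.

### Reconciling the two ends of a contig

A single contig collects anchors at both of its ends. For a contig that is
collinear with the genome — a gap fill — both ends predict the same start.
For an *inserted* contig the genome contains no copy of it: both junctions
anchor the same reference point, so anchors at the genome-left end predict
the insertion point while anchors at the genome-right end predict the point
minus the contig length. Clustering all predictions naively would split
every insertion into two spurious loci. gapfillr therefore clusters
genome-left and genome-right evidence separately (single linkage, radius
$2\mu$) and reconciles a left cluster at $s_L$ with a right cluster at $s_R$
when they share an orientation and $s_R - s_L$ lies between $-L$ and $0$
(within the cluster radius). The reported locus is the *reference span* the
contig corresponds to, $[s_L,\; s_R + L)$: the full gap span for a fill, a
short junction interval for an insertion. This follows from using the 5'
and 3' coordinates of each contig jointly rather than pooling them, and it
is what lets one contig class cover both gap closure and insertion
detection.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| trim window / mean phred | 4 bases / 20 | sliding-window cut threshold |
| end-clip phred | 3 | leading/trailing bases at or below are clipped |
| minimum read length | 50 bp | shorter reads are discarded |
| mapper seed length | 21 | exact k-mer seeds; N never indexed |
| mapper identity floor | 0.90 | below this a read is unmapped |
| banded-extension band | 15% of read length | bounds indel exploration |
| assembly overlap (reads / contigs) | 40 / 100 bp | minimum qualifying overlap |
| assembly overlap identity | 0.97 | mismatch tolerance in overlaps |
| anchor mapping quality | ≥ 30 both sides | uniqueness filter |
| cluster radius | 2 × insert mean | single-linkage radius |
| minimum locus support | 2 anchors | suppresses singleton mismaps |
| verification pad | 2 × insert mean | realignment window margin |
| DUST / entropy flags | > 7 / < 70 | report-only low-complexity marks |

Mapping quality is a three-valued surrogate {0, 30, 60}: 60 for a unique
locus with no qualifying second candidate, 30 for a unique best with a
weaker second, 0 for ties. The pipeline only ever consumes the ≥ 30
threshold, so a calibrated probabilistic quality would add nothing the
downstream logic could use.

## The synthetic data generator

`simulate_dataset()` builds the study the pipeline assumes: a random
reference (GC 0.41) carrying non-overlapping gene models (≥ 2 exons,
introns, UTRs, a fraction of ncRNA genes) and N-run gaps placed half inside
gene bodies and half intergenic, each at least two insert lengths from
sequence ends and from each other; a donor genome in which a chosen subset
of gaps is replaced by novel sequence of the gap's length (gap fills),
additional novel segments are inserted at non-gap points (at least one
insert length from any gap), and SNPs are applied outside novel segments;
and paired-end reads drawn uniformly from the donor with Normal(290, 30)
inserts truncated at the read length, 100 bp mates, substitution errors at
the configured rate, and constant phred-37 qualities apart from a
low-quality tail on a configurable fraction of reads (so the trimmer has
real work). Read names encode the true fragment coordinates, which several
tests use as an oracle. Default novel-segment lengths (500–5,000 bp) are a
design choice spanning typical short-read contig N50s, not an empirical
estimate.

Two generator decisions deserve note. Unfilled gaps remain N in the donor,
and fragments that would contain N are redrawn: a sequencer reports no such
reads, and this keeps "error-free reads are exact donor substrings" exactly
true. And `build_donor()` returns its SNP table alongside the truth
records, so the reconstruction oracle (reference + truth + SNPs must
rebuild the donor byte-for-byte) stays exact at any SNP rate.

What the generator does **not** emulate: indel and structural-variant read
errors, PCR duplicates, quality-dependent error profiles, repetitive
sequence, and real gap flanks' composition biases. Passing tests therefore
demonstrate algorithmic correctness on clean, repeat-poor genomes, not
performance on real vertebrate data — on real data the mapper, assembler
and placement stages all face repeats this simulation does not pose, and
the package accepts externally produced SAM at the mapper interface for
exactly that reason.

## Numerical and design choices

* **Alignment scoring** is match +1, mismatch −1, gap −2 everywhere; local
  alignment ties resolve toward the lowest target coordinate. The local
  aligner is exact Smith–Waterman (checked against an independent
  implementation); read extension is banded global alignment over a seeded
  window.
* **Assembly overlap verification is ungapped.** Overlap candidates come
  from shared-k-mer diagonals and are verified by mismatch-tolerant direct
  comparison. The generator's error model is substitution-only, so indel
  handling in overlaps would never be exercised; the banded aligner handles
  indels where they can occur (read-to-reference mapping).
* **Consensus** is per-column majority, ties broken by summed phred weight,
  then alphabetically. Merging is deterministic: the longest qualifying
  overlap wins, ties broken lexicographically by contig id, so a fixed
  input order yields a fixed assembly.
* **"Singlet" means** a secondary-stage contig supported by exactly one
  primary contig; a minimum-length filter exists but is off by default.
* **Discordant pairs** join the assembly pool by default (they did not align
  concordantly; a flag excludes them).
* **Near-match contigs** (high identity but below exact containment) are
  retained as novel with identity/coverage reported — only exact full-length
  matches are provably non-novel; anything else is the user's filtering
  decision.
* **Splice sites** are the 2 bp windows at each intron end.
* **Degenerate inputs**: all-N sequences have undefined GC/complexity
  (returned `NA`, flagged); sequences shorter than 3 bp have undefined
  triplet scores; empty pools, empty contig sets and donor-equals-reference
  runs complete with explicit zero summaries rather than errors.
* **Complexity score denominators** use the count of N-free triplet
  windows, which equals $L-2$ for N-free sequences (the only case the
  worked examples and thresholds address).

## Problem sizes used by the test suite

The full-conditions check runs a 2 Mb single-chromosome reference, 10 gaps
of 300–800 bp, 5 gap fills and 5 non-gap insertions of 1–3 kb, 3 samples at
10× coverage, 0.2% base error — about 100,000 read pairs per sample —
and completes in a few minutes on one CPU. Module tests use 50–300 kb
genomes so each oracle comparison stays near-instant. Metric oracles (N50,
GC, DUST, entropy, interval arithmetic) run on 1,000 random instances each.

## Known limitations

* The greedy assembler is not a production assembler: coverage dips can
  fragment a segment, and junction-spanning reads occasionally assemble
  into a separate flank contig rather than extending the main one, leaving
  that contig without reference flanks (its placement still resolves, but
  realignment cannot verify it).
* Placement resolution is insert-scale (~±30–60 bp with default support),
  not breakpoint-exact; no split-read refinement is attempted.
* Repeats defeat the uniqueness filter by design — anchors with mapping
  quality 0 are discarded, so contigs of repetitive sequence go unplaced
  rather than misplaced.
* The contaminant screen is an exact k-mer filter against a user-supplied
  set; it does not identify contaminants de novo.
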