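---
title: "Methods: post-assembly processing for multiple-k transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-assembly processing for multiple-k transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multika)
```

# The problem

De novo transcriptome assembly from short paired-end reads (here 50 bp) has
no single best k-mer size: transcript coverage follows expression, which is
heavily long-tailed, and de Bruijn graph assemblers resolve highly expressed
transcripts best at large k while rare transcripts need small k. The additive
multiple-k strategy assembles the same reads at several k values
(21, 25, 29, 33, 37, 41 by default here) and merges the results. What remains
after the external assembler has run is a series of bespoke processing
stages, and those are what this package implements: read quality trimming,
per-locus representative selection, cross-k redundancy removal, coverage
based misassembly filtering, repeat and microsatellite scanning, BLAST result
merging, and summary statistics.

# Models and rules, stage by stage

## Read trimming

Each read is cut to its **longest contiguous run of bases with Phred ≥ 13**
(per-base error probability ≤ ~0.05). Two phrasings of this rule circulate —
"quality above p = 0.05" and "Phred < 13 removed" — which differ microscopically
because Q13 corresponds to p ≈ 0.0501; we adopt the operational integer-Phred
form, *keep iff Q ≥ 13*. Ties between equally long runs are broken leftmost
(5' biased, like common trimmers). Reads shorter than 25 bp after trimming
are removed; when exactly one mate of a pair survives it is rerouted to a
singleton file, and `n_removed` counts individual reads, so
`removed + 2·pairs + singletons` always equals the input count (a tested
invariant). The Q20 summary metric is the percent of reads whose *mean*
per-base error probability $10^{-Q/10}$ is strictly below 1%; a read of all
Q20 bases sits exactly at 1% and is excluded by the strict inequality.
Summaries cover retained reads only — whether removed reads should count
toward post-trim length statistics is ambiguous in the source material, and
excluding them is the interpretation we fixed.

## Representative selection and the multiple-k merge

Assembler output arrives as one FASTA per k with headers
`Locus_<i>_Transcript_<j>/<m>_Confidence_<c>_Length_<L>`; the declared length
is verified against the sequence at load, and transcripts under 100 bp are
discarded there. Within each locus one representative is kept: **longest
first, then highest confidence, then lowest transcript index**. The upstream
description ("best transcript on the basis of coverage and sequence length")
does not state a precedence; length-first is consistent with the
longest-wins rule the subsequent clustering uses, and that consistency is why
we chose it.

The merge pools all representatives and clusters greedily: sort by length
descending (ties by input order), then each sequence joins the *first*
existing cluster whose representative it matches at ≥ 95% identity, else
founds its own cluster — the incremental first-fit scheme of CD-HIT-EST,
whose word size and other internals we deliberately do not emulate beyond
the stated threshold. Identity is defined as identical aligned bases divided
by the **length of the shorter sequence**, computed from a semi-global
alignment (shorter sequence global, longer local; match +1, mismatch −1, gap
open −2, −1 per further gap base). This denominator is the point of the
additive strategy: an exact high-k fragment scores identity 1 against its
full-length low-k parent and is absorbed. A shared 11-mer prefilter skips
hopeless pairs; at a 95% threshold and ≥ 100 bp minimum length, any
qualifying pair has at most 5% mismatch events over ≥ 100 positions and hence
a clean run of ≥ 16 > 11 matching bases by pigeonhole, so the prefilter can
never change the outcome (also verified against a no-prefilter oracle in the
tests).

## Coverage validation and chimera detection

Reads are mapped back to the merged transcripts externally (any SAM-emitting
end-to-end mapper); the package consumes plain-text SAM. Depth counts the
reference bases a read actually matches: CIGAR `M`, `=`, `X` increment depth,
`D` spans the reference without read support and does not, `I/S/H/N/P`
contribute nothing. Two filters follow:

* **Low coverage**: mean depth strictly below 3 removes the transcript.
* **Coverage gap**: any base with depth ≤ 1/10 of the transcript's own mean
  flags it as a suspected chimera — two contigs joined incorrectly leave an
  internal trough because few genuine fragments span the false junction. The
  threshold is *inclusive* ("dropped to one tenth" read as attainment); the
  strict variant is one argument away, and the boundary is pinned by tests.

Precedence when several rules apply is rRNA → low coverage → coverage gap,
so the removal tallies are disjoint and sum to the input count. The gap rule
applies to every base by default (`end_margin = 0`). With an end-to-end
mapper, however, coverage necessarily ramps to ~0 within a read length of
each transcript end (hanging reads do not map), and on data of modest depth
the terminal bases alone would flag nearly everything; `end_margin`
excludes that many bases at each end from gap detection, and the synthetic
pipeline runs use `end_margin = read_length`. The gap rule is scale
invariant (multiplying depth by any positive constant changes nothing), and
raising the mean threshold can only move transcripts toward removal — both
tested properties.

## Microsatellites and repeats

The scanner reports every **maximal perfect tandem repeat** of a primitive
2–4 bp motif meeting its unit threshold — 10, 7 and 5 units for di-, tri- and
tetranucleotides respectively, so every reported hit spans ≥ 20 bp. "Primitive"
excludes motifs that are powers of shorter ones (a poly-A run is not an "AA"
dinucleotide repeat); each run is reported once under its canonical motif,
the lexicographic minimum over rotations of the motif and of its reverse
complement; coordinates are 1-based inclusive, anchored at the leftmost full
unit. Imperfect (interrupted) repeats are out of scope, and adjacent runs of
different motifs stay separate hits — a known divergence risk versus tools
that merge compound repeats, which is why the acceptance check on the
archived assembly carries a ±2-per-class investigation band. The scanner is
verified hit-for-hit against a brute-force enumeration of all primitive
motifs at all start positions.

RepeatMasker `.out` files are parsed as-is (coordinates kept 1-based
inclusive) and summarised into the standard repeat category tree
(retroelements split into SINE/LINE/LTR families, DNA transposon families,
small RNA, satellites, simple repeats, low complexity), with within-category
overlaps union-merged per transcript before bases are counted; unknown class
strings fall into the unclassified bucket. Transcripts with any rRNA-class
feature feed the rRNA removal list.

## Annotation merging and ORF completeness

BLAST results (12-column tabular) from several reference sets are merged: a
transcript is *annotated* if some source gives a hit at e-value ≤ 1e-5. The
source material says "less than"; we use ≤, BLAST's own cut-off convention,
with a strict switch exposed. Top hits minimise e-value, tie-break on
bitscore and then file order. Unique-subject counts over top hits divided by
the reference set size give a transcriptome coverage estimate (6,968 distinct
genes of a 31,576-gene reference set ≈ 22%).

The completeness call is this package's documented analog of external
full-length classifiers whose internals are not published: the longest ORF
over all six frames (on length ties a complete ORF wins, then forward
frames); `full_length` needs both start and stop codons and, when a protein
hit is supplied, subject coverage ≥ 90%; complete ORFs covering 50–90% are
`putative_full_length`; everything else is `partial`. The 0.9/0.5 thresholds
are exposed constants.

## Summary statistics

N50 is the largest length L such that sequences of length ≥ L together hold
at least half of all assembled bases — the standard contig N50, equivalent on
every tested fuzzed instance to the brute-force definition. Mean lengths are
rounded half-up to integers as in conventional assembly summary tables
(e.g. 14,828,283 bases over 32,911 transcripts → 450.57 → 451). The 100 bp
floor is applied at every load point. Histogram bins are left-closed,
right-open, with an overflow bin, so counts conserve totals.

# The synthetic-data generator

The generator emulates the study conditions at desk scale so every stage has
a test surface without downloads:

* **Truth transcriptome** — `n_loci` random sequences, log-normal lengths
  (median ≈ 450 bp, the scale of short-read transcriptome contigs) clipped
  to 100–5,750 bp; expression weights follow a discretised power law
  (rank$^{-s}$, `expression_shape` s = 1 by default), creating the
  high/low-coverage dichotomy that motivates multiple-k assembly.
* **k-assemblies** — for each of k = 21…41, each locus is captured with
  probability `capture_prob_per_k` as 1–2 isoforms, each a contiguous
  substring (uniform anchor, retained fraction drawn from
  `truncation_frac_range`), emulating the shorter contigs that high-k
  assemblies produce. A `chimera_rate` fraction of extra transcripts fuse
  the 5' half of one locus to the 3' half of another, junction recorded.
* **Reads** — fragments drawn proportional to weight × length, paired 50 bp
  ends, mate 2 reverse-complemented; per-base Phred from a linearly decaying
  per-cycle profile with Gaussian jitter, substitution errors injected at
  $10^{-Q/10}$, ~0.1% of bases masked to N; a `p_degraded` fraction of reads
  collapse to low quality from a random cycle onward, which is what makes
  trimming remove reads and create singletons. The defaults (Q36 start,
  −0.28/cycle, 15% degraded) give a raw Q20 of ~80% and ~7% of reads removed
  at desk scale; the real study's joint figures (90.5% Q20 yet 20% of reads
  removed) are not reproducible by a two-component per-cycle model and we
  did not chase them — the generator's contract is to exercise the logic,
  not to re-create one instrument's error structure.
* **Alignments** — truth-guided placement: a mate maps to a transcript iff
  its source interval lies fully inside the transcript's recorded source
  region (end-to-end mapper semantics, no soft clips), choosing uniformly at
  random among multiple candidates as mappers do with multireads. No read
  ever spans a chimeric junction because chimeras exist only in the
  assemblies, never in the truth — producing exactly the internal trough the
  filter detects. This is a placement harness, not an alignment algorithm.

Determinism: every generator stage reseeds from the master seed plus a
stage offset, so identical configurations give byte-identical FASTA/FASTQ
output regardless of ambient RNG state, and regenerating reads does not
perturb the transcript draw.

What passing on synthetic data does *not* show: real misassemblies are not
clean half/half fusions; real coverage has GC and positional biases; real
reads have indels and adapter remnants (both out of scope, substitutions
only); and the placement harness sidesteps alignment ambiguity entirely. The
synthetic results validate the *rules*, not the biology.

# Numerical and design choices

* Tie-breaks are all deterministic: leftmost trimming run, first-fit
  clustering with length-then-input order, confidence-then-index
  representative selection, complete-ORF-then-forward-frame on equal length.
* Oases confidence semantics are undocumented; simulated confidences are
  uniform on (0, 1] and used only for tie-breaking.
* The alignment scoring (1/−1, gap open −2, extend −1) is fixed; it matters
  only near the 95% boundary, and the clustering contract is defined in
  terms of this package's `pairwise_identity`.
* Depth vectors are 0-based internally; every emitted table is 1-based
  inclusive except the BEDGraph export (0-based half-open by convention).
* Degenerate inputs are first-class: empty FASTQ, empty SAM (all-zero
  profiles), header-only RepeatMasker files, zero-length transcripts
  (error), empty reads after trimming (mean error treated as 1, so never
  Q20).

Problem sizes in the shipped tests and in `scripts/acceptance.R` are chosen
for a desk-scale study: tens of loci, thousands of read pairs, six
k-assemblies, 1,000-instance oracle sweeps — enough to exercise every branch
and invariant while a full run stays within about a minute.

# Known limitations

* Identity is computed from one optimal alignment; co-optimal alignments
  with different matched-base counts are theoretically possible near the
  threshold.
* The repeat category tree is a fixed mapping; repeat libraries with novel
  class strings land in the unclassified bucket rather than failing.
* The microsatellite scanner's per-strand anchoring of runs with a partial
  trailing unit can shift reported windows by up to one motif length between
  a sequence and its reverse complement (hit counts and motifs are strand
  stable; the tests pin this tolerance).
* The coverage-gap rule with `end_margin = 0` is faithful to the described
  filter but aggressive at transcript ends under end-to-end mapping; choose
  the margin to match the mapper's behaviour.
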