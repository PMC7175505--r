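---
title: "Methods: peak quantification and scaled coverage tracks"
author: "binscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak quantification and scaled coverage tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and conventions behind `binscale`: what
each quantity is, which parameters matter, the numerical choices made where
the design was genuinely open, what the synthetic-data generator emulates,
and what the test suite does and does not establish about real data.

# Read filtering and effective library size

Every computation starts from the same read-level predicate
(`readPassesFilter()` with an `AlignmentFilter`). Defaults: drop
duplicates, secondary, supplementary, QC-fail and unmapped records; drop
paired reads whose mapped mate sits on a different chromosome; no MAPQ
cutoff (`minMapq = 0`). The mate-chromosome rule exists because a locus
piled with inter-chromosomal read pairs can masquerade as a strong peak; on
synthetic data the rule removes exactly the planted discordant pairs and
nothing else. Strand selection is *not* part of the predicate: the
counting and coverage functions apply it, because matching a peak's feature
strand requires knowing the peak.

The effective library size comes from a full pass over the BAM
(`computeLibraryStats()`), not from the index: index totals include
duplicates and low-quality reads and would bias every normalization that
divides by depth. The pass yields four numbers: passing reads, distinct
passing fragments (read names), aligned bases (sum of CIGAR `M`/`=`/`X`
lengths — `N` and `D` consume reference but carry no signal), and the
genome length from the header.

For paired data, the strand of a fragment is the strand of mate 1; mate 2
is flipped. `orientation = "reverse"` inverts the convention for
dUTP-style protocols where mate 1 is antisense. This is a convention the
alignment flags cannot decide for you, so it is user-selectable everywhere
a strand matters.

# Peak quantification

`countReadsInPeaks()` counts a read for every peak its outermost aligned
reference span overlaps by at least one base. Two deliberate choices:

* a read overlapping two peaks counts in both — no apportioning; merging
  overlapping peaks beforehand is the caller's responsibility;
* the outermost span (including `N` skips) is used for counting, not the
  spliced segments. Peak counting is dominated by DNA assays where `N` is
  absent; RNA users should know that a junction-spanning read counts
  toward a peak inside its intron.

In fragment mode a properly paired fragment is evaluated once, on the
leftmost mate (TLEN > 0), as the interval from its start over |TLEN|
bases; pairs without a usable TLEN fall back to single-read counting,
which is robust to half-mapped pairs. The effective library size used by
the normalizations switches to fragment counts in this mode, keeping
numerator and denominator in the same units.

Normalizations, per sample with effective size $N$ and peak length $L$ bp:

* FPKM: $c \cdot 10^9 / (L \cdot N)$;
* TPM: $10^6 \, r_i / \sum_j r_j$ with $r_i = c_i / (L_i/10^3)$; columns
  sum to $10^6$ whenever any count is nonzero, and an all-zero column
  stays zero;
* library-size: $c \cdot \min_s N_s / N$, so the smallest library's counts
  pass through unchanged.

# Coverage tracks

`binnedCoverage()` computes, per fixed bin, the **mean per-base depth**:
covered bases in the bin divided by the true bin width (the last bin of a
chromosome is narrower and uses its real width). Mean rather than sum was
an open choice; the mean makes values independent of bin size and is the
quantity for which log2 ratios and RFD are well defined, so anyone
comparing bit-level outputs against a summing implementation should divide
by bin width first. At `binSize = 1` the track equals per-base coverage.
Reads contribute only their overlapping bases to a partially overlapped
bin, consistent with the per-base definition.

Scaling options (`scaleTrack()`):

* genome-size: factor $= G / B$ (genome length over aligned bases), the
  reciprocal of mean depth. Deeper-than-1x samples are scaled down,
  shallower ones up; each sample can be scaled alone.
* smallest-library: factor $= \min_s n_s / n$ over a co-processed set.
* custom: any positive factor per sample, e.g. reciprocal size factors
  from a differential-expression fit.

Smoothing (`smoothTrack(track, n)`) replaces each bin by the mean of the
window of $2n+1$ bins, truncated at chromosome ends — no zero padding, so
edges are not biased downward — and never crossing chromosomes. When both
scaling and smoothing are requested, scaling is applied first; the scalar
commutes with the windowed mean, so the order is a presentation choice,
fixed here for determinism of the pipeline description.

Two-file operations require identical bin size and reference geometry.
`log2Ratio()` uses the **first file as numerator** with default
pseudocount 0, under which any bin with a zero on either side becomes `NA`
and is omitted by the writers — no ratio is fabricated from an empty bin.
A positive pseudocount emits every bin. `subtractTracks()` is the plain
bin-wise difference and may go negative.

## Replication fork directionality (OK-seq)

Per bin $i$, with Watson = forward-strand and Crick = reverse-strand mean
coverage under the same filter:

$$\mathrm{RFD}_i = \frac{X_{\mathrm{Crick},i} - X_{\mathrm{Watson},i}}
                       {X_{\mathrm{Crick},i} + X_{\mathrm{Watson},i}}$$

RFD lies in $[-1, 1]$; bins with no reads on either strand are `NA`
rather than 0, so balanced fork directions remain distinguishable from
missing data. The flag-to-strand mapping (Watson = SAM flag 0x10 unset on
mate 1) is a convention, flippable with `orientation`. Default bin size
1,000 bp; generic tracks default to 5 bp and END-seq to 1 bp — the
assay-typical resolutions, all overridable.

## Replication timing

`reptimeTrack()` bins both files (100 bp default), smooths each over 500
adjacent bins, then takes the log2 ratio with the first file as numerator.
The numerator convention is genuinely ambiguous in the field (G1-first and
S-first conventions both circulate, with opposite signs); `binscale` fixes
*first argument = numerator* and leaves the biological orientation to
argument order. The 50 kb / 4-bin parameterization used for single-cell
Repli-seq and BrdU-IP data is reached by overriding `binSize` and
`smoothen`.

## END-seq

`endseqTracks()` returns forward and reverse coverage separately;
`negateReverse = TRUE` (the "endseqr" preset) multiplies the reverse track
by -1 so both can be overlaid in a single panel. The two stranded tracks
sum, bin-wise, to the unstranded track.

## Splice-aware RNA-seq with adaptive resolution

Fixed-bin coverage blurs exon–intron boundaries: a bin straddling the
boundary averages exonic and intronic signal. `adaptiveBins()` tiles the
chromosome at `binSize` (default 15 bases) and checks every adjacent-base
pair: if the absolute coverage difference **exceeds 4 reads** (strictly
greater — i.e. a jump of at least 5), the bin containing the pair is
emitted at single-base resolution; other bins are emitted at their mean.
The pair straddling two bins is attributed to the downstream bin so every
pair is checked exactly once. Three further choices:

* zero runs are emitted explicitly, making intron gaps visible and
  re-expansion to per-base values total;
* adjacent equal-valued runs are merged (this never changes the expanded
  per-base function);
* non-triggered bins report the mean, not the sum, consistent with every
  other track in the package.

Consequences proved in the tests: within any triggered bin the output
reproduces true coverage exactly at every base (so boundaries with a > 4
jump are exact to the base); total absolute reconstruction error never
exceeds that of plain fixed bins at the same width; `binSize = 1`
degenerates to per-base coverage.

# Coordinates, writers, determinism

Internally all containers are Bioconductor-native (GRanges/IRanges,
1-based closed); all file I/O follows each format's own convention —
BED/bedGraph/bigWig are 0-based half-open — so the on-disk semantics match
what genome browsers expect. Writers merge consecutive equal-valued bins,
omit `NA` bins, keep chromosome order exactly as in the BAM header, and
store bigWig values as 32-bit floats (round-trip checks tolerate 1e-6
relative error accordingly). `writeBedGraph()` emits the same intervals as
`writeBigWig()` in text form.

Optional per-chromosome parallelism (`threads`) uses a fixed merge order
(header order), so outputs are identical for any worker count; the test
suite asserts bit-identical results for 1 versus 4 workers and across
repeated seeded runs.

# The synthetic-data generator

`simulateAssay()` produces indexed BAMs plus truth tables:

* **atac/chip** — FR read pairs (50 bp reads, 150–400 bp fragments)
  drawn 70% from 200 planted peaks of 200–2,000 bp on three 50 kb
  chromosomes, 30% background, 25,000 pairs, 5% duplicate-flagged pairs;
  optionally a block of inter-chromosomal pairs piled on one peak. These
  defaults mirror a small but realistically structured ATAC library:
  enough depth that every peak is covered, enough background that counts
  are not trivially saturated.
* **okseq** — single-end reads, Watson-biased (90%) left of each planted
  origin and Crick-biased right of it, so true RFD switches from -/+ at
  the origin.
* **endseq** — stranded read stacks ending at planted break positions.
* **reptime** — an S/G1 pair on a 1.5 Mb chromosome with a 500 kb early
  block in which S coverage is doubled. The chromosome is long on purpose:
  the 50 kb / 4-bin parameterization needs a 9-bin (450 kb) smoothing
  window to fit inside the block.
* **rna** — spliced reads over two toy genes (three exons on +, two on -)
  at ~75x exon depth, so exon edges always exceed the adaptive-binning
  trigger.

What the generator does **not** emulate: GC and mappability bias,
realistic base qualities or error models, soft-clipped or chimeric
alignments, fragment-length distributions conditioned on chromatin, copy
number. Tests passing on this data therefore establish algorithmic
correctness (counting, normalization arithmetic, strand bookkeeping,
boundary exactness, determinism), not robustness to real-library
artifacts.

The counting oracle (`oracleCounts()`) re-derives filter decisions from
the generator's spec columns and re-parses CIGAR strings with regular
expressions — it shares no code or containers with the production path,
which is the point: agreement between the two is evidence, not tautology.

# Problem sizes and degenerate inputs

The test suite runs ten ~50,000-read fixtures through every counting mode
against the oracle, plus smaller targeted fixtures per module; the whole
suite completes in about a minute on one CPU. Degenerate inputs are
defined, not accidental: empty peak sets produce header-only tables;
all-zero counts give zero TPM; empty bins give `NA` (omitted) rather than
0 in ratio tracks; zero-length BED intervals and malformed lines abort
with the line number; a zero effective library size is fatal rather than
silently producing infinities.

# Known limitations

* No CRAM support; BAM with BAI only.
* Base qualities are ignored; coverage is purely positional.
* Whole-chromosome per-base vectors are materialized during RNA-mode and
  per-base queries; memory scales with chromosome length (fine for
  mammalian chromosomes, ~250 MB per double-precision chromosome at the
  extreme, but worth knowing).
* Peak counting loads one chromosome's filtered records at a time; BAMs
  with extreme single-chromosome depth bound memory accordingly.
* Strand-switch segmentation on RFD/reptime tracks (calling initiation
  zones or timing domains) is out of scope; the tracks are the product.
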