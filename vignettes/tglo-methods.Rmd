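---
title: "Methods: the TGLO discovery screen and its synthetic testbed"
author: "tgloscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the TGLO discovery screen and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The screen

`tgloscreen` identifies transcribed germline-limited ORFs (TGLOs): coding
sequences present in a ciliate's germline micronuclear (MIC) genome,
transcribed during the sexual life cycle, and eliminated from the somatic
macronuclear (MAC) genome. The screen combines four kinds of evidence on
one germline reference:

* **Candidate ORFs.** A six-frame scan reports every maximal start-to-stop
  ORF under the ciliate nuclear genetic code (translation table 6: TAA and
  TAG encode glutamine, TGA is the sole stop). The start is the first ATG
  after the previous in-frame stop, the reported interval includes the
  stop codon, and nested ORFs sharing a stop reduce to the longest. The
  default minimum length is 45 aa, chosen to cover the shortest coding
  class the simulator plants; the scan accepts externally produced gene
  models (GFF3) instead, in which case exon structure and intron fractions
  become available.
* **Somatic DNA absence.** Whole-cell DNA libraries from growing cells are
  dominated by MAC copies, so read counts measure somatic presence. A
  candidate is rejected if *any* DNA library places more reads on it than
  that library's calibrated lower-tail threshold. We apply the per-library
  ALL-pass rule (rather than pooling) because library depths differ and a
  single somatically retained copy in one strain must be enough to reject.
* **Transcription.** Per RNA library (one per developmental time point),
  a candidate's support is its any-overlap read count and the fraction of
  CDS bases with depth at least 1. Classification is per library ("in at
  least one time point"): *high transcription* when some library reaches
  the calibrated upper-tail read count and covers more than 80% of the
  CDS; otherwise *low transcription* at a permissive floor of at least
  2 reads and more than 20% coverage; otherwise rejected. Count rules are
  inclusive, coverage rules strict — the boundary case (enough reads,
  exactly 80% covered) is low, not high. High takes precedence, so the
  final sets are mutually exclusive. The low floor of 2 reads is not a
  percentile: it is the screen's deliberate recovery margin for weakly
  expressed loci.
* **Redundancy control.** One model per transcribed locus (single-linkage
  components of same-strand overlapping calls keep their best-supported
  member: highest read count, then highest coverage fraction, then
  longest, then smallest id); then greedy longest-first sequence
  clustering at 90% identity over at least 70% of the shorter sequence
  (both orientations), and removal of sequences more than half masked by
  low-complexity windows (20 bp Shannon entropy below 1.2 bits) or exact
  tandem arrays (unit 1–6 bp, at least 3 copies and 10 bp total — the
  array-length floor exists because 3 bp homopolymers occur in ~8% of
  random DNA and are not repeats in any useful sense).

## Monte Carlo threshold calibration

Absolute read-count cutoffs are meaningless across libraries of different
depth. The screen therefore builds an empirical null: every candidate
locus is placed uniformly at random (lengths preserved, placements wholly
inside one interval) into the germline-limited space — the merged
complement of MDS intervals — 100 times, and per-locus read counts are
recorded per library. Thresholds are **nearest-rank (type-1) quantiles**
of these backgrounds: the smallest attained count whose empirical CDF
reaches the level. Nearest-rank guarantees the threshold is a realizable
integer count; on a zero-dominated DNA background the 5th percentile is 0,
which makes the DNA rule "no somatic reads at all". Placements may overlap
each other within a shuffle (a no-overlap mode exists but is off by
default: candidates are placed independently because nothing in the
decision logic couples them). The RNA background pools libraries by
default — one pair of transcription thresholds governs the whole time
course — with a per-library mode available.

## Nanochromosome assembly and MDS decomposition

The assembler formalizes an iterative manual procedure: seed with one
locus read, then repeatedly extend either contig end with an unused read
(either orientation) whose end matches exactly with overlap of at least
`min_overlap` (default 30 bp). The free choices are pinned down so the
result is reproducible: a candidate read's overlap is its *maximal* exact
overlap; among candidates the read adding the most new sequence wins; ties
break on the lexicographically smallest read id; a side closes once the
contig end carries two tandem telomere units (C4A4 at the 5' end, its
reverse complement at the 3' end; a partial terminal unit is tolerated);
assembly stops when both sides are closed or no extension exists. Every
step is logged in an extension trace. The output orientation is inherited
from the seed read — the reverse complement of a telomere-capped
chromosome is itself telomere-capped, so reconstructions are exact up to
orientation. Mismatched overlaps never merge; error-free reads are the
supported regime.

Decomposition aligns the contig core (telomere runs trimmed) to the
germline locus by maximal exact matches (shared-k-mer diagonals, both
strands, minimum block 20 bp), selected greedily longest-first without
double-using contig bases; a candidate block colliding with already
claimed bases is trimmed to its longest free sub-span rather than
discarded, because maximal matches can overrun annotated block edges by a
few coincidentally matching junction bases. Ordered blocks recover the
somatic permutation and inversions of a scrambled locus, and the germline
coordinates flanking the terminal blocks are reported as telomere addition
sites. Chimeric telomere/locus reads give an independent, per-read view of
addition sites with support counts.

## Quantification and enrichment

Per-feature counts over libraries are normalized with the median-of-ratios
estimator (reference per feature: geometric mean across libraries over
features nonzero everywhere; factor per library: median ratio to the
reference). Only *ratios* of size factors are identified — scaling one
library by c multiplies its factor relative to any other library's by
exactly c, while the common geometric-mean reference absorbs
c^(1/m). Expression heat-map inputs are `log2(count/factor + 1)` with
complete-linkage Euclidean hierarchical row clustering. Feature-class
enrichment (e.g. 27-nt small RNAs over MDSs versus TGLOs) uses per-feature
RPKM (library total: all mapped reads) compared by the two-sample
Kolmogorov–Smirnov test. The p-value defaults to the asymptotic Kolmogorov
distribution evaluated at `D * sqrt(n_a*n_b/(n_a+n_b))`; an exhaustive
permutation mode exists for samples of at most 10 per class. At n = 5+5
the asymptotic and exact p agree to within 0.05 at every achievable D
except D = 0.4, where the gap is 0.054 — worth knowing if the asymptotic
mode is used on very small classes. Under the null (classes simulated
identically) the asymptotic test at level 0.05 rejects slightly
conservatively (about 3.5–5% in our checks), a consequence of the
asymptotic approximation, not of the implementation.

Strain retention per locus follows the DNA-threshold logic: somatic when
counts exceed the strain threshold in every strain, germline-limited when
in none, strain-specific somatic otherwise (with the retaining strains
listed) — the signature of a nanochromosome kept in only one parental
line.

# The synthetic testbed

The generator builds the architecture the screen assumes, with known
truth:

* Germline contigs alternate long germline-limited spacers (default
  8–16 kb) with precursor loci of 3–8 MDSs (200–800 bp) separated by IESs
  (50–200 bp); one fifth of loci are scrambled (random non-identity
  somatic permutation, random subset of MDSs inverted). Base composition
  is AT-rich (GC 0.31), as in ciliate germline genomes.
* The MAC genome is derived, not simulated: per locus, MDSs concatenated
  in somatic order/orientation, capped with five tandem telomere units per
  end by default.
* Planted ORFs are exact cassettes: an upstream in-frame stop pins the
  scanner's start; body codons are random non-stops. Every ~18 body codons
  a **stop-seeding motif** (`CTGACTGACTCACTCACTCAA`) is written in: it
  carries TGA at frame offsets 1 and 2 and TCA (a reverse-strand TGA) at
  all three offsets, with no frame-0 stop or ATG. This terminates all five
  alternative reading frames regularly, so no alternative-frame ORF of
  screening length can nest inside or span a cassette. Without it the
  planted truth is ambiguous — several maximal ORFs can explain the same
  transcription evidence, and no classifier could be scored against a
  unique answer.
* Expression truth is an expected read count per transcript per time
  point on the developmental grid {0, 12, 18, 24, 36, 48, 60, 72} h.
  TGLOs are near-silent before 24 h and peak at 36–60 h at 20-fold
  transcript coverage. Low-transcription TGLOs transcribe only a fragment
  (default half) of their CDS: sparse partial coverage is precisely what
  separates the low class from the high class under the coverage rules,
  and a contiguous expressed fragment makes that separation deterministic
  rather than a coin flip on Poisson coverage. MAC genes receive diverse
  profiles (constitutive, early, declining, mid-peak) so normalization has
  always-nonzero features. Realized RNA counts are Poisson around the
  planted expectation; reads are drawn uniformly within the transcript on
  its sense strand (a stranded protocol).
* Whole-cell DNA mixes MAC and MIC templates at a per-copy,
  length-weighted ratio (default 100:1), with the library sized so the MAC
  genome reaches the requested fold coverage. Small RNAs are exactly 27 nt
  and drawn only from inside MDSs; template RNAs span nanochromosome
  cores. All simulators are bit-reproducible under a fixed seed.

## What the testbed does and does not show

Error-free reads, exact mapping and clean MDS junctions mean the tests
exercise the screen's decision logic, not robustness to sequencing error,
mapping ambiguity or pointer-sequence processing; repeats exist only as
the planted low-complexity cases. Passing tests therefore demonstrate the
algorithmic contracts, calibrated thresholds and bookkeeping — not
performance on real libraries.

One quantitative limit deserves emphasis. With a 100:1 MAC:MIC template
ratio and 30-fold MAC coverage, germline-limited space still receives
about 0.3-fold MIC coverage — roughly one stray read per TGLO-sized locus
per library. The calibrated DNA threshold over such a background is 0, so
each planted TGLO survives only if it drew exactly zero whole-cell reads
in every DNA library; across 30 TGLOs and three libraries the chance of
full recovery is about e^-60. Recall under this mixture is therefore low
by construction (~10–15% at our default scale), while precision and the
zero-false-positive properties hold. In real whole-cell libraries the
somatic excess is far larger and germline-limited coverage is effectively
zero, which is the regime the screen was designed for; the package's
somatic-DNA control (`dna$kind = "dna_mac"`) realizes it and recovers the
planted sets perfectly (precision = recall = 1 for both classes across
seeds). `scripts/acceptance.R` reports both conditions side by side.

## Problem sizes used in tests

The standard study scale is a ~0.8–1 Mb germline genome (50 loci, 5
contigs), 15 high + 15 low TGLOs, 30 silent germline ORFs, 20 MAC genes,
three whole-cell DNA libraries at 30x (2x250-style read length 250), one
75 bp RNA library per time point; the full screen runs in well under a
minute. Unit tests use a ~60 kb, 6-locus genome. The assembly oracle uses
100 random 1–3 kb nanochromosomes with evenly tiled 100 bp reads at 20x
and minimum overlap 30 — at that depth every overlap is at least 70 bp and
unique in random sequence. Oracle chromosomes carry exactly two tandem
telomere units per end so that the assembler's two-unit termination rule
coincides with the chromosome end, making byte-exact reconstruction
well-defined; with the default five-unit caps the assembler still closes
correctly but may stop within the cap.

## Numerical conventions

Coordinates are GRanges-style 1-based closed intervals everywhere inside
the package; GFF3 maps 1:1 and BED is converted at the file boundary.
Quantiles are nearest-rank (note `{0..99}` at level 0.95 gives 94 — the
smallest value whose ECDF reaches 0.95). Deterministic orderings: ORFs by
(contig, start, end, strand); alignments by (contig, start, read id);
clustering input by (length descending, id ascending); assembler ties by
read id. All stochastic stages derive their seeds from one global seed.
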