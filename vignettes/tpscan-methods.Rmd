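---
title: "Methods: peak discovery, consensus differential expression, and target scanning for small RNA-seq"
author: "tpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak discovery, consensus differential expression, and target scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpscan)
```

# Scope and model

`tpscan` implements an annotation-agnostic discovery pipeline for small-RNA
loci from strand-aware short-read alignments, of the kind used to ask which
small RNAs respond when *C. elegans* feeds on mildly pathogenic bacteria
(*P. aeruginosa* PAO1, *S. enterica* MST1) versus its standard food
(*E. coli* OP50) across two consecutive generations.  Rather than counting
reads over an existing annotation, the pipeline defines its own features --
**transcriptional peaks (TPs)** -- from the data, classifies them against
the reference annotation, and then asks which of them respond to *both*
pathogens in *both* generations.  That cross-condition intersection is the
scientifically interesting operation: a single universally upregulated
locus is the candidate common effector of the phenotype, and the
universally downregulated set is its mirror image.

The stages, each exposed as ordinary functions:

1. **Peak discovery** (`poolCoverage()`, `segmentPeaks()`, `filterPeaks()`,
   `callPeaks()`).  Per-base read depth is computed per contig and strand
   from the *pooled* alignments of all libraries (features are defined once,
   from merged data, so feature identity is stable across conditions).  A
   peak is a maximal run of bases whose depth is **strictly greater than
   10** reads; retained peaks must be **17--150 nt** long (inclusive) with
   **mean depth at least 10** (inclusive).  The two thresholds deliberately
   use different operators -- strict for the per-base rule, inclusive for
   the mean -- and the bounds are inclusive on both ends.  A single
   sub-threshold base splits a peak; no gap merging is done by default
   (`mergeGap = 0`), since any merge distance would be an extra assumption.
   The mean is computed over the candidate's own bases, not a padded
   window.  Coverage is raw pooled depth; no normalization is applied
   before thresholding.
2. **Classification** (`classifyTps()`).  A decision cascade per peak:
   *known* if it matches an annotated sRNA (miRNA, pre-miRNA, 21ur piRNA,
   tRNA, sno/snRNA) on the same strand with reciprocal overlap at least
   0.8; else *partially novel / nested* if fully contained in any feature
   (either strand); else *partially novel / overlapping* if it intersects
   one; else *novel / intergenic*.  Orientation (sense/antisense) is taken
   from the host with the largest overlap, ties broken by the smaller
   feature, then by id.  Classification is against leaf features (exons,
   introns, UTRs, the sRNAs themselves), so a peak inside an intron is
   "nested in an intron".  rRNA is deliberately *not* an sRNA biotype here:
   fragments inside an rRNA gene classify as nested, which is how
   rRNA-internal peaks are conventionally reported.  The 0.8 reciprocal
   threshold is a package choice (no published criterion exists for
   "matching" an annotated sRNA); it is configurable, and we make no claim
   that any particular published known/partially-novel/novel split is
   reproduced by it.
3. **Counting** (`countReads()`).  featureCounts-style defaults: a read is
   assigned to a feature it intersects by at least 1 nt; reads hitting more
   than one feature are discarded as ambiguous; unstranded by default (the
   upstream tool's default), with a stranded mode because TPs are
   strand-specific.  All four read buckets (assigned, ambiguous, no
   feature, unknown contig) are reported and always sum to the library
   total.
4. **Differential expression** (`runConsensusDE()`).  Two deliberately
   simple estimators re-implemented in the package (see below) and a
   three-part consensus rule: a feature is *up* in a contrast iff
   log2 fold change > 1 **and** BH-adjusted Wald p < 0.05 **and** exact-test
   p < 0.05; *down* symmetrically with log2fc < -1.  The down gate is the
   assumed mirror of the published up gate.  Each pathogen x generation
   cell is compared to the control of the same generation; BH adjustment is
   within contrast.
5. **Cross-condition set logic** (`buildVenn()`,
   `flagUniversalCandidates()`).  Exact set algebra on consensus calls over
   the four contrasts; reported cells include shared-in-all,
   bacterium-specific (both generations of exactly one pathogen) and
   generation-specific (a single contrast).  Because features come from one
   pooled peak call, membership across contrasts is well defined;
   re-calling peaks per condition is deliberately rejected.
6. **Target scan** (`screenTargets()`).  For a mature miRNA against
   candidate transcripts (typically the universally downregulated mRNAs),
   the longest contiguous perfect antiparallel Watson-Crick complement is
   found per candidate (G-U wobble excluded by default, toggleable);
   hits need seed >= 12 nt, seeds are capped at 20 nt, and each hit gets a
   nearest-neighbor hybridization free energy at 20 degrees C -- the
   experimental temperature -- with hits ranked by seed length then energy.
   Scanning uses the full candidate sequence, not only 3'UTRs, because the
   relevant silencing mechanism is RNAi-like near-perfect pairing.
7. **RT-qPCR arithmetic** (`relativeExpression()`).  Classic
   delta-delta-Ct against a calibrator (U6): replicates are averaged on the
   dCt scale, fold = 2^(-ddCt) with amplification efficiency fixed at 2
   (a config scalar for sensitivity analysis).

# The differential-expression model

The package implements the *decision rule* of a two-package consensus, not
numerical identity with any released implementation.  Both estimators
assume counts $K_{ij} \sim \mathrm{NB}(\mu_{ij},\ \phi)$ with
$\mathrm{Var}(K) = \mu + \phi\mu^2$.

**Normalization.**  Method A uses median-of-ratios size factors: the
median over features (positive in all libraries) of the ratio of each
library's count to the feature's geometric mean.  Method B uses a
simplified TMM: log2 ratios of library-proportions against a reference
library (the one whose upper quartile is closest to the mean), trimmed 30%
from each M tail and 5% from each A tail, averaged unweighted, re-centered
to geometric mean 1.

**Dispersion.**  Method-of-moments, pooled across condition groups:
$\hat\phi = \max\{0, (s^2 - \bar m)/\bar m^2\}$ on normalized counts, with
$s^2$ the replicate variance pooled within groups.  The default "shrunken"
mode moves each feature's estimate toward the mean-expression trend (10
abundance bins) with weight proportional to the residual degrees of
freedom against a prior weight of 10.  The raw moments mode is retained
because it is the estimator the simulation oracles check directly.

**Method A (Wald).**  log2fc from normalized group means with a 0.5
pseudo-count; the standard error propagates the NB variance through the
delta method (the same 0.5 pseudo-count stabilizes zero-count groups);
two-sided p from the standard normal.  Features with all-zero counts on
both sides report (log2fc = 0, p = 1).

**Method B (conditional exact).**  Counts are equalized to a common
effective library size (library size x TMM factor) and rounded; given the
two group sums, the p-value is the total probability of splits at least as
improbable as the observed one under NB with equal means and a common
dispersion (the median of the per-feature shrunken estimates).  At
$\phi = 0$ this collapses to the exact binomial split test, which is one of
its test oracles.

Under the global null (NB, $\phi = 0.1$, 3 vs 3) the raw Wald rejection
rate at 0.05 sits near 0.06 and the consensus false-positive rate is
below 1%; planted two-log2 effects at mean 100 are recovered by the full
consensus in well over 90% of features.  Those numbers are recomputed, not
quoted, by the test suite and the acceptance script.

# The energy model

`duplexEnergy()` computes $\Delta G(T) = \Delta H - T\Delta S$ summed over
stacked base-pair terms plus a duplex-initiation term and a terminal-A-U
penalty per A-U-closed helix end, using the standard Watson-Crick RNA
nearest-neighbor parameter set (Xia et al. 1998, as adopted in the
Turner 2004 rules), shipped as a plain table (`nnParameters()`).
Temperature is converted to Kelvin internally; the default 20 degrees C
matches the experimental temperature of the biology being modelled, and
colder temperatures give more negative stacking terms, so a helix is never
less stable at 20 than at 37 degrees.  The parameter table covers
Watson-Crick stacks only; if G-U wobble seeds are enabled in the scan,
such hits carry `NA` energy rather than an invented wobble parameter --
a documented limitation.  There is no published numeric cutoff for a
"strong" interaction energy; the scan ranks hits and flags those below a
configurable -10 kcal/mol default, clearly a package default.

# The synthetic study

`simulateGenomeAnnotation()`, `simulatePlantedLoci()`,
`simulateAlignments()` and `simulateCounts()` generate every input the
pipeline consumes, with known ground truth, emulating the 3-bacteria x
2-generation x 3-replicate design (single-end reads, 22 nt by default,
within the 17-36 nt range typical of small-RNA libraries).

The default planted-locus set (~18 loci on a 50 kb contig) is built to
straddle every decision boundary: coverage well above and below the 10x
rules, a 16 nt locus (below the length floor) and a 160 nt locus (above
the ceiling), a zero-coverage locus, and at least one representative of
every context class.  Two loci are universally responsive across all four
pathogen contrasts -- one up (+2 log2fc; the planted analog of a mature
miRNA induced by both pathogens in both generations) and one down (-2; the
analog of a universally repressed pre-miRNA) -- plus bacterium-specific
and generation-specific loci that populate the other Venn cells.  The
universal loci are planted at high coverage (600x pooled) because they
model a strongly expressed, strongly induced mature miRNA; threshold
straddlers sit at 0-25x.  Since neither sequencing depth nor library size
is prescribed by the modelled study, pooled coverage targets are free
parameters of the generator chosen once so that planted loci bracket the
10x thresholds.

Reads are laid on fixed tiling offsets that cover each locus end to end;
the pooled read total per locus is fixed at its expectation (so pooled
coverage calibrates deterministically to the target within rounding) and
allocated to libraries multinomially in proportion to each library's
condition multiplier, giving per-library counts binomial-thinned
(approximately Poisson) sampling variability.  Condition effects are
applied as library-level read-count multipliers, matching the count-level
NB model downstream.  Background reads sit on a coarse grid at pooled
depth at most 2, at least 200 nt away from any planted locus.

What the generator does *not* emulate: realistic read sequences or base
qualities, sequencing error, adapter content, multi-mapping ambiguity,
biological overdispersion *within* the alignment simulator (the count-level
simulator `simulateCounts()` provides NB overdispersion separately), or
annotation complexity such as overlapping genes and alternative isoforms.
A green suite therefore demonstrates the correctness of the computation on
data satisfying its assumptions, not performance on real libraries.

# Numerical and convention choices

- **Coordinates.**  Internally everything is a `GRanges` (1-based, closed
  intervals -- the Bioconductor convention).  GFF3 is read/written natively
  in that convention; SAM positions and BED half-open intervals are
  converted by the underlying parsers (Rsamtools/rtracklayer).  A 36 nt
  read at SAM position 100 occupies bases 100..135, i.e. the 0-based
  half-open interval [99, 135).
- **Peak ids** are stable and deterministic: `TP_<contig>_<strand>_<start>`.
- **Ties** in classification hosts: largest overlap, then smallest
  feature, then lexicographic id.  Ties in seed search: smallest target
  start, then smallest miRNA start; a seed longer than the 20 nt cap
  reports the capped-length window chosen by the same rule.
- **Degenerate inputs.**  Empty BED files give empty streams; an empty
  peak set writes a header-only GFF3; all-zero features test as
  non-differential (p = 1) rather than erroring; a library with all-zero
  counts is an error in TMM (named in the message); dispersion estimation
  refuses single-replicate groups.
- **Multi-mapped reads** all contribute to coverage (primary-only is a
  flag); no MAPQ filter by default.
- **RNG.**  Every generator takes an explicit integer seed and restores
  the caller's RNG state; identical seeds give byte-identical outputs.

# Problem sizes used by the checks

The shipped tests and the acceptance script run at sizes chosen to
exercise every code path at desk scale: one 50 kb contig with ~18 planted
loci and 18 libraries for the end-to-end study; 100 random tracks up to
10 kb against a per-base brute-force scanner; 1,000 random peaks against
1,000 random features for the classifier oracle; a 5,000-feature null and
20 replicated 250-feature planted simulations for DE calibration; 1,000
random miRNA/target pairs against the exhaustive all-substring seed
oracle.

# Known limitations

- The two DE estimators are intentionally simplified; they share the
  decision rule, not the code paths, of the mature packages they evoke
  (no independent filtering, no outlier replacement, no GLM designs beyond
  two-group contrasts).
- The energy model scores only the contiguous seed helix -- no
  accessibility, ensemble, or multi-site effects -- and has no G-U stack
  parameters.
- Peak calling on pooled depth means a locus expressed in only one
  condition must still clear the pooled thresholds; a per-sample mode
  exists but is secondary.
- The classifier reports all intersecting hosts but assigns one category
  per peak; peaks spanning several features take the containment-first
  cascade above.
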