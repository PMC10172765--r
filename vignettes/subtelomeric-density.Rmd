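---
title: "Quantifying chromatin accessibility and transcription at chromosome ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin accessibility and transcription at chromosome ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtelo)
```

## The measurement model

Subtelomeric chromatin differs from the chromosome body in ways that are
invisible to gene- or peak-centric analyses: accessibility and
transcription (notably of TERRA, the telomeric repeat-containing lncRNA)
change over length scales of kilobases to megabases from the telomere.
subtelo quantifies this with nested, end-anchored windows.

**Effective chromosome end.** Assembled chromosomes end in telomeric
repeat arrays that attract alignment artifacts. The coordinate where the
annotated telomeric repeat region begins is therefore used both as *the
end* of the chromosome (the anchor all windows hang off) and as its
*total length* (the denominator of the genome-average density). Without
an annotation the raw length is used; only the distal end is trimmed,
since mouse chromosomes are acrocentric and all analysis here anchors on
the centromere-distal end.

**Windows.** For each chromosome with effective end $L$ and each distance
class $d \in \{5, 45, 450, 4{,}500\}$ kb (the defaults), the window is
$[\max(0, L-d),\, L)$ in 0-based half-open coordinates. Windows of
increasing $d$ are nested, so the 5-kb signal is contained in every
larger class; classes differ by an order of magnitude so that localized
terminal enrichment visibly dilutes as the window grows. When
$d > L$ the window is the whole chromosome and carries a truncation
flag.

**Densities.** With $x$ reads overlapping a window of length $w$, the
per-bp density is $x/w$ (e.g. $x/5{,}000$ for the 5-kb class). The
chromosome's genome-average density is its total read count divided by
$L$. The *normalized density* is their ratio — dimensionless, equal to 1
in expectation under uniform coverage, and comparable across chromosomes
and libraries of different depth. A read is counted in a window if its
interval overlaps it at all (the semantics of a `samtools view` region
query); start-in and midpoint rules are available for sensitivity
analysis. Multi-mapped alignments are counted once per alignment record
by default, which is what a region query over a BAM produces; an
optional $1/n$ fractional weighting counts each read once in total.

**Fold changes.** For each chromosome and distance class, replicates are
averaged per genotype *before* the ratio, giving one mutant/control fold
change per chromosome — a per-chromosome distribution per distance
class, not a single pooled number. Averaging before the ratio (rather
than averaging per-replicate ratios) keeps the estimand "ratio of mean
accessibilities", which is stable when a replicate has few reads in a
small window.

**Genotype comparison.** Chromosomes are the observational units: each
contributes one replicate-mean normalized density per genotype. The
genotypes are compared in a one-way layout with Tukey's honest
significant difference across all genotype pairs, with a two-way
(genotype + chromosome) ANOVA cross-check reported alongside. No
adjustment is applied across distance classes beyond Tukey within class;
each class is its own analysis.

**Nested transcript fractions.** For RNA data the summed read count in
all $d$-windows, across chromosomes, is expressed as a percentage of the
count in the largest (reference) class. The reference is exactly 100%
and the percentages are nondecreasing in $d$; under uniform coverage
they equal the window-length ratios (0.111%, 1%, 10%, 100% for the
defaults), so departures from those ratios measure terminal
concentration of transcription.

## Normalization denominator

Two denominators are defensible for the genome-average density: each
chromosome's own average (so a chromosome with globally high coverage is
not mistaken for subtelomeric enrichment) or a single genome-wide
average. The per-chromosome denominator is the default and the one the
fold-change analysis assumes; `genome_wide_denominator = TRUE` switches
to the single shared denominator, and its use is recorded in the run
log. The two agree exactly when coverage is proportional to chromosome
length.

## Companion quantifications

**Relative qPCR expression.** Technical duplicates are averaged on the
Ct scale; $\Delta Ct$ subtracts the reference gene (beta-actin) per
sample, $\Delta\Delta Ct$ subtracts the calibrator sample, and relative
expression is $E^{-\Delta\Delta Ct}$ with amplification efficiency $E=2$
assumed (configurable). The calibrator is exactly 1; adding a constant
to all Cts of a sample cancels identically; changing the calibrator
rescales all samples by one factor, leaving between-sample ratios
invariant. Genotype groups are summarized as mean ± SE with the ratio of
means and an unpaired t test.

**Chromosome-end cytology.** Starting from measurement tables (image
segmentation is upstream), the package computes per-cell signal counts
and total intensity per cell area, and damaged : non-damaged ratios of
total intensity, signal area and mean intensity. Pooling all ends of a
genotype before the ratio is the default, matching a per-end scatter;
a per-cell mode (ratio within each cell, then averaged) is provided
because the grouping the original figure used is ambiguous — neither is
asserted as canonical. Mann-Whitney, unpaired t, Tukey and Dunn tests
are available; Dunn's rank-based pairwise test is implemented in the
package (tie-corrected z statistics, Bonferroni-adjusted by default)
since no installed package provides it.

## The synthetic-data generator

Every pipeline input can be simulated with known ground truth:

* `simulate_genome()` — a desk-scale karyotype, by default 19
  chromosomes of 0.6–2 Mb (the mouse autosome complement scaled down two
  orders of magnitude), with an optional terminal telomere annotation.
* `simulate_reads()` — read start positions drawn from a
  piecewise-constant density: background 1 everywhere except a
  configurable multiplier within a configurable distance of each distal
  end. Inverse-CDF sampling over the segments; chromosomes weighted by
  their total density mass. The manifest records the closed-form
  expected normalized density of every window: for a single band of
  multiplier $m$ and width $s$ on a chromosome of length $L$, the
  $d$-window expectation is
  $\frac{ms + (d-s)}{d} \Big/ \frac{L + (m-1)s}{L}$ for $d \ge s$ —
  e.g. $2.997$ for $m=3$, $s=d=5$ kb, $L=10$ Mb, slightly below $m$
  because the genome average includes the enriched tail.
* `simulate_qpcr()` — target Ct = baseline − log2(true fold) + Gaussian
  cycle noise; reference constant + noise; duplicate wells.
* `simulate_end_table()` — Poisson signal counts per cell (default mean
  41, matching observed per-spermatocyte counts), lognormal intensities
  and areas, and a planted damaged-end intensity multiplier.

A single master seed fans out deterministically to per-stage child seeds
(`child_seed()`), so one integer reproduces an entire study; every
simulator is a pure function of its parameters and seed.

What the generator does **not** emulate: sequence content, mappability,
GC bias, fragment-length structure of real ATAC libraries, duplicate
reads, or biological variation between replicates beyond multinomial
sampling noise. Passing tests therefore demonstrate that the *analysis*
is correct and calibrated — not that real subtelomeric coverage is free
of artifacts; with real data the upstream pipeline's filtering still
matters.

## Numerical and design choices

* Coordinates are 0-based half-open throughout; BED is consumed
  natively, BAM positions are converted on read (reference span from the
  CIGAR).
* At desk scale the 4,500-kb class exceeds every chromosome, so those
  windows are the whole chromosome: normalized density is then
  identically 1 and carries no cross-chromosome information. Truncated
  windows are kept and flagged, and excluded from fold changes and
  genotype statistics by default (their density denominator is no longer
  $d$); validation of all four classes on untruncated windows uses a
  ten-fold larger simulated genome (6–19.5 Mb chromosomes).
* Per-chromosome fold-change distributions are summarized by their
  median: with tens of reads per 5-kb control window the per-chromosome
  ratio is right-skewed and its mean is biased upward, while the median
  tracks the closed-form expectation.
* With the overlap counting rule, a window of length $d$ effectively
  gains one read length at its interior boundary, inflating expected
  normalized density by $\approx (d + \ell)/d$ for read length $\ell$ —
  about 1% at 5 kb with 50-bp reads, negligible at larger classes, and
  cancelling exactly in fold changes. Null-calibration checks use
  Monte-Carlo standard-error bands that accommodate it.
* Zero genome-average density flags the record rather than substituting
  a pseudocount; the pseudocount (default 0) applies only in the fold
  change, where a zero control mean with pseudocount 0 yields an
  explicit undefined flag.
* Tukey HSD with two groups reduces to the unadjusted comparison, which
  is what the null-calibration check exercises; with three or more
  groups per-pair rejection is deliberately below the familywise level.
* Validation problem sizes: 19 chromosomes, $10^5$ reads per sample,
  3 replicates per genotype for density calibration and recovery;
  $5\times10^5$ uniform reads for the nested-fraction closed form; 1,000
  repetitions for test calibration; 50 cells for cytology recovery.
  These run in seconds and give Monte-Carlo error well inside every
  asserted band.

## A worked miniature

```{r example}
st <- simulate_study(profiles = list(wt = enrichment_profile(),
                                     mut = enrichment_profile(5e3, 3)),
                     n_replicates = 2, n_reads = 2e4, seed = 11)
dir <- tempfile(); write_study(st, dir)
cfg <- run_config(chrom_sizes = file.path(dir, "chrom.sizes"), seed = 11)
res <- suppressWarnings(run_subtelo(cfg, file.path(dir, "sample_sheet.tsv")))
res
```

The median 5-kb fold change sits near the planted value of 3 (its exact
closed-form expectation is slightly lower, near 2.98, because the genome
average includes the enriched tail), decaying toward 1 as the window
grows — the signature the window design exists to detect.

## Limitations

* The pipeline quantifies *density*, not peaks or genes; it is not a
  differential-expression method and estimates no dispersions.
* Counting is alignment-record based; whether paired mates should count
  as one fragment is an upstream decision the package does not make.
* The effective-end rule trims only the anchored (distal) end; if an
  annotation marked both ends, the proximal telomere would be ignored.
* qPCR efficiency is assumed, not estimated; no dilution-series or
  melt-curve processing is included.
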