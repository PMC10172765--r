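# subtelo

Multi-scale quantification of chromatin accessibility and transcription
near chromosome ends, for ATAC-seq and RNA-seq read alignments — plus
the two small quantifications that typically accompany such studies:
reference-gene-normalized qPCR expression (ΔΔCt) and per-chromosome-end
cytological signal summaries.

## The problem and the method

Telomere-proximal chromatin (and TERRA, the telomeric repeat-containing
lncRNA transcribed from subtelomeric promoters) changes over length
scales from kilobases to megabases, which peak- or gene-level analyses
average away. subtelo measures it directly:

1. **Effective chromosome end.** The start of the annotated telomeric
   repeat region is used as the chromosome's end and as its total
   length; without an annotation, the raw length is used.
2. **Nested end-anchored windows.** For distances
   d ∈ {5, 45, 450, 4,500} kb (defaults), the window on each chromosome
   is `[max(0, L − d), L)`, 0-based half-open.
3. **Normalized density.** x reads in a w-bp window give density x/w
   (e.g. x/5,000); dividing by the chromosome's genome-average density
   (total reads / L) gives a dimensionless normalized density with
   expectation 1 under uniform coverage.
4. **Per-chromosome fold changes.** Replicates are averaged per
   genotype, then ratioed (mutant/control) per chromosome and distance
   class; genotypes are compared with Tukey's multiple comparison using
   chromosomes as observational units (two-way ANOVA cross-check
   included).
5. **Nested transcript fractions.** Reads per distance class as a
   percentage of the largest class (100% reference; window-length ratios
   0.111/1/10/100 % under uniformity).

A synthetic-data module simulates genomes, read sets with planted
subtelomeric enrichment, qPCR Ct tables and end-measurement tables, each
with a manifest of closed-form expected values, so every stage is
verifiable without any deposited data.

## Worked example

Simulate a two-genotype study with a planted 3× enrichment within 5 kb
of every distal end, then run the pipeline:

```r
library(subtelo)
st <- simulate_study(profiles = list(wt  = enrichment_profile(),
                                     mut = enrichment_profile(5e3, 3)),
                     n_replicates = 2, n_reads = 2e4, seed = 11)
dir <- tempfile(); write_study(st, dir)
cfg <- run_config(chrom_sizes = file.path(dir, "chrom.sizes"), seed = 11)
res <- run_subtelo(cfg, file.path(dir, "sample_sheet.tsv"))
res
#> subtelo run: 19 chromosomes, 76 windows, 4 samples
#> median per-chromosome fold change by distance class:
#>  distance_class case fold_change
#>            5000  mut    2.768730
#>           45000  mut    1.152299
#>          450000  mut    1.001008
print(res$comparisons[["atac_d5000"]])
#> Genotype comparison at distance class 5,000 bp
#>   one-way ANOVA: F = 172.173, p = 2.763e-15 (two-way cross-check p = 2.955e-11)
#>   Tukey pairwise adjusted p-values:
#>     wt-mut               diff = -1.9296  p = 0
```

The planted 3× band is recovered at the 5-kb class (median 2.77 here;
the closed-form expectation is slightly under 3 because the genome
average includes the enriched tail) and decays toward 1 as the window
grows to 450 kb — the dilution signature the nested design detects. The
4,500-kb windows exceed these desk-scale chromosomes and are flagged as
truncated rather than analysed.

`res$densities`, `res$fold_changes`, `res$fractions` and
`res$comparisons` hold the full tables; `write_run(res, dir)` emits them
as TSV with a config-hash header, `render_report(res, dir)` draws
per-distance strip plots and the nested-fraction bar chart.

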