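#' Count aligned reads in subtelomeric windows
#'
#' The default rule, `"overlap"`, counts a read if its interval intersects
#' the window at all — the semantics of a `samtools view` region query.
#' `"start-in"` requires the read's leftmost coordinate to fall inside the
#' window and `"midpoint"` its midpoint; both are provided for sensitivity
#' analysis. With the overlap rule a read near a window boundary may be
#' counted by several nested windows.
#'
#' Counts are weighted sums of each read's `weight` column (all 1 by
#' default, so plain integer counts); the optional 1/n multi-mapping
#' weighting of [quantify_sample()] flows through here.
#'
#' @param alignments read table ([read_alignments()] format).
#' @param windows window table from [build_subtelomeric_windows()] (any
#'   number of rows).
#' @param rule counting rule.
#' @return numeric vector of counts, one per window row.
#' @export
count_reads <- function(alignments, windows,
                        rule = c("overlap", "start-in", "midpoint")) {
  rule <- match.arg(rule)
  # a window on a read-free chromosome counts 0; chromosomes absent from
  # the genome model are rejected upstream in quantify_sample()
  if (!nrow(alignments)) return(rep(0, nrow(windows)))
  pts <- switch(rule,
    "overlap" = alignments,
    "start-in" = transform(alignments, end = start + 1),
    "midpoint" = {
      mid <- floor((alignments$start + alignments$end) / 2)
      transform(alignments, start = mid, end = mid + 1)
    })
  lv <- union(unique(windows$chrom), unique(pts$chrom))
  q <- intervals_to_granges(windows, seqlevels = lv)
  s <- intervals_to_granges(pts, seqlevels = lv)
  hits <- GenomicRanges::findOverlaps(q, s)
  w <- pts$weight
  counts <- rep(0, nrow(windows))
  if (length(hits)) {
    agg <- tapply(w[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    counts[as.integer(names(agg))] <- as.numeric(agg)
  }
  counts
}

#' Per-bp read density of a window
#'
#' x reads in a w-bp window give a density of x/w reads per bp (for the
#' 5-kb window, x/5,000).
#'
#' @param read_count reads in the window.
#' @param window_length_bp window length in bp; must be positive.
#' @return reads per bp, full floating precision.
#' @export
density_per_bp <- function(read_count, window_length_bp) {
  if (any(window_length_bp <= 0))
    subtelo_error("subtelo_config_error", "window length must be positive")
  read_count / window_length_bp
}

#' Genome-average read density of a chromosome
#'
#' Total reads assigned to the chromosome divided by its effective length
#' (the telomere-annotation-trimmed length, used as the chromosome's total
#' length). Reads are assigned by the same counting rule as the windows,
#' against the interval `[0, effective_end)`.
#'
#' @param alignments read table.
#' @param chrom one row of the effective-chromosome table.
#' @param rule counting rule, as in [count_reads()].
#' @return reads per bp; 0 when the chromosome has no reads (downstream
#'   normalization flags that case).
#' @export
genome_average_density <- function(alignments, chrom,
                                   rule = c("overlap", "start-in", "midpoint")) {
  rule <- match.arg(rule)
  win <- data.frame(chrom = chrom$name, start = 0, end = chrom$effective_end,
                    stringsAsFactors = FALSE)
  n <- count_reads(alignments, win, rule = rule)
  n / chrom$effective_length
}

#' Quantify one sample over the subtelomeric windows
#'
#' For every window: the read count, the per-bp density (count divided by
#' window length), the chromosome's genome-average density, and the
#' normalized density (per-bp density divided by the genome average; 1
#' under a uniform read distribution). Windows on chromosomes with zero
#' genome-average density get `NA` normalized density and are flagged so
#' downstream statistics exclude them; no pseudocount is substituted here.
#'
#' @param alignments read table for one sample.
#' @param windows window table.
#' @param chroms effective-chromosome table.
#' @param sample_id identifier recorded in every output row.
#' @param rule counting rule.
#' @param multimap_weighting if `"fractional"` and the read table has a
#'   `name` column, each alignment is weighted 1/n where n is the number of
#'   alignments sharing its read name (multi-mapped reads counted once in
#'   total); default `"per-alignment"` counts every alignment record once.
#' @return data.frame of window density records: `sample_id`, `chrom`,
#'   `distance_class`, `window_length`, `read_count`, `density`,
#'   `genome_avg_density`, `normalized_density`, `truncated`, `flagged`.
#' @export
quantify_sample <- function(alignments, windows, chroms, sample_id = "sample",
                            rule = c("overlap", "start-in", "midpoint"),
                            multimap_weighting = c("per-alignment", "fractional")) {
  rule <- match.arg(rule)
  multimap_weighting <- match.arg(multimap_weighting)
  bad <- setdiff(unique(alignments$chrom), chroms$name)
  if (length(bad))
    subtelo_error("subtelo_chrom_error",
                  "alignments on chromosome(s) absent from the genome model: %s",
                  paste(bad, collapse = ", "))
  if (multimap_weighting == "fractional" && "name" %in% names(alignments)) {
    n_aln <- table(alignments$name)
    alignments$weight <- alignments$weight /
      as.numeric(n_aln[alignments$name])
  }
  counts <- count_reads(alignments, windows, rule = rule)
  wlen <- windows$end - windows$start
  dens <- density_per_bp(counts, wlen)
  gavg <- vapply(seq_len(nrow(chroms)), function(i)
    genome_average_density(alignments, chroms[i, ], rule = rule), 0)
  names(gavg) <- chroms$name
  g <- gavg[windows$chrom]
  norm <- ifelse(g > 0, dens / g, NA_real_)
  data.frame(sample_id = sample_id,
             chrom = windows$chrom,
             distance_class = windows$distance_class,
             window_length = wlen,
             read_count = counts,
             density = dens,
             genome_avg_density = unname(g),
             normalized_density = norm,
             truncated = windows$truncated,
             flagged = !is.finite(norm),
             stringsAsFactors = FALSE)
}
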