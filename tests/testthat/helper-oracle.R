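# Independent brute-force oracles and tiny fixture builders shared across
# test files. The oracle never calls the package's counting path.

# per-read linear scan over all alignments, independent of GenomicRanges
brute_force_count <- function(alignments, window,
                              rule = c("overlap", "start-in", "midpoint")) {
  rule <- match.arg(rule)
  hit <- logical(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    if (alignments$chrom[i] != window$chrom) next
    s <- alignments$start[i]; e <- alignments$end[i]
    hit[i] <- switch(rule,
      "overlap" = s < window$end && e > window$start,
      "start-in" = s >= window$start && s < window$end,
      "midpoint" = {
        m <- floor((s + e) / 2)
        m >= window$start && m < window$end
      })
  }
  sum(alignments$weight[hit])
}

# numeric integration of an enrichment profile over the terminal span,
# independent of the package's closed-form segment arithmetic
integrate_profile_tail <- function(profile, L, span, step = 10) {
  x <- seq(0.5 * step, min(span, L), by = step)  # distance from the end
  dens <- vapply(x, function(d) {
    band <- which(profile$distances >= d)
    if (length(band)) profile$multipliers[min(band)] else 1
  }, 0)
  sum(dens) * step
}

tiny_chroms <- function() {
  data.frame(name = c("chrT", "chrU"),
             raw_length = c(200000, 100000),
             effective_end = c(200000, 100000),
             effective_length = c(200000, 100000),
             stringsAsFactors = FALSE)
}

random_reads <- function(n, chroms, read_length = 50) {
  i <- sample.int(nrow(chroms), n, replace = TRUE)
  start <- floor(runif(n, 0, chroms$effective_end[i] - 1))
  data.frame(chrom = chroms$name[i], start = start,
             end = pmin(start + read_length, chroms$raw_length[i]),
             strand = "*", weight = 1, stringsAsFactors = FALSE)
}

write_chrom_sizes <- function(chroms, path = tempfile(fileext = ".sizes")) {
  writeLines(sprintf("%s\t%d", chroms$name, chroms$raw_length), path)
  path
}
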