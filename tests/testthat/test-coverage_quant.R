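test_that("counting rules treat boundary reads as documented", {
  aln <- data.frame(chrom = "chrT", start = 194990, end = 195010,
                    strand = "*", weight = 1)
  win <- data.frame(chrom = "chrT", start = 195000, end = 200000)
  expect_equal(count_reads(aln, win, rule = "overlap"), 1)
  expect_equal(count_reads(aln, win, rule = "start-in"), 0)
  # midpoint 195000 is inside the half-open window
  expect_equal(count_reads(aln, win, rule = "midpoint"), 1)
  # abutting read does not overlap a half-open window
  aln2 <- data.frame(chrom = "chrT", start = 194950, end = 195000,
                     strand = "*", weight = 1)
  expect_equal(count_reads(aln2, win, rule = "overlap"), 0)
})

test_that("region counting equals a brute-force per-read scan", {
  ch <- tiny_chroms()
  w <- build_subtelomeric_windows(ch, c(5e3, 45e3))
  set.seed(42)
  for (rep in 1:5) {
    reads <- random_reads(sample(1:5000, 1), ch)
    for (rule in c("overlap", "start-in", "midpoint")) {
      got <- count_reads(reads, w, rule = rule)
      want <- vapply(seq_len(nrow(w)), function(i)
        brute_force_count(reads, w[i, ], rule = rule), 0)
      expect_identical(got, want)
    }
  }
})

test_that("per-bp density is the exact quotient", {
  expect_equal(density_per_bp(10, 5000), 0.002)
  expect_equal(density_per_bp(0, 1234), 0)
  expect_equal(density_per_bp(45, 45000), 0.001)
  expect_error(density_per_bp(1, 0), class = "subtelo_config_error")
})

test_that("genome-average density divides by the effective length", {
  ch <- tiny_chroms()[1, ]
  ch$effective_end <- ch$effective_length <- 100000
  set.seed(1)
  reads <- data.frame(chrom = "chrT",
                      start = floor(runif(200, 0, 99950)),
                      strand = "*", weight = 1)
  reads$end <- reads$start + 50
  expect_equal(genome_average_density(reads, ch), 200 / 100000)
  expect_equal(genome_average_density(reads[0, ], ch), 0)
})

test_that("uniform reads give normalized densities centered on 1", {
  ch <- data.frame(name = "chr1", raw_length = 1e6, effective_end = 1e6,
                   effective_length = 1e6)
  w <- build_subtelomeric_windows(ch, c(5e3, 45e3, 450e3))
  set.seed(7)
  norm <- replicate(60, {
    reads <- random_reads(5000, ch)
    quantify_sample(reads, w, ch)$normalized_density
  })
  m <- rowMeans(norm)
  se <- apply(norm, 1, sd) / sqrt(ncol(norm))
  # small positive bias from read-length edge overlap is within 3 SE
  expect_true(all(abs(m - 1) < 3 * se + 0.02))
})

test_that("a planted 3x terminal band matches its closed-form density", {
  ch <- data.frame(name = "chr1", raw_length = 1e7, effective_end = 1e7,
                   effective_length = 1e7)
  w <- build_subtelomeric_windows(ch, c(5e3, 45e3))
  prof <- enrichment_profile(5e3, 3)
  # expected normalized density in the 5-kb window: 3 / (1 + 2*5e3/1e7)
  expected <- 3 / (1 + 2 * 5e3 / 1e7)
  expect_equal(
    expected_normalized_density(prof, ch, 5e3)$expected_normalized_density,
    expected)
  sim <- simulate_reads(list(chroms = ch), prof, n_reads = 2e5, seed = 11)
  q <- quantify_sample(sim$reads, w, ch)
  got <- q$normalized_density[q$distance_class == 5e3]
  # ~600 reads in the band: Poisson CV ~4%
  expect_lt(abs(got - expected) / expected, 0.15)
})

test_that("degenerate and flagged cases propagate", {
  ch <- tiny_chroms()
  w <- build_subtelomeric_windows(ch, c(5e3))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      weight = numeric())
  q <- quantify_sample(empty, w, ch)
  expect_true(all(q$read_count == 0))
  expect_true(all(q$flagged))
  expect_true(all(is.na(q$normalized_density)))
  bad <- data.frame(chrom = "chrZ", start = 0, end = 50, strand = "*",
                    weight = 1)
  expect_error(quantify_sample(bad, w, ch), class = "subtelo_chrom_error")
})

test_that("nested windows count monotonically and weights scale out", {
  ch <- tiny_chroms()
  w <- build_subtelomeric_windows(ch, c(5e3, 45e3))
  set.seed(3)
  reads <- random_reads(2000, ch)
  q <- quantify_sample(reads, w, ch, sample_id = "s")
  for (cn in ch$name) {
    cc <- q$read_count[q$chrom == cn]
    expect_true(all(diff(cc[order(q$distance_class[q$chrom == cn])]) >= 0))
  }
  # doubling every weight leaves normalized density unchanged
  reads2 <- reads; reads2$weight <- 2
  q2 <- quantify_sample(reads2, w, ch, sample_id = "s")
  expect_equal(q2$normalized_density, q$normalized_density)
  # duplicating the read set likewise
  q3 <- quantify_sample(rbind(reads, reads), w, ch, sample_id = "s")
  expect_equal(q3$normalized_density, q$normalized_density)
})

test_that("fractional multi-mapping weights count each read once in total", {
  ch <- tiny_chroms()
  w <- build_subtelomeric_windows(ch, c(5e3))
  aln <- data.frame(chrom = "chrT", start = c(195100, 196000, 10),
                    end = c(195150, 196050, 60), name = c("r1", "r1", "r2"),
                    strand = "*", weight = 1)
  q <- quantify_sample(aln, w, ch, multimap_weighting = "fractional")
  expect_equal(q$read_count[q$chrom == "chrT"], 1)  # 0.5 + 0.5
})
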