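test_that("simulators are pure functions of parameters and seed", {
  g1 <- simulate_genome(seed = 4, telomere_trim = 2000)
  g2 <- simulate_genome(seed = 4, telomere_trim = 2000)
  expect_identical(g1, g2)
  expect_false(identical(g1$chrom_sizes,
                         simulate_genome(seed = 5)$chrom_sizes))
  prof <- enrichment_profile(5e3, 3)
  r1 <- simulate_reads(g1, prof, n_reads = 5000, seed = 6)
  r2 <- simulate_reads(g1, prof, n_reads = 5000, seed = 6)
  expect_identical(r1$reads, r2$reads)
  q1 <- simulate_qpcr(data.frame(sample_id = "s", genotype = "wt",
                                 true_fold = 1), seed = 2)
  q2 <- simulate_qpcr(data.frame(sample_id = "s", genotype = "wt",
                                 true_fold = 1), seed = 2)
  expect_identical(q1$ct_table, q2$ct_table)
  e1 <- simulate_end_table(n_cells = 5, seed = 9)
  e2 <- simulate_end_table(n_cells = 5, seed = 9)
  expect_identical(e1$measurements, e2$measurements)
})

test_that("simulated genomes honour karyotype and telomere trim", {
  g <- simulate_genome(n_chrom = 19, length_range = c(6e5, 2e6),
                       telomere_trim = 2000, seed = 1)
  expect_equal(nrow(g$chrom_sizes), 19)
  expect_true(all(g$chrom_sizes$length >= 6e5 & g$chrom_sizes$length <= 2e6))
  expect_equal(g$chroms$effective_end, g$chrom_sizes$length - 2000)
  # round-trips through the chrom.sizes reader
  p <- tempfile()
  writeLines(sprintf("%s\t%d", g$chrom_sizes$name, g$chrom_sizes$length), p)
  expect_equal(load_chrom_sizes(p)$raw_length, g$chrom_sizes$length)
})

test_that("profile construction validates its bands", {
  expect_error(enrichment_profile(c(5e3, 4e3), c(2, 3)),
               class = "subtelo_config_error")
  expect_error(enrichment_profile(5e3, -1), class = "subtelo_config_error")
  expect_error(enrichment_profile(background = 0))
})

test_that("closed-form expected densities match numeric integration", {
  prof <- enrichment_profile(c(5e3, 45e3), c(3, 1.5))
  ch <- data.frame(name = "chr1", raw_length = 2e6, effective_end = 2e6,
                   effective_length = 2e6)
  e <- expected_normalized_density(prof, ch, c(5e3, 45e3, 450e3))
  for (i in seq_len(nrow(e))) {
    d <- e$distance_class[i]
    num <- (integrate_profile_tail(prof, 2e6, d) / d) /
      (integrate_profile_tail(prof, 2e6, 2e6) / 2e6)
    expect_equal(e$expected_normalized_density[i], num, tolerance = 1e-3)
  }
  # single-band headline case: 3x within 5 kb of a 10-Mb chromosome
  ch10 <- data.frame(name = "c", raw_length = 1e7, effective_end = 1e7,
                     effective_length = 1e7)
  e10 <- expected_normalized_density(enrichment_profile(5e3, 3), ch10, 5e3)
  expect_equal(e10$expected_normalized_density, 3 / (1 + 2 * 5e3 / 1e7))
  expect_equal(round(e10$expected_normalized_density, 3), 2.997)
})

test_that("flat profiles give uniform reads with unit normalized density", {
  g <- simulate_genome(n_chrom = 4, length_range = c(4e5, 8e5), seed = 2)
  sim <- simulate_reads(g, enrichment_profile(), n_reads = 4e4, seed = 3)
  w <- build_subtelomeric_windows(g$chroms, c(45e3))
  q <- quantify_sample(sim$reads, w, g$chroms)
  expect_lt(abs(mean(q$normalized_density) - 1), 0.1)
  expect_true(all(sim$manifest$expected$expected_normalized_density == 1))
})

test_that("reads stay inside chromosome bounds and sort deterministically", {
  g <- simulate_genome(n_chrom = 3, length_range = c(1e5, 2e5), seed = 7)
  sim <- simulate_reads(g, enrichment_profile(5e3, 4), n_reads = 2e4,
                        seed = 8)
  rd <- sim$reads
  raw <- g$chroms$raw_length[match(rd$chrom, g$chroms$name)]
  expect_true(all(rd$start >= 0 & rd$end <= raw & rd$start < rd$end))
  expect_false(is.unsorted(rd$start[rd$chrom == rd$chrom[1]]))
})

test_that("qPCR simulation plants the designed ddCt", {
  design <- data.frame(sample_id = c("a", "b"), genotype = c("wt", "mut"),
                       true_fold = c(1, 8))
  sim <- simulate_qpcr(design, noise_sd = 0, seed = 1)
  rel <- relative_expression(sim$ct_table, "Actb", "a")
  expect_equal(rel$dd_ct[rel$sample_id == "b"], -3)
  expect_equal(rel$relative_expression[rel$sample_id == "b"], 8)
})

test_that("end-table simulation with unit multiplier gives unit ratios", {
  sim <- simulate_end_table(n_cells = 120, damage_intensity_multiplier = 1,
                            seed = 5)
  r <- damaged_ratio(sim$measurements)
  expect_lt(abs(unname(r$ratios["total_intensity"]) - 1), 0.1)
})

test_that("written studies round-trip through the pipeline readers", {
  st <- simulate_study(n_replicates = 1, n_reads = 3000, seed = 10,
                       profiles = list(wt = enrichment_profile(),
                                       mut = enrichment_profile(5e3, 3)))
  dir <- tempfile()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "chrom.sizes")))
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_equal(nrow(sheet), 2)
  rd <- read_bed(sheet$path[1])
  expect_equal(nrow(rd), 3000)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$control, "wt")
})
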