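make_density <- function(sample_id, chrom, d, norm, count = 10,
                         genotype = NULL) {
  out <- data.frame(sample_id = sample_id, chrom = chrom, distance_class = d,
                    window_length = d, read_count = count,
                    density = count / d, genome_avg_density = 1,
                    normalized_density = norm, truncated = FALSE,
                    flagged = !is.finite(norm), stringsAsFactors = FALSE)
  if (!is.null(genotype)) out$genotype <- genotype
  out
}

test_that("fold change of identical inputs is exactly 1", {
  set.seed(5)
  recs <- do.call(rbind, lapply(1:3, function(r)
    make_density(paste0("s", r), rep(c("chr1", "chr2"), each = 2),
                 rep(c(5e3, 45e3), 2), runif(4, 0.5, 3))))
  fc <- fold_change(recs, recs)
  expect_true(all(fc$fold_change == 1))  # bit-exact
  expect_equal(fc$n_case, fc$n_control)
})

test_that("zero control mean without pseudocount is flagged undefined", {
  ca <- make_density("a", "chr1", 5e3, 2)
  co <- make_density("b", "chr1", 5e3, 0)
  fc <- fold_change(ca, co, pseudocount = 0)
  expect_true(fc$undefined)
  expect_true(is.na(fc$fold_change))
  # a pseudocount makes it finite
  fc2 <- fold_change(ca, co, pseudocount = 0.1)
  expect_equal(fc2$fold_change, 2.1 / 0.1)
  # disjoint windows: hard error
  expect_error(fold_change(ca, make_density("b", "chr9", 45e3, 1)),
               class = "subtelo_contract_error")
})

test_that("replicates are averaged per side before the ratio", {
  ca <- rbind(make_density("a1", "chr1", 5e3, 2),
              make_density("a2", "chr1", 5e3, 4))
  co <- rbind(make_density("b1", "chr1", 5e3, 1),
              make_density("b2", "chr1", 5e3, 3))
  fc <- fold_change(ca, co)
  expect_equal(fc$fold_change, mean(c(2, 4)) / mean(c(1, 3)))
  expect_equal(fc$n_case, 2L)
})

test_that("null fold changes center log at zero", {
  ch <- data.frame(name = paste0("chr", 1:6),
                   raw_length = 5e5, effective_end = 5e5,
                   effective_length = 5e5)
  w <- build_subtelomeric_windows(ch, c(5e3, 45e3))
  qs <- lapply(1:4, function(i) {
    set.seed(100 + i)
    quantify_sample(random_reads(30000, ch), w, ch,
                    sample_id = paste0("s", i))
  })
  fc <- fold_change(rbind(qs[[1]], qs[[2]]), rbind(qs[[3]], qs[[4]]))
  lg <- log(fc$fold_change)
  expect_lt(abs(mean(lg)), 3 * sd(lg) / sqrt(length(lg)))
})

test_that("genotype comparison uses chromosomes as units with Tukey HSD", {
  set.seed(9)
  recs <- do.call(rbind, lapply(c("wt", "mutA", "mutB"), function(g)
    do.call(rbind, lapply(1:2, function(r)
      make_density(paste0(g, r), paste0("chr", 1:8), 5e3,
                   rnorm(8, ifelse(g == "mutA", 3, 1), 0.2),
                   genotype = g)))))
  cmp <- compare_genotypes(recs, 5e3)
  expect_s3_class(cmp, "subtelo_comparison")
  expect_equal(nrow(cmp$tukey), 3)          # all genotype pairs
  expect_true(all(cmp$tukey$p_adj >= 0 & cmp$tukey$p_adj <= 1))
  shifted <- grepl("mutA", cmp$tukey$contrast)
  expect_true(all(cmp$tukey$p_adj[shifted] < 0.01))
  expect_true(cmp$tukey$p_adj[!shifted] > 0.05)
  # one value per chromosome per genotype
  expect_equal(nrow(cmp$data), 8 * 3)
  expect_output(print(cmp), "Tukey")

  expect_error(compare_genotypes(recs[recs$genotype == "wt", ], 5e3),
               class = "subtelo_contract_error")
})

test_that("degenerate all-identical comparison is flagged with p = 1", {
  recs <- do.call(rbind, lapply(c("wt", "mut"), function(g)
    make_density(paste0(g, 1), paste0("chr", 1:4), 5e3, 1, genotype = g)))
  cmp <- compare_genotypes(recs, 5e3)
  expect_true(cmp$degenerate)
  expect_true(all(cmp$tukey$p_adj == 1))
})

test_that("Tukey adjusted p-values dominate unadjusted pairwise p-values", {
  set.seed(21)
  for (rep in 1:10) {
    vals <- rnorm(24)
    grp <- factor(rep(c("a", "b", "c"), each = 8))
    fit <- aov(vals ~ grp)
    tk <- TukeyHSD(fit)$grp
    mse <- sum(fit$residuals^2) / fit$df.residual
    for (ct in rownames(tk)) {
      pair <- strsplit(ct, "-")[[1]]
      dd <- mean(vals[grp == pair[1]]) - mean(vals[grp == pair[2]])
      tstat <- dd / sqrt(mse * (1 / 8 + 1 / 8))
      p_un <- 2 * pt(-abs(tstat), fit$df.residual)
      expect_gte(tk[ct, "p adj"] + 1e-12, p_un)
    }
  }
})

test_that("transcript fractions follow counts and are depth-invariant", {
  recs <- rbind(make_density("s", "chr1", 5e3, 1, count = 4),
                make_density("s", "chr1", 4500e3, 1, count = 100))
  fr <- transcript_fractions(recs)
  expect_equal(fr$percent, c(4, 100))
  # reference class is exactly 100
  expect_identical(fr$percent[fr$distance_class == 4500e3], 100)
  # scaling depth leaves percentages unchanged
  recs2 <- recs; recs2$read_count <- recs2$read_count * 7
  expect_equal(transcript_fractions(recs2)$percent, fr$percent)
  # all reads inside the smallest window: 100% everywhere
  recs3 <- rbind(make_density("s", "chr1", 5e3, 1, count = 50),
                 make_density("s", "chr1", 45e3, 1, count = 50),
                 make_density("s", "chr1", 4500e3, 1, count = 50))
  expect_true(all(transcript_fractions(recs3)$percent == 100))
  # zero reference reads: flagged undefined
  recs4 <- make_density("s", "chr1", 4500e3, 1, count = 0)
  expect_true(all(transcript_fractions(recs4)$flagged))
})
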