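#' Per-chromosome fold changes of normalized density between genotypes
#'
#' For each (chromosome, distance class), replicates are averaged on each
#' side first and the fold change is the ratio of mean normalized
#' densities, case over control — one value per chromosome and distance,
#' as plotted in per-chromosome fold-change distributions. Flagged records
#' (zero genome-average denominator) and, by default, truncated windows
#' are excluded. With `pseudocount = 0` (the default) a zero control mean
#' yields an `NA` fold change flagged `undefined` rather than a silently
#' shifted ratio.
#'
#' @param records_case,records_control density tables from
#'   [quantify_sample()], possibly several samples (replicates) each.
#' @param pseudocount added to both means before the ratio; default 0.
#' @param drop_truncated exclude truncated windows (default `TRUE`).
#' @return data.frame with `chrom`, `distance_class`, `mean_case`,
#'   `mean_control`, `fold_change`, `n_case`, `n_control`, `undefined`.
#' @export
fold_change <- function(records_case, records_control, pseudocount = 0,
                        drop_truncated = TRUE) {
  prep <- function(r) {
    r <- r[!r$flagged, , drop = FALSE]
    if (drop_truncated) r <- r[!r$truncated, , drop = FALSE]
    r
  }
  ca <- prep(records_case); co <- prep(records_control)
  key <- function(r) paste(r$chrom, r$distance_class, sep = "\r")
  shared <- intersect(unique(key(ca)), unique(key(co)))
  if (!length(shared))
    subtelo_error("subtelo_contract_error",
                  "case and control share no usable windows")
  agg <- function(r) {
    k <- key(r)
    list(mean = tapply(r$normalized_density, k, mean),
         n = tapply(r$sample_id, k, function(s) length(unique(s))))
  }
  a <- agg(ca); b <- agg(co)
  mc <- as.numeric(a$mean[shared]); mk <- as.numeric(b$mean[shared])
  fc <- ifelse(mk + pseudocount > 0,
               (mc + pseudocount) / (mk + pseudocount), NA_real_)
  parts <- strsplit(shared, "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    distance_class = as.numeric(vapply(parts, `[`, "", 2L)),
                    mean_case = mc, mean_control = mk,
                    fold_change = fc,
                    n_case = as.integer(a$n[shared]),
                    n_control = as.integer(b$n[shared]),
                    undefined = !is.finite(fc),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance_class, out$chrom), ]
  rownames(out) <- NULL
  out
}

#' Compare genotypes at one distance class (Tukey multiple comparison)
#'
#' Chromosomes are the observational units: each chromosome contributes
#' one value per genotype (its replicate-mean normalized density). The
#' genotypes are compared in a one-way layout with Tukey's honest
#' significant difference over all genotype pairs; a two-way layout
#' (genotype + chromosome) cross-check is reported alongside.
#'
#' @param density_records density table(s) bearing a `genotype` column (as
#'   assembled by [run_subtelo()], or rbind-ed [quantify_sample()] outputs
#'   with `genotype` added).
#' @param distance_class which distance class to analyse, bp.
#' @param drop_truncated exclude truncated windows (default `TRUE`).
#' @return a list of class `subtelo_comparison`: `distance_class`, `test`,
#'   `anova` (one-way F and p), `tukey` (data.frame of pairwise adjusted
#'   p-values and differences), `two_way` (genotype p-value from the
#'   genotype + chromosome layout), `degenerate` (TRUE when the residual
#'   variance is zero), and the per-chromosome `data` used.
#' @export
compare_genotypes <- function(density_records, distance_class,
                              drop_truncated = TRUE) {
  r <- density_records
  stopifnot("genotype" %in% names(r))
  r <- r[r$distance_class == distance_class & !r$flagged, , drop = FALSE]
  if (drop_truncated) r <- r[!r$truncated, , drop = FALSE]
  if (length(unique(r$genotype)) < 2L)
    subtelo_error("subtelo_contract_error",
                  "need at least 2 genotypes, got %d",
                  length(unique(r$genotype)))
  # one value per chromosome per genotype: mean across replicates
  agg <- stats::aggregate(normalized_density ~ chrom + genotype, data = r,
                          FUN = mean)
  if (min(table(agg$genotype)) < 2L)
    subtelo_error("subtelo_contract_error",
                  "need at least 2 chromosomes per genotype")
  agg$genotype <- factor(agg$genotype)
  agg$chrom <- factor(agg$chrom)
  degenerate <- stats::var(agg$normalized_density) == 0
  if (degenerate) {
    pairs <- utils::combn(levels(agg$genotype), 2)
    tk <- data.frame(contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
                     diff = 0, lwr = 0, upr = 0, p_adj = 1,
                     stringsAsFactors = FALSE)
    one <- list(F = NA_real_, p_value = NA_real_)
    two <- NA_real_
  } else {
    fit1 <- stats::aov(normalized_density ~ genotype, data = agg)
    s1 <- summary(fit1)[[1]]
    one <- list(F = s1$`F value`[1], p_value = s1$`Pr(>F)`[1])
    tk0 <- stats::TukeyHSD(fit1, "genotype")$genotype
    tk <- data.frame(contrast = rownames(tk0), diff = tk0[, "diff"],
                     lwr = tk0[, "lwr"], upr = tk0[, "upr"],
                     p_adj = tk0[, "p adj"], stringsAsFactors = FALSE)
    rownames(tk) <- NULL
    two <- tryCatch({
      fit2 <- stats::aov(normalized_density ~ genotype + chrom, data = agg)
      summary(fit2)[[1]]$`Pr(>F)`[1]
    }, error = function(e) NA_real_)
  }
  structure(list(distance_class = distance_class, test = "tukey_hsd",
                 anova = one, tukey = tk, two_way_p = two,
                 degenerate = degenerate, data = agg),
            class = "subtelo_comparison")
}

#' @export
print.subtelo_comparison <- function(x, ...) {
  cat(sprintf("Genotype comparison at distance class %s bp\n",
              format(x$distance_class, big.mark = ",")))
  if (x$degenerate) cat("  (degenerate: zero variance)\n")
  else cat(sprintf("  one-way ANOVA: F = %.3f, p = %.4g (two-way cross-check p = %.4g)\n",
                   x$anova$F, x$anova$p_value, x$two_way_p))
  cat("  Tukey pairwise adjusted p-values:\n")
  for (i in seq_len(nrow(x$tukey)))
    cat(sprintf("    %-20s diff = %+.4f  p = %.4g\n",
                x$tukey$contrast[i], x$tukey$diff[i], x$tukey$p_adj[i]))
  invisible(x)
}

#' Nested-region transcript fractions
#'
#' For one sample, the percentage of reads in each distance class relative
#' to the largest (reference) distance class, summed across chromosomes:
#' `100 * sum(reads in d-windows) / sum(reads in reference windows)`.
#' Because the windows are nested the percentages are nondecreasing in d,
#' and the reference class is exactly 100. Under uniform coverage the
#' percentages converge to the window-length ratios (0.111%, 1%, 10%,
#' 100% for the default distances).
#'
#' @param records density table for one sample (or pooled replicates of
#'   one genotype).
#' @param distances distance classes to report; default all present.
#' @return data.frame `distance_class`, `reads`, `percent`, `flagged`.
#' @export
transcript_fractions <- function(records, distances = NULL) {
  if (is.null(distances)) distances <- sort(unique(records$distance_class))
  distances <- sort(distances)
  ref <- max(distances)
  tot <- vapply(distances, function(d)
    sum(records$read_count[records$distance_class == d]), 0)
  ref_total <- tot[distances == ref]
  if (ref_total == 0) {
    return(data.frame(distance_class = distances, reads = tot,
                      percent = NA_real_, flagged = TRUE))
  }
  data.frame(distance_class = distances, reads = tot,
             percent = 100 * tot / ref_total, flagged = FALSE)
}
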