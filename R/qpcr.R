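#' Reference-gene-normalized relative expression (2^-ddCt)
#'
#' Technical duplicates are averaged on the Ct scale, the reference gene
#' (e.g. beta-actin) Ct is subtracted per sample (dCt), the calibrator
#' sample's dCt is subtracted (ddCt), and relative expression is
#' `efficiency^(-ddCt)` with an assumed amplification efficiency of 2
#' (perfect doubling per cycle) unless overridden. The calibrator's
#' relative expression is exactly 1.
#'
#' @param ct_table data.frame with columns `sample_id`, `genotype`,
#'   `target`, `replicate`, `ct`.
#' @param reference_target name of the housekeeping target (e.g. `"Actb"`).
#' @param calibrator_sample sample_id whose expression anchors the scale.
#' @param efficiency amplification efficiency per cycle; must be > 1.
#' @return data.frame with one row per sample x non-reference target:
#'   `sample_id`, `genotype`, `target`, `d_ct`, `dd_ct`,
#'   `relative_expression`, `flagged` (reference missing in that sample).
#' @export
relative_expression <- function(ct_table, reference_target,
                                calibrator_sample, efficiency = 2) {
  need <- c("sample_id", "genotype", "target", "ct")
  stopifnot(all(need %in% names(ct_table)))
  if (efficiency <= 1)
    subtelo_error("subtelo_config_error",
                  "amplification efficiency must exceed 1")
  if (any(ct_table$ct <= 0))
    subtelo_error("subtelo_parse_error", "Ct values must be positive")
  if (!reference_target %in% ct_table$target)
    subtelo_error("subtelo_contract_error",
                  "reference target '%s' absent from Ct table", reference_target)
  if (!calibrator_sample %in% ct_table$sample_id)
    subtelo_error("subtelo_contract_error",
                  "calibrator sample '%s' absent from Ct table", calibrator_sample)
  mean_ct <- stats::aggregate(ct ~ sample_id + genotype + target,
                              data = ct_table, FUN = mean)
  ref <- mean_ct[mean_ct$target == reference_target, c("sample_id", "ct")]
  names(ref)[2] <- "ref_ct"
  tgt <- mean_ct[mean_ct$target != reference_target, , drop = FALSE]
  tgt <- merge(tgt, ref, by = "sample_id", all.x = TRUE)
  tgt$flagged <- is.na(tgt$ref_ct)
  if (any(tgt$flagged))
    subtelo_warn("reference target missing in sample(s): %s (excluded)",
                 paste(unique(tgt$sample_id[tgt$flagged]), collapse = ", "))
  tgt$d_ct <- tgt$ct - tgt$ref_ct
  out <- do.call(rbind, lapply(split(tgt, tgt$target), function(g) {
    cal <- g$d_ct[g$sample_id == calibrator_sample]
    if (length(cal) != 1L || is.na(cal))
      subtelo_error("subtelo_contract_error",
                    "calibrator dCt unavailable for target '%s'", g$target[1])
    g$dd_ct <- g$d_ct - cal
    g$relative_expression <- efficiency^(-g$dd_ct)
    g
  }))
  out <- out[!out$flagged,
             c("sample_id", "genotype", "target", "d_ct", "dd_ct",
               "relative_expression", "flagged")]
  rownames(out) <- NULL
  out
}

#' Per-genotype expression summary and unpaired t test
#'
#' Summarizes relative expression by genotype (mean, SE, n), forms the
#' ratio of group means (first genotype over second by default), and runs
#' an unpaired two-sample t test. Zero within-group variance in both
#' groups makes the t statistic undefined; the ratio is still returned
#' with a degenerate-variance flag.
#'
#' @param rel data.frame from [relative_expression()] for one target (or
#'   any data.frame with `genotype` and `relative_expression`).
#' @param numerator,denominator genotype names; defaults are the first two
#'   in order of appearance.
#' @return list: `summary` (per-genotype mean/se/n), `ratio_of_means`,
#'   `p_value`, `degenerate`.
#' @export
group_fold <- function(rel, numerator = NULL, denominator = NULL) {
  g <- unique(rel$genotype)
  if (is.null(numerator)) numerator <- g[1]
  if (is.null(denominator)) denominator <- setdiff(g, numerator)[1]
  a <- rel$relative_expression[rel$genotype == numerator]
  b <- rel$relative_expression[rel$genotype == denominator]
  if (length(a) < 2L || length(b) < 2L)
    subtelo_error("subtelo_contract_error",
                  "each genotype needs at least 2 samples")
  smry <- data.frame(
    genotype = c(numerator, denominator),
    mean = c(mean(a), mean(b)),
    se = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b))),
    n = c(length(a), length(b)))
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  p <- if (degenerate) NA_real_ else stats::t.test(a, b)$p.value
  list(summary = smry, ratio_of_means = mean(a) / mean(b),
       p_value = p, degenerate = degenerate)
}
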