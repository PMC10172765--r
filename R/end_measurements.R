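#' Read a per-chromosome-end measurement table
#'
#' @param path TSV with columns `cell_id`, `genotype`, `end_id`,
#'   `damaged` (0/1), `modality`, `total_intensity`, `area`,
#'   `mean_intensity`, `cell_area`.
#' @return data.frame; `damaged` coerced to logical. Rows where all three
#'   of total intensity, area and mean intensity are present are checked
#'   for internal consistency (mean = total/area within 1e-6 relative).
#' @export
read_end_measurements <- function(path) {
  x <- read_tsv_table(path)
  need <- c("cell_id", "genotype", "end_id", "damaged", "total_intensity", "area")
  miss <- setdiff(need, names(x))
  if (length(miss))
    subtelo_error("subtelo_parse_error",
                  "end-measurement table missing column(s): %s",
                  paste(miss, collapse = ", "))
  x$damaged <- as.logical(as.integer(x$damaged))
  if (any(x$area <= 0))
    subtelo_error("subtelo_parse_error", "signal area must be positive")
  if ("mean_intensity" %in% names(x)) {
    ok <- is.finite(x$mean_intensity) & x$mean_intensity > 0
    rel <- abs(x$mean_intensity[ok] - x$total_intensity[ok] / x$area[ok]) /
      x$mean_intensity[ok]
    if (any(rel > 1e-6))
      subtelo_warn("%d row(s) where mean_intensity != total_intensity/area",
                   sum(rel > 1e-6))
  } else {
    x$mean_intensity <- x$total_intensity / x$area
  }
  x
}

#' Per-cell signal count and total intensity per cell area
#'
#' For each cell: the number of signals and the summed total intensity
#' divided by the cell area (total signal intensity per cell area, the
#' per-spermatocyte statistic). Cells without a cell area get the count
#' only.
#'
#' @param measurements end-measurement table (one row per signal).
#' @param cell_area optional named vector of cell areas keyed by cell_id;
#'   if `NULL`, a `cell_area` column in `measurements` is used.
#' @return data.frame `cell_id`, `genotype`, `n_signals`,
#'   `intensity_per_area` (`NA` when the area is unknown).
#' @export
per_cell_summary <- function(measurements, cell_area = NULL) {
  cells <- unique(measurements[, c("cell_id", "genotype")])
  # cells named only in the area vector (no signals) still get a count of 0
  extra <- setdiff(names(cell_area), cells$cell_id)
  if (length(extra))
    cells <- rbind(cells, data.frame(cell_id = extra, genotype = NA_character_))
  n <- table(measurements$cell_id)
  tot <- tapply(measurements$total_intensity, measurements$cell_id, sum)
  area <- if (!is.null(cell_area)) {
    as.numeric(cell_area[cells$cell_id])
  } else if ("cell_area" %in% names(measurements)) {
    as.numeric(tapply(measurements$cell_area, measurements$cell_id,
                      function(v) v[1])[cells$cell_id])
  } else rep(NA_real_, nrow(cells))
  if (any(is.finite(area) & area <= 0))
    subtelo_error("subtelo_parse_error", "cell area must be positive")
  cnt <- as.integer(n[cells$cell_id])
  cnt[is.na(cnt)] <- 0L
  ti <- as.numeric(tot[cells$cell_id])
  ti[is.na(ti)] <- 0
  data.frame(cell_id = cells$cell_id, genotype = cells$genotype,
             n_signals = cnt,
             intensity_per_area = ti / area,
             stringsAsFactors = FALSE)
}

#' Damaged : non-damaged ratios of intensity, area and mean intensity
#'
#' Ratios of group means between damaged and non-damaged chromosome ends,
#' for total signal intensity, signal area and mean signal intensity. The
#' grouping unit is configurable: `"pooled"` (default) pools all ends
#' across cells before taking means, matching a per-chromosome-end
#' scatter; `"per_cell"` forms the three ratios within each cell (cells
#' lacking either class are dropped with a flag) and averages them.
#'
#' @param measurements end-measurement table.
#' @param grouping `"pooled"` or `"per_cell"`.
#' @return list: `ratios` (named numeric: `total_intensity`, `area`,
#'   `mean_intensity`), `grouping`, `n_damaged`, `n_undamaged`,
#'   `flagged` (TRUE when a class is empty and ratios are undefined).
#' @export
damaged_ratio <- function(measurements, grouping = c("pooled", "per_cell")) {
  grouping <- match.arg(grouping)
  vars <- c("total_intensity", "area", "mean_intensity")
  measurements$damaged <- as.logical(measurements$damaged)
  one <- function(m) {
    d <- m[m$damaged, vars, drop = FALSE]
    u <- m[!m$damaged, vars, drop = FALSE]
    if (!nrow(d) || !nrow(u)) return(rep(NA_real_, 3))
    colMeans(d) / colMeans(u)
  }
  if (grouping == "pooled") {
    r <- one(measurements)
  } else {
    per <- t(vapply(split(measurements, measurements$cell_id), one,
                    numeric(3)))
    keep <- stats::complete.cases(per)
    if (sum(keep) < nrow(per))
      subtelo_warn("%d cell(s) lacking damaged or non-damaged ends dropped",
                   sum(!keep))
    r <- if (any(keep)) colMeans(per[keep, , drop = FALSE]) else rep(NA_real_, 3)
  }
  names(r) <- vars
  list(ratios = r, grouping = grouping,
       n_damaged = sum(measurements$damaged),
       n_undamaged = sum(!measurements$damaged),
       flagged = any(!is.finite(r)))
}

#' Dunn's multiple comparison test
#'
#' Rank-based pairwise comparisons following a Kruskal-Wallis layout: all
#' observations are ranked jointly, pairwise z statistics are formed from
#' mean-rank differences with the tie-corrected variance, and two-sided
#' normal p-values are adjusted for the number of pairs.
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 3 levels).
#' @param p_adjust_method passed to [stats::p.adjust()]; default
#'   `"bonferroni"`, the classical Dunn adjustment.
#' @return data.frame `contrast`, `z`, `p_unadjusted`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust_method = "bonferroni") {
  groups <- factor(groups)
  if (nlevels(groups) < 3L)
    subtelo_error("subtelo_contract_error",
                  "Dunn's test requires at least 3 groups")
  N <- length(values)
  rk <- rank(values)
  mean_rk <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(levels(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(v0 * (1 / n[[i1]] + 1 / n[[i2]]))
    z[j] <- (mean_rk[[i1]] - mean_rk[[i2]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(contrast = paste(pairs[1, ], pairs[2, ], sep = "-"),
             z = z, p_unadjusted = p,
             p_adj = pmin(1, stats::p.adjust(p, method = p_adjust_method)),
             stringsAsFactors = FALSE)
}

#' Compare measurement distributions between groups
#'
#' Dispatches to the tests used for cytological comparisons: Mann-Whitney
#' (unpaired nonparametric, 2 groups), unpaired t (2 groups), Tukey's
#' multiple comparison (>= 2 groups) or Dunn's multiple comparison
#' (>= 3 groups, pairwise adjusted p-values).
#'
#' @param values numeric vector of measurements.
#' @param groups grouping factor.
#' @param test one of `"mann_whitney"`, `"t"`, `"tukey"`, `"dunn"`.
#' @return list with `test`, `p_value` (overall or two-group), and for the
#'   multiple-comparison tests a `pairwise` data.frame of adjusted
#'   p-values.
#' @export
compare_distributions <- function(values, groups,
                                  test = c("mann_whitney", "t", "tukey", "dunn")) {
  test <- match.arg(test)
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L)
    subtelo_error("subtelo_contract_error", "need at least 2 groups")
  if (test %in% c("mann_whitney", "t") && k != 2L)
    subtelo_error("subtelo_contract_error",
                  "%s test requires exactly 2 groups, got %d", test, k)
  switch(test,
    mann_whitney = {
      sp <- split(values, groups)
      w <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]]))
      list(test = test, statistic = unname(w$statistic), p_value = w$p.value)
    },
    t = {
      sp <- split(values, groups)
      tt <- stats::t.test(sp[[1]], sp[[2]])
      list(test = test, statistic = unname(tt$statistic), p_value = tt$p.value)
    },
    tukey = {
      fit <- stats::aov(values ~ groups)
      tk0 <- stats::TukeyHSD(fit, "groups")$groups
      pw <- data.frame(contrast = rownames(tk0), diff = tk0[, "diff"],
                       p_adj = tk0[, "p adj"], stringsAsFactors = FALSE)
      rownames(pw) <- NULL
      list(test = test, p_value = summary(fit)[[1]]$`Pr(>F)`[1], pairwise = pw)
    },
    dunn = {
      pw <- dunn_test(values, groups)
      list(test = test, p_value = min(pw$p_adj), pairwise = pw)
    })
}
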