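#' Build a run configuration
#'
#' Collects every tunable of the end-to-end analysis. The configuration
#' serializes losslessly to JSON/YAML and its hash is recorded in the
#' header of every output table.
#'
#' @param chrom_sizes path to a chrom.sizes file.
#' @param telomere_bed optional telomere-annotation BED path.
#' @param distances window distance classes, bp.
#' @param anchor `"distal"` or `"both"`.
#' @param rule counting rule (see [count_reads()]).
#' @param pseudocount pseudocount for fold changes.
#' @param genome_wide_denominator normalize by the genome-wide average
#'   density instead of the per-chromosome average (off by default; use
#'   of the switch is logged).
#' @param contrasts list of `c(case, control)` genotype pairs.
#' @param seed integer seed recorded in outputs.
#' @return a `subtelo_config` list.
#' @export
run_config <- function(chrom_sizes = NULL, telomere_bed = NULL,
                       distances = c(5e3, 45e3, 450e3, 4500e3),
                       anchor = "distal", rule = "overlap", pseudocount = 0,
                       genome_wide_denominator = FALSE,
                       contrasts = NULL, seed = 1) {
  cfg <- list(chrom_sizes = chrom_sizes, telomere_bed = telomere_bed,
              distances = distances, anchor = anchor, rule = rule,
              pseudocount = pseudocount,
              genome_wide_denominator = genome_wide_denominator,
              contrasts = contrasts, seed = seed)
  class(cfg) <- "subtelo_config"
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

#' Run the subtelomeric density pipeline end to end
#'
#' Loads the genome model, builds the nested end-anchored windows,
#' quantifies every sample in the sheet, computes per-chromosome fold
#' changes for each configured contrast, runs the per-distance genotype
#' comparison (Tukey), and computes nested-region transcript fractions
#' per genotype for RNA samples (per sample otherwise). Deterministic
#' given inputs and configuration; every exclusion (truncated window,
#' zero denominator) is flagged in the tables.
#'
#' @param config a [run_config()].
#' @param sample_sheet path to a sample-sheet TSV or an equivalent
#'   data.frame; a `reads` list column (in-memory read tables keyed by
#'   sample) may replace `path`.
#' @param samples optional named list of read tables overriding `path`
#'   (used for in-memory simulated studies).
#' @param output_dir if non-NULL, TSV outputs are written there.
#' @return list of class `subtelo_run`: `config`, `chroms`, `windows`,
#'   `densities`, `fold_changes`, `comparisons`, `fractions`, `log`.
#' @export
run_subtelo <- function(config, sample_sheet, samples = NULL,
                        output_dir = NULL) {
  logs <- character()
  note <- function(...) logs <<- c(logs, sprintf(...))
  sheet <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet)
           else sample_sheet
  chroms <- load_chrom_sizes(config$chrom_sizes)
  if (!is.null(config$telomere_bed)) {
    chroms <- apply_telomere_annotation(chroms, config$telomere_bed)
    note("telomere annotation applied: %s", config$telomere_bed)
  }
  windows <- build_subtelomeric_windows(chroms, config$distances,
                                        anchor = config$anchor)
  if (any(windows$truncated))
    note("%d truncated window(s) flagged", sum(windows$truncated))

  densities <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
    aln <- if (!is.null(samples)) samples[[sheet$sample_id[i]]]
           else read_alignments(sheet$path[i])
    d <- quantify_sample(aln, windows, chroms,
                         sample_id = sheet$sample_id[i], rule = config$rule)
    if (isTRUE(config$genome_wide_denominator)) {
      # single genome-wide reads-per-bp denominator across chromosomes
      per_chr <- unique(d[, c("chrom", "genome_avg_density")])
      eff <- chroms$effective_length[match(per_chr$chrom, chroms$name)]
      gw <- sum(per_chr$genome_avg_density * eff) / sum(chroms$effective_length)
      d$genome_avg_density <- gw
      d$normalized_density <- ifelse(gw > 0, d$density / gw, NA_real_)
      d$flagged <- !is.finite(d$normalized_density)
    }
    d$genotype <- sheet$genotype[i]
    d$replicate <- sheet$replicate[i]
    d$assay <- sheet$assay[i]
    d
  }))
  if (isTRUE(config$genome_wide_denominator))
    note("genome-wide denominator in use (per-chromosome is the default)")
  if (any(densities$flagged))
    note("%d density record(s) flagged (zero genome-average denominator)",
         sum(densities$flagged))

  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    gts <- unique(sheet$genotype)
    contrasts <- lapply(setdiff(gts, gts[1]), function(g) c(g, gts[1]))
  }
  fold_changes <- NULL
  for (ct in contrasts) {
    for (as_ in unique(densities$assay)) {
      dc <- densities[densities$assay == as_, , drop = FALSE]
      if (!all(ct %in% dc$genotype)) next
      fc <- fold_change(dc[dc$genotype == ct[1], ],
                        dc[dc$genotype == ct[2], ],
                        pseudocount = config$pseudocount)
      fc$assay <- as_; fc$case <- ct[1]; fc$control <- ct[2]
      fold_changes <- rbind(fold_changes, fc)
    }
  }

  comparisons <- list()
  for (as_ in unique(densities$assay)) {
    dc <- densities[densities$assay == as_, , drop = FALSE]
    if (length(unique(dc$genotype)) < 2L) next
    for (d in config$distances) {
      key <- sprintf("%s_d%s", as_, format(d, scientific = FALSE))
      comparisons[[key]] <- tryCatch(
        compare_genotypes(dc, d),
        subtelo_error = function(e) { note("comparison %s: %s", key,
                                           conditionMessage(e)); NULL })
    }
  }

  fractions <- do.call(rbind, lapply(unique(sheet$genotype), function(g) {
    dc <- densities[densities$genotype == g, , drop = FALSE]
    fr <- transcript_fractions(dc, config$distances)
    fr$genotype <- g
    fr
  }))

  res <- structure(list(config = config, chroms = chroms, windows = windows,
                        densities = densities, fold_changes = fold_changes,
                        comparisons = comparisons, fractions = fractions,
                        log = logs),
                   class = "subtelo_run")
  if (!is.null(output_dir)) write_run(res, output_dir)
  res
}

#' Write the pipeline tables of a run to a directory
#'
#' Emits `densities.tsv`, `fold_changes.tsv`, `comparisons.tsv`,
#' `fractions.tsv` and `run_log.txt`, each table headed by the package
#' version and the configuration hash. Byte-identical across repeated
#' runs on the same inputs.
#'
#' @param res a `subtelo_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(tool = paste0("subtelo ",
                         as.character(utils::packageVersion("subtelo"))),
           config_hash = config_hash(res$config),
           seed = as.character(res$config$seed))
  write_tsv_table(res$densities, file.path(dir, "densities.tsv"), hdr)
  if (!is.null(res$fold_changes))
    write_tsv_table(res$fold_changes, file.path(dir, "fold_changes.tsv"), hdr)
  cmp <- do.call(rbind, lapply(names(res$comparisons), function(k) {
    x <- res$comparisons[[k]]
    if (is.null(x)) return(NULL)
    data.frame(group = k, distance_class = x$distance_class,
               contrast = x$tukey$contrast, diff = x$tukey$diff,
               p_adj = x$tukey$p_adj, anova_p = x$anova$p_value,
               two_way_p = x$two_way_p, degenerate = x$degenerate,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cmp))
    write_tsv_table(cmp, file.path(dir, "comparisons.tsv"), hdr)
  write_tsv_table(res$fractions, file.path(dir, "fractions.tsv"), hdr)
  writeLines(c(sprintf("# %s: %s", names(hdr), hdr), res$log),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.subtelo_run <- function(x, ...) {
  cat(sprintf("subtelo run: %d chromosomes, %d windows, %d samples\n",
              nrow(x$chroms), nrow(x$windows),
              length(unique(x$densities$sample_id))))
  if (!is.null(x$fold_changes)) {
    med <- stats::aggregate(fold_change ~ distance_class + case,
                            data = x$fold_changes, FUN = stats::median)
    cat("median per-chromosome fold change by distance class:\n")
    print(med, row.names = FALSE)
  }
  invisible(x)
}

#' Render figure-style summaries of a run
#'
#' Per-distance strip plots of per-chromosome fold changes and a bar
#' chart of nested-region transcript fractions, regenerated purely from
#' the run's tables (re-rendering is idempotent). Empty tables yield an
#' explicit "no data" panel rather than an error.
#'
#' @param res a `subtelo_run`.
#' @param dir output directory for PNG files.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  png_dev <- function(path) grDevices::png(path, width = 900, height = 600)
  f1 <- file.path(dir, "fold_change_strips.png")
  png_dev(f1)
  fc <- res$fold_changes
  if (is.null(fc) || !nrow(fc)) {
    graphics::plot.new(); graphics::title("fold changes: no data")
  } else {
    dists <- sort(unique(fc$distance_class))
    graphics::par(mfrow = c(1, length(dists)))
    for (d in dists) {
      sub <- fc[fc$distance_class == d & !fc$undefined, ]
      graphics::stripchart(fold_change ~ case, data = sub, vertical = TRUE,
                           method = "jitter", pch = 16,
                           main = sprintf("%s kb", format(d / 1e3)),
                           ylab = "fold change vs control")
      graphics::abline(h = 1, lty = 2)
    }
  }
  grDevices::dev.off()
  files <- c(files, f1)
  f2 <- file.path(dir, "transcript_fractions.png")
  png_dev(f2)
  fr <- res$fractions
  if (is.null(fr) || !nrow(fr) || all(is.na(fr$percent))) {
    graphics::plot.new(); graphics::title("transcript fractions: no data")
  } else {
    tab <- stats::reshape(fr[, c("genotype", "distance_class", "percent")],
                          direction = "wide", idvar = "distance_class",
                          timevar = "genotype")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- sprintf("%s kb", format(tab$distance_class / 1e3))
    graphics::barplot(t(m), beside = TRUE,
                      ylab = "% of reads within reference region",
                      legend.text = sub("^percent\\.", "", colnames(m)))
  }
  grDevices::dev.off()
  files <- c(files, f2)
  invisible(files)
}
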