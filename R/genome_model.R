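#' Load chromosome sizes
#'
#' Reads a UCSC-style `chrom.sizes` file (two whitespace-delimited columns:
#' chromosome name, length in bp) into the effective-chromosome table the
#' rest of the pipeline hangs off. Until a telomere annotation is applied
#' (see [apply_telomere_annotation()]), the effective end of each
#' chromosome is its raw length.
#'
#' @param path path to a chrom.sizes file.
#' @return a data.frame with columns `name`, `raw_length`, `effective_end`
#'   and `effective_length` (bp). `effective_length` always equals
#'   `effective_end`: the coordinate where the telomeric repeat region
#'   starts is used both as the chromosome end and as its total length.
#' @export
load_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(name = character(), raw_length = numeric(),
                      effective_end = numeric(), effective_length = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2L || is.na(suppressWarnings(as.numeric(f[2L]))))
      subtelo_error("subtelo_parse_error",
                    "malformed chrom.sizes line %d: '%s'", i, lines[i])
    if (as.numeric(f[2L]) <= 0)
      subtelo_error("subtelo_parse_error",
                    "non-positive chromosome length at line %d: '%s'",
                    i, lines[i])
  }
  name <- vapply(fields, `[`, "", 1L)
  len <- vapply(fields, function(f) as.numeric(f[2L]), 0)
  dup <- name[duplicated(name)]
  if (length(dup))
    subtelo_error("subtelo_parse_error",
                  "duplicate chromosome name(s): %s (line %d)",
                  paste(unique(dup), collapse = ", "),
                  which(duplicated(name))[1L])
  data.frame(name = name, raw_length = len, effective_end = len,
             effective_length = len, stringsAsFactors = FALSE)
}

#' Apply a telomere annotation to set effective chromosome ends
#'
#' The coordinate where the annotated telomeric repeat region begins is
#' taken as the effective end of the chromosome, and therefore also as its
#' effective (total) length for genome-average normalization. Chromosomes
#' without an annotation keep `effective_end = raw_length`.
#'
#' Only the distal end is trimmed: when several records exist for one
#' chromosome the most distal one (largest end coordinate) is used and a
#' warning is emitted.
#'
#' @param chroms effective-chromosome table from [load_chrom_sizes()].
#' @param annotation BED-style annotation: either a path to a BED3+ file or
#'   a data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @return the chromosome table with updated `effective_end` /
#'   `effective_length`.
#' @export
apply_telomere_annotation <- function(chroms, annotation) {
  if (is.character(annotation)) annotation <- read_bed(annotation)
  stopifnot(all(c("chrom", "start", "end") %in% names(annotation)))
  for (cn in unique(annotation$chrom)) {
    idx <- match(cn, chroms$name)
    recs <- annotation[annotation$chrom == cn, , drop = FALSE]
    if (is.na(idx)) {
      subtelo_warn("telomere annotation for unknown chromosome '%s' skipped", cn)
      next
    }
    if (any(recs$end > chroms$raw_length[idx]) || any(recs$start < 0))
      subtelo_error("subtelo_annotation_error",
                    "telomere interval outside [0, %d] on %s",
                    chroms$raw_length[idx], cn)
    if (nrow(recs) > 1L)
      subtelo_warn("%d telomere records on %s; using the most distal", nrow(recs), cn)
    distal <- recs[which.max(recs$end), ]
    chroms$effective_end[idx] <- distal$start
    chroms$effective_length[idx] <- distal$start
  }
  if (any(chroms$effective_end <= 0))
    subtelo_error("subtelo_annotation_error",
                  "telomere annotation leaves zero-length chromosome(s): %s",
                  paste(chroms$name[chroms$effective_end <= 0], collapse = ", "))
  chroms
}

#' Build nested end-anchored subtelomeric windows
#'
#' For each chromosome and each distance class d, the distal window is the
#' terminal interval `[max(0, effective_end - d), effective_end)` in
#' 0-based half-open coordinates. Windows of increasing d on one
#' chromosome are nested. When d exceeds the effective chromosome length
#' the window covers the whole chromosome and is flagged `truncated`;
#' truncated windows are kept but excluded from cross-chromosome
#' statistics by default because their density denominator differs from d.
#'
#' @param chroms effective-chromosome table.
#' @param distances strictly increasing vector of distances from the
#'   chromosome end, in bp. Default 5 kb, 45 kb, 450 kb and 4,500 kb.
#' @param anchor `"distal"` (default; mouse chromosomes are acrocentric) or
#'   `"both"` to also anchor windows on the proximal end.
#' @return a data.frame with columns `chrom`, `start`, `end`,
#'   `distance_class`, `anchor`, `truncated`.
#' @export
build_subtelomeric_windows <- function(chroms,
                                       distances = c(5e3, 45e3, 450e3, 4500e3),
                                       anchor = c("distal", "both")) {
  anchor <- match.arg(anchor)
  if (any(distances <= 0) || is.unsorted(distances, strictly = TRUE))
    subtelo_error("subtelo_config_error",
                  "distances must be positive and strictly increasing")
  one_end <- function(which_end) {
    do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
      L <- chroms$effective_end[i]
      trunc <- distances > L
      if (which_end == "distal") {
        start <- pmax(0, L - distances); end <- rep(L, length(distances))
      } else {
        start <- rep(0, length(distances)); end <- pmin(distances, L)
      }
      data.frame(chrom = chroms$name[i], start = start, end = end,
                 distance_class = distances, anchor = which_end,
                 truncated = trunc, stringsAsFactors = FALSE)
    }))
  }
  out <- one_end("distal")
  if (anchor == "both") out <- rbind(out, one_end("proximal"))
  if (any(out$truncated))
    subtelo_warn("%d window(s) truncated to full chromosome length",
                 sum(out$truncated))
  rownames(out) <- NULL
  out
}

#' Export subtelomeric windows as BED6
#'
#' Names follow `CHROM:d<distance>` so window identity survives a round
#' trip through standard interval tools.
#'
#' @param windows window table from [build_subtelomeric_windows()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
windows_to_bed <- function(windows, path) {
  bed <- data.frame(chrom = windows$chrom,
                    start = format(windows$start, scientific = FALSE, trim = TRUE),
                    end = format(windows$end, scientific = FALSE, trim = TRUE),
                    name = sprintf("%s:d%s", windows$chrom,
                                   format(windows$distance_class,
                                          scientific = FALSE, trim = TRUE)),
                    score = 0L,
                    strand = ifelse(windows$anchor == "distal", "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
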