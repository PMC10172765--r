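#' Read a BED3+ file of aligned reads or intervals
#'
#' BED coordinates are 0-based half-open and are kept that way: all
#' internal interval arithmetic in this package uses the BED convention.
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end`, and `strand`
#'   plus `name` when present in the file. A `weight` column (default 1)
#'   is added for optional multiplicity weighting.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#",
                         col.names = paste0("V", 1:12), fill = TRUE)[
                           , 1:6, drop = FALSE]
  out <- data.frame(chrom = as.character(x$V1),
                    start = as.numeric(x$V2),
                    end = as.numeric(x$V3),
                    stringsAsFactors = FALSE)
  if (!all(is.na(x$V4)) && any(nzchar(as.character(x$V4))))
    out$name <- as.character(x$V4)
  strand <- as.character(x$V6)
  out$strand <- ifelse(is.na(strand) | !strand %in% c("+", "-"), "*", strand)
  out$weight <- 1
  if (any(out$start >= out$end))
    subtelo_error("subtelo_parse_error",
                  "BED record with start >= end at line %d",
                  which(out$start >= out$end)[1L])
  out
}

#' Read aligned reads from a coordinate-sorted indexed BAM
#'
#' Alignment records are extracted with their reference span and converted
#' from the 1-based closed BAM convention to the package's 0-based
#' half-open convention. Unmapped records are dropped. If the index is
#' missing it is built in place.
#'
#' @param path BAM file path.
#' @param region optional `GRanges` restricting the query.
#' @return data.frame as from [read_bed()].
#' @export
read_bam <- function(path, region = NULL) {
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path))) {
    Rsamtools::indexBam(path)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "cigar", "strand"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    which = if (is.null(region)) GenomicRanges::GRanges() else region)
  if (is.null(region))
    param <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "qwidth", "cigar", "strand"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(path, param = param)
  res <- do.call(Map, c(list(f = c), res))
  width <- GenomicAlignments_width(res$cigar, res$qwidth)
  data.frame(chrom = as.character(res$rname),
             start = res$pos - 1,             # BAM 1-based -> BED 0-based
             end = res$pos - 1 + width,
             strand = as.character(res$strand),
             weight = 1,
             stringsAsFactors = FALSE)
}

## Reference-span width from CIGAR (M/D/N/=/X consume reference); falls
## back to query width when the CIGAR is absent.
GenomicAlignments_width <- function(cigar, qwidth) {
  vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (is.na(cg) || cg == "*") return(as.numeric(qwidth[i]))
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.numeric(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 0)
}

#' Read aligned reads from BED or BAM, dispatching on extension
#' @param path file path ending in `.bed` or `.bam`.
#' @return data.frame as from [read_bed()].
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) read_bam(path)
  else read_bed(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `path`, `genotype`,
#'   `replicate`, `assay` (`atac` or `rna`).
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  x <- read_tsv_table(path)
  need <- c("sample_id", "path", "genotype", "replicate", "assay")
  miss <- setdiff(need, names(x))
  if (length(miss))
    subtelo_error("subtelo_parse_error",
                  "sample sheet missing column(s): %s",
                  paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    subtelo_error("subtelo_parse_error", "duplicate sample_id in sample sheet")
  if (!all(x$assay %in% c("atac", "rna")))
    subtelo_error("subtelo_parse_error", "assay must be 'atac' or 'rna'")
  # relative paths resolve against the sheet's own directory
  rel <- !is.na(x$path) & !grepl("^(/|[A-Za-z]:)", x$path)
  x$path[rel] <- file.path(dirname(path), x$path[rel])
  x
}

## data.frame of 0-based half-open intervals -> GRanges (1-based closed)
intervals_to_granges <- function(df, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(df$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}
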