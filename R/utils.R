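#' Derive a reproducible child seed from a master seed
#'
#' A single integer master seed fans out deterministically to per-stage
#' seeds so that one flag reproduces an entire simulated study. The
#' derivation hashes the stage label into an offset and keeps the result
#' inside the 32-bit positive integer range `set.seed()` accepts.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"reads:wt:rep1"`).
#' @return a single integer seed.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 7919 + h * 104729 + 17) %% 2147483629)
}

## Evaluate `expr` with a local RNG state so simulators are pure functions
## of (parameters, seed) and never disturb the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Write a table as TSV with an optional header comment
#'
#' All pipeline outputs are plain TSV. A `# key: value` comment block may
#' be prepended (run configuration, hashes) without breaking `read_tsv`-
#' style readers that honour `#` comments.
#'
#' @param x data.frame.
#' @param path output path.
#' @param header named character vector written as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) {
    writeLines(sprintf("# %s: %s", names(header), unname(header)), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a TSV table, skipping `#` comment lines
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

## stop() with a named error class so callers and the CLI can dispatch on
## failure mode.
subtelo_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "subtelo_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

subtelo_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}
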