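# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @importFrom data.table data.table as.data.table setkey setorder := .N .SD
#' @importFrom data.table fread fwrite setnames rbindlist copy setkeyv fifelse
#' @importFrom data.table J setcolorder
#' @importFrom stats median quantile setNames p.adjust r2dtable rmultinom runif rnorm dhyper
NULL

# deterministic TSV writer: tab-separated, no quoting, fixed NA string
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA",
                     scipen = 50, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA", ...)
}

# strand-aware signed distance from a to b in transcription direction
# (strand may be scalar or vector; result recycles over positions)
sense_dist <- function(from, to, strand) {
  sign <- ifelse(strand == "+", 1L, -1L)
  sign * (to - from)
}

# strand-aware comparison: is a more 3' (distal) than b?
more_distal <- function(a, b, strand) {
  sense_dist(b, a, strand) > 0
}

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-")))
    stopf("strand must be '+' or '-' (got: %s)",
          paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  invisible(TRUE)
}

# derive a child seed (< 2^31) from a parent seed and a stream label
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
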