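# Core I/O: transcript models from GTF, read alignments from BED12,
# site databases from BED6, genome FASTA access.
#
# Internal coordinate convention: 0-based half-open intervals everywhere
# (BED-native). Strand-aware termini of a feature spanning [start, end):
#   + strand: five_prime = start, three_prime = end
#   - strand: five_prime = end,   three_prime = start
# A point site (TSS or PAS) is stored as a single integer `pos` in this
# same terminus convention, so |read terminus - site pos| is directly the
# assignment distance on either strand.

#' Genomic interval constructor
#'
#' Plain validated data.table of 0-based half-open intervals; the basic
#' currency of all coordinate arithmetic in the package.
#'
#' @param chrom character chromosome names.
#' @param start 0-based inclusive starts.
#' @param end exclusive ends.
#' @param strand "+" or "-".
#' @return data.table with columns chrom, start, end, strand.
#' @export
genome_interval <- function(chrom, start, end, strand) {
  check_strand(strand)
  if (any(start < 0)) stopf("interval start must be >= 0")
  if (any(start >= end)) stopf("interval must satisfy start < end")
  data.table(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand))
}

empty_tx_table <- function() {
  data.table(transcript_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             tx_start = integer(), tx_end = integer(), n_exons = integer(),
             five_prime = integer(), three_prime = integer(),
             orf_end = integer())
}

new_tx_set <- function(exons, cds = NULL) {
  setorder(exons, transcript_id, start)
  if (!nrow(exons))
    return(structure(list(exons = exons[], tx = empty_tx_table()),
                     class = "tx_set"))
  tx <- exons[, {
    if (.N > 1L && any(start[-1L] < end[-.N]))
      stopf("transcript '%s': overlapping exons", transcript_id[1])
    .(gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
      tx_start = min(start), tx_end = max(end), n_exons = .N)
  }, by = transcript_id]
  tx[, five_prime := fifelse(strand == "+", tx_start, tx_end)]
  tx[, three_prime := fifelse(strand == "+", tx_end, tx_start)]
  tx[, orf_end := NA_integer_]
  if (!is.null(cds) && nrow(cds)) {
    # ORF end = strand-aware 3' boundary of the CDS
    oe <- cds[, .(orf_end = if (strand[1] == "+") max(end) else min(start)),
              by = transcript_id]
    tx[oe, orf_end := i.orf_end, on = "transcript_id"]
  }
  structure(list(exons = exons[], tx = tx[]), class = "tx_set")
}

#' @export
print.tx_set <- function(x, ...) {
  cat(sprintf("<tx_set> %d transcripts, %d genes, %d exons\n",
              nrow(x$tx), length(unique(x$tx$gene_id)), nrow(x$exons)))
  invisible(x)
}

#' Parse transcript models from a GTF file
#'
#' Reads exon (and, when present, CDS) features, converts 1-based closed
#' GTF coordinates to the internal 0-based half-open convention, groups
#' exons per transcript and sorts them in genomic order. Transcripts
#' without exons are skipped with a warning; a transcript with exons on
#' mixed strands is an error.
#'
#' @param path GTF file.
#' @return a `tx_set`: list with `$exons` (one row per exon) and `$tx`
#'   (one row per transcript with strand-aware `five_prime`,
#'   `three_prime` and, if CDS features exist, `orf_end`).
#' @export
parse_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")))
    return(new_tx_set(data.table(transcript_id = character(),
                                 gene_id = character(), chrom = character(),
                                 strand = character(), start = integer(),
                                 end = integer())))
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stopf("failed to parse GTF '%s': %s",
                                           path, conditionMessage(e)))
  d <- as.data.table(as.data.frame(gr))
  if (!nrow(d))
    return(new_tx_set(data.table(transcript_id = character(), gene_id = character(),
                                 chrom = character(), strand = character(),
                                 start = integer(), end = integer())))
  if (!all(c("gene_id", "transcript_id") %in% names(d)))
    stopf("GTF '%s' lacks gene_id/transcript_id attributes", path)
  keep <- d$type %in% c("exon", "CDS")
  d <- d[keep]
  all_tx <- unique(d$transcript_id)
  ex <- d[type == "exon",
          .(transcript_id, gene_id, chrom = as.character(seqnames),
            strand = as.character(strand),
            start = as.integer(start - 1L), end = as.integer(end))]
  check_strand(ex$strand)
  bad <- ex[, .(ns = length(unique(strand))), by = transcript_id][ns > 1L]
  if (nrow(bad))
    stopf("mixed strands within transcript(s): %s",
          paste(bad$transcript_id, collapse = ", "))
  no_exon <- setdiff(all_tx, unique(ex$transcript_id))
  if (length(no_exon))
    warnf("skipping %d transcript(s) with zero exons: %s", length(no_exon),
          paste(no_exon, collapse = ", "))
  cds <- d[type == "CDS",
           .(transcript_id, strand = as.character(strand),
             start = as.integer(start - 1L), end = as.integer(end))]
  new_tx_set(ex, cds = if (nrow(cds)) cds else NULL)
}

#' Write transcript models as GTF
#'
#' Inverse of [parse_gtf()]: emits exon features (1-based closed), one
#' per exon, sorted by transcript then genomic position, plus CDS stubs
#' when an ORF end is recorded.
#'
#' @param txs a `tx_set`.
#' @param path output path.
#' @export
write_gtf <- function(txs, path) {
  ex <- copy(txs$exons)
  setorder(ex, transcript_id, start)
  lines <- ex[, sprintf(
    "%s\tisocoupler\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    chrom, start + 1L, end, strand, gene_id, transcript_id)]
  tx <- txs$tx[!is.na(orf_end)]
  if (nrow(tx)) {
    # represent the ORF end as a 1-nt CDS stub at the stop-codon boundary
    cds_start <- fifelse(tx$strand == "+", tx$orf_end - 1L, tx$orf_end)
    lines <- c(lines, tx[, sprintf(
      "%s\tisocoupler\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"%s\"; transcript_id \"%s\";",
      chrom, cds_start + 1L, cds_start + 1L, strand, gene_id, transcript_id)])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse long-read alignments from BED12 with a poly(A) sidecar table
#'
#' Reconstructs aligned blocks from blockStarts/blockSizes, derives
#' strand-aware 5'/3' termini and attaches poly(A)-tail evidence: a read
#' has a tail iff its id appears in the sidecar table.
#'
#' @param path BED12 file.
#' @param polya_path optional TSV with columns `read_id`, `tail_length`;
#'   `NULL` means no read carries a tail.
#' @return a `read_set` data.table: one row per read with `block_starts`/
#'   `block_ends` list-columns (0-based half-open genomic blocks),
#'   `five_prime`, `three_prime`, `has_polya`, `tail_length`.
#' @export
parse_read_bed12 <- function(path, polya_path = NULL) {
  d <- fread(path, sep = "\t", header = FALSE,
             colClasses = list(character = c(1, 4, 6, 11, 12)))
  if (!nrow(d)) {
    rs <- data.table(read_id = character(), chrom = character(),
                     strand = character(), start = integer(), end = integer(),
                     n_blocks = integer(), block_starts = list(),
                     block_ends = list(), five_prime = integer(),
                     three_prime = integer(), has_polya = logical(),
                     tail_length = integer())
    return(structure(rs, class = c("read_set", class(rs))))
  }
  if (ncol(d) < 12L)
    stopf("'%s' is not BED12 (%d columns)", path, ncol(d))
  setnames(d, 1:12, c("chrom", "start", "end", "read_id", "score", "strand",
                      "thick_start", "thick_end", "rgb", "n_blocks",
                      "block_sizes", "block_starts_rel"))
  check_strand(d$strand)
  parse_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  bs <- lapply(d$block_starts_rel, parse_ints)
  bz <- lapply(d$block_sizes, parse_ints)
  for (i in seq_len(nrow(d))) {
    if (length(bs[[i]]) != d$n_blocks[i] || length(bz[[i]]) != d$n_blocks[i])
      stopf("BED12 parse error at line %d: blockCount=%d but %d starts / %d sizes",
            i, d$n_blocks[i], length(bs[[i]]), length(bz[[i]]))
    if (d$n_blocks[i] < 1L)
      stopf("BED12 parse error at line %d: blockCount < 1", i)
    abs_start <- d$start[i] + bs[[i]]
    abs_end <- abs_start + bz[[i]]
    if (abs_start[1] != d$start[i] || abs_end[length(abs_end)] != d$end[i] ||
        any(abs_end > d$end[i]))
      stopf("BED12 validation error at line %d: blocks out of bounds", i)
    if (length(abs_start) > 1L && any(abs_start[-1L] < abs_end[-length(abs_end)]))
      stopf("BED12 validation error at line %d: overlapping/unsorted blocks", i)
    bs[[i]] <- abs_start
    bz[[i]] <- abs_end
  }
  rs <- d[, .(read_id, chrom, strand, start, end, n_blocks)]
  rs[, block_starts := bs]
  rs[, block_ends := bz]
  rs[, five_prime := fifelse(strand == "+", start, end)]
  rs[, three_prime := fifelse(strand == "+", end, start)]
  tails <- if (is.null(polya_path)) {
    data.table(read_id = character(), tail_length = integer())
  } else {
    fread(polya_path, sep = "\t", header = TRUE,
          colClasses = list(character = "read_id"))
  }
  rs[, has_polya := read_id %in% tails$read_id]
  rs[, tail_length := NA_integer_]
  if (nrow(tails))
    rs[tails, tail_length := as.integer(i.tail_length), on = "read_id"]
  structure(rs[], class = c("read_set", class(rs)))
}

#' Write read alignments as BED12 (+ poly(A) sidecar TSV)
#'
#' @param reads a `read_set`.
#' @param path BED12 output path.
#' @param polya_path optional path for the `read_id`/`tail_length` table of
#'   tail-bearing reads.
#' @export
write_read_bed12 <- function(reads, path, polya_path = NULL) {
  fmt <- function(v) paste0(paste(v, collapse = ","), ",")
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    st <- reads$block_starts[[i]]; en <- reads$block_ends[[i]]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            reads$chrom[i], reads$start[i], reads$end[i], reads$read_id[i],
            reads$strand[i], reads$start[i], reads$end[i], length(st),
            fmt(en - st), fmt(st - reads$start[i]))
  }, "")
  writeLines(lines, path)
  if (!is.null(polya_path)) {
    tails <- as.data.table(reads)[has_polya == TRUE,
                                  .(read_id, tail_length)]
    write_tsv(tails, polya_path)
  }
  invisible(path)
}

#' Read a TSS or PAS database from BED6
#'
#' Site positions are stored in the package's terminus convention: the
#' BED interval [start, end) encodes position `start` on the + strand and
#' position `end` on the - strand, matching read `five_prime`/
#' `three_prime` coordinates. The BED name field is `<gene_id>:<site_id>`
#' and the score field is the read support.
#'
#' @param path BED6 file.
#' @return data.table chrom, pos, strand, gene_id, site_id, support.
#' @export
read_site_bed <- function(path) {
  d <- fread(path, sep = "\t", header = FALSE,
             colClasses = list(character = c(1, 4, 6)))
  if (!nrow(d))
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), gene_id = character(),
                      site_id = character(), support = integer()))
  setnames(d, 1:6, c("chrom", "start", "end", "name", "score", "strand"))
  check_strand(d$strand)
  nm <- strsplit(d$name, ":", fixed = TRUE)
  d[, `:=`(pos = fifelse(strand == "+", start, end),
           gene_id = vapply(nm, `[`, "", 1L),
           site_id = vapply(nm, function(x) paste(x[-1L], collapse = ":"), ""),
           support = as.integer(score))]
  d[site_id == "", site_id := gene_id]
  d[, .(chrom, pos, strand, gene_id, site_id, support)]
}

#' Write a site database as BED6
#' @param sites data.table as returned by [read_site_bed()].
#' @param path output path.
#' @export
write_site_bed <- function(sites, path) {
  s <- as.data.table(sites)
  lines <- s[, sprintf("%s\t%d\t%d\t%s\t%d\t%s", chrom,
                       fifelse(strand == "+", pos, pos - 1L),
                       fifelse(strand == "+", pos + 1L, pos),
                       paste0(gene_id, ":", site_id),
                       as.integer(support), strand)]
  writeLines(lines, path)
  invisible(path)
}

#' Load a genome FASTA as a DNAStringSet
#' @param path FASTA file.
#' @return named `Biostrings::DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# fetch sense-strand sequence of [start, end) on `strand` of `chrom`
fetch_seq <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome)) stopf("chromosome '%s' absent from FASTA", chrom)
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# junctions of each transcript: (donor, acceptor) = (exon end, next exon start)
tx_junctions <- function(txs) {
  ex <- copy(txs$exons)
  setorder(ex, transcript_id, start)
  ex[, if (.N > 1L)
    .(donor = end[-.N], acceptor = start[-1L], chrom = chrom[1],
      strand = strand[1], gene_id = gene_id[1]),
    by = transcript_id]
}
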