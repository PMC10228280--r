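# Confident 3'-end database construction and 3'-end QC operations.

#' Ranked poly(A) signal hexamers
#'
#' Twelve known poly(A) signals ordered by strength; screening reports the
#' highest-ranked hexamer present in the scanned window.
#' @export
POLYA_SIGNALS <- c("AATAAA", "ATTAAA", "AATATA", "AAGAAA", "AATACA",
                   "AATAGA", "AATGAA", "ACTAAA", "CATAAA", "GATAAA",
                   "TATAAA", "TTTAAA")

# single-linkage chaining on sorted positions: consecutive gaps <= window
chain_positions <- function(pos, window) {
  o <- order(pos)
  sp <- pos[o]
  grp <- cumsum(c(1L, as.integer(diff(sp) > window)))
  split(sp, grp)
}

cluster_representative <- function(members, strand, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(members))
  agg <- tapply(weights, members, sum)
  cand <- as.integer(names(agg)[agg == max(agg)])
  if (strand == "+") max(cand) else min(cand)  # ties: 3'-most
}

#' Build the confident PAS database from tail-anchored reads
#'
#' Reads must all carry a poly(A) tail; each contributes its 3' terminus
#' (the nucleotide preceding the tail). Per chromosome and strand,
#' positions are chained by single linkage (consecutive sorted gaps
#' \code{<= window}); clusters supported by fewer than `min_support`
#' reads are dropped. The representative position is the member with the
#' highest read count, ties broken towards the 3'-most position.
#'
#' @param reads a `read_set`, pre-filtered to `has_polya == TRUE`.
#' @param window clustering window (nt).
#' @param min_support minimum reads per kept cluster.
#' @return data.table: chrom, strand, pos, support, members (list-column).
#' @export
build_pas_database <- function(reads, window = 20L, min_support = 2L) {
  r <- as.data.table(reads)
  if (!nrow(r))
    return(data.table(chrom = character(), strand = character(),
                      pos = integer(), support = integer(), members = list()))
  if (any(!r$has_polya))
    stopf("build_pas_database: %d read(s) without a poly(A) tail; filter first",
          sum(!r$has_polya))
  out <- r[, {
    cl <- chain_positions(three_prime, window)
    data.table(pos = vapply(cl, cluster_representative, 0L,
                            strand = strand[1]),
               support = vapply(cl, length, 0L),
               members = lapply(cl, function(m) sort(unique(m))))
  }, by = .(chrom, strand)]
  out <- out[support >= min_support]
  setorder(out, chrom, strand, pos)
  out[]
}

#' Cluster 3'-seq cleavage sites
#'
#' Per-base 3'-seq counts are thresholded at `min_cov` reads (per sample
#' when a `sample` column is present), then merged by chaining positions
#' at most `merge` bp apart on the same chromosome and strand.
#'
#' @param cov data.table with chrom, strand, pos, cov and optionally
#'   sample.
#' @param merge merge distance (bp).
#' @param min_cov minimum per-sample coverage.
#' @return data.table: chrom, strand, pos (coverage-weighted modal
#'   position, ties 3'-most), support (total coverage), members.
#' @export
cluster_3seq_sites <- function(cov, merge = 15L, min_cov = 5L) {
  d <- as.data.table(cov)[cov >= min_cov]
  if (!nrow(d))
    return(data.table(chrom = character(), strand = character(),
                      pos = integer(), support = integer(), members = list()))
  d <- d[, .(cov = sum(cov)), by = .(chrom, strand, pos)]
  d[, {
    o <- order(pos)
    sp <- pos[o]; sc <- cov[o]
    grp <- cumsum(c(1L, as.integer(diff(sp) > merge)))
    gs <- split(seq_along(sp), grp)
    data.table(pos = vapply(gs, function(ix)
      cluster_representative(sp[ix], strand[1], sc[ix]), 0L),
      support = vapply(gs, function(ix) as.integer(sum(sc[ix])), 0L),
      members = lapply(gs, function(ix) sp[ix]))
  }, by = .(chrom, strand)][]
}

#' Strand-specific internal-priming blacklist
#'
#' A genomic position is blacklisted iff the 10-nt window immediately
#' upstream on the read's sense strand (a T-run on the reference for -
#' strand positions) contains strictly more than `a_frac` adenosines, and
#' the position lies more than `tes_exempt` bp from every annotated
#' transcript 3' end on the same strand. Positions are in the package's
#' terminus convention (+: exclusive end; -: inclusive start).
#'
#' @param genome DNAStringSet.
#' @param txs annotated transcripts (`tx_set`) supplying transcript ends.
#' @param a_frac strict A-fraction cutoff (0.70).
#' @param window upstream window (bp).
#' @param tes_exempt exemption distance around annotated 3' ends (bp).
#' @return data.table: chrom, pos, strand.
#' @export
internal_priming_mask <- function(genome, txs, a_frac = 0.70, window = 10L,
                                  tes_exempt = 250L) {
  tes <- txs$tx[, .(chrom, strand, pos = three_prime)]
  need <- unique(tes$chrom)
  missing <- setdiff(need, names(genome))
  if (length(missing))
    stopf("chromosome '%s' absent from FASTA", missing[1])
  out <- vector("list", 2L * length(genome))
  k <- 0L
  for (ch in names(genome)) {
    chars <- strsplit(as.character(genome[[ch]]), "")[[1]]
    len <- length(chars)
    if (len < window) next
    csA <- c(0L, cumsum(chars == "A"))
    csT <- c(0L, cumsum(chars == "T"))
    thresh <- a_frac * window
    # + strand: position p has upstream window [p-window, p); valid p >= window
    p_plus <- window:len
    nA <- csA[p_plus + 1L] - csA[p_plus - window + 1L]
    p_plus <- p_plus[nA > thresh]
    # - strand: position p has upstream window [p, p+window); sense A = ref T
    p_minus <- 0:(len - window)
    nT <- csT[p_minus + window + 1L] - csT[p_minus + 1L]
    p_minus <- p_minus[nT > thresh]
    for (st in c("+", "-")) {
      pos <- if (st == "+") p_plus else p_minus
      tp <- tes[chrom == ch & strand == st, pos]
      if (length(tp) && length(pos)) {
        near <- vapply(pos, function(p) min(abs(p - tp)) <= tes_exempt, TRUE)
        pos <- pos[!near]
      }
      k <- k + 1L
      out[[k]] <- data.table(chrom = ch, pos = as.integer(pos), strand = st)
    }
  }
  res <- rbindlist(out[seq_len(k)])
  if (!nrow(res))
    return(data.table(chrom = character(), pos = integer(),
                      strand = character()))
  setorder(res, chrom, strand, pos)
  res[]
}

#' Remove blacklisted clusters from a PAS table
#' @param clusters cluster table with chrom, pos, strand.
#' @param mask blacklist from [internal_priming_mask()].
#' @return clusters whose representative position is not blacklisted.
#' @export
apply_blacklist <- function(clusters, mask) {
  cl <- as.data.table(clusters)
  if (!nrow(cl) || !nrow(mask)) return(cl)
  hit <- mask[cl, on = c("chrom", "pos", "strand"), which = TRUE]
  cl[is.na(hit)]
}

#' Scan for a poly(A) signal upstream of a cleavage site
#'
#' Screens the last `window` nt of the provided sense-strand upstream
#' sequence for the twelve ranked hexamers and returns the highest-ranked
#' one present (set membership first, then rank; independent of scan
#' direction).
#'
#' @param seq sense-strand sequence immediately upstream of cleavage.
#' @param window scan window (20 nt for QC enrichment, 50 nt for
#'   PAS-usage analyses).
#' @return list with `signal` ("none" if absent) and `offset`, the nt
#'   upstream of the cleavage site at which the hexamer starts (NA when
#'   absent).
#' @export
scan_polya_signal <- function(seq, window = 50L) {
  seq <- toupper(seq)
  if (nchar(seq) < window)
    stopf("scan window (%d) longer than provided sequence (%d nt)",
          window, nchar(seq))
  sub <- substring(seq, nchar(seq) - window + 1L, nchar(seq))
  for (hex in POLYA_SIGNALS) {
    m <- gregexpr(hex, sub, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      i <- max(m)  # occurrence closest to the cleavage site
      return(list(signal = hex, offset = window - i + 1L))
    }
  }
  list(signal = "none", offset = NA_integer_)
}

#' Scan poly(A) signals for a table of PASs against a genome
#'
#' @param sites table with chrom, pos, strand.
#' @param genome DNAStringSet.
#' @param window scan window (nt).
#' @return input with `signal` and `offset` columns appended.
#' @export
scan_polya_signals <- function(sites, genome, window = 50L) {
  s <- copy(as.data.table(sites))
  res <- lapply(seq_len(nrow(s)), function(i) {
    chrom <- s$chrom[i]; pos <- s$pos[i]; st <- s$strand[i]
    if (st == "+") {
      if (pos < window) return(list(signal = "none", offset = NA_integer_))
      up <- fetch_seq(genome, chrom, pos - window, pos, "+")
    } else {
      len <- Biostrings::width(genome[names(genome) == chrom])
      if (pos + window > len) return(list(signal = "none", offset = NA_integer_))
      up <- fetch_seq(genome, chrom, pos, pos + window, "-")
    }
    scan_polya_signal(up, window)
  })
  s[, signal := vapply(res, `[[`, "", "signal")]
  s[, offset := vapply(res, `[[`, 0L, "offset")]
  s[]
}

#' Nucleotide composition profile around cleavage sites
#'
#' Sense-strand base frequencies in a window centered on the cleavage
#' nucleotide (the last transcribed base). Sites whose flanks exceed the
#' contig are skipped with a warning.
#'
#' @param sites table with chrom, pos, strand.
#' @param genome DNAStringSet.
#' @param flank nt on each side.
#' @return 4 x (2*flank+1) matrix of frequencies (columns sum to 1),
#'   rows A/C/G/T, column names relative positions -flank..flank.
#' @export
nucleotide_profile <- function(sites, genome, flank = 100L) {
  s <- as.data.table(sites)
  w <- 2L * flank + 1L
  counts <- matrix(0L, 4L, w, dimnames = list(c("A", "C", "G", "T"),
                                              as.character(-flank:flank)))
  skipped <- 0L
  for (i in seq_len(nrow(s))) {
    chrom <- s$chrom[i]; pos <- s$pos[i]; st <- s$strand[i]
    len <- Biostrings::width(genome[names(genome) == chrom])
    # center = last transcribed base: 0-based pos-1 (+) / pos (-)
    if (st == "+") { a <- pos - 1L - flank; b <- pos + flank }
    else { a <- pos - flank; b <- pos + 1L + flank }
    if (a < 0L || b > len) { skipped <- skipped + 1L; next }
    sq <- strsplit(fetch_seq(genome, chrom, a, b, st), "")[[1]]
    hit <- match(sq, rownames(counts))
    ok <- !is.na(hit)
    counts[cbind(hit[ok], which(ok))] <- counts[cbind(hit[ok], which(ok))] + 1L
  }
  if (skipped)
    warnf("nucleotide_profile: skipped %d site(s) at contig edges", skipped)
  tot <- colSums(counts)
  sweep(counts, 2L, pmax(tot, 1L), "/")
}

#' Median poly(A)-tail lengths per group
#'
#' @param reads a `read_set`.
#' @param groups data.table mapping read_id to a `group` column (gene or
#'   transcript id).
#' @return data.table group, n_reads, median_tail; groups without tailed
#'   reads are omitted.
#' @export
summarize_tail_lengths <- function(reads, groups) {
  r <- as.data.table(reads)[has_polya == TRUE & !is.na(tail_length)]
  d <- merge(r[, .(read_id, tail_length)], as.data.table(groups),
             by = "read_id")
  out <- d[, .(n_reads = .N, median_tail = stats::median(as.numeric(tail_length))),
           by = group]
  setorder(out, group)
  out[]
}

#' Call 5' end pile-ups and flag TSS-database overlaps
#'
#' Reads are trimmed to their 5' terminus and counted in fixed,
#' non-overlapping `window`-nt genomic bins (anchored at coordinate 0)
#' per chromosome and strand. Bins with counts-per-million strictly above
#' `min_cpm` are retained and flagged when a database TSS lies within
#' `window` nt of the bin's modal 5' position.
#'
#' @param reads a `read_set` (the whole library: its size sets CPM).
#' @param window bin size and overlap window (nt).
#' @param min_cpm strict CPM cutoff.
#' @param tss_db site table with chrom, pos, strand.
#' @return data.table: chrom, strand, bin_start, peak_pos, count, cpm,
#'   tss_overlap.
#' @export
call_5prime_pileups <- function(reads, window = 50L, min_cpm = 30,
                                tss_db = NULL) {
  r <- as.data.table(reads)
  if (!nrow(r)) stopf("call_5prime_pileups: empty library")
  lib <- nrow(r)
  r[, bin := (five_prime %/% window) * window]
  pk <- r[, {
    tab <- tapply(rep(1L, .N), five_prime, sum)
    cand <- as.integer(names(tab)[tab == max(tab)])
    peak <- if (strand[1] == "+") min(cand) else max(cand)  # ties: 5'-most
    .(peak_pos = peak, count = .N)
  }, by = .(chrom, strand, bin)]
  pk[, cpm := 1e6 * count / lib]
  pk <- pk[cpm > min_cpm]
  pk[, tss_overlap := FALSE]
  if (!is.null(tss_db) && nrow(pk)) {
    ts <- as.data.table(tss_db)
    for (i in seq_len(nrow(pk))) {
      tp <- ts[chrom == pk$chrom[i] & strand == pk$strand[i], pos]
      if (length(tp))
        pk[i, tss_overlap := min(abs(tp - pk$peak_pos[i])) <= window]
    }
  }
  setnames(pk, "bin", "bin_start")
  setorder(pk, chrom, strand, bin_start)
  pk[]
}
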