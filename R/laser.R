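# LASER: TSS-exon and exon-PAS couplings from full-length junction chains.

#' Extract the junction chain of each read
#'
#' Junctions are the gaps between consecutive aligned blocks, keyed by
#' orientation-free genomic (donor, acceptor) pairs with donor <
#' acceptor. Single-block reads yield no junctions.
#'
#' @param reads a `read_set`.
#' @return data.table: read_id, chrom, strand, donor, acceptor, in
#'   genomic order per read.
#' @export
extract_junction_chain <- function(reads) {
  r <- as.data.table(reads)
  rows <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    bs <- r$block_starts[[i]]; be <- r$block_ends[[i]]
    if (length(bs) > 1L && any(bs[-1L] < be[-length(be)]))
      stopf("read '%s': overlapping blocks", r$read_id[i])
    if (length(bs) < 2L) next
    rows[[i]] <- data.table(read_id = r$read_id[i], chrom = r$chrom[i],
                            strand = r$strand[i],
                            donor = be[-length(be)], acceptor = bs[-1L])
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.table(read_id = character(), chrom = character(),
                      strand = character(), donor = integer(),
                      acceptor = integer()))
  rbindlist(rows)
}

#' Junction database excluding first/last-exon-dependent junctions
#'
#' From annotated transcript models, collects every exon junction and
#' excludes those whose flanking exon is an alternative first or last
#' exon: an exon is alternative-first when it is the strand-aware first
#' exon of at least one isoform of a gene with more than one distinct
#' first exon (alternative-last likewise).
#'
#' @param txs annotation (`tx_set`).
#' @return data.table: gene_id, chrom, strand, donor, acceptor, kept.
#' @export
junction_database <- function(txs) {
  ex <- copy(txs$exons)
  setorder(ex, transcript_id, start)
  ex[, rank := seq_len(.N), by = transcript_id]
  ex[, nex := .N, by = transcript_id]
  ex[, first := fifelse(strand == "+", rank == 1L, rank == nex)]
  ex[, last := fifelse(strand == "+", rank == nex, rank == 1L)]
  firsts <- unique(ex[first == TRUE, .(gene_id, start, end)])
  lasts <- unique(ex[last == TRUE, .(gene_id, start, end)])
  alt_first <- firsts[, .(alt = .N > 1L), by = gene_id]
  alt_last <- lasts[, .(alt = .N > 1L), by = gene_id]
  ex[alt_first, g_alt_first := i.alt, on = "gene_id"]
  ex[alt_last, g_alt_last := i.alt, on = "gene_id"]
  ex[, bad := (first & g_alt_first) | (last & g_alt_last)]
  jn <- ex[, if (.N > 1L) .(
    donor = end[-.N], acceptor = start[-1L],
    flank_bad = bad[-.N] | bad[-1L],
    gene_id = gene_id[1], chrom = chrom[1], strand = strand[1]),
    by = transcript_id]
  db <- jn[, .(kept = !any(flank_bad)),
           by = .(gene_id, chrom, strand, donor, acceptor)]
  setorder(db, gene_id, donor)
  db[]
}

#' Build TSS-junction or junction-PAS link matrices
#'
#' Counts, per gene, reads carrying each (TSS, junction) or
#' (junction, PAS) combination over kept database junctions. Genes are
#' retained only when their reads show more than one distinct junction
#' combination, and the same matrix filters as for coupling matrices
#' apply (at least two levels per axis, at least `min_isoforms` cells
#' with `min_reads_per_isoform` reads).
#'
#' @param assignments full-length assignments from
#'   [assign_full_length_reads()].
#' @param chains read junction chains from [extract_junction_chain()].
#' @param junction_db from [junction_database()]; only `kept` junctions
#'   are counted.
#' @param mode "tss-junction" or "junction-pas".
#' @param min_isoforms,min_reads_per_isoform cell-support filters.
#' @return `coupling_set`: rows = TSS ids (or junction keys), cols =
#'   junction keys (or PAS ids).
#' @export
build_link_matrices <- function(assignments, chains, junction_db,
                                mode = c("tss-junction", "junction-pas"),
                                min_isoforms = 2L, min_reads_per_isoform = 2L) {
  mode <- match.arg(mode)
  a <- as.data.table(assignments)[assigned == TRUE]
  jd <- as.data.table(junction_db)[kept == TRUE]
  ch <- as.data.table(chains)
  hits <- merge(ch, jd, by = c("chrom", "strand", "donor", "acceptor"))
  hits <- merge(hits, a[, .(read_id, gene_id, tss_id, pas_id)],
                by = c("read_id", "gene_id"))
  if (!nrow(hits)) return(structure(list(), class = "coupling_set"))
  hits[, junction := sprintf("%d-%d", donor, acceptor)]
  # distinct junction combinations per gene (chain over kept junctions)
  combos <- hits[, .(combo = paste(sort(junction), collapse = ";")),
                 by = .(gene_id, read_id)]
  multi <- combos[, .(n_combo = length(unique(combo))), by = gene_id][n_combo > 1L]
  hits <- hits[gene_id %in% multi$gene_id]
  out <- list()
  for (g in unique(hits$gene_id)) {
    hg <- hits[gene_id == g]
    cells <- if (mode == "tss-junction")
      hg[, .N, by = .(row = tss_id, col = junction)]
    else hg[, .N, by = .(row = junction, col = pas_id)]
    if (sum(cells$N >= min_reads_per_isoform) < min_isoforms) next
    rn <- sort(unique(cells$row)); cn <- sort(unique(cells$col))
    if (length(rn) < 2L || length(cn) < 2L) next
    m <- matrix(0L, length(rn), length(cn), dimnames = list(rn, cn))
    m[cbind(match(cells$row, rn), match(cells$col, cn))] <- cells$N
    out[[g]] <- m
  }
  structure(out, class = "coupling_set")
}

#' Test TSS-junction / junction-PAS links
#'
#' Same Monte-Carlo multinomial engine as the TSS-bias test. Per gene,
#' the linkage score is the sum of squared Pearson residuals over all
#' tested feature pairs (identically the chi-squared statistic;
#' conventionally displayed x 100), and pairs with absolute residual
#' strictly above `residual_bias_cut` are flagged biased.
#'
#' @param matrices a `coupling_set` from [build_link_matrices()].
#' @param B Monte-Carlo replicates.
#' @param alpha BH-adjusted cutoff for link significance.
#' @param seed RNG seed.
#' @param residual_bias_cut strict |residual| cutoff for biased pairs.
#' @param null null model, as in [test_tss_bias()].
#' @return data.table: gene_id, X2, p_mc, p_adj, significant,
#'   linkage_score, n_biased, biased_pairs (list-column of row/col/
#'   residual), residuals (list-column).
#' @export
test_feature_links <- function(matrices, B = 2000L, alpha = 0.1, seed = 1L,
                               residual_bias_cut = 0.7,
                               null = "fixed_margins") {
  tests <- test_tss_bias(matrices, B = B, alpha = alpha, seed = seed,
                         null = null)
  if (!nrow(tests))
    return(data.table(gene_id = character(), X2 = numeric(),
                      p_mc = numeric(), p_adj = numeric(),
                      significant = logical(), linkage_score = numeric(),
                      n_biased = integer(), biased_pairs = list(),
                      residuals = list()))
  tests[, linkage_score := vapply(residuals, function(r) sum(r^2), 0)]
  tests[, biased_pairs := lapply(residuals, function(r) {
    idx <- which(abs(r) > residual_bias_cut, arr.ind = TRUE)
    data.table(row = rownames(r)[idx[, 1]], col = colnames(r)[idx[, 2]],
               residual = r[idx])
  })]
  tests[, n_biased := vapply(biased_pairs, nrow, 0L)]
  setnames(tests, "biased", "significant")
  tests[, dominance_score := NULL]
  setcolorder(tests, c("gene_id", "X2", "p_mc", "p_adj", "significant",
                       "linkage_score", "n_biased", "biased_pairs",
                       "residuals"))
  tests[]
}
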