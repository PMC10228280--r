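# Post-assembly transcript curation: 3'-end filtering against the PAS
# database, 3'-end correction via 3'UTR bins, tolerance-based merging.

# gene spans from a reference annotation: min/max over its transcripts
reference_gene_spans <- function(reference) {
  reference$tx[, .(span_start = min(tx_start), span_end = max(tx_end)),
               by = .(gene_id, chrom, strand)]
}

#' Filter transcript 3' ends against the PAS database
#'
#' A transcript is retained iff its 3' end lies within `overlap` nt of a
#' database cluster (`retained_db_overlap`), or is strand-aware more
#' distal than every cluster of its gene while falling inside an
#' annotated transcript span on the same strand and carrying an AATAAA
#' signal in the upstream scan window
#' (`retained_distal_annotated_AATAAA`). Everything else is discarded;
#' transcripts of genes with zero database clusters are discarded and
#' counted separately.
#'
#' @param txs assembled transcripts (`tx_set`).
#' @param pas_db cluster table (chrom, strand, pos).
#' @param reference reference annotation (`tx_set`) defining gene spans.
#' @param genome DNAStringSet (for the AATAAA check).
#' @param overlap filter window (nt).
#' @param signal_window AATAAA scan window (nt).
#' @return list with `$kept` (tx_set) and `$report` (one row per input
#'   transcript: status, reason, correction_delta = 0).
#' @export
filter_3prime_ends <- function(txs, pas_db, reference, genome,
                               overlap = 100L, signal_window = 50L) {
  db <- as.data.table(pas_db)
  spans <- reference_gene_spans(reference)
  ref_tx <- reference$tx
  tx <- txs$tx
  status <- character(nrow(tx)); reason <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    tp <- tx$three_prime[i]
    cl <- db[chrom == tx$chrom[i] & strand == tx$strand[i], pos]
    if (length(cl) && min(abs(tp - cl)) <= overlap) {
      status[i] <- "retained_db_overlap"; reason[i] <- "db_overlap"
      next
    }
    gsp <- spans[gene_id == tx$gene_id[i] & strand == tx$strand[i]]
    gene_cl <- if (nrow(gsp))
      cl[cl >= gsp$span_start[1] - overlap & cl <= gsp$span_end[1] + overlap]
    else integer()
    if (!length(gene_cl)) {
      status[i] <- "discarded"; reason[i] <- "no_db_cluster"
      next
    }
    distal <- all(more_distal(tp, gene_cl, tx$strand[i]))
    in_ref <- any(ref_tx$strand == tx$strand[i] &
                  ref_tx$chrom == tx$chrom[i] &
                  ref_tx$tx_start <= tp & tp <= ref_tx$tx_end)
    has_sig <- FALSE
    if (distal && in_ref) {
      sc <- scan_polya_signals(data.table(chrom = tx$chrom[i], pos = tp,
                                          strand = tx$strand[i]),
                               genome, window = signal_window)
      has_sig <- sc$signal == "AATAAA"
    }
    if (distal && in_ref && has_sig) {
      status[i] <- "retained_distal_annotated_AATAAA"; reason[i] <- "distal_AATAAA"
    } else {
      status[i] <- "discarded"
      reason[i] <- if (!distal) "no_overlap" else if (!in_ref)
        "outside_reference" else "no_AATAAA"
    }
  }
  report <- data.table(transcript_id = tx$transcript_id,
                       gene_id = tx$gene_id, status = status, reason = reason,
                       correction_delta = 0L)
  keep_ids <- tx$transcript_id[status != "discarded"]
  kept <- new_tx_set(txs$exons[transcript_id %in% keep_ids])
  kept$tx[tx, orf_end := i.orf_end, on = "transcript_id"]
  list(kept = kept, report = report)
}

#' Correct transcript 3' ends using 3'UTR bins
#'
#' 3'UTR bins are the intervals between consecutive strand-ordered
#' database PASs from the ORF end to the distal-most PAS. An end strictly
#' inside the last bin is moved to the distal PAS when it covers more
#' than `cover_frac` of that bin, and to the bin's proximal PAS
#' otherwise. Ends elsewhere snap to a cluster within `overlap` nt
#' (nearest; no move across a non-adjacent PAS) and are otherwise left
#' unchanged. Single-PAS genes are snap-only.
#'
#' @param txs kept transcripts (`tx_set`) with `orf_end` on `$tx` (or
#'   supplied via `orf_ends`).
#' @param pas_db cluster table.
#' @param orf_ends optional data.table gene_id, orf_end overriding the
#'   annotation-derived ORF ends.
#' @param cover_frac last-bin coverage fraction (strict >).
#' @param overlap snap window (nt).
#' @return list with `$txs` (corrected tx_set) and `$deltas` (per
#'   transcript, sense-signed correction: positive = moved distal).
#' @export
correct_3prime_ends <- function(txs, pas_db, orf_ends = NULL,
                                cover_frac = 0.10, overlap = 100L) {
  db <- as.data.table(pas_db)
  tx <- copy(txs$tx)
  if (!is.null(orf_ends))
    tx[as.data.table(orf_ends), orf_end := i.orf_end, on = "gene_id"]
  new_tp <- tx$three_prime
  for (i in seq_len(nrow(tx))) {
    tp <- tx$three_prime[i]; st <- tx$strand[i]
    orf <- tx$orf_end[i]
    cl <- db[chrom == tx$chrom[i] & strand == st, pos]
    if (!is.na(orf)) {
      # clusters downstream of the ORF end, ordered proximal -> distal
      utr_cl <- cl[sense_dist(orf, cl, st) >= 0]
      utr_cl <- utr_cl[order(sense_dist(orf, utr_cl, st))]
    } else utr_cl <- integer()
    if (length(utr_cl) >= 2L) {
      n <- length(utr_cl)
      prox <- utr_cl[n - 1L]; dist_pas <- utr_cl[n]
      covered <- sense_dist(prox, tp, st)
      bin_len <- sense_dist(prox, dist_pas, st)
      if (covered > 0 && covered < bin_len) {
        new_tp[i] <- if (covered / bin_len > cover_frac) dist_pas else prox
        next
      }
    }
    if (length(cl) && min(abs(tp - cl)) <= overlap)
      new_tp[i] <- cl[which.min(abs(tp - cl))]
  }
  deltas <- data.table(transcript_id = tx$transcript_id,
                       gene_id = tx$gene_id,
                       delta = as.integer(sense_dist(tx$three_prime, new_tp,
                                                     tx$strand)))
  ex <- copy(txs$exons)
  setorder(ex, transcript_id, start)
  for (i in which(new_tp != tx$three_prime)) {
    tid <- tx$transcript_id[i]
    ix <- which(ex$transcript_id == tid)
    if (tx$strand[i] == "+") ex[ix[length(ix)], end := new_tp[i]]
    else ex[ix[1L], start := new_tp[i]]
  }
  out <- new_tx_set(ex)
  out$tx[tx, orf_end := i.orf_end, on = "transcript_id"]
  list(txs = out, deltas = deltas)
}

# union-find for transitive closure of the mergeable relation
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Merge isoforms by end/boundary tolerances (transitive closure)
#'
#' Two isoforms of the same gene and strand are mergeable iff they have
#' the same junction count, every corresponding internal boundary differs
#' by less than `tol_exon` nt, 5' termini by less than `tol_5p` nt and
#' 3' termini by less than `tol_3p` nt (all strict). Groups are connected
#' components of the pairwise mergeable relation; the representative is
#' the member with the highest read support (ties: longest span, then
#' lexicographic id).
#'
#' @param txs `tx_set`.
#' @param tol_3p,tol_5p,tol_exon tolerances (nt).
#' @param support optional named vector transcript_id -> read support
#'   (default 1 each).
#' @return list with `$txs` (representative models) and `$members`
#'   (data.table rep_id, member_id).
#' @export
merge_isoforms <- function(txs, tol_3p = 150L, tol_5p = 50L, tol_exon = 10L,
                           support = NULL) {
  tx <- txs$tx
  jn <- tx_junctions(txs)
  jlist <- split(jn[, .(donor, acceptor)], jn$transcript_id)
  sup <- stats::setNames(rep(1, nrow(tx)), tx$transcript_id)
  if (!is.null(support)) sup[names(support)] <- support
  members <- vector("list", 0L)
  for (key in unique(paste(tx$gene_id, tx$strand))) {
    g <- tx[paste(gene_id, strand) == key]
    n <- nrow(g)
    parent <- seq_len(n)
    jns <- lapply(g$transcript_id, function(id)
      jlist[[id]] %||% data.table(donor = integer(), acceptor = integer()))
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (b <= a) next
      ja <- jns[[a]]; jb <- jns[[b]]
      if (nrow(ja) != nrow(jb)) next
      if (nrow(ja) && (any(abs(ja$donor - jb$donor) >= tol_exon) ||
                       any(abs(ja$acceptor - jb$acceptor) >= tol_exon))) next
      if (abs(g$five_prime[a] - g$five_prime[b]) >= tol_5p) next
      if (abs(g$three_prime[a] - g$three_prime[b]) >= tol_3p) next
      ra <- uf_find(parent, a); rb <- uf_find(parent, b)
      if (ra != rb) parent[rb] <- ra
    }
    comp <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
    for (cid in unique(comp)) {
      ix <- which(comp == cid)
      s <- sup[g$transcript_id[ix]]
      len <- g$tx_end[ix] - g$tx_start[ix]
      o <- order(-s, -len, g$transcript_id[ix])
      rep_id <- g$transcript_id[ix][o[1L]]
      members[[length(members) + 1L]] <-
        data.table(rep_id = rep_id, member_id = g$transcript_id[ix])
    }
  }
  mem <- rbindlist(members)
  merged <- new_tx_set(txs$exons[transcript_id %in% mem$rep_id])
  merged$tx[tx, orf_end := i.orf_end, on = "transcript_id"]
  list(txs = merged, members = mem[])
}
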