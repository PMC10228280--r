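# LATER: quantify 5'-3' isoforms from full-length reads, test per-gene
# TSS bias by Monte-Carlo chi-squared, call dominant promoters.

#' Annotate PAS clusters with gene and site ids
#'
#' Assigns each cluster to the gene whose annotated span (same strand)
#' contains its position; clusters matching zero or several genes are
#' dropped with a message. Site ids are `pas1..pasN` in proximal-to-
#' distal (sense) order per gene.
#'
#' @param clusters table with chrom, strand, pos, support.
#' @param txs annotation (`tx_set`).
#' @return site table: chrom, pos, strand, gene_id, site_id, support.
#' @export
annotate_clusters <- function(clusters, txs) {
  cl <- as.data.table(clusters)
  spans <- txs$tx[, .(span_start = min(tx_start), span_end = max(tx_end)),
                  by = .(gene_id, chrom, strand)]
  gene <- character(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    hit <- spans[chrom == cl$chrom[i] & strand == cl$strand[i] &
                 span_start <= cl$pos[i] & cl$pos[i] <= span_end, gene_id]
    gene[i] <- if (length(hit) == 1L) hit else NA_character_
  }
  n_bad <- sum(is.na(gene))
  if (n_bad)
    message(sprintf("annotate_clusters: dropped %d cluster(s) matching 0 or >1 genes",
                    n_bad))
  out <- cl[!is.na(gene)]
  out[, gene_id := gene[!is.na(gene)]]
  out[, sense_pos := fifelse(strand == "+", as.numeric(pos), -as.numeric(pos))]
  setorder(out, gene_id, sense_pos)
  out[, site_id := sprintf("pas%d", seq_len(.N)), by = gene_id]
  out[, sense_pos := NULL]
  if (!"support" %in% names(out)) out[, support := 1L]
  out[, .(chrom, pos, strand, gene_id, site_id, support)]
}

# vectorized nearest-site matching with strand-aware tie-breaking:
# tie = "five": 5'-most (+: smaller pos; -: larger); tie = "three": 3'-most.
# Returns, per read row, the matching row index into `sites` or NA.
match_nearest_site <- function(r, sites, col, window, tie) {
  out <- rep(NA_integer_, nrow(r))
  groups <- unique(sites[, .(chrom, strand)])
  for (k in seq_len(nrow(groups))) {
    ch <- groups$chrom[k]; st <- groups$strand[k]
    sidx <- which(sites$chrom == ch & sites$strand == st)
    o <- order(sites$pos[sidx])
    sidx <- sidx[o]
    spos <- sites$pos[sidx]
    sel <- which(r$chrom == ch & r$strand == st)
    if (!length(sel)) next
    q <- r[[col]][sel]
    i <- findInterval(q, spos)
    n <- length(spos)
    d_lo <- rep(Inf, length(q)); d_hi <- rep(Inf, length(q))
    w <- i >= 1L; d_lo[w] <- q[w] - spos[i[w]]
    w <- i < n;  d_hi[w] <- spos[i[w] + 1L] - q[w]
    prefer_hi <- (tie == "three") == (st == "+")
    pick_hi <- (d_hi < d_lo) | (d_hi == d_lo & prefer_hi)
    loc <- ifelse(pick_hi, i + 1L, i)
    dist <- pmin(d_lo, d_hi)
    ok <- is.finite(dist) & dist <= window
    out[sel[ok]] <- sidx[loc[ok]]
  }
  out
}

#' Assign reads to TSS and PAS databases (full-length calling)
#'
#' A read is full-length iff a database TSS lies within `tss_window` nt
#' of its 5' terminus and a database PAS within `pas_window` nt of its 3'
#' terminus, on the read's strand. Among several qualifying sites the
#' nearest wins; exact distance ties go to the 5'-most TSS and the
#' 3'-most PAS. Reads whose matched TSS and PAS belong to different
#' genes are left unassigned (reason `gene_conflict`).
#'
#' @param reads a `read_set`.
#' @param tss_db,pas_db site tables with chrom, pos, strand, gene_id,
#'   site_id.
#' @param tss_window,pas_window assignment windows (nt).
#' @return data.table: read_id, assigned, gene_id, tss_id, pas_id,
#'   tss_pos, pas_pos, reason.
#' @export
assign_full_length_reads <- function(reads, tss_db, pas_db,
                                     tss_window = 50L, pas_window = 150L) {
  r <- as.data.table(reads)
  ts <- as.data.table(tss_db)
  ps <- as.data.table(pas_db)
  ti <- match_nearest_site(r, ts, "five_prime", tss_window, tie = "five")
  pi <- match_nearest_site(r, ps, "three_prime", pas_window, tie = "three")
  n <- nrow(r)
  gene <- tss <- pas <- reason <- rep(NA_character_, n)
  tpos <- ppos <- rep(NA_integer_, n)
  both <- !is.na(ti) & !is.na(pi)
  same <- both & ts$gene_id[ti] == ps$gene_id[pi]
  gene[same] <- ts$gene_id[ti[same]]
  tss[same] <- ts$site_id[ti[same]]; pas[same] <- ps$site_id[pi[same]]
  tpos[same] <- ts$pos[ti[same]]; ppos[same] <- ps$pos[pi[same]]
  reason[both & !same] <- "gene_conflict"
  reason[is.na(ti) & is.na(pi)] <- "no_site"
  reason[is.na(ti) & !is.na(pi)] <- "no_tss"
  reason[!is.na(ti) & is.na(pi)] <- "no_pas"
  data.table(read_id = r$read_id, assigned = !is.na(gene), gene_id = gene,
             tss_id = tss, pas_id = pas, tss_pos = tpos, pas_pos = ppos,
             reason = reason)
}

#' Build per-gene TSS x PAS coupling matrices
#'
#' Counts full-length reads per (TSS, PAS) isoform. Cells whose
#' representative transcript span (|TSS - PAS|) exceeds `max_tx_len` are
#' excluded; genes are kept only if their expression exceeds
#' `tpm_cutoff` (TPM over assigned full-length reads), they have at
#' least `min_isoforms` isoforms with at least `min_reads_per_isoform`
#' reads each, and the resulting matrix has at least two TSS rows and
#' two PAS columns.
#'
#' @param assignments from [assign_full_length_reads()].
#' @param min_isoforms,min_reads_per_isoform,max_tx_len,tpm_cutoff gene
#'   filters.
#' @return named list of integer matrices (rows = TSS ids, cols = PAS
#'   ids), class `coupling_set`.
#' @export
build_coupling_matrices <- function(assignments, min_isoforms = 2L,
                                    min_reads_per_isoform = 2L,
                                    max_tx_len = 10000L, tpm_cutoff = 2) {
  a <- as.data.table(assignments)[assigned == TRUE]
  if (!nrow(a)) return(structure(list(), class = "coupling_set"))
  total <- nrow(a)
  cells <- a[, .N, by = .(gene_id, tss_id, pas_id, tss_pos, pas_pos)]
  cells <- cells[abs(tss_pos - pas_pos) <= max_tx_len]
  gtpm <- cells[, .(tpm = 1e6 * sum(N) / total), by = gene_id]
  cells <- cells[gtpm[tpm > tpm_cutoff], on = "gene_id", nomatch = NULL]
  out <- list()
  for (g in unique(cells$gene_id)) {
    cg <- cells[gene_id == g]
    if (sum(cg$N >= min_reads_per_isoform) < min_isoforms) next
    rn <- sort(unique(cg$tss_id)); cn <- sort(unique(cg$pas_id))
    if (length(rn) < 2L || length(cn) < 2L) next
    m <- matrix(0L, length(rn), length(cn), dimnames = list(rn, cn))
    m[cbind(match(cg$tss_id, rn), match(cg$pas_id, cn))] <- cg$N
    out[[g]] <- m
  }
  structure(out, class = "coupling_set")
}

chisq_stat <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

pearson_residuals <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  (m - E) / sqrt(E)
}

# Monte-Carlo chi-squared p for one table; null with both margins fixed
# (Patefield sampler) or multinomial from the expected cell probabilities
mc_chisq_p <- function(m, B, null = c("fixed_margins", "multinomial")) {
  null <- match.arg(null)
  obs <- chisq_stat(m)
  N <- sum(m)
  sims <- if (null == "fixed_margins") {
    stats::r2dtable(B, rowSums(m), colSums(m))
  } else {
    E <- outer(rowSums(m), colSums(m)) / N
    pr <- as.vector(E) / N
    draws <- stats::rmultinom(B, N, pr)
    lapply(seq_len(B), function(b) matrix(draws[, b], nrow(m), ncol(m)))
  }
  x2 <- vapply(sims, chisq_stat, 0)
  (1 + sum(x2 >= obs)) / (B + 1)
}

#' Monte-Carlo chi-squared TSS-bias test per gene
#'
#' Each gene's coupling matrix is tested against independence of TSS and
#' PAS usage. Null tables are sampled uniformly with both margins fixed
#' (Patefield algorithm; a multinomial alternative is available), the
#' p-value estimate is (1 + #\{X2_sim >= X2_obs\}) / (B + 1), and
#' Benjamini-Hochberg correction is applied across genes. Rows or
#' columns with a zero margin are dropped with a warning before testing.
#'
#' @param matrices a `coupling_set`.
#' @param B Monte-Carlo replicates.
#' @param alpha BH-adjusted significance cutoff for the bias call.
#' @param seed RNG seed.
#' @param null null model: "fixed_margins" (default) or "multinomial".
#' @return data.table: gene_id, X2, p_mc, p_adj, biased,
#'   dominance_score (max |Pearson residual|), residuals (list-column).
#' @export
test_tss_bias <- function(matrices, B = 2000L, alpha = 0.1, seed = 1L,
                          null = "fixed_margins") {
  set.seed(seed)
  genes <- names(matrices)
  rows <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    m <- matrices[[k]]
    zr <- rowSums(m) == 0; zc <- colSums(m) == 0
    if (any(zr) || any(zc)) {
      warnf("gene %s: dropping %d zero-margin row(s)/col(s)", genes[k],
            sum(zr) + sum(zc))
      m <- m[!zr, !zc, drop = FALSE]
    }
    if (nrow(m) < 2L || ncol(m) < 2L) next
    r <- pearson_residuals(m)
    rows[[k]] <- data.table(gene_id = genes[k], X2 = chisq_stat(m),
                            p_mc = mc_chisq_p(m, B, null),
                            dominance_score = max(abs(r)),
                            residuals = list(r))
  }
  out <- rbindlist(rows[!vapply(rows, is.null, TRUE)])
  if (!nrow(out))
    return(data.table(gene_id = character(), X2 = numeric(),
                      p_mc = numeric(), p_adj = numeric(),
                      biased = logical(), dominance_score = numeric(),
                      residuals = list()))
  out[, p_adj := stats::p.adjust(p_mc, method = "BH")]
  out[, biased := p_adj < alpha]
  setcolorder(out, c("gene_id", "X2", "p_mc", "p_adj", "biased",
                     "dominance_score", "residuals"))
  out[]
}

#' Call dominant promoters from bias tests and coupling matrices
#'
#' For every cell (i, j): TSS contribution = O_ij / column j total, PAS
#' contribution = O_ij / row i total. The cell is a dominant
#' (TSS, PAS) pair iff the gene is transcriptionally biased
#' (`p_adj < alpha`), TSS contribution exceeds `tss_contrib_min` and PAS
#' contribution exceeds `pas_contrib_min` (both strict). All cells are
#' reported with their contributions regardless of the call.
#'
#' @param tests from [test_tss_bias()].
#' @param matrices the tested `coupling_set`.
#' @param tss_contrib_min,pas_contrib_min strict contribution cutoffs.
#' @param alpha adjusted p-value cutoff.
#' @return data.table: gene_id, tss_id, pas_id, count, tss_contribution,
#'   pas_contribution, p_adj, is_dominant.
#' @export
call_promoter_dominance <- function(tests, matrices, tss_contrib_min = 0.20,
                                    pas_contrib_min = 0.60, alpha = 0.1) {
  rows <- vector("list", nrow(tests))
  for (k in seq_len(nrow(tests))) {
    g <- tests$gene_id[k]
    m <- matrices[[g]]
    tc <- sweep(m, 2L, colSums(m), "/")
    pc <- sweep(m, 1L, rowSums(m), "/")
    idx <- which(m >= 0, arr.ind = TRUE)
    rows[[k]] <- data.table(
      gene_id = g, tss_id = rownames(m)[idx[, 1]],
      pas_id = colnames(m)[idx[, 2]], count = m[idx],
      tss_contribution = tc[idx], pas_contribution = pc[idx],
      p_adj = tests$p_adj[k],
      is_dominant = tests$p_adj[k] < alpha & tc[idx] > tss_contrib_min &
        pc[idx] > pas_contrib_min)
  }
  out <- rbindlist(rows)
  setorder(out, gene_id, tss_id, pas_id)
  out[]
}

#' Subsample reads reproducibly
#'
#' Exact sample of floor(fraction * n) reads without replacement,
#' preserving input order.
#'
#' @param reads a `read_set`.
#' @param fraction in (0, 1].
#' @param seed RNG seed.
#' @return a `read_set` subset.
#' @export
subsample_reads <- function(reads, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  n <- nrow(reads)
  k <- floor(fraction * n)
  set.seed(seed)
  idx <- sort(sample.int(n, k))
  out <- as.data.table(reads)[idx]
  structure(out, class = c("read_set", class(out)))
}
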