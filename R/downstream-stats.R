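# Downstream APA statistics: diversity indices, proximal/distal PAS
# classification, poly(A)-signal skipping contingency analysis.

#' Shannon and Simpson diversity of isoform usage
#'
#' With p_i the category proportions per gene: Shannon H = -sum p_i ln p_i
#' (natural log) and Simpson D = 1 - sum p_i^2, computed with
#' `vegan::diversity()`. All-zero genes are excluded with a warning.
#'
#' @param counts categories x genes matrix of nonnegative counts.
#' @return data.table: gene (column name), shannon, simpson.
#' @export
diversity_indices <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("g%d", seq_len(ncol(counts)))
  if (any(counts < 0)) stopf("counts must be nonnegative")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    warnf("diversity_indices: excluding %d all-zero gene(s)", sum(zero))
    counts <- counts[, !zero, drop = FALSE]
  }
  data.table(gene = colnames(counts),
             shannon = as.numeric(vegan::diversity(t(counts), index = "shannon")),
             simpson = as.numeric(vegan::diversity(t(counts), index = "simpson")))
}

#' Classify PASs as proximal or distal along the 3'UTR
#'
#' The 3'UTR span runs strand-aware from the ORF end to the distal-most
#' PAS of the gene. A PAS with relative position <= `proximal_frac` is
#' proximal (boundary inclusive). Genes whose span is zero (single PAS
#' at the ORF end) are flagged degenerate with `NA` class and a warning.
#'
#' @param pas site table: gene_id, pas_id, pos, strand.
#' @param orf_ends data.table: gene_id, orf_end.
#' @param proximal_frac proximal cutoff on relative position.
#' @return data.table: gene_id, pas_id, rel_pos, class, degenerate.
#' @export
classify_pas_position <- function(pas, orf_ends, proximal_frac = 0.20) {
  p <- merge(as.data.table(pas), as.data.table(orf_ends), by = "gene_id")
  p[, sdist := sense_dist(orf_end, pos, strand)]
  p[, span := max(sdist), by = gene_id]
  p[, degenerate := span <= 0]
  if (any(p$degenerate))
    warnf("classify_pas_position: %d degenerate gene(s) with zero 3'UTR span",
          length(unique(p$gene_id[p$degenerate])))
  p[, rel_pos := fifelse(degenerate, NA_real_, sdist / span)]
  p[, class := fifelse(degenerate, NA_character_,
                       fifelse(rel_pos <= proximal_frac, "proximal", "distal"))]
  out <- p[, .(gene_id, pas_id, rel_pos, class, degenerate)]
  setorder(out, gene_id, pas_id)
  out[]
}

#' Two-sided Fisher exact p for a 2x2 table (hypergeometric enumeration)
#'
#' Sums, over all tables with the observed margins, the probabilities of
#' tables no more probable than the observed one (with the customary
#' 1 + 1e-7 relative slack). Any zero margin yields `NA`.
#'
#' @param tab 2x2 integer matrix.
#' @return p-value or NA.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) return(NA_real_)
  x <- max(0L, cs[1] - rs[2]):min(rs[1], cs[1])
  d <- stats::dhyper(x, rs[1], rs[2], cs[1])
  d_obs <- stats::dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  sum(d[d <= d_obs * (1 + 1e-7)])
}

#' Poly(A)-signal skipping contingency analysis
#'
#' Per gene group (e.g. single-promoter APA genes vs dominant-promoter
#' ATSS-APA genes), builds the 2x2 table of proximal vs distal PAS usage
#' stratified by the signal found within the scan window of the gene's
#' most proximal PAS (canonical AATAAA vs none; genes with another
#' hexamer are excluded), and tests association with a two-sided Fisher
#' exact test. `usage = "reads"` sums read counts; `usage = "pas"`
#' counts genes contributing any usage in the category.
#'
#' @param genes data.table with columns gene_id, group, signal (from
#'   [scan_polya_signal()] at the most proximal PAS), n_proximal,
#'   n_distal (read counts at proximal / distal PASs).
#' @param usage counting mode.
#' @return data.table: group, and the four cell counts
#'   (aataaa_proximal, aataaa_distal, none_proximal, none_distal), p.
#' @export
pas_skipping_table <- function(genes, usage = c("reads", "pas")) {
  usage <- match.arg(usage)
  empty <- data.table(group = character(), aataaa_proximal = integer(),
                      aataaa_distal = integer(), none_proximal = integer(),
                      none_distal = integer(), p = numeric())
  if (!nrow(as.data.table(genes))) return(empty)
  g <- as.data.table(genes)[signal %in% c("AATAAA", "none")]
  groups <- sort(unique(as.data.table(genes)$group))
  rows <- lapply(groups, function(gr) {
    d <- g[group == gr]
    val <- function(sig, col) {
      v <- d[signal == sig][[col]]
      if (usage == "reads") sum(v) else sum(v > 0)
    }
    tab <- matrix(c(val("AATAAA", "n_proximal"), val("AATAAA", "n_distal"),
                    val("none", "n_proximal"), val("none", "n_distal")),
                  2L, 2L, byrow = TRUE)
    data.table(group = gr,
               aataaa_proximal = tab[1, 1], aataaa_distal = tab[1, 2],
               none_proximal = tab[2, 1], none_distal = tab[2, 2],
               p = fisher_exact_2x2(tab))
  })
  rbindlist(rows)
}
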