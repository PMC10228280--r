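# Promoter-3'UTR co-evolution: MSA refinement, mutual information with
# average product correction, peak-based region scores, classification.

msa_to_matrix <- function(msa) {
  if (is.matrix(msa)) return(toupper(msa))
  seqs <- as.character(msa)
  if (length(unique(nchar(seqs))) != 1L)
    stopf("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(msa) %||% sprintf("row%d", seq_along(seqs))
  m
}

#' Refine a multiple sequence alignment
#'
#' Drops rows with non-gap occupancy below `row_occ`, then greedily
#' deduplicates: scanning rows in input order (reference first), a row
#' is dropped when its identity to an already-kept row exceeds
#' `max_ident` (identity computed over mutually non-gap columns). The
#' reference row is never dropped; a reference below the occupancy
#' cutoff is an error.
#'
#' @param msa DNAStringSet or character matrix (rows = species).
#' @param row_occ minimum non-gap fraction per kept row.
#' @param max_ident strict identity cutoff for deduplication.
#' @param reference index or name of the reference row.
#' @return object of class `refined_msa`: list with `$mat` (character
#'   matrix, reference first), `$col_map` (0-based reference coordinate
#'   per column; NA where the reference is gapped).
#' @export
refine_msa <- function(msa, row_occ = 0.4, max_ident = 0.98, reference = 1L) {
  m <- msa_to_matrix(msa)
  if (is.character(reference)) reference <- match(reference, rownames(m))
  if (is.na(reference) || reference < 1L || reference > nrow(m))
    stopf("reference row not found")
  nongap <- m != "-"
  occ <- rowMeans(nongap)
  if (occ[reference] < row_occ)
    stopf("reference row occupancy %.2f below cutoff %.2f",
          occ[reference], row_occ)
  ord <- c(reference, setdiff(seq_len(nrow(m)), reference))
  ord <- ord[occ[ord] >= row_occ]
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      both <- nongap[i, ] & nongap[j, ]
      if (!any(both)) next
      if (mean(m[i, both] == m[j, both]) > max_ident) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  out <- m[kept, , drop = FALSE]
  refgaps <- out[1L, ] == "-"
  col_map <- cumsum(!refgaps) - 1L
  col_map[refgaps] <- NA_integer_
  structure(list(mat = out, col_map = col_map), class = "refined_msa")
}

#' Mutual information map with average product correction
#'
#' Pairwise MI (base 2) between alignment columns over the 4-letter
#' alphabet, computed on pairwise-complete rows (both columns non-gap;
#' non-ACGT characters count as gaps). Column pairs with fewer than 3
#' complete rows score 0. The APC correction
#' MIc(i,j) = MI(i,j) - mean_i * mean_j / grand_mean (means excluding
#' the diagonal) is subtracted and negative values floored at 0.
#'
#' @param rmsa a `refined_msa` (or object coercible via [refine_msa()]
#'   inputs).
#' @return object of class `coevolution_map`: list with `$mi`, `$mic`
#'   (L x L symmetric matrices) and `$col_map`.
#' @export
mi_apc_map <- function(rmsa) {
  if (!inherits(rmsa, "refined_msa"))
    stopf("mi_apc_map expects a refined_msa; call refine_msa() first")
  m <- rmsa$mat
  if (nrow(m) < 3L) stopf("need >= 3 rows after refinement")
  L <- ncol(m)
  alpha <- c("A", "C", "G", "T")
  Ind <- lapply(alpha, function(a) (m == a) * 1)
  G <- Reduce(`+`, Ind)          # non-gap indicator
  Np <- crossprod(G)             # pairwise-complete row counts
  MI <- matrix(0, L, L)
  for (a in seq_along(alpha)) {
    Ma <- crossprod(Ind[[a]], G) # rows with col_i == a and col_j non-gap
    for (b in seq_along(alpha)) {
      Mb <- crossprod(G, Ind[[b]])
      nab <- crossprod(Ind[[a]], Ind[[b]])
      term <- nab / Np * log2((nab * Np) / (Ma * Mb))
      term[!is.finite(term) | nab == 0] <- 0
      MI <- MI + term
    }
  }
  MI[Np < 3L] <- 0
  diag(MI) <- 0
  # average product correction with diagonal-free means
  rm_i <- rowSums(MI) / (L - 1L)
  grand <- sum(MI) / (L * (L - 1L))
  MIc <- if (grand > 0) MI - outer(rm_i, rm_i) / grand else MI * 0
  MIc[MIc < 0] <- 0
  diag(MIc) <- 0
  structure(list(mi = MI, mic = MIc, col_map = rmsa$col_map),
            class = "coevolution_map")
}

#' 1-D peak finding on a score profile
#'
#' A peak is a local maximum with height >= `min_height` whose base span
#' (distance between the flanking local minima) is >= `min_width`;
#' plateau maxima are counted once at their first position. Peaks closer
#' than `min_distance` positions are merged keeping the higher.
#'
#' @param x numeric profile.
#' @param min_height,min_distance,min_width peak constraints.
#' @return data.table: pos (1-based), height.
#' @export
find_peaks <- function(x, min_height = 0.2, min_distance = 2L,
                       min_width = 2L) {
  n <- length(x)
  empty <- data.table(pos = integer(), height = numeric())
  if (n == 0L) return(empty)
  r <- rle(x)
  k <- length(r$values)
  run_start <- cumsum(c(1L, r$lengths[-k]))
  peaks <- list()
  for (i in seq_len(k)) {
    v <- r$values[i]
    up <- i == 1L || r$values[i - 1L] < v
    down <- i == k || r$values[i + 1L] < v
    if (!(up && down)) next
    if (v < min_height) next
    # base span: from the flanking local minima (monotone descent ends)
    j <- i
    while (j > 1L && r$values[j - 1L] < r$values[j]) j <- j - 1L
    left_base <- run_start[j]
    j <- i
    while (j < k && r$values[j + 1L] < r$values[j]) j <- j + 1L
    right_base <- run_start[j] + r$lengths[j] - 1L
    width <- right_base - left_base
    if (r$lengths[i] > 1L) width <- max(width, r$lengths[i])  # plateau
    if (width < min_width) next
    peaks[[length(peaks) + 1L]] <- data.table(pos = run_start[i], height = v)
  }
  if (!length(peaks)) return(empty)
  pk <- rbindlist(peaks)
  setorder(pk, pos)
  repeat {
    gaps <- diff(pk$pos)
    close <- which(gaps < min_distance)
    if (!length(close)) break
    i <- close[1L]
    drop <- if (pk$height[i] >= pk$height[i + 1L]) i + 1L else i
    pk <- pk[-drop]
  }
  pk[]
}

#' Score promoter-3'UTR co-evolution per TSS region
#'
#' For each TSS region, builds the 3'UTR profile
#' profile\[k\] = max over TSS-region columns of corrected MI against
#' UTR column k, runs 1-D peak finding and reports the sum of peak
#' heights. Regions are given in reference coordinates and mapped to
#' alignment columns via the refinement coordinate map.
#'
#' @param map a `coevolution_map`.
#' @param tss_regions named list of reference-coordinate ranges
#'   `c(start, end)` (0-based half-open), one per TSS.
#' @param utr_region reference-coordinate range of the 3'UTR.
#' @param min_height,min_distance,min_width peak parameters.
#' @return list with `$scores` (data.table region, score, n_peaks) and
#'   `$profiles` (named list of UTR profiles).
#' @export
score_region_coevolution <- function(map, tss_regions, utr_region,
                                     min_height = 0.2, min_distance = 2L,
                                     min_width = 2L) {
  cols_of <- function(range, label) {
    cols <- which(!is.na(map$col_map) & map$col_map >= range[1] &
                  map$col_map < range[2])
    if (!length(cols)) stopf("region '%s' outside the alignment", label)
    cols
  }
  utr_cols <- cols_of(utr_region, "utr")
  profiles <- list()
  rows <- lapply(names(tss_regions), function(nm) {
    tss_cols <- cols_of(tss_regions[[nm]], nm)
    prof <- apply(map$mic[tss_cols, utr_cols, drop = FALSE], 2L, max)
    profiles[[nm]] <<- prof
    pk <- find_peaks(prof, min_height, min_distance, min_width)
    data.table(region = nm, score = sum(pk$height), n_peaks = nrow(pk))
  })
  list(scores = rbindlist(rows), profiles = profiles)
}

#' Classify TSSs and genes as co-evolving
#'
#' A TSS is co-evolving iff its score is at or above the
#' (1 - `percentile`) quantile of all TSS scores in the dataset (the
#' median for the default 0.50); a gene is co-evolving iff at least one
#' of its TSSs is.
#'
#' @param scores data.table with gene_id, tss_id, score.
#' @param percentile top fraction called co-evolving.
#' @return list with `$tss` (scores plus `coevolving`), `$genes`
#'   (gene_id, coevolving) and `$threshold`.
#' @export
classify_coevolution <- function(scores, percentile = 0.50) {
  s <- as.data.table(scores)
  if (nrow(s) < 2L) stopf("classify_coevolution: need >= 2 TSS scores")
  thr <- as.numeric(stats::quantile(s$score, 1 - percentile, names = FALSE))
  s[, coevolving := score >= thr]
  genes <- s[, .(coevolving = any(coevolving)), by = gene_id]
  list(tss = s[], genes = genes[], threshold = thr)
}
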