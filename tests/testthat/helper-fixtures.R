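# Shared fixtures and independent oracles used across the suite.

library(data.table)

# --- fixture builders -------------------------------------------------------

# read_set from a list of block matrices (2-col: start, end per block)
make_reads <- function(blocks, strand = "+", chrom = "chr1",
                       has_polya = TRUE, tail_length = 50L,
                       ids = NULL) {
  n <- length(blocks)
  ids <- ids %||% sprintf("r%03d", seq_len(n))
  strand <- rep_len(strand, n)
  hp <- rep_len(has_polya, n)
  tl <- rep_len(tail_length, n)
  rs <- data.table(
    read_id = ids, chrom = rep_len(chrom, n), strand = strand,
    start = vapply(blocks, function(b) as.integer(min(b[, 1])), 0L),
    end = vapply(blocks, function(b) as.integer(max(b[, 2])), 0L),
    n_blocks = vapply(blocks, nrow, 0L))
  rs[, block_starts := lapply(blocks, function(b) as.integer(b[, 1]))]
  rs[, block_ends := lapply(blocks, function(b) as.integer(b[, 2]))]
  rs[, five_prime := fifelse(strand == "+", start, end)]
  rs[, three_prime := fifelse(strand == "+", end, start)]
  rs[, has_polya := hp]
  rs[, tail_length := fifelse(hp, as.integer(tl), NA_integer_)]
  structure(rs, class = c("read_set", class(rs)))
}

# single-position reads (one block of given width ending at pos for +)
make_end_reads <- function(pos, strand = "+", chrom = "chr1", width = 200L,
                           has_polya = TRUE) {
  blocks <- lapply(pos, function(p) {
    if (strand == "+") cbind(p - width, p) else cbind(p, p + width)
  })
  make_reads(blocks, strand = strand, chrom = chrom, has_polya = has_polya)
}

# tx_set from per-transcript exon matrices
make_txs <- function(exon_list, gene_ids = NULL, strand = "+",
                     chrom = "chr1") {
  ids <- names(exon_list) %||% sprintf("t%02d", seq_along(exon_list))
  gene_ids <- gene_ids %||% rep("g1", length(exon_list))
  strand <- rep_len(strand, length(exon_list))
  ex <- rbindlist(lapply(seq_along(exon_list), function(i)
    data.table(transcript_id = ids[i], gene_id = gene_ids[i],
               chrom = chrom, strand = strand[i],
               start = as.integer(exon_list[[i]][, 1]),
               end = as.integer(exon_list[[i]][, 2]))))
  isocoupler:::new_tx_set(ex)
}

make_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles ----------------------------------------------------

# brute-force single-linkage clustering: all-pairs chaining on positions
oracle_linkage <- function(pos, window) {
  n <- length(pos)
  if (!n) return(list())
  adj <- abs(outer(pos, pos, "-")) <= window
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(pos, comp), sort))
}

# connected components of an undirected adjacency matrix (merge oracle)
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# exact P(X2 >= observed) under the uniform fixed-margin null, by full
# enumeration of contingency tables with the observed margins
oracle_exact_fixed_margin_p <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  obs <- oracle_chisq(m)
  logconst <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  ptot <- 0
  enumerate <- function(row, remaining_cs, acc) {
    if (row > length(rs)) {
      tab <- do.call(rbind, acc)
      p <- exp(logconst - sum(lfactorial(tab)))
      if (oracle_chisq(tab) >= obs - 1e-9) ptot <<- ptot + p
      return(invisible())
    }
    fill_row <- function(col, left, cur) {
      if (col == length(cs)) {
        if (left <= remaining_cs[col])
          enumerate(row + 1L, remaining_cs - c(cur, left),
                    c(acc, list(c(cur, left))))
        return(invisible())
      }
      for (v in 0:min(left, remaining_cs[col]))
        fill_row(col + 1L, left - v, c(cur, v))
    }
    fill_row(1L, rs[row], integer(0))
    invisible()
  }
  enumerate(1L, cs, list())
  min(ptot, 1)
}

oracle_chisq <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# mutual information of two columns by direct summation over the joint
oracle_mi <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(0)
  jt <- table(x, y) / length(x)
  px <- rowSums(jt); py <- colSums(jt)
  s <- 0
  for (a in rownames(jt)) for (b in colnames(jt)) {
    p <- jt[a, b]
    if (p > 0) s <- s + p * log2(p / (px[a] * py[b]))
  }
  as.numeric(s)
}

# random contingency table with all margins <= max_margin and no zero margin
random_small_table <- function(nr, nc, max_cell = 3L) {
  repeat {
    m <- matrix(sample(0:max_cell, nr * nc, replace = TRUE), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0) &&
        all(rowSums(m) <= 12) && all(colSums(m) <= 12))
      return(m)
  }
}
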