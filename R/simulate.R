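# Synthetic data generator: multi-TSS / multi-PAS gene models, full-length
# reads with 5'-truncation and internal-priming artifacts, and species
# alignments with planted promoter-3'UTR covariation.
#
# Gene geometry (in sense coordinates, TSS1 at 0):
#   TSS t ....... (t-1)*151            (alternative TSSs >= 151 nt apart,
#                                       i.e. > 2 x the 50-nt assignment window)
#   first exons . [TSS_t, D1) shared donor D1 = (n_tss-1)*151 + 400
#   E1 .......... [D1+200,  D1+500)
#   cassette A .. [D1+700,  D1+850)    (optional; included or skipped per read)
#   E2 .......... [D1+1050, D1+1350)
#   last exon ... starts L0 = D1 + 1550 + extra
#   ORF end ..... L0 + 100
#   PAS p ....... ORF_end + 350 + (p-1)*pas_sep   (pas_sep >= 601, i.e.
#                                       > 2 x the 150-nt assignment window)
#   IP tract .... mid last bin (n_pas >= 2) or PAS1 - 300 (n_pas = 1);
#                 always > 250 nt from every annotated transcript end so the
#                 internal-priming blacklist is allowed to flag it.
# The genome carries, per PAS, a planted AATAAA 14-19 nt upstream of the
# cleavage site and an A-free 10-mer immediately upstream (so true PASs are
# never A-rich), and a genomic A10 tract immediately upstream of the IP site.

TSS_SEP <- 151L
PAS_SEP_MIN <- 601L
BENIGN10 <- "TGCGTCTGCG"  # no A: keeps true PAS upstream windows below 70% A

#' Specification of one simulated gene class
#'
#' @param n_tss,n_pas number of alternative TSSs / PASs (>= 1).
#' @param coupling n_tss x n_pas probability matrix over (TSS, PAS)
#'   isoforms; entries sum to 1. Default: independent uniform.
#' @param expression reads emitted per gene.
#' @param utr_span distance from ORF end to the distal-most PAS; default
#'   350 + 650*(n_pas-1). Must leave >= 601 nt between consecutive PASs.
#' @param tx_span total gene span (sense nt); default minimal. Extra span
#'   is absorbed by the last intron.
#' @param with_cassette simulate an optional internal cassette exon.
#' @param p_inc cassette inclusion probability per TSS (recycled);
#'   deviating values across TSSs plant a TSS-splicing link.
#' @return object of class `sim_gene_spec`.
#' @export
sim_gene_spec <- function(n_tss = 2L, n_pas = 2L, coupling = NULL,
                          expression = 100L, utr_span = NULL, tx_span = NULL,
                          with_cassette = TRUE, p_inc = 0.5) {
  n_tss <- as.integer(n_tss); n_pas <- as.integer(n_pas)
  if (n_tss < 1L || n_pas < 1L) stopf("n_tss and n_pas must be >= 1")
  if (is.null(coupling))
    coupling <- matrix(1 / (n_tss * n_pas), n_tss, n_pas)
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == c(n_tss, n_pas)))
    stopf("coupling must be %d x %d", n_tss, n_pas)
  if (any(coupling < 0) || abs(sum(coupling) - 1) > 1e-8)
    stopf("coupling entries must be >= 0 and sum to 1")
  if (is.null(utr_span))
    utr_span <- 350L + 650L * (n_pas - 1L)
  utr_span <- as.integer(utr_span)
  if (n_pas == 1L) {
    if (utr_span < 350L)
      stopf("utr_span %d too small: need >= 350 for a single PAS", utr_span)
    pas_sep <- 0L
  } else {
    pas_sep <- (utr_span - 350L) %/% (n_pas - 1L)
    if (pas_sep < PAS_SEP_MIN)
      stopf("utr_span %d too small for %d PASs: separation %d < %d",
            utr_span, n_pas, pas_sep, PAS_SEP_MIN)
  }
  minimal <- (n_tss - 1L) * TSS_SEP + 400L + 1650L + utr_span
  if (is.null(tx_span)) tx_span <- minimal
  tx_span <- as.integer(tx_span)
  if (tx_span < minimal)
    stopf("tx_span %d too small: need >= %d for %d TSSs and utr_span %d",
          tx_span, minimal, n_tss, utr_span)
  structure(list(n_tss = n_tss, n_pas = n_pas, coupling = coupling,
                 expression = as.integer(expression), utr_span = utr_span,
                 tx_span = tx_span, extra = tx_span - minimal,
                 pas_sep = pas_sep, with_cassette = isTRUE(with_cassette),
                 p_inc = rep_len(p_inc, n_tss)),
            class = "sim_gene_spec")
}

#' Preset gene specifications
#'
#' `null`: independent uniform 2x2 coupling. `dominant`: diagonal 2x2
#' coupling (0.45/0.05; odds ratio 81) with a planted dominant promoter.
#' `mixed`: alternating null and dominant.
#'
#' @param preset one of "null", "dominant", "mixed".
#' @param expression reads per gene.
#' @return a `sim_gene_spec` or list of them.
#' @export
sim_preset <- function(preset = c("null", "dominant", "mixed"),
                       expression = 100L) {
  preset <- match.arg(preset)
  nul <- sim_gene_spec(2L, 2L, expression = expression)
  dom <- sim_gene_spec(2L, 2L,
                       coupling = matrix(c(0.45, 0.05, 0.05, 0.45), 2, 2),
                       expression = expression)
  switch(preset, null = nul, dominant = dom, mixed = list(nul, dom))
}

# sense-coordinate layout of one gene
gene_layout <- function(spec) {
  d1 <- (spec$n_tss - 1L) * TSS_SEP + 400L
  l0 <- d1 + 1550L + spec$extra
  orf <- l0 + 100L
  pas <- orf + 350L + (seq_len(spec$n_pas) - 1L) * spec$pas_sep
  ip <- if (spec$n_pas >= 2L) pas[spec$n_pas - 1L] + spec$pas_sep %/% 2L
        else pas[1L] - 300L
  list(tss = (seq_len(spec$n_tss) - 1L) * TSS_SEP, d1 = d1, l0 = l0,
       orf = orf, pas = pas, ip = ip, span = pas[spec$n_pas],
       e1 = c(d1 + 200L, d1 + 500L), cassette = c(d1 + 700L, d1 + 850L),
       e2 = c(d1 + 1050L, d1 + 1350L))
}

# map a sense point/interval to genomic coordinates
sense_point <- function(s, origin, strand)
  if (strand == "+") origin + s else origin - s
sense_interval <- function(s1, s2, origin, strand) {
  if (strand == "+") c(origin + s1, origin + s2) else c(origin - s2, origin - s1)
}

# exon chain (sense intervals) of isoform (tss t, pas p, cassette included?)
isoform_chain <- function(lay, t, p, include) {
  ex <- list(c(lay$tss[t], lay$d1), lay$e1)
  if (include) ex <- c(ex, list(lay$cassette))
  ex <- c(ex, list(lay$e2, c(lay$l0, lay$pas[p])))
  ex
}

#' Simulate gene models, site databases and a genome
#'
#' Emits, for `n_genes` genes alternating between the + and - strand of
#' one synthetic chromosome: annotated transcript models (every
#' TSS x PAS x splice-variant combination), the true TSS and PAS site
#' databases, a genome sequence with planted poly(A) signals and one
#' internal-priming A10 tract per gene, and the ground-truth coupling.
#'
#' @param n_genes number of genes (>= 0).
#' @param spec a [sim_gene_spec()] or list of them, recycled over genes.
#' @param seed RNG seed; output is byte-identical under a fixed seed.
#' @param chrom chromosome name.
#' @param spacing intergenic gap (nt).
#' @param ambiguous if `TRUE`, place alternative sites closer than the
#'   assignment windows (40/80 nt separations) to exercise tie-breaking;
#'   no artifacts are plantable in this mode.
#' @return object of class `sim_models`: list with `$txs` (tx_set),
#'   `$tss`/`$pas` (site tables), `$genome` (DNAStringSet), `$genes`
#'   (per-gene layout table), `$coupling` (long-format truth).
#' @export
simulate_gene_models <- function(n_genes, spec = sim_gene_spec(), seed = 1L,
                                 chrom = "chrS", spacing = 1000L,
                                 ambiguous = FALSE) {
  set.seed(seed)
  specs <- if (inherits(spec, "sim_gene_spec")) list(spec) else spec
  empty_sites <- data.table(chrom = character(), pos = integer(),
                            strand = character(), gene_id = character(),
                            site_id = character(), support = integer())
  if (n_genes == 0L) {
    ex0 <- data.table(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer())
    return(structure(list(txs = new_tx_set(ex0), tss = empty_sites,
                          pas = copy(empty_sites),
                          genome = Biostrings::DNAStringSet(),
                          genes = data.table(), coupling = data.table()),
                     class = "sim_models"))
  }
  exons <- vector("list", n_genes)
  genes <- vector("list", n_genes)
  tss_l <- vector("list", n_genes)
  pas_l <- vector("list", n_genes)
  coup_l <- vector("list", n_genes)
  plants <- vector("list", n_genes)  # genomic sense-sequence plantings
  cursor <- 500L
  for (i in seq_len(n_genes)) {
    sp <- specs[[(i - 1L) %% length(specs) + 1L]]
    lay <- gene_layout(sp)
    if (ambiguous) {
      lay$tss <- (seq_len(sp$n_tss) - 1L) * 40L
      lay$pas <- lay$orf + 350L + (seq_len(sp$n_pas) - 1L) * 80L
      lay$span <- max(lay$pas)
      lay$ip <- NA_integer_
    }
    strand <- if (i %% 2L == 1L) "+" else "-"
    gid <- sprintf("g%04d", i)
    origin <- if (strand == "+") cursor else cursor + lay$span
    cursor <- cursor + lay$span + spacing
    # transcript models: every (tss, pas, variant) combination
    variants <- if (sp$with_cassette) c(TRUE, FALSE) else TRUE
    ex_g <- list()
    for (t in seq_len(sp$n_tss)) for (p in seq_len(sp$n_pas))
      for (v in variants) {
        txid <- sprintf("%s.t%dp%d%s", gid, t, p, if (v) "i" else "s")
        ch <- isoform_chain(lay, t, p, v)
        iv <- t(vapply(ch, function(s)
          sense_interval(s[1], s[2], origin, strand), numeric(2)))
        ex_g[[txid]] <- data.table(transcript_id = txid, gene_id = gid,
                                   chrom = chrom, strand = strand,
                                   start = as.integer(iv[, 1]),
                                   end = as.integer(iv[, 2]))
      }
    exons[[i]] <- rbindlist(ex_g)
    tss_l[[i]] <- data.table(chrom = chrom,
                             pos = as.integer(sense_point(lay$tss, origin, strand)),
                             strand = strand, gene_id = gid,
                             site_id = sprintf("tss%d", seq_len(sp$n_tss)),
                             support = sp$expression)
    pas_l[[i]] <- data.table(chrom = chrom,
                             pos = as.integer(sense_point(lay$pas, origin, strand)),
                             strand = strand, gene_id = gid,
                             site_id = sprintf("pas%d", seq_len(sp$n_pas)),
                             support = sp$expression)
    cc <- sp$coupling / sum(sp$coupling)
    indep <- max(abs(cc - outer(rowSums(cc), colSums(cc)))) < 1e-9
    coup_l[[i]] <- data.table(
      gene_id = gid,
      tss_id = rep(sprintf("tss%d", seq_len(sp$n_tss)), sp$n_pas),
      pas_id = rep(sprintf("pas%d", seq_len(sp$n_pas)), each = sp$n_tss),
      prob = as.vector(cc),
      dominant = !indep &
        as.vector(cc / rep(colSums(cc), each = sp$n_tss)) > 0.2 &
        as.vector(cc / rep(rowSums(cc), sp$n_pas)) > 0.6)
    genes[[i]] <- data.table(
      gene_id = gid, chrom = chrom, strand = strand, origin = origin,
      spec_idx = (i - 1L) %% length(specs) + 1L,
      n_tss = sp$n_tss, n_pas = sp$n_pas, expression = sp$expression,
      orf_end = as.integer(sense_point(lay$orf, origin, strand)),
      ip_pos = if (ambiguous) NA_integer_
               else as.integer(sense_point(lay$ip, origin, strand)),
      span_start = min(sense_point(c(0L, lay$span), origin, strand)),
      span_end = max(sense_point(c(0L, lay$span), origin, strand)))
    if (!ambiguous) {
      pl <- lapply(lay$pas, function(q) {
        up1 <- sample(c("C", "G", "T"), 1)  # no chance of forming AATAAA
        list(s1 = q - 20L, s2 = q,
             seq = paste0(up1, "AATAAA", "CGT", BENIGN10))
      })
      pl <- c(pl, list(list(s1 = lay$ip - 10L, s2 = lay$ip,
                            seq = strrep("A", 10L))))
      plants[[i]] <- data.table(
        start = vapply(pl, function(x)
          min(sense_interval(x$s1, x$s2, origin, strand)), 0),
        seq = vapply(pl, function(x)
          if (strand == "+") x$seq
          else as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(x$seq))), ""))
    }
  }
  genome_len <- cursor + 500L
  chars <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  pls <- rbindlist(plants[!vapply(plants, is.null, TRUE)])
  if (!is.null(pls) && nrow(pls)) {
    for (k in seq_len(nrow(pls))) {
      s <- strsplit(pls$seq[k], "")[[1]]
      chars[(pls$start[k] + 1L):(pls$start[k] + length(s))] <- s
    }
  }
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- chrom
  txs <- new_tx_set(rbindlist(exons))
  gene_tab <- rbindlist(genes)
  txs$tx[gene_tab, orf_end := i.orf_end, on = "gene_id"]
  structure(list(txs = txs,
                 tss = rbindlist(tss_l), pas = rbindlist(pas_l),
                 genome = genome, genes = gene_tab,
                 coupling = rbindlist(coup_l), specs = specs),
            class = "sim_models")
}

#' @export
print.sim_models <- function(x, ...) {
  cat(sprintf("<sim_models> %d genes, %d transcripts, genome %d nt\n",
              nrow(x$genes), nrow(x$txs$tx),
              if (length(x$genome)) sum(Biostrings::width(x$genome)) else 0L))
  invisible(x)
}

#' Simulate full-length reads with artifacts
#'
#' Per gene, (TSS, PAS) labels are a multinomial draw of size `expression`
#' from the gene's coupling matrix; each read's exon chain is the labeled
#' isoform's chain (with the cassette exon included per the gene's
#' TSS-conditional inclusion probability). Artifacts, applied per read:
#' 5' truncation moves the 5' terminus at least `tss_window`+1 nt into the
#' gene body while avoiding the vicinity of every other TSS; internal
#' priming re-anchors the 3' terminus at the gene's planted genomic A10
#' tract (the read still looks tail-bearing); `p_tailless` removes the
#' poly(A)-tail flag only. Reads are never dropped: each gene emits
#' exactly `expression` reads.
#'
#' @param models a `sim_models` object.
#' @param rates list with `p_truncate_5p`, `p_internal_prime`,
#'   `p_tailless`, each in \[0,1\].
#' @param seed RNG seed.
#' @param tail_mean mean simulated poly(A)-tail length (nt).
#' @return list with `$reads` (a `read_set`) and `$truth` (per-read table:
#'   gene_id, tss_id, pas_id, variant, truncated_5p, internal_primed).
#' @export
simulate_reads <- function(models, rates = list(), seed = 1L,
                           tail_mean = 60) {
  rates <- utils::modifyList(
    list(p_truncate_5p = 0, p_internal_prime = 0, p_tailless = 0), rates)
  for (k in names(rates))
    if (rates[[k]] < 0 || rates[[k]] > 1) stopf("rate '%s' not in [0,1]", k)
  set.seed(seed)
  genes <- models$genes
  read_rows <- vector("list", nrow(genes))
  truth_rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    sp <- models$specs[[g$spec_idx]]
    lay <- gene_layout(sp)
    cc <- as.vector(sp$coupling)
    n <- g$expression
    cell <- sample.int(length(cc), n, replace = TRUE, prob = cc)
    t_idx <- (cell - 1L) %% sp$n_tss + 1L
    p_idx <- (cell - 1L) %/% sp$n_tss + 1L
    include <- if (sp$with_cassette)
      stats::runif(n) < sp$p_inc[t_idx] else rep(TRUE, n)
    trunc <- stats::runif(n) < rates$p_truncate_5p
    iprime <- stats::runif(n) < rates$p_internal_prime
    tailless <- stats::runif(n) < rates$p_tailless
    tails <- pmax(10L, as.integer(round(stats::rnorm(n, tail_mean, 15))))
    # truncation offsets that avoid +/- tss_window of every other TSS
    allowed <- lapply(seq_len(sp$n_tss), function(t) {
      off <- 51:350
      for (t2 in seq_len(sp$n_tss)) {
        if (t2 == t) next
        rel <- lay$tss[t2] - lay$tss[t]
        off <- off[abs(off - rel) > 50L]
      }
      off
    })
    rows <- vector("list", n)
    for (r in seq_len(n)) {
      ch <- isoform_chain(lay, t_idx[r], p_idx[r], include[r])
      if (trunc[r]) {
        delta <- allowed[[t_idx[r]]][sample.int(length(allowed[[t_idx[r]]]), 1L)]
        ch[[1]][1] <- ch[[1]][1] + delta
      }
      if (iprime[r] && !is.na(lay$ip)) {
        last <- length(ch)
        ch[[last]][2] <- lay$ip
      }
      iv <- t(vapply(ch, function(s)
        sense_interval(s[1], s[2], g$origin, g$strand), numeric(2)))
      o <- order(iv[, 1])
      rows[[r]] <- list(bs = as.integer(iv[o, 1]), be = as.integer(iv[o, 2]))
    }
    rid <- sprintf("%s.r%04d", g$gene_id, seq_len(n))
    rs <- data.table(read_id = rid, chrom = g$chrom, strand = g$strand,
                     start = vapply(rows, function(x) x$bs[1], 0L),
                     end = vapply(rows, function(x) x$be[length(x$be)], 0L),
                     n_blocks = vapply(rows, function(x) length(x$bs), 0L))
    rs[, block_starts := lapply(rows, `[[`, "bs")]
    rs[, block_ends := lapply(rows, `[[`, "be")]
    rs[, five_prime := fifelse(strand == "+", start, end)]
    rs[, three_prime := fifelse(strand == "+", end, start)]
    rs[, has_polya := !tailless]
    rs[, tail_length := fifelse(has_polya, tails, NA_integer_)]
    read_rows[[i]] <- rs
    truth_rows[[i]] <- data.table(
      read_id = rid, gene_id = g$gene_id,
      tss_id = sprintf("tss%d", t_idx), pas_id = sprintf("pas%d", p_idx),
      variant = fifelse(rep(sp$with_cassette, n),
                        fifelse(include, "inclusion", "skipping"), NA_character_),
      truncated_5p = trunc, internal_primed = iprime & !is.na(lay$ip))
  }
  reads <- rbindlist(read_rows)
  structure(list(reads = structure(reads, class = c("read_set", class(reads))),
                 truth = rbindlist(truth_rows)), class = "sim_reads")
}

#' Simulate a species alignment with planted promoter-3'UTR covariation
#'
#' Star phylogeny over a 4-letter alphabet, no gaps, reference row first.
#' Background columns substitute independently at `sub_rate`; each planted
#' pair links one promoter-1 column to one 3'UTR column: both columns take
#' two equiprobable states and, with probability `rho`, a species' UTR
#' state is determined by its promoter state through a fixed bijection.
#' Promoter 2 carries background columns only and acts as the
#' no-coupling control.
#'
#' @param n_species alignment rows including the reference (default 27).
#' @param layout named lengths (columns) of regions `promoter1`,
#'   `promoter2`, `utr`, laid out contiguously in that order.
#' @param n_pairs number of planted covarying column pairs.
#' @param rho linkage probability in \[0,1\].
#' @param sub_rate background substitution probability per species/column.
#' @param seed RNG seed.
#' @return list with `$msa` (DNAStringSet, reference first), `$regions`
#'   (0-based half-open column spans) and `$pairs` (planted column pairs,
#'   0-based).
#' @export
simulate_msa <- function(n_species = 27L,
                         layout = c(promoter1 = 60L, promoter2 = 60L, utr = 80L),
                         n_pairs = 6L, rho = 0.9, sub_rate = 0.3, seed = 1L) {
  if (rho < 0 || rho > 1) stopf("rho must be in [0,1]")
  stopifnot(all(c("promoter1", "promoter2", "utr") %in% names(layout)))
  set.seed(seed)
  L <- sum(layout)
  starts <- cumsum(c(0L, layout))[seq_along(layout)]
  names(starts) <- names(layout)
  regions <- data.table(region = names(layout), start = as.integer(starts),
                        end = as.integer(starts + layout))
  alpha <- c("A", "C", "G", "T")
  ref <- sample(alpha, L, replace = TRUE)
  M <- matrix(rep(ref, each = n_species), nrow = n_species)
  sub <- matrix(stats::runif(n_species * L) < sub_rate, n_species, L)
  sub[1L, ] <- FALSE  # reference row fixed
  if (any(sub)) {
    idx <- which(sub)
    cur <- M[idx]
    repl <- vapply(cur, function(a) sample(setdiff(alpha, a), 1L), "")
    M[idx] <- repl
  }
  # planted pairs: spaced columns in promoter1 x utr; promoter2 receives
  # the same number of independent two-state columns so it is a
  # composition-matched control (scores differ only through the linkage)
  p1 <- regions[region == "promoter1"]
  p2 <- regions[region == "promoter2"]
  ut <- regions[region == "utr"]
  if (n_pairs > 0L) {
    c1 <- as.integer(round(seq(p1$start + 2L, p1$end - 3L,
                               length.out = n_pairs)))
    c2 <- as.integer(round(seq(ut$start + 2L, ut$end - 3L,
                               length.out = n_pairs)))
    c3 <- as.integer(round(seq(p2$start + 2L, p2$end - 3L,
                               length.out = n_pairs)))
    for (k in seq_len(n_pairs)) {
      st1 <- sample(alpha, 2L)
      st2 <- sample(alpha, 2L)
      st3 <- sample(alpha, 2L)
      s1 <- sample(st1, n_species, replace = TRUE)
      linked <- stats::runif(n_species) < rho
      s2 <- ifelse(linked, st2[match(s1, st1)],
                   sample(st2, n_species, replace = TRUE))
      s3 <- sample(st3, n_species, replace = TRUE)
      s1[1L] <- st1[1L]; s2[1L] <- st2[1L]; s3[1L] <- st3[1L]
      M[, c1[k] + 1L] <- s1
      M[, c2[k] + 1L] <- s2
      M[, c3[k] + 1L] <- s3
    }
    pairs <- data.table(col_promoter = c1, col_utr = c2)
  } else pairs <- data.table(col_promoter = integer(), col_utr = integer())
  seqs <- apply(M, 1L, paste, collapse = "")
  msa <- Biostrings::DNAStringSet(seqs)
  names(msa) <- c("ref", sprintf("sp%02d", seq_len(n_species - 1L)))
  list(msa = msa, regions = regions, pairs = pairs)
}

#' Write a simulated dataset to a directory
#'
#' Emits `annotation.gtf`, `tss.bed`, `pas_true.bed`, `reads.bed12`,
#' `polya.tsv`, `truth.tsv`, `genome.fasta`, `msa.fasta`, `regions.bed`.
#'
#' @param models from [simulate_gene_models()].
#' @param sim_reads from [simulate_reads()].
#' @param msa from [simulate_msa()] or `NULL`.
#' @param dir output directory (created if needed).
#' @export
write_sim <- function(models, sim_reads, msa = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(models$txs, file.path(dir, "annotation.gtf"))
  write_site_bed(models$tss, file.path(dir, "tss.bed"))
  write_site_bed(models$pas, file.path(dir, "pas_true.bed"))
  write_read_bed12(sim_reads$reads, file.path(dir, "reads.bed12"),
                   file.path(dir, "polya.tsv"))
  write_tsv(sim_reads$truth, file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(models$genome, file.path(dir, "genome.fasta"),
                              width = 80L)
  if (!is.null(msa)) {
    Biostrings::writeXStringSet(msa$msa, file.path(dir, "msa.fasta"),
                                width = 200L)
    reg <- msa$regions
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", "msa", reg$start, reg$end,
                       reg$region), file.path(dir, "regions.bed"))
  }
  invisible(dir)
}
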