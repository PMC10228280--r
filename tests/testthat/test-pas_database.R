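# pas_database: clustering, blacklist, signal hierarchy, profiles,
# tail summaries, 5' pile-ups.

test_that("build_pas_database clusters and thresholds per contract", {
  # two reads at the same base -> one cluster, support 2
  db <- build_pas_database(make_end_reads(c(100, 100)))
  expect_equal(db[, .(pos, support)], data.table(pos = 100L, support = 2L))
  # [100,110,135], window 20: {100,110} kept, {135} dropped as a singleton
  db <- build_pas_database(make_end_reads(c(100, 110, 135)),
                           window = 20, min_support = 2)
  expect_equal(nrow(db), 1L)
  expect_equal(db$members[[1]], c(100L, 110L))
  expect_equal(db$support, 2L)
  # empty input and tailless rejection
  expect_equal(nrow(build_pas_database(make_end_reads(integer(0)))), 0L)
  expect_error(build_pas_database(make_end_reads(c(100, 100),
                                                 has_polya = FALSE)),
               "without a poly\\(A\\) tail")
})

test_that("clustering matches the brute-force linkage oracle exactly", {
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(1:15, 1)
    pos <- sort(sample(0:300, n, replace = TRUE))
    st <- sample(c("+", "-"), 1)
    db <- build_pas_database(make_end_reads(pos, strand = st),
                             window = 20, min_support = 1)
    oc <- oracle_linkage(pos, 20)
    expect_equal(db$members, lapply(oc, function(x) sort(unique(x))))
    expect_equal(db$support, vapply(oc, length, 0L))
    # support conservation incl. dropped singletons
    db2 <- build_pas_database(make_end_reads(pos, strand = st),
                              window = 20, min_support = 2)
    dropped <- sum(vapply(oc, length, 0L)[vapply(oc, length, 0L) < 2])
    expect_equal(sum(db2$support) + dropped, n)
    # representative: modal member, ties 3'-most
    for (k in seq_len(nrow(db))) {
      mem <- pos[pos %in% db$members[[k]]]
      tab <- table(mem)
      modal <- as.integer(names(tab)[tab == max(tab)])
      expect_equal(db$pos[k], if (st == "+") max(modal) else min(modal))
    }
  }
})

test_that("cluster_3seq_sites applies coverage and 15-bp merge rules", {
  cov <- data.table(chrom = "c", strand = "+",
                    pos = c(50L, 100L, 114L, 200L, 216L),
                    cov = c(4L, 6L, 7L, 8L, 9L))
  cl <- cluster_3seq_sites(cov, merge = 15, min_cov = 5)
  expect_equal(length(cl$members), 3L)           # 50 dropped (cov 4)
  expect_equal(cl$members[[1]], c(100L, 114L))   # 14 <= 15: merged
  expect_equal(cl$members[[2]], 200L)            # 16 > 15: split
  expect_equal(cl$members[[3]], 216L)
  expect_equal(cl$support, c(13L, 8L, 9L))
})

test_that("internal_priming_mask applies the strict A rule and TES exemption", {
  # position 60 (+): upstream window [50,60) planted below
  base <- paste(rep("C", 400), collapse = "")
  plant <- function(s, at, what) {  # 0-based
    paste0(substr(s, 1, at), what, substr(s, at + nchar(what) + 1, nchar(s)))
  }
  g8 <- make_genome(list(c1 = plant(base, 50, "AAAAAAAATC")))
  g7 <- make_genome(list(c1 = plant(base, 50, "AAAAAAATTC")))
  far_tx <- make_txs(list(t1 = cbind(350, 390)), chrom = "c1")  # TES at 390: > 250 from 60
  m8 <- internal_priming_mask(g8, far_tx)
  expect_true(nrow(m8[strand == "+" & pos == 60]) == 1)  # 8/10 = 80% > 70%
  m7 <- internal_priming_mask(g7, far_tx)
  expect_equal(nrow(m7[strand == "+" & pos == 60]), 0L)  # 70% not > 70%
  # same A-run within 250 bp of an annotated TES -> exempt
  near_tx <- make_txs(list(t1 = cbind(100, 160)), chrom = "c1")  # TES 160: 100 bp away
  expect_equal(nrow(internal_priming_mask(g8, near_tx)[strand == "+" &
                                                       pos == 60]), 0L)
  # - strand: T-run on the reference is the sense-strand A-run
  gm <- make_genome(list(c1 = plant(base, 60, "TTTTTTTTTT")))
  mm <- internal_priming_mask(gm, far_tx)
  expect_true(nrow(mm[strand == "-" & pos == 60]) == 1)
  expect_error(internal_priming_mask(g8, make_txs(list(t1 = cbind(1, 5)),
                                                  chrom = "nope")),
               "nope")
})

test_that("scan_polya_signal follows the hexamer hierarchy", {
  pad <- function(s) paste0(strrep("C", 50 - nchar(s)), s)
  both <- scan_polya_signal(pad("ATTAAACCCCAATAAACCCC"), 50)
  expect_equal(both$signal, "AATAAA")            # rank 1 wins
  low <- scan_polya_signal(pad("TTTAAACCCC"), 50)
  expect_equal(low$signal, "TTTAAA")             # last-ranked still found
  none <- scan_polya_signal(strrep("GC", 25), 50)
  expect_equal(none$signal, "none")
  expect_true(is.na(none$offset))
  # hierarchy is rank-based, not scan-order-based
  rev_order <- scan_polya_signal(pad("AATAAACCCCATTAAACCCC"), 50)
  expect_equal(rev_order$signal, "AATAAA")
  expect_error(scan_polya_signal("AATAAA", 50), "longer than")
  # offset: hexamer start, in nt upstream of the cleavage site
  at_end <- scan_polya_signal(pad("AATAAA"), 50)
  expect_equal(at_end$offset, 6L)
})

test_that("nucleotide_profile normalizes and centers on the cleavage base", {
  g <- make_genome(list(c1 = paste0(strrep("G", 50), "T", strrep("A", 50))))
  sites <- data.table(chrom = "c1", pos = 51L, strand = "+")  # center = T
  pr <- nucleotide_profile(sites, g, flank = 10)
  expect_equal(dim(pr), c(4L, 21L))
  expect_true(all(abs(colSums(pr) - 1) < 1e-12))
  expect_equal(pr["T", "0"], 1)                   # indicator profile
  expect_true(all(pr["A", as.character(1:10)] == 1))  # A-rich downstream
  expect_true(all(pr["G", as.character(-10:-1)] == 1))
  # site at the contig edge: skipped with a warning
  edge <- data.table(chrom = "c1", pos = c(51L, 3L), strand = "+")
  expect_warning(pr2 <- nucleotide_profile(edge, g, flank = 10),
                 "skipped 1")
  expect_equal(pr2, pr)
})

test_that("summarize_tail_lengths computes group medians", {
  rs <- make_end_reads(c(100, 200, 300, 400, 500))
  rs$tail_length <- c(50L, 100L, 150L, 50L, 100L)
  rs$has_polya <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  groups <- data.table(read_id = rs$read_id,
                       group = c("a", "a", "a", "b", "c"))
  out <- summarize_tail_lengths(rs, groups)
  expect_equal(out$group, c("a", "b"))            # c has no tailed reads
  expect_equal(out$median_tail, c(100, 50))
  rs$has_polya <- TRUE
  out2 <- summarize_tail_lengths(rs, groups)
  expect_equal(out2[group == "c", median_tail], 100)  # single read
  groups2 <- copy(groups)[, group := c("a", "a", "b", "b", "c")]
  expect_equal(summarize_tail_lengths(rs, groups2)[group == "a", median_tail],
               75)                                 # even-n: mean of mid pair
})

test_that("call_5prime_pileups thresholds CPM strictly and flags TSS", {
  pos <- c(rep(110L, 31L), rep(310L, 30L))
  blocks <- lapply(pos, function(p) cbind(p, p + 500L))
  rs <- make_reads(blocks)
  # pad the library to exactly 1e3 reads -> CPM = 1000 * count
  pad <- make_reads(lapply(seq_len(1000 - length(pos)),
                           function(i) cbind(5000L + 10L * i, 6000L + 10L * i)),
                    ids = sprintf("p%03d", seq_len(1000 - length(pos))))
  lib <- structure(rbind(rs, pad), class = class(rs))
  tssdb <- data.table(chrom = "chr1", pos = 150L, strand = "+")
  # library 1000 reads: 31 reads -> CPM 31000 > 30000 kept; 30 -> dropped
  pk <- call_5prime_pileups(lib, window = 50, min_cpm = 30000, tss_db = tssdb)
  expect_true(110L %in% pk$peak_pos)
  expect_false(310L %in% pk$peak_pos)
  expect_true(pk[peak_pos == 110L, tss_overlap])  # TSS 40 nt away
  expect_error(call_5prime_pileups(make_end_reads(integer(0))), "empty")
})

test_that("blacklist flags all planted IP tracts and no true PAS", {
  m <- simulate_gene_models(10, sim_preset("mixed"), seed = 31)
  mask <- internal_priming_mask(m$genome, m$txs)
  found <- m$genes[mask, on = c(chrom = "chrom", ip_pos = "pos",
                                strand = "strand"), nomatch = NULL]
  expect_equal(nrow(found), 10L)
  pas_hit <- m$pas[mask, on = c("chrom", "pos", "strand"), nomatch = NULL]
  expect_equal(nrow(pas_hit), 0L)
})
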