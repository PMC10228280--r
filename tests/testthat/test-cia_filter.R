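# cia_filter: 3'-end filtering, bin-based correction, tolerance merging.

# shared fixture: one + strand gene, clusters at 1000 and 1500, ORF at 800;
# reference span covers [0, 1700); AATAAA planted at 1580-1586 upstream of
# a putative distal end at 1620
filter_fixture <- function() {
  db <- data.table(chrom = "chr1", strand = "+",
                   pos = c(1000L, 1500L), support = c(5L, 5L))
  seq <- strrep("C", 2000)
  seq <- paste0(substr(seq, 1, 1580), "AATAAA", substr(seq, 1587, 2000))
  ref <- make_txs(list(ref1 = rbind(c(100, 400), c(500, 1700))))
  list(db = db, genome = make_genome(list(chr1 = seq)), ref = ref)
}

end_tx <- function(tp, id = "tx") {
  tx <- make_txs(stats::setNames(list(rbind(c(100, 400), c(500, tp))), id))
  tx
}

test_that("filter_3prime_ends applies the db-overlap and distal-AATAAA rules", {
  fx <- filter_fixture()
  # 80 nt from the 1000 cluster -> retained_db_overlap
  r1 <- filter_3prime_ends(end_tx(1080L), fx$db, fx$ref, fx$genome)
  expect_equal(r1$report$status, "retained_db_overlap")
  # 120 nt beyond the distal cluster, inside reference, AATAAA upstream
  r2 <- filter_3prime_ends(end_tx(1620L), fx$db, fx$ref, fx$genome)
  expect_equal(r2$report$status, "retained_distal_annotated_AATAAA")
  # same distal end without the signal -> discarded
  plain <- make_genome(list(chr1 = strrep("C", 2000)))
  r3 <- filter_3prime_ends(end_tx(1620L), fx$db, fx$ref, plain)
  expect_equal(r3$report$status, "discarded")
  expect_equal(r3$report$reason, "no_AATAAA")
  # beyond the reference span -> discarded even with AATAAA
  far <- filter_fixture()
  r4 <- filter_3prime_ends(end_tx(1790L), far$db, far$ref, far$genome)
  expect_equal(r4$report$status, "discarded")
  # gene with zero database clusters is counted separately
  r5 <- filter_3prime_ends(end_tx(1620L),
                           data.table(chrom = "chr9", strand = "+",
                                      pos = 5L, support = 2L),
                           fx$ref, fx$genome)
  expect_equal(r5$report$reason, "no_db_cluster")
})

test_that("filtering is idempotent", {
  fx <- filter_fixture()
  txs <- make_txs(list(a = rbind(c(100, 400), c(500, 1080)),
                       b = rbind(c(100, 400), c(500, 1620)),
                       c = rbind(c(100, 400), c(500, 1320))))
  f1 <- filter_3prime_ends(txs, fx$db, fx$ref, fx$genome)
  f2 <- filter_3prime_ends(f1$kept, fx$db, fx$ref, fx$genome)
  expect_equal(sort(f2$kept$tx$transcript_id), sort(f1$kept$tx$transcript_id))
  expect_true(all(f2$report$status != "discarded"))
})

test_that("correct_3prime_ends applies the last-bin 10% rule and snapping", {
  # bin [1000, 1500): the two distal-most PASs
  db <- data.table(chrom = "chr1", strand = "+",
                   pos = c(1000L, 1500L), support = c(5L, 5L))
  orf <- data.table(gene_id = "g1", orf_end = 800L)
  corr <- function(tp) {
    out <- correct_3prime_ends(end_tx(tp), db, orf)
    list(tp = out$txs$tx$three_prime, delta = out$deltas$delta)
  }
  c1 <- corr(1060L)  # covers 60/500 = 12% > 10% -> distal PAS
  expect_equal(c1$tp, 1500L)
  expect_equal(c1$delta, 440L)
  c2 <- corr(1040L)  # 8% <= 10% -> proximal PAS
  expect_equal(c2$tp, 1000L)
  expect_equal(c2$delta, -40L)
  c3 <- corr(1500L)  # exactly at a cluster -> delta 0
  expect_equal(c3$delta, 0L)
  c4 <- corr(950L)   # outside the last bin, within 100 of cluster -> snap
  expect_equal(c4$tp, 1000L)
  # single-PAS gene: snap-only, no bins
  db1 <- db[1]
  out <- correct_3prime_ends(end_tx(1060L), db1, orf)
  expect_equal(out$txs$tx$three_prime, 1000L)
  out2 <- correct_3prime_ends(end_tx(1300L), db1, orf)
  expect_equal(out2$deltas$delta, 0L)
  # |delta| never exceeds the span of the bin it acts in
  expect_true(abs(c1$delta) <= 500 && abs(c2$delta) <= 500)
})

test_that("correction works strand-aware on the minus strand", {
  # - strand: ORF end at 1200 (sense), PASs at 800 (proximal) and 300
  db <- data.table(chrom = "chr1", strand = "-",
                   pos = c(300L, 800L), support = c(3L, 3L))
  orf <- data.table(gene_id = "g1", orf_end = 1200L)
  tx <- make_txs(list(m1 = rbind(c(740, 1500))), strand = "-")
  # end at 740: covers 60/500 of the last bin (800 -> 300) = 12% -> distal
  out <- correct_3prime_ends(tx, db, orf)
  expect_equal(out$txs$tx$three_prime, 300L)
  expect_equal(out$deltas$delta, 440L)
})

test_that("merge_isoforms applies strict tolerances", {
  base <- rbind(c(1000, 2000), c(3000, 4000))
  near <- rbind(c(1049, 2009), c(3000, 4149))   # 49 / 9 / 149: mergeable
  far3 <- rbind(c(1000, 2000), c(3000, 4310))   # >= 150 from both: not
  txs <- make_txs(list(a = base, b = near, c = far3))
  mg <- merge_isoforms(txs)
  grp <- mg$members[, .(n = .N), by = rep_id]
  expect_equal(nrow(mg$txs$tx), 2L)
  expect_equal(sort(grp$n), c(1L, 2L))
  expect_true(all(c("a", "b") %in% mg$members[rep_id == mg$members[member_id == "a", rep_id], member_id]))
  # different junction counts never merge
  txs2 <- make_txs(list(a = base, b = rbind(c(1000, 4000))))
  expect_equal(nrow(merge_isoforms(txs2)$txs$tx), 2L)
})

test_that("merging is the transitive closure of pairwise mergeability", {
  # chain: a~b (140 apart at 3'), b~c (140), a vs c 280 apart: one group of 3
  a <- rbind(c(1000, 2000), c(3000, 4000))
  b <- rbind(c(1000, 2000), c(3000, 4140))
  cc <- rbind(c(1000, 2000), c(3000, 4280))
  mg <- merge_isoforms(make_txs(list(a = a, b = b, c = cc)))
  expect_equal(nrow(mg$txs$tx), 1L)
  expect_equal(sort(mg$members$member_id), c("a", "b", "c"))
  # random instances against the connected-components oracle
  set.seed(5)
  for (rep in 1:15) {
    n <- sample(2:8, 1)
    ends <- 4000L + sample(0:600, n, replace = TRUE)
    fives <- 1000L + sample(0:120, n, replace = TRUE)
    exs <- lapply(seq_len(n), function(i)
      rbind(c(fives[i], 2000), c(3000, ends[i])))
    names(exs) <- sprintf("t%02d", seq_len(n))
    mg <- merge_isoforms(make_txs(exs))
    adj <- abs(outer(ends, ends, "-")) < 150 &
      abs(outer(fives, fives, "-")) < 50
    diag(adj) <- TRUE
    comp <- oracle_components(adj)
    expect_equal(nrow(mg$txs$tx), length(unique(comp)))
    got <- merge(mg$members, data.table(member_id = names(exs), comp = comp),
                 by = "member_id")
    expect_equal(got[, length(unique(comp)), by = rep_id]$V1,
                 rep(1L, length(unique(comp))))
  }
})
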