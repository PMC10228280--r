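# later: full-length assignment, coupling matrices, Monte-Carlo
# chi-squared bias test, promoter dominance, subsampling.

site_tab <- function(pos, gene = "g1", ids = NULL, strand = "+") {
  data.table(chrom = "chr1", pos = as.integer(pos), strand = strand,
             gene_id = gene, site_id = ids %||% sprintf("s%d", seq_along(pos)),
             support = 10L)
}

test_that("assignment windows and tie-breaking follow the contract", {
  tss <- site_tab(1000L, ids = "tss1")
  pas <- site_tab(3000L, ids = "pas1")
  rd <- function(fp, tp) make_reads(list(cbind(fp, tp)))
  # deltas (30, 120): within 50/150 -> assigned
  expect_true(assign_full_length_reads(rd(1030, 3120), tss, pas)$assigned)
  # deltas (60, 10): outside the 5' window -> unassigned
  a2 <- assign_full_length_reads(rd(1060, 3010), tss, pas)
  expect_false(a2$assigned)
  expect_equal(a2$reason, "no_tss")
  # two TSSs 40 and 45 nt away: nearest wins
  tss2 <- site_tab(c(1040L, 1125L), ids = c("tssA", "tssB"))
  a3 <- assign_full_length_reads(rd(1080, 3000), tss2, pas)
  expect_equal(a3$tss_id, "tssA")
  # exact distance tie: 5'-most TSS (smaller coordinate on +)
  a4 <- assign_full_length_reads(rd(1082, 2980), site_tab(c(1042L, 1122L),
                                                          ids = c("L", "R")),
                                 pas)
  expect_equal(a4$tss_id, "L")
  # exact PAS tie: 3'-most PAS (larger coordinate on +)
  a5 <- assign_full_length_reads(rd(1000, 3000),
                                 tss, site_tab(c(2950L, 3050L),
                                               ids = c("P", "D")))
  expect_equal(a5$pas_id, "D")
  # TSS and PAS from different genes -> unassigned with gene_conflict
  a6 <- assign_full_length_reads(rd(1000, 3000), tss,
                                 site_tab(3000L, gene = "g2", ids = "pas1"))
  expect_false(a6$assigned)
  expect_equal(a6$reason, "gene_conflict")
})

test_that("build_coupling_matrices applies gene and cell filters", {
  mk_asn <- function(cells, gene = "g1", tss_pos = NULL, pas_pos = NULL) {
    rbindlist(lapply(seq_len(nrow(cells)), function(i)
      data.table(read_id = sprintf("%s_%d_%d", gene, i, seq_len(cells$n[i])),
                 assigned = TRUE, gene_id = gene,
                 tss_id = cells$tss[i], pas_id = cells$pas[i],
                 tss_pos = tss_pos %||% 1000L,
                 pas_pos = pas_pos %||% 3000L, reason = NA_character_)))
  }
  # gene with isoform read counts {5, 1}: only one isoform with >= 2 reads
  a <- mk_asn(data.table(tss = c("t1", "t2"), pas = c("p1", "p2"),
                         n = c(5L, 1L)))
  expect_length(build_coupling_matrices(a, tpm_cutoff = 0), 0L)
  # 2x2 with all cells >= 2 -> kept, counts laid out by site ids
  cells <- data.table(tss = rep(c("t1", "t2"), 2),
                      pas = rep(c("p1", "p2"), each = 2), n = c(5L, 3L, 2L, 8L))
  m <- build_coupling_matrices(mk_asn(cells), tpm_cutoff = 0)
  expect_equal(m[["g1"]], matrix(c(5L, 3L, 2L, 8L), 2, 2,
                                 dimnames = list(c("t1", "t2"),
                                                 c("p1", "p2"))))
  # cells from an 11-kb transcript span are excluded
  a3 <- rbind(mk_asn(cells),
              mk_asn(data.table(tss = "t3", pas = "p3", n = 4L),
                     tss_pos = 1000L, pas_pos = 12500L))
  m3 <- build_coupling_matrices(a3, tpm_cutoff = 0)
  expect_false("t3" %in% rownames(m3[["g1"]]))
  # TPM cutoff: strictly more than `tpm_cutoff` required
  two_genes <- rbind(mk_asn(cells),
                     mk_asn(cells[, .(tss, pas, n = n * 100L)], gene = "g2"))
  mt <- build_coupling_matrices(two_genes, tpm_cutoff = 2e4)
  expect_equal(names(mt), "g2")
})

test_that("chi-squared MC test matches closed forms and the estimator bound", {
  flat <- matrix(c(10, 10, 10, 10), 2, 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  ts <- test_tss_bias(structure(list(g = flat), class = "coupling_set"),
                      B = 200, seed = 1)
  expect_equal(ts$X2, 0)
  expect_equal(ts$p_mc, 1)
  expect_equal(ts$dominance_score, 0)
  diagm <- matrix(c(5, 0, 0, 5), 2, 2,
                  dimnames = list(c("a", "b"), c("x", "y")))
  # exact P(X2 >= 10 | margins 5,5/5,5) = 2/252
  expect_equal(oracle_exact_fixed_margin_p(diagm), 2 / 252, tolerance = 1e-12)
  B <- 4000
  td <- test_tss_bias(structure(list(g = diagm), class = "coupling_set"),
                      B = B, seed = 2)
  expect_equal(td$X2, 10)
  se <- sqrt((2 / 252) * (1 - 2 / 252) / B)
  expect_lt(abs(td$p_mc - 2 / 252), 3 * se + 1 / (B + 1))
  expect_gte(td$p_mc, 1 / (B + 1))
  # zero-margin rows are dropped with a warning before testing
  zm <- matrix(c(5, 0, 3, 0, 0, 0, 2, 0, 6), 3, 3,
               dimnames = list(letters[1:3], LETTERS[1:3]))
  expect_warning(tz <- test_tss_bias(structure(list(g = zm),
                                               class = "coupling_set"),
                                     B = 100, seed = 3), "zero-margin")
  expect_equal(nrow(tz), 1L)
})

test_that("MC p-values track the exact fixed-margin enumeration", {
  set.seed(99)
  B <- 2000
  for (rep in 1:8) {
    dims <- list(c(2L, 2L), c(2L, 3L), c(3L, 2L))[[sample(3, 1)]]
    m <- random_small_table(dims[1], dims[2])
    dimnames(m) <- list(sprintf("r%d", seq_len(nrow(m))),
                        sprintf("c%d", seq_len(ncol(m))))
    p_ex <- oracle_exact_fixed_margin_p(m)
    tt <- test_tss_bias(structure(list(g = m), class = "coupling_set"),
                        B = B, seed = 1000 + rep)
    tol <- 3 * sqrt(p_ex * (1 - p_ex) / B) + 1 / (B + 1)
    expect_lt(abs(tt$p_mc - p_ex), tol + 1e-12)
  }
})

test_that("multinomial null mode runs and agrees on the flat table", {
  flat <- matrix(c(10, 10, 10, 10), 2, 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  tm <- test_tss_bias(structure(list(g = flat), class = "coupling_set"),
                      B = 200, seed = 4, null = "multinomial")
  expect_equal(tm$p_mc, 1)
})

test_that("promoter dominance needs bias plus both contribution cutoffs", {
  m <- matrix(c(18L, 2L, 2L, 18L), 2, 2,
              dimnames = list(c("t1", "t2"), c("p1", "p2")))
  mats <- structure(list(g1 = m), class = "coupling_set")
  tests <- test_tss_bias(mats, B = 2000, seed = 5)
  expect_lt(tests$p_adj, 0.1)
  dom <- call_promoter_dominance(tests, mats)
  d11 <- dom[tss_id == "t1" & pas_id == "p1"]
  expect_equal(d11$tss_contribution, 0.9)
  expect_equal(d11$pas_contribution, 0.9)
  expect_true(d11$is_dominant)
  expect_false(dom[tss_id == "t1" & pas_id == "p2", is_dominant])
  expect_false(dom[tss_id == "t2" & pas_id == "p1", is_dominant])
  # same matrix but non-significant gene -> no calls
  fake <- copy(tests)[, p_adj := 0.5]
  expect_false(any(call_promoter_dominance(fake, mats)$is_dominant))
  # contributions (0.9, 0.5): PAS contribution at 0.5 <= 0.6 fails
  m2 <- matrix(c(9L, 1L, 9L, 21L), 2, 2,
               dimnames = list(c("t1", "t2"), c("p1", "p2")))
  mats2 <- structure(list(g1 = m2), class = "coupling_set")
  t2 <- copy(tests)[, p_adj := 1e-6]
  d2 <- call_promoter_dominance(t2, mats2)
  cell <- d2[tss_id == "t1" & pas_id == "p1"]
  expect_equal(cell$tss_contribution, 0.9)
  expect_equal(cell$pas_contribution, 0.5)
  expect_false(cell$is_dominant)
  # column-wise TSS contribution normalization
  expect_equal(dom[, sum(tss_contribution), by = pas_id]$V1, c(1, 1))
})

test_that("subsample_reads is exact, ordered and deterministic", {
  rs <- make_end_reads(seq(100L, 1000L, by = 100L))
  expect_equal(subsample_reads(rs, 1, seed = 3)$read_id, rs$read_id)
  s5 <- subsample_reads(rs, 0.5, seed = 3)
  expect_equal(nrow(s5), 5L)
  expect_false(is.unsorted(match(s5$read_id, rs$read_id)))
  expect_equal(subsample_reads(rs, 0.5, seed = 3)$read_id, s5$read_id)
  expect_equal(nrow(subsample_reads(rs, 0.26, seed = 1)), 2L)  # floor rule
  expect_error(subsample_reads(rs, 0), "fraction")
  expect_error(subsample_reads(rs, 1.2), "fraction")
})
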