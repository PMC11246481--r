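test_that("cis filter keeps the 1 Mb flank around gene bounds, inclusive", {
  gene <- tiny_gene()  # [1,500,000, 1,520,000]
  ss <- make_sumstats(list(
    assoc_row("in_low", pos = 1500000 - 999999),
    assoc_row("out_low", pos = 1500000 - 1000001),
    assoc_row("in_high", pos = 1520000 + 1000000),
    assoc_row("other_chr", pos = 1510000, chrom = "2")))
  kept <- cis_filter(ss, gene)$records$snp_id
  expect_setequal(kept, c("in_low", "in_high"))
})

test_that("significance filter is strict at the genome-wide threshold", {
  ss <- make_sumstats(list(
    assoc_row("rs_a", pval = 4.9e-8), assoc_row("rs_b", pos = 2e6, pval = 5e-8),
    assoc_row("rs_c", pos = 3e6, pval = 0.5)))
  expect_equal(significance_filter(ss)$records$snp_id, "rs_a")
  expect_equal(nrow(significance_filter(
    make_sumstats(list(assoc_row("rs_d", pval = 0.5))))$records), 0L)
})

test_that("MHC exclusion removes chr6 26-34 Mb inclusively and nothing else", {
  ss <- make_sumstats(list(
    assoc_row("mhc_mid", chrom = "6", pos = 30e6),
    assoc_row("mhc_edge_low", chrom = "6", pos = 26e6),
    assoc_row("just_below", chrom = "6", pos = 25999999),
    assoc_row("just_above", chrom = "6", pos = 34000001),
    assoc_row("other_chr", chrom = "7", pos = 30e6)))
  kept <- mhc_exclude(ss)$records$snp_id
  expect_setequal(kept, c("just_below", "just_above", "other_chr"))
})

test_that("greedy clumping follows the p-value/LD rule on the worked example", {
  ss <- make_sumstats(list(
    assoc_row("A", pos = 1000, pval = 1e-10),
    assoc_row("B", pos = 2000, pval = 1e-9),
    assoc_row("C", pos = 3000, pval = 1e-8)))
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.5
  r2[1, 3] <- r2[3, 1] <- 0.0005
  r2[2, 3] <- r2[3, 2] <- 0.3
  ld <- ld_matrix(c("A", "B", "C"), r2)
  expect_setequal(clump(ss, ld, 0.001)$records$snp_id, c("A", "C"))

  # identity LD keeps everything; total LD keeps only the smallest p
  expect_equal(nrow(clump(ss, identity_ld(c("A", "B", "C")))$records), 3L)
  all1 <- ld_matrix(c("A", "B", "C"), matrix(1, 3, 3))
  expect_equal(clump(ss, all1)$records$snp_id, "A")
})

test_that("clumping matches the brute-force greedy oracle on random instances", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    ids <- paste0("s", seq_len(n))
    A <- matrix(runif(n * n), n)
    r <- cov2cor(crossprod(A) + diag(n))
    r2 <- r^2; diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)
    pv <- round(runif(n, 1e-12, 1e-6), 10)  # rounding creates occasional ties
    ss <- make_sumstats(lapply(seq_len(n), function(i)
      assoc_row(ids[i], pos = i * 100, pval = pv[i])))
    thr <- sample(c(0.001, 0.1, 0.5), 1)
    got <- clump(ss, ld_matrix(ids, r2), thr)$records$snp_id
    want <- clump_oracle(ids, pv, seq_len(n) * 100, r2, thr)
    expect_setequal(got, want)
    # output pairwise independent at the threshold
    sub <- r2[got, got, drop = FALSE]; diag(sub) <- 0
    expect_true(all(sub < thr))
  }
})

test_that("SNPs missing from the LD matrix are treated as independent", {
  ss <- make_sumstats(list(assoc_row("A", pval = 1e-10),
                           assoc_row("B", pos = 2000, pval = 1e-9)))
  expect_message(out <- clump(ss, identity_ld("A")), "absent from LD")
  expect_setequal(out$records$snp_id, c("A", "B"))
})

test_that("variance explained follows the Z-based pseudo-R2", {
  expect_equal(variance_explained(0, 0.1, 100), 0)
  expect_equal(variance_explained(1, 0.1, 1000), 100 / 1098)
  # strictly increasing in |Z| at fixed n
  z <- seq(0.5, 10, by = 0.5)
  r2 <- variance_explained(z * 0.1, 0.1, 500)
  expect_true(all(diff(r2) > 0))
  expect_error(variance_explained(1, 0.1, 3), "at least 4")
  # frequency-based alternative
  expect_equal(variance_explained(0.5, 0.1, 100, method = "frequency",
                                  eaf = 0.5), 2 * 0.5 * 0.5 * 0.25)
})

test_that("F statistic formula and domain checks", {
  expect_equal(f_statistic(0, 1000), 0)
  expect_equal(f_statistic(0.5, 102, k = 1), 1 * 100)
  expect_error(f_statistic(1, 1000), "\\[0, 1\\)")
  expect_error(f_statistic(0.5, 2, k = 1))
})

test_that("filters commute: any order gives the same pre-clumping set", {
  set.seed(5)
  rows <- lapply(1:40, function(i)
    assoc_row(paste0("rs", i),
              chrom = sample(c("1", "6"), 1),
              pos = sample(c(1e6, 2.6e7, 3.0e7, 1.51e6, 9e6), 1) + i,
              pval = 10^runif(1, -12, -4)))
  ss <- make_sumstats(rows)
  gene <- gene_annotation("P1", "G1", "6", 28e6, 28.1e6)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  apply_filter <- function(s, k) switch(k, cis_filter(s, gene),
                                        significance_filter(s), mhc_exclude(s))
  results <- lapply(perms, function(p) {
    s <- ss
    for (k in p) s <- apply_filter(s, k)
    sort(s$records$snp_id)
  })
  for (r in results[-1]) expect_equal(r, results[[1]])
})

test_that("select_instruments composes the filters and attaches diagnostics", {
  inst <- select_instruments(tiny_pqtl(), tiny_gene(),
                             identity_ld(c("rs1", "rs2", "rs3")))
  expect_s3_class(inst, "instrument_set")
  expect_equal(inst$n_snps, 3L)
  expect_equal(inst$records$r2_explained,
               variance_explained(inst$records$beta, inst$records$se, 7213))
  expect_equal(inst$records$f_stat,
               f_statistic(inst$records$r2_explained, 7213))

  # correlated significant SNPs collapse to the lowest p
  r2 <- matrix(0.9, 2, 2); diag(r2) <- 1
  two <- make_sumstats(list(assoc_row("rs1", pos = 1.5e6, pval = 1e-10),
                            assoc_row("rs2", pos = 1.51e6, pval = 1e-9)))
  inst2 <- select_instruments(two, tiny_gene(), ld_matrix(c("rs1", "rs2"), r2))
  expect_equal(inst2$n_snps, 1L)
  expect_equal(inst2$records$snp_id, "rs1")

  # only-MHC input leaves an empty set
  mhc_only <- make_sumstats(list(assoc_row("rs1", chrom = "6", pos = 30e6,
                                           pval = 1e-10)))
  gene6 <- gene_annotation("P2", "G2", "6", 30e6, 30.1e6)
  expect_equal(select_instruments(mhc_only, gene6,
                                  identity_ld("rs1"))$n_snps, 0L)
})
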