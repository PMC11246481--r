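test_that("simulated LD is block-exchangeable, symmetric, and PSD", {
  expect_equal(simulate_ld(6, 3, 0)$r2, diag(6), ignore_attr = TRUE)

  ld <- simulate_ld(10, 5, 0.9)
  within <- ld$r2[1:5, 1:5]
  expect_true(all(abs(within[upper.tri(within)] - 0.81) < 1e-12))
  expect_true(all(ld$r2[1:5, 6:10] == 0))

  ld2 <- simulate_ld(30, 7, 0.8)
  expect_equal(ld2$r2, t(ld2$r2))
  # the signed correlation (sqrt of r2 within blocks) must be PSD
  R <- sqrt(ld2$r2) * sign(ld2$r2)
  expect_true(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >
                -1e-10)
})

test_that("the same seed reproduces byte-identical study files", {
  cfg <- simulation_config(n_proteins = 2, snps_per_region = 20, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 6)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # a different seed changes the draws
  other <- simulate_study(simulation_config(n_proteins = 2,
                                            snps_per_region = 20, seed = 100))
  expect_false(identical(other$pqtl[[1]]$records$beta,
                         simulate_study(cfg)$pqtl[[1]]$records$beta))
})

test_that("a null pQTL region yields essentially no genome-wide hits", {
  hits <- 0L
  for (seed in 1:5) {
    cfg <- simulation_config(snps_per_region = 200, ld_rho = 0.6,
                             pqtl_effect_b = 0, seed = seed)
    ps <- simulate_pqtl(cfg)
    hits <- hits + sum(ps$records$pval < 5e-8)
  }
  expect_lte(hits, 2L)  # 1000 null SNPs in total
})

test_that("a planted causal pQTL with expected z = 10 is nearly always significant", {
  cfg <- simulation_config(snps_per_region = 30, ld_block_size = 5,
                           pqtl_effect_z = 10, seed = 123)
  set.seed(cfg$seed)
  hit <- logical(500)
  for (r in seq_along(hit)) {
    ps <- simulate_pqtl(cfg, reseed = FALSE)
    causal <- attr(ps, "truth")$causal_exp
    hit[r] <- ps$records$pval[causal] < 5e-8
  }
  expect_gte(mean(hit), 0.99)
})

test_that("observed causal-SNP effects are unbiased for the planted truth", {
  cfg <- simulation_config(snps_per_region = 20, ld_block_size = 5,
                           pqtl_effect_z = 10, seed = 321)
  set.seed(cfg$seed)
  n_rep <- 1000
  obs <- true <- se <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ps <- simulate_pqtl(cfg, reseed = FALSE)
    tr <- attr(ps, "truth")
    c1 <- tr$causal_exp
    obs[r] <- ps$records$beta[c1]
    true[r] <- tr$b_joint[c1]
    se[r] <- tr$se[c1]
  }
  mc_se <- sd(obs - true) / sqrt(n_rep)
  expect_lt(abs(mean(obs - true)), 3 * mc_se)
})

test_that("outcome SEs follow the effective-sample-size rule and truth is recorded", {
  cfg <- simulation_config(snps_per_region = 20, ld_block_size = 5, seed = 5,
                           shared_causal = FALSE)
  st <- simulate_study(cfg)
  os <- st$outcome
  f <- os$records$eaf
  neff <- 4 / (1 / cfg$n_cases + 1 / (cfg$n_outcome - cfg$n_cases))
  expect_equal(os$records$se, 1 / sqrt(2 * f * (1 - f) * neff))

  tr <- st$truth[[1]]
  expect_equal(tr$theta, 0.3)
  expect_false(tr$shared_causal)
  # distinct-causal configuration: outcome causal SNP differs from exposure's
  expect_false(any(tr$causal_snps_outcome %in% tr$causal_snps_exposure))
})

test_that("full-delta IVW intervals attain nominal coverage for a planted effect", {
  # With strong per-SNP outcome signals the SNP-exposure noise contributes
  # (z_out/z_x)^2 extra ratio variance, so coverage is checked with the
  # second-order delta SEs that include that term.
  cfg <- simulation_config(snps_per_region = 30, ld_block_size = 5,
                           n_causal = 3, causal_effect_theta = 0.3,
                           pqtl_effect_z = 10, seed = 888)
  set.seed(cfg$seed)
  cover <- logical(0)
  for (r in 1:600) {
    ps <- simulate_pqtl(cfg, reseed = FALSE)
    tr <- attr(ps, "truth")
    os <- simulate_outcome(cfg, tr)
    inst <- select_instruments(ps, tr$layout$gene,
                               ld_matrix(tr$layout$snp_ids, tr$R^2))
    if (inst$n_snps == 0) next
    keep <- match(inst$records$snp_id, ps$records$snp_id)
    sub <- ps; sub$records <- ps$records[keep, , drop = FALSE]
    harm <- harmonized_kept(harmonize(sub, os))
    if (nrow(harm) == 0) next
    est <- ivw(harm, second_order = TRUE)
    lo <- est$estimate - qnorm(0.975) * est$se
    hi <- est$estimate + qnorm(0.975) * est$se
    cover <- c(cover, lo <= 0.3 && 0.3 <= hi)
  }
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("the generator's Steiger premise holds: exposure R2 dominates", {
  cfg <- simulation_config(snps_per_region = 30, ld_block_size = 5,
                           causal_effect_theta = 0.3, seed = 777)
  set.seed(cfg$seed)
  ok <- logical(200)
  for (r in seq_along(ok)) {
    ps <- simulate_pqtl(cfg, reseed = FALSE)
    os <- simulate_outcome(cfg, attr(ps, "truth"))
    inst <- select_instruments(ps, attr(ps, "truth")$layout$gene,
                               ld_matrix(attr(ps, "truth")$layout$snp_ids,
                                         attr(ps, "truth")$R^2))
    if (inst$n_snps == 0) { ok[r] <- TRUE; next }
    st <- mr_steiger(inst, ps$meta, os$meta, os)
    ok[r] <- st$correct_direction
  }
  expect_gte(mean(ok), 0.99)
})
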