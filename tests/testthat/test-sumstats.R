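test_that("reading a delimited table yields validated records and a round-trip identity", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1",
                   POS = c(100, 200, 300), EA = c("A", "C", "G"),
                   OA = c("G", "T", "A"), EAF = c(0.2, 0.5, 0.8),
                   BETA = c(0.1, -0.2, 0.05), SE = c(0.02, 0.03, 0.01),
                   P = c(1e-8, 1e-10, 0.5), N = 1000, N_CASES = NA)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- trait_meta("prot", "continuous", n = 1000)
  ss <- read_sumstats(path, meta)
  expect_s3_class(ss, "sumstats")
  expect_equal(nrow(ss$records), 3L)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, out)
  back <- read_sumstats(out, meta)
  expect_equal(back$records, ss$records)
})

test_that("rows violating record invariants are dropped and tallied", {
  rows <- rbind(assoc_row("rs1"), assoc_row("rs2", se = 0),
                assoc_row("rs3", pval = 0), assoc_row("rs4", ea = "AT"),
                assoc_row("rs5", ea = "A", oa = "A"),
                assoc_row("rs6", eaf = 1.4), assoc_row("rs1", pos = 2e6))
  suppressMessages(ss <- sumstats(rows, trait_meta("p", "continuous", 100)))
  expect_equal(ss$records$snp_id, "rs1")
  tally <- attr(ss, "drop_tally")
  expect_equal(unname(tally["invalid_se"]), 1L)
  expect_equal(unname(tally["invalid_pval"]), 1L)
  expect_equal(unname(tally["invalid_alleles"]), 2L)
  expect_equal(unname(tally["invalid_eaf"]), 1L)
  expect_equal(unname(tally["duplicate_id"]), 1L)
})

test_that("missing mandatory columns and all-invalid files raise errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(SNP = "rs1", BETA = 0.1), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- trait_meta("p", "continuous", 100)
  expect_error(read_sumstats(path, meta), "missing mandatory column")

  bad <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = "rs1", CHR = "1", POS = 1, EA = "A", OA = "G",
                   EAF = 0.5, BETA = 0.1, SE = 0, P = 0.5, N = 100,
                   N_CASES = NA)
  write.table(df, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(read_sumstats(bad, meta)), "no valid rows")
})

test_that("column_map resolves dialect headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rsid = "rs1", chrom = "1", bp = 100, a1 = "A", a2 = "G",
                   freq = 0.2, b = 0.1, std_err = 0.02, pvalue = 1e-8,
                   samples = 1000)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- read_sumstats(path, trait_meta("p", "continuous", 1000),
                      column_map = c(rsid = "SNP", chrom = "CHR", bp = "POS",
                                     a1 = "EA", a2 = "OA", freq = "EAF",
                                     b = "BETA", std_err = "SE",
                                     pvalue = "P", samples = "N"))
  expect_equal(ss$records$snp_id, "rs1")
  expect_error(
    read_sumstats(path, trait_meta("p", "continuous", 1000),
                  column_map = c(nope = "SNP")),
    "not found")
})

test_that("harmonization aligns, flips, and drops as specified", {
  exp <- make_sumstats(list(
    assoc_row("rs_same", ea = "A", oa = "G", beta = 0.10, eaf = 0.2),
    assoc_row("rs_swap", ea = "A", oa = "G", beta = 0.10, eaf = 0.2),
    assoc_row("rs_pal_amb", ea = "A", oa = "T", beta = 0.10, eaf = 0.2),
    assoc_row("rs_pal_ok", ea = "A", oa = "T", beta = 0.10, eaf = 0.2),
    assoc_row("rs_mis", ea = "A", oa = "G", beta = 0.10, eaf = 0.2)))
  out <- make_sumstats(list(
    assoc_row("rs_same", ea = "A", oa = "G", beta = 0.05, eaf = 0.2),
    assoc_row("rs_swap", ea = "G", oa = "A", beta = 0.05, eaf = 0.8),
    assoc_row("rs_pal_amb", ea = "A", oa = "T", beta = 0.05, eaf = 0.51),
    assoc_row("rs_pal_ok", ea = "T", oa = "A", beta = 0.05, eaf = 0.85),
    assoc_row("rs_mis", ea = "C", oa = "T", beta = 0.05, eaf = 0.2)),
    trait_id = "out")
  h <- harmonize(exp, out, eaf_window = 0.08)
  h <- h[match(exp$records$snp_id, h$snp_id), ]

  expect_equal(h$dropped_reason,
               c("none", "none", "palindromic_ambiguous", "none",
                 "allele_mismatch"))
  expect_false(h$flipped[h$snp_id == "rs_same"])
  expect_equal(h$beta_out[h$snp_id == "rs_same"], 0.05)
  # swapped labels force a sign flip and frequency reflection
  expect_true(h$flipped[h$snp_id == "rs_swap"])
  expect_equal(h$beta_out[h$snp_id == "rs_swap"], -0.05)
  expect_equal(h$eaf_out[h$snp_id == "rs_swap"], 0.2)
  # palindromic outside the window aligns by frequency: 0.2 vs 0.85 disagree
  expect_true(h$flipped[h$snp_id == "rs_pal_ok"])
  expect_equal(h$beta_out[h$snp_id == "rs_pal_ok"], -0.05)
})

test_that("palindromic SNPs with missing EAF are ambiguous", {
  exp <- make_sumstats(list(assoc_row("rs1", ea = "C", oa = "G", eaf = 0.2)))
  out <- make_sumstats(list(assoc_row("rs1", ea = "C", oa = "G", eaf = NA)),
                       trait_id = "out")
  h <- harmonize(exp, out)
  expect_equal(h$dropped_reason, "palindromic_ambiguous")
})

test_that("harmonization is idempotent on already-aligned pairs", {
  exp <- tiny_pqtl()
  out <- exp
  out$meta <- trait_meta("out", "binary", n = 1000, n_cases = 100)
  out$records$beta <- out$records$beta * 0.3
  h <- harmonize(exp, out)
  expect_true(all(h$dropped_reason == "none"))
  expect_true(all(!h$flipped))
  expect_equal(h$beta_out, out$records$beta)
})

test_that("flipping outcome allele labels, betas and EAFs leaves harmonized effects invariant", {
  set.seed(7)
  exp <- make_sumstats(lapply(1:8, function(i)
    assoc_row(paste0("rs", i), pos = i * 1000,
              ea = sample(c("A", "C"), 1), oa = "G",
              beta = rnorm(1, 0, 0.05), eaf = runif(1, 0.1, 0.4))))
  out <- exp
  out$meta <- trait_meta("out", "binary", n = 1000, n_cases = 100)
  out$records$beta <- rnorm(8, 0, 0.05)
  out$records$pval <- 2 * pnorm(-abs(out$records$beta / out$records$se))

  flipped <- out
  flipped$records$effect_allele <- out$records$other_allele
  flipped$records$other_allele <- out$records$effect_allele
  flipped$records$beta <- -out$records$beta
  flipped$records$eaf <- 1 - out$records$eaf

  h1 <- harmonize(exp, out)
  h2 <- harmonize(exp, flipped)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$se_out, h1$se_out)
  expect_equal(h2$dropped_reason, h1$dropped_reason)
})

test_that("disjoint SNP sets harmonize to an empty result with a message", {
  exp <- make_sumstats(list(assoc_row("rs1")))
  out <- make_sumstats(list(assoc_row("rs2")), trait_id = "out")
  expect_message(h <- harmonize(exp, out), "no shared SNPs")
  expect_equal(nrow(h), 0L)
})
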