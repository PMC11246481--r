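# In-code builders for tiny summary-statistic fixtures.

assoc_row <- function(snp_id, pos = 1e6, chrom = "1", ea = "A", oa = "G",
                      eaf = 0.3, beta = 0.1, se = 0.02, pval = NULL,
                      n = 7213, n_cases = NA) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se, pval = pval,
             n = n, n_cases = n_cases, stringsAsFactors = FALSE)
}

make_sumstats <- function(rows, trait_id = "protein",
                          trait_type = "continuous", n = 7213,
                          n_cases = NA) {
  meta <- trait_meta(trait_id, trait_type, n = n, n_cases = n_cases)
  sumstats(do.call(rbind, rows), meta)
}

# three independent, significant cis SNPs near a gene at [1.50, 1.52] Mb
tiny_pqtl <- function() {
  make_sumstats(list(
    assoc_row("rs1", pos = 1490000, beta = 0.30, se = 0.02),
    assoc_row("rs2", pos = 1510000, beta = -0.25, se = 0.02),
    assoc_row("rs3", pos = 1530000, beta = 0.20, se = 0.02)))
}

tiny_gene <- function() gene_annotation("P1", "GENE1", "1", 1500000, 1520000)

identity_ld <- function(ids) ld_matrix(ids, diag(length(ids)))
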