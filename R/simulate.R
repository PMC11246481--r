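#' Configuration for the summary-statistic simulator
#'
#' Defines the shape of a simulated cis-MR study: one LD-structured cis
#' region per protein with planted causal pQTLs, a continuous exposure cohort
#' sized like a proteogenomic panel, and a heavily imbalanced case-control
#' outcome. Defaults emulate an ARIC-scale exposure (n = 7213) against a
#' FinnGen-scale basal-cell-carcinoma outcome (16,328 cases / 259,583
#' controls), a strong cis-pQTL (expected marginal |z| = 10 at the causal
#' variant, first-stage F around 100), and a causal effect of 0.3 log-odds
#' per SD (OR about 1.35).
#'
#' @param n_proteins Number of proteins (one cis region each).
#' @param snps_per_region SNPs per cis region.
#' @param ld_block_size SNPs per exchangeable LD block.
#' @param ld_rho Within-block correlation (in \[0, 1)); squared correlation is
#'   `ld_rho^2`.
#' @param n_exposure Exposure (pQTL) sample size.
#' @param n_outcome,n_cases Outcome GWAS total and case counts.
#' @param causal_effect_theta True causal effect, log-odds per SD of protein;
#'   scalar or one value per protein (0 = null protein).
#' @param pqtl_effect_b Per-allele causal pQTL effect in SD units; when `NA`
#'   (default) it is derived per causal SNP from `pqtl_effect_z`.
#' @param pqtl_effect_z Expected marginal z of the causal pQTL, used when
#'   `pqtl_effect_b` is `NA`.
#' @param n_causal Causal pQTLs per region (placed in distinct LD blocks).
#' @param shared_causal If `TRUE` the outcome's causal variants coincide with
#'   the exposure's (colocalizing); if `FALSE` they sit in different LD
#'   blocks (distinct signals).
#' @param pleiotropy_frac Fraction of SNPs given direct outcome effects
#'   bypassing the protein.
#' @param seed Integer seed; mandatory, so studies are reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 1, snps_per_region = 100,
                              ld_block_size = 10, ld_rho = 0.8,
                              n_exposure = 7213, n_outcome = 275911,
                              n_cases = 16328, causal_effect_theta = 0.3,
                              pqtl_effect_b = NA_real_, pqtl_effect_z = 10,
                              n_causal = 1, shared_causal = TRUE,
                              pleiotropy_frac = 0, seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_proteins >= 1, snps_per_region >= 2, ld_block_size >= 1,
            ld_rho >= 0, ld_rho < 1, n_exposure >= 4, n_cases < n_outcome,
            n_causal >= 1, pleiotropy_frac >= 0, pleiotropy_frac <= 1)
  theta <- rep_len(causal_effect_theta, n_proteins)
  structure(list(n_proteins = as.integer(n_proteins),
                 snps_per_region = as.integer(snps_per_region),
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 n_cases = as.integer(n_cases),
                 causal_effect_theta = theta,
                 pqtl_effect_b = pqtl_effect_b,
                 pqtl_effect_z = pqtl_effect_z,
                 n_causal = as.integer(n_causal),
                 shared_causal = isTRUE(shared_causal),
                 pleiotropy_frac = pleiotropy_frac,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# signed within-block exchangeable correlation matrix
sim_correlation <- function(n_snps, block_size, rho) {
  R <- diag(n_snps)
  if (rho > 0 && block_size > 1) {
    starts <- seq(1, n_snps, by = block_size)
    for (s in starts) {
      idx <- s:min(s + block_size - 1, n_snps)
      R[idx, idx] <- rho
      diag(R)[idx] <- 1
    }
  }
  R
}

#' Simulate a block-diagonal LD matrix
#'
#' Exchangeable correlation `rho` within consecutive blocks, zero across;
#' the stored squared correlations are `rho^2` off-diagonal within blocks.
#'
#' @param n_snps Number of SNPs.
#' @param block_size Block size.
#' @param rho Within-block correlation in \[0, 1).
#' @param snp_ids Optional identifiers (default `snp1..snpN`).
#' @return An [ld_matrix()].
#' @export
simulate_ld <- function(n_snps, block_size, rho, snp_ids = NULL) {
  stopifnot(rho >= 0, rho < 1)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(n_snps))
  ld_matrix(snp_ids, sim_correlation(n_snps, block_size, rho)^2)
}

region_layout <- function(cfg, protein) {
  m <- cfg$snps_per_region
  bs <- cfg$ld_block_size
  snp_ids <- sprintf("rs%d_%04d", protein, seq_len(m))
  pos <- 1400000 + 1000 * seq_len(m)
  chrom <- as.character(protein)
  gene <- gene_annotation(sprintf("P%03d", protein), sprintf("GENE%d", protein),
                          chrom, 1500000, 1520000)
  n_blocks <- ceiling(m / bs)
  # exposure causal variants in the first n_causal blocks (block centers);
  # distinct outcome variants shifted by half the block count
  block_center <- function(b) min(m, (b - 1) * bs + max(1, bs %/% 2))
  exp_blocks <- seq_len(min(cfg$n_causal, n_blocks))
  out_blocks <- ((exp_blocks - 1 + max(1, n_blocks %/% 2)) %% n_blocks) + 1
  list(chrom = chrom, pos = pos, snp_ids = snp_ids, gene = gene,
       causal_exp = vapply(exp_blocks, block_center, numeric(1)),
       causal_out = vapply(out_blocks, block_center, numeric(1)))
}

effective_n <- function(n, n_cases) {
  4 / (1 / n_cases + 1 / (n - n_cases))
}

mvn_draw <- function(mean, sd, L) {
  # L = chol(R); returns mean + diag(sd) %*% t(L) %*% z ~ N(mean, D R D)
  mean + sd * drop(crossprod(L, stats::rnorm(length(mean))))
}

assoc_frame <- function(layout, f, beta, se) {
  data.frame(snp_id = layout$snp_ids, chrom = layout$chrom, pos = layout$pos,
             effect_allele = "A", other_allele = "G", eaf = f,
             beta = beta, se = se,
             pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                         .Machine$double.xmin),
             n = NA_real_, n_cases = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate cis-pQTL summary statistics for one protein
#'
#' Draws allele frequencies uniform(0.05, 0.95), sets per-SNP standard errors
#' to `1/sqrt(2 f (1 - f) n_exposure)`, plants per-allele causal effects, and
#' draws observed marginal effects from a multivariate normal with mean
#' `R b_joint` (the LD projection of the joint effects) and covariance
#' `D R D` (`D = diag(se)`).
#'
#' @param cfg A [simulation_config()].
#' @param protein Protein index (drives region identifiers).
#' @param reseed Set the RNG from `cfg$seed` first (default `TRUE`; the
#'   study-level generator seeds once and passes `FALSE`).
#' @return A [sumstats()] for the protein, with a `truth` attribute (list:
#'   `layout`, `f`, `se`, `b_joint`, `R`, `L`, causal indices) consumed by
#'   [simulate_outcome()].
#' @export
simulate_pqtl <- function(cfg, protein = 1, reseed = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (reseed) set.seed(cfg$seed)
  layout <- region_layout(cfg, protein)
  m <- cfg$snps_per_region
  R <- sim_correlation(m, cfg$ld_block_size, cfg$ld_rho)
  L <- chol(R)
  f <- stats::runif(m, 0.05, 0.95)
  se <- 1 / sqrt(2 * f * (1 - f) * cfg$n_exposure)
  b_joint <- numeric(m)
  b <- if (is.na(cfg$pqtl_effect_b)) cfg$pqtl_effect_z * se[layout$causal_exp]
       else rep_len(cfg$pqtl_effect_b, length(layout$causal_exp))
  b_joint[layout$causal_exp] <- b
  beta <- mvn_draw(drop(R %*% b_joint), se, L)
  rec <- assoc_frame(layout, f, beta, se)
  rec$n <- cfg$n_exposure
  meta <- trait_meta(layout$gene$protein_id, "continuous", cfg$n_exposure,
                     source_label = "simulated pQTL")
  out <- sumstats(rec, meta)
  attr(out, "truth") <- list(layout = layout, f = f, se = se,
                             b_joint = b_joint, R = R, L = L,
                             causal_exp = layout$causal_exp,
                             causal_out = layout$causal_out)
  out
}

#' Simulate outcome GWAS summary statistics over a protein's cis region
#'
#' Per-SNP outcome log-odds means are `theta` times the true exposure joint
#' effects (projected through LD), placed at the exposure's causal variants
#' when `cfg$shared_causal` is `TRUE` and at distinct variants in other LD
#' blocks otherwise, plus optional direct (pleiotropic) effects on a random
#' fraction of SNPs. Standard errors use the effective sample size
#' `4 / (1/n_cases + 1/n_controls)` scaled by `2 f (1 - f)`.
#'
#' @param cfg A [simulation_config()].
#' @param pqtl_truth The `truth` attribute of a [simulate_pqtl()] result.
#' @param theta Causal effect used for this protein (default the config's
#'   first value).
#' @return A [sumstats()] for the outcome restricted to the region, with a
#'   `truth` attribute recording the outcome's causal indices and any
#'   pleiotropic SNPs.
#' @export
simulate_outcome <- function(cfg, pqtl_truth,
                             theta = cfg$causal_effect_theta[1]) {
  stopifnot(inherits(cfg, "simulation_config"), is.list(pqtl_truth))
  layout <- pqtl_truth$layout
  m <- cfg$snps_per_region
  f <- pqtl_truth$f
  se <- 1 / sqrt(2 * f * (1 - f) * effective_n(cfg$n_outcome, cfg$n_cases))
  g_joint <- numeric(m)
  if (theta != 0) {
    if (cfg$shared_causal) {
      causal <- pqtl_truth$causal_exp
      b_at <- pqtl_truth$b_joint[causal]
    } else {
      # plant the distinct signal at the same standardized strength the
      # exposure formula would give at that SNP
      causal <- pqtl_truth$causal_out
      b_at <- if (is.na(cfg$pqtl_effect_b))
        cfg$pqtl_effect_z * pqtl_truth$se[causal]
      else rep_len(cfg$pqtl_effect_b, length(causal))
    }
    g_joint[causal] <- theta * b_at
  }
  pleio_idx <- integer(0)
  if (cfg$pleiotropy_frac > 0) {
    pleio_idx <- which(stats::runif(m) < cfg$pleiotropy_frac)
    if (length(pleio_idx)) {
      b_ref <- if (is.na(cfg$pqtl_effect_b))
        cfg$pqtl_effect_z * mean(pqtl_truth$se) else cfg$pqtl_effect_b
      g_joint[pleio_idx] <- g_joint[pleio_idx] +
        stats::rnorm(length(pleio_idx), 0, 0.5 * abs(theta) * b_ref)
    }
  }
  beta <- mvn_draw(drop(pqtl_truth$R %*% g_joint), se, pqtl_truth$L)
  rec <- assoc_frame(layout, f, beta, se)
  rec$n <- cfg$n_outcome
  rec$n_cases <- cfg$n_cases
  meta <- trait_meta("outcome", "binary", cfg$n_outcome, cfg$n_cases,
                     source_label = "simulated GWAS")
  out <- sumstats(rec, meta)
  attr(out, "truth") <- list(causal_out = which(g_joint != 0),
                             pleiotropy = pleio_idx, theta = theta)
  out
}

#' Simulate a complete multi-protein study with known ground truth
#'
#' Seeds the RNG once from the config, then generates, per protein, a cis
#' region with LD, pQTL summary statistics, and the matching slice of the
#' outcome GWAS. The outcome records of all regions are concatenated into a
#' single genome-wide outcome trait.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `synthetic_study`: `pqtl` (named list of
#'   [sumstats()] per protein), `outcome` (one binary-trait [sumstats()]),
#'   `ld` (named list of [ld_matrix()]), `annotation` (named list of
#'   [gene_annotation()]), `truth` (named list per protein: causal SNP ids,
#'   true theta, shared/distinct flag), and `config`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  pqtl <- list(); ld <- list(); anno <- list(); truth <- list()
  outcome_rec <- vector("list", cfg$n_proteins)
  for (p in seq_len(cfg$n_proteins)) {
    ps <- simulate_pqtl(cfg, protein = p, reseed = FALSE)
    tr <- attr(ps, "truth")
    theta_p <- cfg$causal_effect_theta[p]
    os <- simulate_outcome(cfg, tr, theta = theta_p)
    id <- tr$layout$gene$protein_id
    pqtl[[id]] <- ps
    ld[[id]] <- ld_matrix(tr$layout$snp_ids, tr$R^2)
    anno[[id]] <- tr$layout$gene
    truth[[id]] <- list(
      causal_snps_exposure = tr$layout$snp_ids[tr$causal_exp],
      causal_snps_outcome = tr$layout$snp_ids[attr(os, "truth")$causal_out],
      theta = theta_p, shared_causal = cfg$shared_causal,
      pleiotropic_snps = tr$layout$snp_ids[attr(os, "truth")$pleiotropy])
    outcome_rec[[p]] <- os$records
  }
  outcome <- sumstats(do.call(rbind, outcome_rec),
                      trait_meta("outcome", "binary", cfg$n_outcome,
                                 cfg$n_cases, "simulated GWAS"))
  structure(list(pqtl = pqtl, outcome = outcome, ld = ld,
                 annotation = anno, truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d protein(s), %d SNPs/region, seed %d\n",
              x$config$n_proteins, x$config$snps_per_region, x$config$seed))
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' One pQTL TSV and one LD TSV per protein, a single outcome TSV, the gene
#' annotation TSV, and the ground truth as JSON. File contents are fully
#' determined by the config seed.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$pqtl)) {
    write_sumstats(study$pqtl[[id]], file.path(dir, paste0("pqtl_", id, ".tsv")))
    write_ld_matrix(study$ld[[id]], file.path(dir, paste0("ld_", id, ".tsv")))
  }
  write_sumstats(study$outcome, file.path(dir, "outcome.tsv"))
  anno <- do.call(rbind, lapply(study$annotation, function(g)
    data.frame(PROTEIN_ID = g$protein_id, GENE = g$gene_symbol, CHR = g$chrom,
               START = g$gene_start, END = g$gene_end)))
  utils::write.table(anno, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
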