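#' Wakefield log approximate Bayes factor
#'
#' Log ABF for a single association against the null, from the effect
#' estimate, its SE, and a normal prior with variance `prior_var` on the true
#' effect: `log ABF = 0.5 log(se^2 / (se^2 + W)) + 0.5 z^2 W / (se^2 + W)`
#' with `z = beta/se`.
#'
#' @param beta,se Effect estimate and standard error (vectorized; `se > 0`).
#' @param prior_var Prior effect variance W (> 0).
#' @return Log Bayes factor(s).
#' @export
log_abf <- function(beta, se, prior_var) {
  stopifnot(all(se > 0), prior_var > 0)
  v <- se^2
  z2 <- (beta / se)^2
  r <- prior_var / (v + prior_var)
  0.5 * log(1 - r) + 0.5 * z2 * r
}

#' A cis region prepared for colocalization
#'
#' Paired summary statistics for the same SNPs under two traits. The trait
#' types pick the default prior effect variances used by
#' [coloc_posteriors()].
#'
#' @param snp_ids SNP identifiers.
#' @param beta1,se1 Trait-1 (exposure) effects and SEs.
#' @param beta2,se2 Trait-2 (outcome) effects and SEs.
#' @param trait1_type,trait2_type `"continuous"` or `"binary"`.
#' @return An object of class `coloc_region`.
#' @export
coloc_region <- function(snp_ids, beta1, se1, beta2, se2,
                         trait1_type = "continuous", trait2_type = "binary") {
  n <- length(snp_ids)
  stopifnot(n >= 1, length(beta1) == n, length(se1) == n,
            length(beta2) == n, length(se2) == n,
            all(se1 > 0), all(se2 > 0))
  structure(list(snp_ids = as.character(snp_ids),
                 beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 trait1_type = match.arg(trait1_type, c("continuous", "binary")),
                 trait2_type = match.arg(trait2_type, c("continuous", "binary"))),
            class = "coloc_region")
}

#' Build a coloc region from two harmonized sumstats over shared SNPs
#'
#' @param exposure,outcome [sumstats()] objects.
#' @param snp_ids Optional subset of SNPs; default all shared.
#' @return A [coloc_region()] over the harmonized shared SNPs.
#' @export
coloc_region_from_sumstats <- function(exposure, outcome, snp_ids = NULL) {
  harm <- harmonized_kept(harmonize(exposure, outcome))
  if (!is.null(snp_ids)) harm <- harm[harm$snp_id %in% snp_ids, , drop = FALSE]
  if (nrow(harm) == 0L) stop("no shared SNPs for colocalization", call. = FALSE)
  coloc_region(harm$snp_id, harm$beta_exp, harm$se_exp,
               harm$beta_out, harm$se_out,
               exposure$meta$trait_type, outcome$meta$trait_type)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

default_prior_var <- function(trait_type) {
  if (trait_type == "binary") 0.2^2 else 0.15^2
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' Single-causal-variant Bayesian colocalization from per-SNP Wakefield ABFs.
#' The five hypotheses over a region are: H0 no causal variant for either
#' trait; H1/H2 a causal variant for trait 1/2 only; H3 distinct causal
#' variants; H4 one shared causal variant. With per-SNP ABFs `A1_i`, `A2_i`
#' the unnormalized posteriors are `H0 = 1`, `H1 = p1 sum_i A1_i`,
#' `H2 = p2 sum_j A2_j`, `H3 = p1 p2 (sum_i A1_i sum_j A2_j - sum_i A1_i
#' A2_i)`, `H4 = p12 sum_i A1_i A2_i`. All sums are taken in log space.
#'
#' @param region A [coloc_region()].
#' @param p1,p2 Prior probability a SNP is causal for trait 1 / trait 2
#'   (defaults 1e-4).
#' @param p12 Prior probability a SNP is causal for both traits (default
#'   1e-5).
#' @param W1,W2 Prior effect variances; defaults 0.15^2 for a continuous
#'   trait and 0.2^2 (log-odds) for a binary trait, by the region's trait
#'   types.
#' @return An object of class `coloc_result`: `pp` (named vector `H0`..`H4`
#'   summing to 1), `n_snps`, `priors`.
#' @export
coloc_posteriors <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             W1 = NULL, W2 = NULL) {
  stopifnot(inherits(region, "coloc_region"),
            p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1)
  if (is.null(W1)) W1 <- default_prior_var(region$trait1_type)
  if (is.null(W2)) W2 <- default_prior_var(region$trait2_type)
  l1 <- log_abf(region$beta1, region$se1, W1)
  l2 <- log_abf(region$beta2, region$se2, W2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lh <- c(H0 = 0,
          H1 = log(p1) + ls1,
          H2 = log(p2) + ls2,
          H3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12),
          H4 = log(p12) + ls12)
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  pp <- pmin(pmax(pp, 0), 1)
  structure(list(pp = pp, n_snps = length(region$snp_ids),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d SNPs; PP: %s\n", x$n_snps,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " ")))
  invisible(x)
}

#' Colocalization verdict
#'
#' Evidence for a shared causal variant when the posterior of H4 reaches the
#' threshold (inclusive; default 0.8).
#'
#' @param result A `coloc_result`.
#' @param threshold PPH4 threshold (default 0.8).
#' @return `TRUE`/`FALSE`.
#' @export
coloc_pass <- function(result, threshold = 0.8) {
  stopifnot(inherits(result, "coloc_result"))
  unname(result$pp["H4"]) >= threshold
}
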