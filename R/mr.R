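#' Wald ratio causal estimate from a single instrument
#'
#' The causal effect of the exposure on the outcome estimated from one SNP:
#' `estimate = by / bx`. The default standard error is the first-order delta
#' approximation `|sy / bx|`; the second-order form
#' `sqrt(sy^2/bx^2 + by^2 sx^2 / bx^4)` additionally propagates uncertainty in
#' the SNP-exposure effect.
#'
#' @param bx,sx SNP-exposure effect and SE.
#' @param by,sy SNP-outcome effect and SE.
#' @param second_order Use the second-order delta SE (default `FALSE`).
#' @return An object of class `mr_estimate` with `estimate`, `se`, `zscore`,
#'   `pval`, `n_snps`, `method`.
#' @export
wald_ratio <- function(bx, sx, by, sy, second_order = FALSE) {
  if (bx == 0) stop("degenerate instrument: bx = 0", call. = FALSE)
  est <- by / bx
  se <- if (second_order) sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4) else abs(sy / bx)
  mr_estimate(est, se, n_snps = 1L, method = "wald")
}

mr_estimate <- function(estimate, se, n_snps, method) {
  stopifnot(se > 0)
  z <- estimate / se
  structure(list(estimate = estimate, se = se, zscore = z,
                 pval = 2 * stats::pnorm(-abs(z)),
                 n_snps = as.integer(n_snps), method = method),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNP): beta = %.4f, se = %.4f, p = %.3g\n",
              x$method, x$n_snps, x$estimate, x$se, x$pval))
  invisible(x)
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect pooling of per-SNP Wald ratios `theta_i = by_i / bx_i` with
#' first-order SEs `sigma_i = |sy_i / bx_i|` and weights `1/sigma_i^2`. With a
#' single instrument this reduces exactly to [wald_ratio()]; it also equals
#' the slope of the zero-intercept regression of `by` on `bx` weighted by
#' `1/sy^2`.
#'
#' @param harm Data frame of harmonized pairs (columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`; e.g. [harmonized_kept()] output), or `NULL` when
#'   the effect vectors are passed directly.
#' @param bx,sx,by,sy Effect vectors, used when `harm` is `NULL`.
#' @param second_order Use second-order delta per-SNP SEs, which also
#'   propagate the SNP-exposure uncertainty (default `FALSE`, first-order).
#'   First-order intervals undercover when the per-SNP outcome signal is not
#'   small relative to the instrument strength.
#' @return An `mr_estimate` with `method = "ivw"` (or `"wald"` for one SNP).
#' @export
ivw <- function(harm = NULL, bx = NULL, sx = NULL, by = NULL, sy = NULL,
                second_order = FALSE) {
  if (!is.null(harm)) {
    bx <- harm$beta_exp; sx <- harm$se_exp
    by <- harm$beta_out; sy <- harm$se_out
  }
  ok <- bx != 0
  if (!any(ok)) stop("all instruments degenerate (bx = 0)", call. = FALSE)
  if (any(!ok)) message("ivw: dropping ", sum(!ok), " instrument(s) with bx = 0")
  sx <- rep_len(if (is.null(sx)) 0 else sx, length(bx))[ok]
  bx <- bx[ok]; by <- by[ok]; sy <- sy[ok]
  if (length(bx) == 1L) return(wald_ratio(bx, sx, by, sy, second_order))
  theta <- by / bx
  sigma <- if (second_order) sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
           else abs(sy / bx)
  w <- 1 / sigma^2
  est <- sum(w * theta) / sum(w)
  mr_estimate(est, 1 / sqrt(sum(w)), n_snps = length(bx), method = "ivw")
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_i (theta_i - theta_pooled)^2` with inverse-variance weights
#' around the fixed-effect pool; `Q ~ chi-square(k - 1)` under homogeneity.
#'
#' @param theta Per-instrument (or per-study) estimates.
#' @param sigma Their standard errors.
#' @return List with `q`, `df`, `pval`.
#' @export
cochran_q <- function(theta, sigma) {
  k <- length(theta)
  if (k < 2) stop("Cochran's Q requires at least 2 estimates", call. = FALSE)
  stopifnot(length(sigma) == k, all(sigma > 0))
  w <- 1 / sigma^2
  pooled <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - pooled)^2)
  df <- k - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Chi-square upper-tail p-value for a Q statistic
#' @param q Q statistic.
#' @param df Degrees of freedom.
#' @return Upper-tail p-value.
#' @export
q_pvalue <- function(q, df) stats::pchisq(q, df, lower.tail = FALSE)

#' Convert a log-odds estimate to an odds ratio with confidence interval
#'
#' @param est An `mr_estimate` (or any list with `estimate` and `se`).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `or`, `ci_low`, `ci_high`.
#' @export
to_or <- function(est, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(or = exp(est$estimate),
    ci_low = exp(est$estimate - z * est$se),
    ci_high = exp(est$estimate + z * est$se))
}

#' Recover a two-sided p-value from an odds ratio and its 95% CI
#'
#' Inverts normal-theory reporting: `se = (ln hi - ln lo) / (2 z)`,
#' `p = 2 Phi(-|ln or| / se)`.
#'
#' @param or_,ci_low,ci_high Odds ratio and confidence bounds,
#'   `0 < ci_low < or_ < ci_high` (vectorized).
#' @param conf Confidence level of the interval (default 0.95).
#' @return Two-sided p-value(s).
#' @export
p_from_or_ci <- function(or_, ci_low, ci_high, conf = 0.95) {
  if (any(!(ci_low < or_ & or_ < ci_high)) || any(ci_low <= 0))
    stop("require 0 < ci_low < or < ci_high", call. = FALSE)
  z_conf <- stats::qnorm(1 - (1 - conf) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z_conf)
  2 * stats::pnorm(-abs(log(or_) / se))
}

#' Standard error implied by an odds-ratio confidence interval
#' @inheritParams p_from_or_ci
#' @return Standard error on the log-OR scale.
#' @export
se_from_or_ci <- function(ci_low, ci_high, conf = 0.95) {
  z_conf <- stats::qnorm(1 - (1 - conf) / 2)
  (log(ci_high) - log(ci_low)) / (2 * z_conf)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment. The family size `m` may exceed the number of
#' p-values supplied, for screens where only a subset of the tested family is
#' carried forward.
#'
#' @param pvals Vector of p-values in (0, 1].
#' @param m Family size (default `length(pvals)`).
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals > 0 & pvals <= 1), m >= length(pvals))
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Full MR analysis of one protein-outcome pair
#'
#' Estimates the causal effect from harmonized instrument pairs (Wald ratio
#' for a single SNP, IVW otherwise), converts to an odds ratio, and attaches
#' Cochran's Q when two or more instruments are available.
#'
#' @param harm Harmonized pairs (kept rows) for the protein's instruments.
#' @param protein_id,outcome_id Identifiers for the output row.
#' @param conf Confidence level for the OR interval.
#' @return One-row data frame with columns `protein_id`, `outcome_id`,
#'   `method`, `n_snps`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `pval`,
#'   `q_stat`, `q_df`, `q_pval` (the Q columns are `NA` for single-SNP rows).
#' @export
mr_analyze <- function(harm, protein_id, outcome_id, conf = 0.95) {
  harm <- harm[harm$beta_exp != 0, , drop = FALSE]
  est <- ivw(harm)
  or <- to_or(est, conf)
  qs <- list(q = NA_real_, df = NA_integer_, pval = NA_real_)
  if (est$n_snps >= 2L) {
    theta <- harm$beta_out / harm$beta_exp
    sigma <- abs(harm$se_out / harm$beta_exp)
    qs <- cochran_q(theta, sigma)
  }
  data.frame(protein_id = protein_id, outcome_id = outcome_id,
             method = est$method, n_snps = est$n_snps,
             beta = est$estimate, se = est$se,
             or = unname(or["or"]), ci_low = unname(or["ci_low"]),
             ci_high = unname(or["ci_high"]), pval = est$pval,
             q_stat = qs$q, q_df = as.integer(qs$df), q_pval = qs$pval,
             stringsAsFactors = FALSE)
}
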