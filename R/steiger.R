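#' Steiger directionality test from summed variance explained
#'
#' Tests whether a set of instruments explains more variance in the exposure
#' than in the outcome, the signature of the assumed causal direction
#' (exposure -> outcome). The per-trait R-squared values are compared through
#' Fisher-transformed correlations with a two-sample z test:
#' `z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp - 3) + 1/(n_out - 3))`.
#'
#' @param r2_exposure,r2_outcome Total variance explained by the instruments
#'   in each trait, in \[0, 1).
#' @param n_exposure,n_outcome Sample sizes (> 3).
#' @return An object of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `correct_direction` (`r2_exposure > r2_outcome`), `steiger_pval`
#'   (two-sided).
#' @export
steiger_test <- function(r2_exposure, r2_outcome, n_exposure, n_outcome) {
  if (n_exposure <= 3 || n_outcome <= 3)
    stop("Steiger test requires sample sizes above 3", call. = FALSE)
  stopifnot(r2_exposure >= 0, r2_exposure < 1, r2_outcome >= 0, r2_outcome < 1)
  z <- (atanh(sqrt(r2_exposure)) - atanh(sqrt(r2_outcome))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  structure(list(r2_exposure = r2_exposure, r2_outcome = r2_outcome,
                 correct_direction = r2_exposure > r2_outcome,
                 steiger_pval = 2 * stats::pnorm(-abs(z))),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("<steiger_result> R2 exposure %.4g vs outcome %.4g: %s (p = %.3g)\n",
              x$r2_exposure, x$r2_outcome,
              if (x$correct_direction) "correct direction" else "reversed",
              x$steiger_pval))
  invisible(x)
}

#' Steiger filtering for an instrument set
#'
#' Sums the Z-score pseudo-R-squared (see [variance_explained()]) of the
#' instrument SNPs in the exposure and in the outcome, then applies
#' [steiger_test()]. For binary outcomes the pseudo-R-squared is taken on the
#' observed scale, a documented approximation.
#'
#' @param inst An [select_instruments()] result.
#' @param exposure_meta,outcome_meta [trait_meta()] for the two traits.
#' @param outcome A [sumstats()] holding the outcome associations of (at
#'   least) the instrument SNPs.
#' @return A `steiger_result`. Instrument SNPs missing from the outcome are
#'   dropped from both sums with a message.
#' @export
mr_steiger <- function(inst, exposure_meta, outcome_meta, outcome) {
  stopifnot(inherits(inst, "instrument_set"), inst$n_snps >= 1)
  orec <- outcome$records
  idx <- match(inst$records$snp_id, orec$snp_id)
  if (anyNA(idx)) {
    message("mr_steiger: ", sum(is.na(idx)),
            " instrument SNP(s) absent from outcome; dropped")
  }
  keep <- !is.na(idx)
  if (!any(keep)) stop("no instrument SNPs present in outcome", call. = FALSE)
  erec <- inst$records[keep, , drop = FALSE]
  orec <- orec[idx[keep], , drop = FALSE]
  cap <- function(x) min(x, 1 - 1e-12)
  r2_exp <- cap(sum(variance_explained(erec$beta, erec$se, exposure_meta$n)))
  r2_out <- cap(sum(variance_explained(orec$beta, orec$se, outcome_meta$n)))
  steiger_test(r2_exp, r2_out, exposure_meta$n, outcome_meta$n)
}
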