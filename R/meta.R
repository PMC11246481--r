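#' I-squared heterogeneity fraction
#'
#' Proportion of variability across estimates attributable to heterogeneity
#' rather than sampling error: `max(0, (Q - df) / Q)`.
#'
#' @param q Cochran's Q statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return Fraction in \[0, 1).
#' @export
i_squared <- function(q, df) {
  if (df < 1) stop("df must be at least 1", call. = FALSE)
  stopifnot(q >= 0)
  if (q <= 0) return(0)
  max(0, (q - df) / q)
}

#' Choose the meta-analysis model from I-squared
#'
#' Random effects iff I-squared strictly exceeds the threshold (default 50%);
#' ties go to fixed effect.
#'
#' @param i2 I-squared fraction in \[0, 1).
#' @param threshold Heterogeneity threshold (default 0.5).
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(i2, threshold = 0.5) {
  stopifnot(i2 >= 0, i2 < 1)
  if (i2 > threshold) "random" else "fixed"
}

meta_result <- function(pooled, se, q, df, i2, tau2, model, labels, conf) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(pooled_log_or = pooled, pooled_se = se,
                 pooled_or = exp(pooled),
                 ci_low = exp(pooled - z * se), ci_high = exp(pooled + z * se),
                 q = q, df = as.integer(df), i2 = i2, tau2 = tau2,
                 model = model,
                 pval = 2 * stats::pnorm(-abs(pooled / se)),
                 k = length(labels), labels = labels),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> %s effect, k = %d: OR %.4f (%.4f-%.4f), p = %.3g, I2 = %.2f%%\n",
    x$model, x$k, x$pooled_or, x$ci_low, x$ci_high, x$pval, 100 * x$i2))
  invisible(x)
}

#' Fixed-effect inverse-variance meta-analysis on the log-OR scale
#'
#' Pools study log-ORs with weights `1/se^2`; Cochran's Q, its degrees of
#' freedom, and I-squared are computed around the fixed-effect pool.
#'
#' @param log_or Study estimates on the log-odds scale.
#' @param se Their standard errors (> 0).
#' @param labels Optional study labels.
#' @param conf Confidence level (default 0.95).
#' @return A `meta_result` with `model = "fixed"` (`tau2 = 0`). With a single
#'   study the pool equals the input and Q is 0 at df 0 (I2 = 0).
#' @export
meta_fixed <- function(log_or, se, labels = NULL, conf = 0.95) {
  k <- length(log_or)
  stopifnot(k >= 1, length(se) == k, all(se > 0))
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  w <- 1 / se^2
  pooled <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - pooled)^2)
  df <- k - 1L
  i2 <- if (df >= 1) i_squared(q, df) else 0
  meta_result(pooled, 1 / sqrt(sum(w)), q, df, i2, tau2 = 0,
              model = "fixed", labels = labels, conf = conf)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` from the
#' fixed-effect Q, then inverse-variance pooling with weights
#' `1/(se^2 + tau2)`. Q, df and I-squared are reported from the fixed-effect
#' stage. With fewer than two studies it falls back to [meta_fixed()] with a
#' warning.
#'
#' @inheritParams meta_fixed
#' @return A `meta_result` with `model = "random"`.
#' @export
meta_random <- function(log_or, se, labels = NULL, conf = 0.95) {
  k <- length(log_or)
  if (k < 2) {
    warning("random-effects meta needs >= 2 studies; falling back to fixed")
    return(meta_fixed(log_or, se, labels, conf))
  }
  stopifnot(length(se) == k, all(se > 0))
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  fe <- meta_fixed(log_or, se, labels, conf)
  w <- 1 / se^2
  tau2 <- max(0, (fe$q - fe$df) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (se^2 + tau2)
  pooled <- sum(w_star * log_or) / sum(w_star)
  meta_result(pooled, 1 / sqrt(sum(w_star)), fe$q, fe$df, fe$i2, tau2,
              model = "random", labels = labels, conf = conf)
}

#' Meta-analysis with the I-squared model-selection rule
#'
#' Computes the fixed-effect pool, and switches to DerSimonian-Laird random
#' effects when I-squared exceeds `i2_threshold` (strictly; default 50%).
#'
#' @inheritParams meta_fixed
#' @param i2_threshold Heterogeneity threshold for the switch (default 0.5).
#' @return A `meta_result` whose `model` records the choice made.
#' @export
meta_auto <- function(log_or, se, labels = NULL, conf = 0.95,
                      i2_threshold = 0.5) {
  fe <- meta_fixed(log_or, se, labels, conf)
  if (fe$df >= 1 && select_model(fe$i2, i2_threshold) == "random")
    meta_random(log_or, se, labels, conf)
  else fe
}

#' Replication verdict from a meta-analysis
#'
#' A candidate replicates when the pooled replication estimate is significant
#' and directionally concordant with the discovery estimate.
#'
#' @param meta A `meta_result` over the replication combinations.
#' @param discovery_sign Sign of the discovery log-OR (+1/-1, or the log-OR
#'   itself).
#' @param alpha Significance level (default 0.05).
#' @return `TRUE`/`FALSE`.
#' @export
replication_pass <- function(meta, discovery_sign, alpha = 0.05) {
  stopifnot(inherits(meta, "meta_result"))
  meta$pval < alpha && sign(meta$pooled_log_or) == sign(discovery_sign)
}
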