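# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition, not from the package's code
# path.

# BH step-up by definition: q(i) = min_{j >= i} p_(j) * m / j, clipped at 1,
# mapped back to input order.
bh_oracle <- function(p, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(p)
  q <- numeric(k)
  for (i in seq_len(k)) q[i] <- min(pmin(1, ps[i:k] * m / (i:k)))
  out <- numeric(k)
  out[ord] <- q
  out
}

# Greedy clumping by definition, written against (p, pos) keys and an
# explicit survivor set.
clump_oracle <- function(snp_id, pval, pos, r2, threshold) {
  stopifnot(nrow(r2) == length(snp_id))
  dimnames(r2) <- list(snp_id, snp_id)
  remaining <- snp_id
  emitted <- character(0)
  while (length(remaining)) {
    keys <- data.frame(p = pval[match(remaining, snp_id)],
                       pos = pos[match(remaining, snp_id)])
    best <- remaining[order(keys$p, keys$pos)][1]
    emitted <- c(emitted, best)
    linked <- remaining[r2[best, remaining] >= threshold]
    remaining <- setdiff(remaining, union(best, linked))
  }
  emitted
}

# Exhaustive configuration enumeration for single-causal-variant
# colocalization: (c1, c2) ranges over {none, 1..n}^2 with priors p1, p2,
# p1*p2 or p12, and likelihood ratio ABF1[c1] * ABF2[c2].
coloc_enum_oracle <- function(beta1, se1, beta2, se2, W1, W2,
                              p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  abf1 <- exp(cismr::log_abf(beta1, se1, W1))
  abf2 <- exp(cismr::log_abf(beta2, se2, W2))
  n <- length(abf1)
  w <- c(H0 = 0, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (c1 in 0:n) for (c2 in 0:n) {
    lik <- (if (c1 > 0) abf1[c1] else 1) * (if (c2 > 0) abf2[c2] else 1)
    if (c1 == 0 && c2 == 0) w["H0"] <- w["H0"] + lik
    else if (c2 == 0) w["H1"] <- w["H1"] + p1 * lik
    else if (c1 == 0) w["H2"] <- w["H2"] + p2 * lik
    else if (c1 == c2) w["H4"] <- w["H4"] + p12 * lik
    else w["H3"] <- w["H3"] + p1 * p2 * lik
  }
  w / sum(w)
}
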