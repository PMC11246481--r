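#' Gene annotation for a protein
#'
#' Location of the gene encoding a measured protein; used to define the cis
#' region. Positions are 1-based and inclusive.
#'
#' @param protein_id,gene_symbol Identifiers.
#' @param chrom Chromosome (character, e.g. `"6"`).
#' @param gene_start,gene_end Gene bounds in base pairs, `gene_start <=
#'   gene_end`.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(protein_id, gene_symbol, chrom, gene_start, gene_end) {
  stopifnot(gene_start <= gene_end, gene_start >= 1)
  structure(list(protein_id = protein_id, gene_symbol = gene_symbol,
                 chrom = as.character(chrom),
                 gene_start = as.numeric(gene_start),
                 gene_end = as.numeric(gene_end)),
            class = "gene_annotation")
}

#' Read gene annotations from a TSV
#'
#' Expects columns `PROTEIN_ID, GENE, CHR, START, END`.
#'
#' @param path File path.
#' @return A named list of [gene_annotation()] objects keyed by protein id.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("PROTEIN_ID", "GENE", "CHR", "START", "END")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    gene_annotation(df$PROTEIN_ID[i], df$GENE[i], df$CHR[i],
                    df$START[i], df$END[i]))
  names(out) <- df$PROTEIN_ID
  out
}

#' LD matrix of squared correlations
#'
#' @param snp_ids Character vector of SNP identifiers.
#' @param r2 Square symmetric matrix of squared correlations in \[0, 1\] with
#'   unit diagonal, in the same order as `snp_ids`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12))
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1", call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from a TSV with SNP ids as header row and first column
#'
#' @param path File path.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  ld_matrix(rownames(df), as.matrix(df))
}

#' Write an LD matrix to TSV
#' @param ld An [ld_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- as.data.frame(ld$r2)
  utils::write.table(cbind(SNP = ld$snp_ids, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict summary statistics to the cis region of a gene
#'
#' Keeps SNPs on the gene's chromosome within `window_bp` of either gene
#' bound, i.e. positions in `[gene_start - window_bp, gene_end + window_bp]`.
#'
#' @param s A [sumstats()] object of pQTL associations.
#' @param gene A [gene_annotation()].
#' @param window_bp Flank size in base pairs (default 1 Mb).
#' @return A [sumstats()] restricted to the cis window (possibly empty).
#' @export
cis_filter <- function(s, gene, window_bp = 1e6) {
  stopifnot(inherits(s, "sumstats"), inherits(gene, "gene_annotation"))
  keep <- s$records$chrom == gene$chrom &
    s$records$pos >= gene$gene_start - window_bp &
    s$records$pos <= gene$gene_end + window_bp
  subset_sumstats(s, keep)
}

#' Keep genome-wide significant associations
#'
#' Retains SNPs with `pval` strictly below `alpha`.
#'
#' @param s A [sumstats()].
#' @param alpha Significance threshold (default 5e-8).
#' @return Filtered [sumstats()].
#' @export
significance_filter <- function(s, alpha = 5e-8) {
  stopifnot(inherits(s, "sumstats"))
  subset_sumstats(s, s$records$pval < alpha)
}

#' Exclude the MHC region
#'
#' Removes SNPs inside the major histocompatibility complex, by default
#' chromosome 6, 26--34 Mb (bounds inclusive). The MHC's extreme long-range
#' LD and pleiotropy make its associations unreliable instruments.
#'
#' @param s A [sumstats()].
#' @param chrom,start_bp,end_bp Exclusion zone (defaults `"6"`, 26e6, 34e6).
#' @return Filtered [sumstats()].
#' @export
mhc_exclude <- function(s, chrom = "6", start_bp = 26e6, end_bp = 34e6) {
  stopifnot(inherits(s, "sumstats"))
  inside <- s$records$chrom == chrom &
    s$records$pos >= start_bp & s$records$pos <= end_bp
  subset_sumstats(s, !inside)
}

subset_sumstats <- function(s, keep) {
  s$records <- s$records[keep, , drop = FALSE]
  rownames(s$records) <- NULL
  s
}

#' Greedy LD clumping
#'
#' Repeatedly selects the remaining SNP with the smallest p-value (ties broken
#' by smaller genomic position), emits it, and discards every remaining SNP in
#' LD (`r2 >= r2_threshold`) with any emitted SNP. The output is pairwise
#' independent at the threshold. SNPs absent from the LD matrix are treated as
#' independent of everything and reported in a message.
#'
#' @param s A [sumstats()].
#' @param ld An [ld_matrix()].
#' @param r2_threshold Squared-correlation threshold (default 0.001).
#' @return Filtered [sumstats()] of index SNPs.
#' @export
clump <- function(s, ld, r2_threshold = 0.001) {
  stopifnot(inherits(s, "sumstats"), inherits(ld, "ld_matrix"),
            r2_threshold > 0)
  rec <- s$records
  if (nrow(rec) <= 1L) return(s)
  missing_ld <- setdiff(rec$snp_id, ld$snp_ids)
  if (length(missing_ld))
    message("clump: ", length(missing_ld),
            " SNP(s) absent from LD matrix, treated as independent")
  ord <- order(rec$pval, rec$pos)
  alive <- rep(TRUE, nrow(rec))
  emitted <- character(0)
  for (i in ord) {
    if (!alive[i]) next
    id <- rec$snp_id[i]
    emitted <- c(emitted, id)
    if (id %in% ld$snp_ids) {
      r2row <- ld$r2[id, ]
      linked <- rec$snp_id %in% names(r2row)[r2row >= r2_threshold]
      alive[linked & rec$snp_id != id] <- FALSE
    }
    alive[i] <- FALSE  # emitted, no longer a candidate
  }
  subset_sumstats(s, s$records$snp_id %in% emitted)
}

#' Variance in a trait explained by one SNP
#'
#' Z-score-based pseudo-R-squared computed from summary statistics alone:
#' `R2 = Z^2 / (Z^2 + n - 2)` with `Z = beta/se`. For binary traits the same
#' quantity is applied on the observed scale, a documented approximation. An
#' allele-frequency-based alternative `2 f (1 - f) beta^2` is available via
#' `method = "frequency"` (assumes a unit-variance trait).
#'
#' @param beta,se Per-allele effect and its standard error (vectorized).
#' @param n Sample size (>= 4).
#' @param method `"zscore"` (default) or `"frequency"`.
#' @param eaf Effect-allele frequency, required for `method = "frequency"`.
#' @return Fraction(s) of variance explained.
#' @export
variance_explained <- function(beta, se, n, method = c("zscore", "frequency"),
                               eaf = NULL) {
  method <- match.arg(method)
  if (any(n < 4)) stop("sample size must be at least 4", call. = FALSE)
  if (method == "zscore") {
    z2 <- (beta / se)^2
    z2 / (z2 + n - 2)
  } else {
    if (is.null(eaf)) stop("frequency method requires `eaf`", call. = FALSE)
    pmin(2 * eaf * (1 - eaf) * beta^2, 1)
  }
}

#' First-stage F statistic from variance explained
#'
#' `F = (R2 / (1 - R2)) * ((n - k - 1) / k)` for `k` instruments; values above
#' ~10 conventionally indicate a non-weak instrument.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Sample size, `n > k + 1`.
#' @param k Number of instruments (default 1).
#' @return F statistic (vectorized over `r2`).
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0) || any(r2 >= 1)) stop("r2 must lie in [0, 1)", call. = FALSE)
  stopifnot(k >= 1, all(n > k + 1))
  (r2 / (1 - r2)) * ((n - k - 1) / k)
}

#' Select cis-pQTL instruments for one protein
#'
#' Applies, in order: cis-window restriction, genome-wide significance, MHC
#' exclusion, and greedy LD clumping; then attaches per-SNP variance explained
#' and F statistics. The three filters commute; clumping runs last.
#'
#' @param pqtl A [sumstats()] of pQTL associations for the protein.
#' @param gene The protein's [gene_annotation()].
#' @param ld An [ld_matrix()] covering the region.
#' @param window_bp Cis window (default 1e6).
#' @param alpha Significance threshold (default 5e-8).
#' @param r2_threshold Clumping threshold (default 0.001).
#' @param mhc List with `chrom`, `start_bp`, `end_bp` for the exclusion zone.
#' @return An object of class `instrument_set`: `protein_id`, `records` (the
#'   selected associations plus `r2_explained` and `f_stat` columns), and
#'   `n_snps`. Empty sets are returned as such so callers can skip the
#'   protein.
#' @export
select_instruments <- function(pqtl, gene, ld, window_bp = 1e6, alpha = 5e-8,
                               r2_threshold = 0.001,
                               mhc = list(chrom = "6", start_bp = 26e6,
                                          end_bp = 34e6)) {
  s <- cis_filter(pqtl, gene, window_bp)
  s <- significance_filter(s, alpha)
  s <- mhc_exclude(s, mhc$chrom, mhc$start_bp, mhc$end_bp)
  s <- clump(s, ld, r2_threshold)
  rec <- s$records
  if (nrow(rec)) {
    rec$r2_explained <- variance_explained(rec$beta, rec$se, pqtl$meta$n)
    rec$f_stat <- f_statistic(rec$r2_explained, pqtl$meta$n, k = 1)
  } else {
    rec$r2_explained <- numeric(0)
    rec$f_stat <- numeric(0)
  }
  structure(list(protein_id = gene$protein_id, records = rec,
                 n_snps = nrow(rec)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instrument(s)\n", x$protein_id, x$n_snps))
  invisible(x)
}
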