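#' Trait metadata
#'
#' Describes the trait behind a set of summary statistics: a stable
#' identifier, whether the trait is continuous (e.g. a plasma protein level in
#' SD units) or binary (a disease, effects on the log-odds scale), and the
#' sample size(s) the per-SNP associations were estimated in.
#'
#' @param trait_id Character scalar identifying the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n Total sample size.
#' @param n_cases Number of cases; required for binary traits and must not
#'   exceed `n`.
#' @param source_label Free-text provenance label (cohort/platform).
#'
#' @return An object of class `trait_meta`.
#' @export
#' @examples
#' trait_meta("BCC", "binary", n = 275911, n_cases = 16328)
trait_meta <- function(trait_id, trait_type = c("continuous", "binary"),
                       n, n_cases = NA_integer_, source_label = "") {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L,
            is.numeric(n), length(n) == 1L, n >= 1)
  if (trait_type == "binary") {
    if (is.na(n_cases)) stop("binary traits require `n_cases`", call. = FALSE)
    if (n_cases > n) stop("`n_cases` must not exceed `n`", call. = FALSE)
  }
  structure(list(trait_id = trait_id, trait_type = trait_type,
                 n = as.integer(n), n_cases = as.integer(n_cases),
                 source_label = source_label),
            class = "trait_meta")
}

#' @export
print.trait_meta <- function(x, ...) {
  cat(sprintf("<trait_meta> %s (%s), n = %d", x$trait_id, x$trait_type, x$n))
  if (!is.na(x$n_cases)) cat(sprintf(" (%d cases)", x$n_cases))
  cat("\n")
  invisible(x)
}

# canonical per-SNP association columns, in storage order
.assoc_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n", "n_cases")

# canonical TSV headers <-> internal column names
.tsv_header <- c(SNP = "snp_id", CHR = "chrom", POS = "pos", EA = "effect_allele",
                 OA = "other_allele", EAF = "eaf", BETA = "beta", SE = "se",
                 P = "pval", N = "n", N_CASES = "n_cases")

#' Validate per-SNP association records
#'
#' Checks each row of a data frame of per-SNP associations against the record
#' invariants (positive SE, p in (0, 1], EAF in \[0, 1\] when present, single-
#' nucleotide A/C/G/T alleles with effect and other allele distinct, unique
#' SNP identifiers) and drops offending rows.
#'
#' @param df Data frame with the canonical columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `n_cases`.
#' @return A list with `records` (the clean data frame) and `tally` (named
#'   integer vector counting rows dropped per reason).
#' @export
validate_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(setdiff(.assoc_cols, c("eaf", "n_cases")), names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.null(df$eaf)) df$eaf <- NA_real_
  if (is.null(df$n_cases)) df$n_cases <- NA_integer_
  df <- df[.assoc_cols]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_cases"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  bases <- c("A", "C", "G", "T")
  bad <- list(
    invalid_se      = !is.finite(df$se) | df$se <= 0,
    invalid_pval    = !is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
    invalid_eaf     = !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1),
    invalid_alleles = !(df$effect_allele %in% bases) |
                      !(df$other_allele %in% bases) |
                      df$effect_allele == df$other_allele,
    invalid_beta    = !is.finite(df$beta)
  )
  drop <- rep(FALSE, nrow(df))
  tally <- integer(0)
  for (reason in names(bad)) {
    hit <- bad[[reason]] & !drop
    if (any(hit)) tally[reason] <- sum(hit)
    drop <- drop | bad[[reason]]
  }
  dup <- duplicated(df$snp_id) & !drop
  if (any(dup)) tally["duplicate_id"] <- sum(dup)
  drop <- drop | dup
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, tally = tally)
}

#' Summary statistics for one trait
#'
#' Bundles a validated table of per-SNP associations with its [trait_meta()].
#'
#' @param records Data frame of per-SNP associations (canonical columns; see
#'   [validate_records()]). Rows violating the record invariants are dropped
#'   and counted in the `drop_tally` attribute.
#' @param meta A [trait_meta()] object.
#' @return An object of class `sumstats`: a list with elements `meta` and
#'   `records`.
#' @export
sumstats <- function(records, meta) {
  stopifnot(inherits(meta, "trait_meta"))
  v <- validate_records(records)
  if (length(v$tally))
    message("sumstats: dropped ", sum(v$tally), " invalid row(s) [",
            paste(names(v$tally), v$tally, sep = ":", collapse = ", "), "]")
  structure(list(meta = meta, records = v$records),
            class = "sumstats", drop_tally = v$tally)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s: %d SNP record(s)\n",
              x$meta$trait_id, nrow(x$records)))
  invisible(x)
}

#' Read summary statistics from a delimited file
#'
#' Reads a TSV (or other delimited) table of per-SNP associations. The
#' canonical header set is `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N,
#' N_CASES`; other dialects are supported through `column_map`. Rows violating
#' the record invariants are dropped and tallied (see [validate_records()]).
#'
#' @param path File path.
#' @param meta A [trait_meta()] for the trait the file describes.
#' @param column_map Named character vector mapping file headers to canonical
#'   headers, e.g. `c(rsid = "SNP", pvalue = "P")`. Headers already canonical
#'   need no entry.
#' @param sep Field separator (default tab).
#' @return A [sumstats()] object; the tally of dropped rows is available as
#'   `attr(x, "drop_tally")`.
#' @export
read_sumstats <- function(path, meta, column_map = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(df))
    if (anyNA(idx))
      stop("column_map names not found in file header: ",
           paste(names(column_map)[is.na(idx)], collapse = ", "), call. = FALSE)
    names(df)[idx] <- unname(column_map)
  }
  known <- names(df) %in% names(.tsv_header)
  missing_cols <- setdiff(setdiff(names(.tsv_header), c("EAF", "N_CASES")),
                          names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[known]
  names(df) <- unname(.tsv_header[names(df)])
  out <- sumstats(df, meta)
  if (nrow(out$records) == 0L)
    stop("no valid rows in ", path, call. = FALSE)
  out
}

#' Write summary statistics to a TSV file
#'
#' Writes the canonical header set understood by [read_sumstats()]; the
#' round-trip reproduces the records exactly.
#'
#' @param x A [sumstats()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  df <- x$records
  names(df) <- names(.tsv_header)[match(names(df), unname(.tsv_header))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) unname(.complement[ea] == oa)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effect alleles to the exposure's for every SNP shared by the
#' two traits. Identically-labelled alleles are kept as-is; swapped labels
#' flip the outcome beta's sign (and reflect the effect-allele frequency);
#' palindromic SNPs (A/T or C/G) with an effect-allele frequency inside the
#' ambiguity window around 0.5 — or missing — are dropped as strand-ambiguous,
#' while palindromic SNPs outside the window are aligned by frequency;
#' any other allele combination is dropped as a mismatch.
#'
#' @param exposure,outcome [sumstats()] objects.
#' @param eaf_window Half-width of the palindromic ambiguity window around
#'   0.5 (default 0.08, i.e. EAF in \[0.42, 0.58\] is ambiguous).
#' @return A data frame with one row per shared SNP: `snp_id`, exposure and
#'   outcome `beta`/`se`/`pval`, `eaf_exp`, `flipped`, and `dropped_reason`
#'   (`"none"`, `"palindromic_ambiguous"`, or `"allele_mismatch"`). Rows with
#'   `dropped_reason != "none"` must be excluded from estimation; the
#'   convenience of doing so is left to callers so drop reasons stay auditable.
#' @export
harmonize <- function(exposure, outcome, eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"),
            eaf_window >= 0, eaf_window < 0.5)
  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$snp_id, ou$snp_id)
  if (length(shared) == 0L) {
    message("harmonize: no shared SNPs between ", exposure$meta$trait_id,
            " and ", outcome$meta$trait_id)
  }
  ex <- ex[match(shared, ex$snp_id), , drop = FALSE]
  ou <- ou[match(shared, ou$snp_id), , drop = FALSE]

  n <- length(shared)
  flipped <- logical(n)
  reason <- rep("none", n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  # palindromic: labels cannot distinguish strand flip from allele swap; the
  # outcome must at least carry the same base pair
  pal_same_pair <- pal & (same | swapped |
    (ou$effect_allele == .complement[ex$effect_allele] &
       ou$other_allele == .complement[ex$other_allele]))

  for (i in seq_len(n)) {
    if (pal[i]) {
      if (!pal_same_pair[i]) { reason[i] <- "allele_mismatch"; next }
      ambiguous <- is.na(ex$eaf[i]) || is.na(ou$eaf[i]) ||
        abs(ex$eaf[i] - 0.5) <= eaf_window || abs(ou$eaf[i] - 0.5) <= eaf_window
      if (ambiguous) { reason[i] <- "palindromic_ambiguous"; next }
      # frequency alignment: minor/major status identifies the shared allele
      if (sign(ex$eaf[i] - 0.5) != sign(ou$eaf[i] - 0.5)) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        flipped[i] <- TRUE
      }
    } else if (same[i]) {
      # aligned already
    } else if (swapped[i]) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      flipped[i] <- TRUE
    } else {
      reason[i] <- "allele_mismatch"
    }
  }

  data.frame(snp_id = shared,
             beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval,
             eaf_exp = ex$eaf,
             beta_out = beta_out, se_out = ou$se, pval_out = ou$pval,
             eaf_out = eaf_out,
             flipped = flipped, dropped_reason = reason,
             stringsAsFactors = FALSE)
}

#' Keep only usable harmonized pairs
#'
#' @param harm Output of [harmonize()].
#' @return The rows with `dropped_reason == "none"`.
#' @export
harmonized_kept <- function(harm) {
  harm[harm$dropped_reason == "none", , drop = FALSE]
}
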