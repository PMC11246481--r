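#' Pipeline configuration
#'
#' Central registry of every threshold the pipeline stages use, with the
#' study defaults: cis window 1 Mb, genome-wide significance 5e-8, clumping
#' r-squared 0.001, MHC exclusion chr6:26-34 Mb, FDR 0.05, heterogeneity
#' I-squared switch at 50%, colocalization priors p1 = p2 = 1e-4 /
#' p12 = 1e-5 with PPH4 threshold 0.8, palindromic ambiguity window 0.08.
#' Configs round-trip through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param window_bp Cis window in bp.
#' @param alpha Instrument significance threshold.
#' @param clump_r2 LD clumping r-squared threshold.
#' @param mhc_chrom,mhc_start,mhc_end MHC exclusion zone.
#' @param eaf_window Palindromic ambiguity half-window.
#' @param fdr_alpha FDR significance level.
#' @param fdr_family_m Family size for BH adjustment; `NA` means the number
#'   of proteins actually tested per outcome.
#' @param steiger_alpha FDR level for the Steiger p-value.
#' @param i2_threshold I-squared threshold for random effects.
#' @param replication_alpha Significance level for replication pass.
#' @param coloc_p1,coloc_p2,coloc_p12 Colocalization priors.
#' @param pph4_threshold Inclusive PPH4 threshold for [coloc_pass()].
#' @param tier1_pph4 Strict PPH4 threshold used by the tier rules.
#' @param conf Confidence level for intervals.
#' @param seed Seed recorded into run manifests.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(window_bp = 1e6, alpha = 5e-8, clump_r2 = 0.001,
                            mhc_chrom = "6", mhc_start = 26e6, mhc_end = 34e6,
                            eaf_window = 0.08, fdr_alpha = 0.05,
                            fdr_family_m = NA_integer_, steiger_alpha = 0.05,
                            i2_threshold = 0.5, replication_alpha = 0.05,
                            coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
                            pph4_threshold = 0.8, tier1_pph4 = 0.8,
                            conf = 0.95, seed = 1L) {
  cfg <- list(window_bp = window_bp, alpha = alpha, clump_r2 = clump_r2,
              mhc_chrom = as.character(mhc_chrom), mhc_start = mhc_start,
              mhc_end = mhc_end, eaf_window = eaf_window,
              fdr_alpha = fdr_alpha, fdr_family_m = fdr_family_m,
              steiger_alpha = steiger_alpha, i2_threshold = i2_threshold,
              replication_alpha = replication_alpha,
              coloc_p1 = coloc_p1, coloc_p2 = coloc_p2, coloc_p12 = coloc_p12,
              pph4_threshold = pph4_threshold, tier1_pph4 = tier1_pph4,
              conf = conf, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Serialize / restore a pipeline configuration (YAML)
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Hash of a pipeline configuration
#' @param cfg A [pipeline_config()].
#' @return Character hash; equal configs hash equal.
#' @export
config_hash <- function(cfg) rlang::hash(unclass(cfg))

#' Discovery-stage proteome-wide MR
#'
#' For every protein: select cis instruments ([select_instruments()]),
#' harmonize against the outcome, estimate the causal effect (Wald ratio or
#' IVW with Cochran's Q), and run Steiger filtering; then adjust p-values by
#' Benjamini-Hochberg across the proteins tested for this outcome (family
#' size `cfg$fdr_family_m` when set). Proteins with no surviving instruments
#' or no harmonizable SNPs are skipped with a message and counted.
#'
#' @param pqtl Named list of [sumstats()], one per protein.
#' @param outcome A [sumstats()] for the outcome trait.
#' @param annotation Named list of [gene_annotation()] keyed like `pqtl`.
#' @param ld Named list of [ld_matrix()] keyed like `pqtl`.
#' @param cfg A [pipeline_config()].
#' @return A data frame with one row per analyzable protein: the
#'   [mr_analyze()] columns plus `fdr_q`, `log_or`, `neg_log10_p`,
#'   `significant` (FDR q below `cfg$fdr_alpha`), `r2_exp`, `r2_out`,
#'   `steiger_pval`, `steiger_pass` (correct direction and Steiger FDR below
#'   `cfg$steiger_alpha`), `f_stat_min`. Attribute `skipped` tallies skip
#'   reasons.
#' @export
run_discovery <- function(pqtl, outcome, annotation, ld, cfg = pipeline_config()) {
  stopifnot(inherits(outcome, "sumstats"), inherits(cfg, "pipeline_config"))
  mhc <- list(chrom = cfg$mhc_chrom, start_bp = cfg$mhc_start,
              end_bp = cfg$mhc_end)
  rows <- list()
  skipped <- c(no_instruments = 0L, no_harmonized = 0L)
  for (id in names(pqtl)) {
    inst <- select_instruments(pqtl[[id]], annotation[[id]], ld[[id]],
                               window_bp = cfg$window_bp, alpha = cfg$alpha,
                               r2_threshold = cfg$clump_r2, mhc = mhc)
    if (inst$n_snps == 0L) {
      message("run_discovery: ", id, " skipped (no instruments)")
      skipped["no_instruments"] <- skipped["no_instruments"] + 1L
      next
    }
    inst_ss <- pqtl[[id]]
    inst_ss$records <- inst$records[names(inst_ss$records)]
    harm <- harmonized_kept(harmonize(inst_ss, outcome, cfg$eaf_window))
    harm <- harm[harm$beta_exp != 0, , drop = FALSE]
    if (nrow(harm) == 0L) {
      message("run_discovery: ", id, " skipped (no harmonizable instruments)")
      skipped["no_harmonized"] <- skipped["no_harmonized"] + 1L
      next
    }
    res <- mr_analyze(harm, id, outcome$meta$trait_id, conf = cfg$conf)
    used <- inst
    used$records <- inst$records[inst$records$snp_id %in% harm$snp_id, ,
                                 drop = FALSE]
    used$n_snps <- nrow(used$records)
    st <- mr_steiger(used, pqtl[[id]]$meta, outcome$meta, outcome)
    res$r2_exp <- st$r2_exposure
    res$r2_out <- st$r2_outcome
    res$steiger_pval <- st$steiger_pval
    res$correct_direction <- st$correct_direction
    res$f_stat_min <- min(used$records$f_stat)
    rows[[id]] <- res
  }
  if (length(rows) == 0L) {
    out <- data.frame()
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- if (is.na(cfg$fdr_family_m)) nrow(out) else max(cfg$fdr_family_m, nrow(out))
  out$fdr_q <- bh_fdr(out$pval, m = m)
  steiger_q <- bh_fdr(out$steiger_pval, m = m)
  out$steiger_pass <- out$correct_direction & steiger_q < cfg$steiger_alpha
  out$log_or <- out$beta
  out$neg_log10_p <- -log10(out$pval)
  out$significant <- out$fdr_q < cfg$fdr_alpha
  attr(out, "skipped") <- skipped
  out
}

#' Full pipeline: discovery, replication meta-analysis, colocalization,
#' grading
#'
#' Runs [run_discovery()] on the discovery study; for each FDR-significant,
#' Steiger-surviving protein, re-estimates the effect in every replication
#' study pair, pools discovery plus replications with the I-squared
#' model-selection rule ([meta_auto()]), colocalizes the protein's cis region
#' against the discovery outcome, merges external evidence flags, and grades
#' the target. Candidates without any replication estimate are graded
#' Excluded.
#'
#' @param discovery List with elements `pqtl`, `outcome`, `annotation`, `ld`
#'   (as for [run_discovery()]); a `synthetic_study` works directly.
#' @param replications List of such lists (possibly empty) providing
#'   independent exposure/outcome combinations.
#' @param evidence_flags Optional data frame (see [read_evidence_flags()])
#'   with per-pair `CAUSE_PASS`, `TWAS_PASS`, `PPI_DRUG_LINK`; missing pairs
#'   or columns default to `FALSE` with a message.
#' @param cfg A [pipeline_config()].
#' @return A list of class `cismr_report`: `discovery` (full table), `meta`
#'   (per-candidate pooled results), `coloc` (per-candidate posteriors),
#'   `grading` ([build_report()] output), and `manifest` (config hash, seed,
#'   stage counts).
#' @export
run_full <- function(discovery, replications = list(), evidence_flags = NULL,
                     cfg = pipeline_config()) {
  disc <- run_discovery(discovery$pqtl, discovery$outcome,
                        discovery$annotation, discovery$ld, cfg)
  candidates <- if (nrow(disc)) disc[disc$significant & disc$steiger_pass, ,
                                     drop = FALSE] else disc
  meta_rows <- list(); coloc_rows <- list(); evidence <- list()
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$protein_id[i]
    disc_row <- candidates[i, ]
    # replication estimates for this protein across all provided combinations
    rep_logor <- numeric(0); rep_se <- numeric(0); rep_labels <- character(0)
    for (j in seq_along(replications)) {
      rep <- replications[[j]]
      if (!id %in% names(rep$pqtl)) next
      rres <- tryCatch(
        run_discovery(rep$pqtl[id], rep$outcome, rep$annotation[id],
                      rep$ld[id], cfg),
        error = function(e) data.frame())
      if (!nrow(rres)) next
      rep_logor <- c(rep_logor, rres$beta)
      rep_se <- c(rep_se, rres$se)
      rep_labels <- c(rep_labels, paste0("replication", j))
    }
    replication_available <- length(rep_logor) > 0
    rep_ok <- FALSE
    if (replication_available) {
      meta <- meta_auto(c(disc_row$beta, rep_logor), c(disc_row$se, rep_se),
                        labels = c("discovery", rep_labels), conf = cfg$conf,
                        i2_threshold = cfg$i2_threshold)
      rep_meta <- meta_auto(rep_logor, rep_se, labels = rep_labels,
                            conf = cfg$conf, i2_threshold = cfg$i2_threshold)
      rep_ok <- replication_pass(rep_meta, disc_row$beta,
                                 alpha = cfg$replication_alpha)
      meta_rows[[id]] <- data.frame(
        protein_id = id, k = meta$k, pooled_or = meta$pooled_or,
        ci_low = meta$ci_low, ci_high = meta$ci_high, pval = meta$pval,
        q = meta$q, i2 = meta$i2, model = meta$model,
        replication_pooled_or = rep_meta$pooled_or,
        replication_pval = rep_meta$pval, replication_pass = rep_ok,
        stringsAsFactors = FALSE)
    }
    region <- coloc_region_from_sumstats(discovery$pqtl[[id]],
                                         discovery$outcome)
    cres <- coloc_posteriors(region, p1 = cfg$coloc_p1, p2 = cfg$coloc_p2,
                             p12 = cfg$coloc_p12)
    pph4 <- unname(cres$pp["H4"])
    coloc_rows[[id]] <- data.frame(
      protein_id = id, n_snps = cres$n_snps,
      pph0 = unname(cres$pp["H0"]), pph1 = unname(cres$pp["H1"]),
      pph2 = unname(cres$pp["H2"]), pph3 = unname(cres$pp["H3"]),
      pph4 = pph4, coloc_pass = pph4 >= cfg$pph4_threshold,
      stringsAsFactors = FALSE)
    flags <- lookup_flags(evidence_flags, id, disc_row$outcome_id)
    evidence[[id]] <- evidence_record(
      id, disc_row$outcome_id,
      discovery_pass = disc_row$fdr_q < cfg$fdr_alpha,
      replication_available = replication_available,
      replication_pass = rep_ok,
      cause_pass = flags$cause, pph4 = pph4,
      coloc_pass = pph4 >= cfg$pph4_threshold,
      twas_pass = flags$twas, steiger_pass = disc_row$steiger_pass,
      ppi_drug_link = flags$ppi)
  }
  grading <- build_report(evidence, tier1_pph4 = cfg$tier1_pph4)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   n_proteins = length(discovery$pqtl),
                   n_tested = nrow(disc),
                   n_significant = if (nrow(disc)) sum(disc$significant) else 0L,
                   n_candidates = nrow(candidates),
                   tier_counts = as.list(grading$summary))
  structure(list(discovery = disc,
                 meta = if (length(meta_rows)) do.call(rbind, meta_rows)
                        else data.frame(),
                 coloc = if (length(coloc_rows)) do.call(rbind, coloc_rows)
                         else data.frame(),
                 grading = grading, manifest = manifest),
            class = "cismr_report")
}

lookup_flags <- function(evidence_flags, protein_id, outcome_id) {
  default <- list(cause = FALSE, twas = FALSE, ppi = FALSE)
  if (is.null(evidence_flags)) {
    message("run_full: no evidence flags for ", protein_id,
            "; CAUSE/TWAS/PPI set to FALSE")
    return(default)
  }
  hit <- evidence_flags$PROTEIN_ID == protein_id &
    evidence_flags$OUTCOME_ID == outcome_id
  if (!any(hit)) {
    message("run_full: no evidence flags for ", protein_id,
            "; CAUSE/TWAS/PPI set to FALSE")
    return(default)
  }
  row <- evidence_flags[which(hit)[1], ]
  list(cause = isTRUE(row$CAUSE_PASS), twas = isTRUE(row$TWAS_PASS),
       ppi = isTRUE(row$PPI_DRUG_LINK))
}

#' @export
print.cismr_report <- function(x, ...) {
  cat(sprintf("<cismr_report> %d tested, %d significant, %d graded\n",
              x$manifest$n_tested, x$manifest$n_significant,
              nrow(x$grading$table)))
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits `discovery.tsv`, `meta.tsv`, `coloc.tsv`, `grading.tsv`, and
#' `manifest.json` under `dir`.
#'
#' @param report A [run_full()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cismr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$discovery, "discovery.tsv")
  wt(report$meta, "meta.tsv")
  wt(report$coloc, "coloc.tsv")
  wt(report$grading$table, "grading.tsv")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
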