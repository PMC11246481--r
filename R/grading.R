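#' Evidence record for one protein-outcome pair
#'
#' Collects the per-stream verdicts that feed tier grading: discovery FDR
#' significance, replication availability and verdict, the CAUSE pleiotropy
#' sensitivity flag, colocalization posterior, tissue-level TWAS validation,
#' Steiger directionality, and a drug-target PPI link. The external flags
#' (CAUSE, TWAS, PPI) are consumed as booleans computed elsewhere.
#'
#' @param protein_id,outcome_id Identifiers.
#' @param discovery_pass Discovery FDR q < threshold.
#' @param replication_available Replication instruments existed at all.
#' @param replication_pass Replication meta significant and concordant.
#' @param cause_pass External CAUSE sensitivity flag.
#' @param pph4 Colocalization posterior for a shared causal variant.
#' @param coloc_pass PPH4 at/above the colocalization threshold.
#' @param twas_pass External TWAS validation flag.
#' @param steiger_pass Steiger directionality upheld.
#' @param ppi_drug_link Protein linked to a known drug target in the PPI
#'   network.
#' @return An object of class `evidence_record`. Missing flags default to
#'   `FALSE` (a message is emitted when `NA` is supplied).
#' @export
evidence_record <- function(protein_id, outcome_id,
                            discovery_pass = FALSE,
                            replication_available = FALSE,
                            replication_pass = FALSE,
                            cause_pass = FALSE,
                            pph4 = 0,
                            coloc_pass = pph4 >= 0.8,
                            twas_pass = FALSE,
                            steiger_pass = FALSE,
                            ppi_drug_link = FALSE) {
  flags <- list(discovery_pass = discovery_pass,
                replication_available = replication_available,
                replication_pass = replication_pass,
                cause_pass = cause_pass, coloc_pass = coloc_pass,
                twas_pass = twas_pass, steiger_pass = steiger_pass,
                ppi_drug_link = ppi_drug_link)
  na_flags <- names(flags)[vapply(flags, is.na, logical(1))]
  if (length(na_flags)) {
    message("evidence_record: missing flag(s) set to FALSE: ",
            paste(na_flags, collapse = ", "))
    flags[na_flags] <- FALSE
  }
  stopifnot(is.numeric(pph4), pph4 >= 0, pph4 <= 1)
  structure(c(list(protein_id = protein_id, outcome_id = outcome_id,
                   pph4 = pph4), flags),
            class = "evidence_record")
}

#' Grade a drug-target candidate into evidence tiers
#'
#' Assigns the four-tier evidence label from an [evidence_record()]:
#' * **Excluded** — no replication data existed for the protein, so the
#'   grading evidence cannot be assembled.
#' * **Tier 4 (CAUSE gate)** — candidates failing the CAUSE pleiotropy
#'   sensitivity analysis are downgraded to Tier 4 outright, as associations
#'   incompatible with CAUSE are likely driven by incoherent pleiotropy.
#' * **Tier 1** — colocalization `PPH4 > tier1_pph4` and validated by both
#'   replication and TWAS.
#' * **Tier 2** — linked to a known drug target in the PPI network and
#'   validated by replication or TWAS.
#' * **Tier 3** — any one of: `PPH4 > tier1_pph4`, replication, TWAS, or a
#'   PPI drug link.
#' * **Tier 4** — none of the above.
#'
#' The Tier-1/Tier-3 colocalization criterion is strict (`>`), while the
#' standalone colocalization verdict [coloc_pass()] is inclusive (`>=`); the
#' two thresholds are independent arguments.
#'
#' @param e An [evidence_record()].
#' @param tier1_pph4 Strict PPH4 threshold for tier rules (default 0.8).
#' @return An object of class `tier_assignment`: `tier` (one of `"Tier 1"`..
#'   `"Tier 4"`, `"Excluded"`) and `rationale` (character vector of rule
#'   hits).
#' @export
grade_target <- function(e, tier1_pph4 = 0.8) {
  stopifnot(inherits(e, "evidence_record"))
  hit <- function(tier, ...) {
    structure(list(tier = tier, rationale = c(...)), class = "tier_assignment")
  }
  if (!e$replication_available)
    return(hit("Excluded", "no replication data available"))
  if (!e$cause_pass)
    return(hit("Tier 4", "failed CAUSE sensitivity analysis (downgraded)"))
  strong_coloc <- e$pph4 > tier1_pph4
  if (strong_coloc && e$replication_pass && e$twas_pass)
    return(hit("Tier 1", sprintf("PPH4 %.3f > %.2f", e$pph4, tier1_pph4),
               "replication validated", "TWAS validated"))
  if (e$ppi_drug_link && (e$replication_pass || e$twas_pass))
    return(hit("Tier 2", "drug-target PPI link",
               if (e$replication_pass) "replication validated"
               else "TWAS validated"))
  any3 <- c(if (strong_coloc) sprintf("PPH4 %.3f > %.2f", e$pph4, tier1_pph4),
            if (e$replication_pass) "replication validated",
            if (e$twas_pass) "TWAS validated",
            if (e$ppi_drug_link) "drug-target PPI link")
  if (length(any3)) return(hit("Tier 3", any3))
  hit("Tier 4", "no supporting evidence stream")
}

#' @export
print.tier_assignment <- function(x, ...) {
  cat(sprintf("<tier_assignment> %s [%s]\n", x$tier,
              paste(x$rationale, collapse = "; ")))
  invisible(x)
}

#' Read externally computed evidence flags from a TSV
#'
#' Expects columns `PROTEIN_ID`, `OUTCOME_ID`, and any of `CAUSE_PASS`,
#' `TWAS_PASS`, `PPI_DRUG_LINK` as TRUE/FALSE; absent columns default to
#' FALSE for every pair.
#'
#' @param path File path.
#' @return Data frame with logical flag columns.
#' @export
read_evidence_flags <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("PROTEIN_ID", "OUTCOME_ID") %in% names(df)))
    stop("evidence file needs PROTEIN_ID and OUTCOME_ID columns", call. = FALSE)
  for (col in c("CAUSE_PASS", "TWAS_PASS", "PPI_DRUG_LINK"))
    df[[col]] <- if (is.null(df[[col]])) FALSE else as.logical(df[[col]])
  df
}

#' Assemble the grading report
#'
#' Joins MR results, replication meta-analyses, colocalization posteriors and
#' external evidence flags into one row per protein-outcome pair with every
#' Pass/Fail verdict and the tier label, plus a per-tier count summary.
#'
#' @param evidence List of [evidence_record()] objects.
#' @param tier1_pph4 Strict PPH4 threshold passed to [grade_target()].
#' @return A list with `table` (data frame, one row per pair: identifiers,
#'   flags, `pph4`, `tier`) and `summary` (named counts per tier label).
#' @export
build_report <- function(evidence, tier1_pph4 = 0.8) {
  tiers <- c("Tier 1", "Tier 2", "Tier 3", "Tier 4", "Excluded")
  if (length(evidence) == 0L) {
    tab <- data.frame(protein_id = character(0), outcome_id = character(0),
                      discovery_pass = logical(0),
                      replication_available = logical(0),
                      replication_pass = logical(0), cause_pass = logical(0),
                      pph4 = numeric(0), coloc_pass = logical(0),
                      twas_pass = logical(0), steiger_pass = logical(0),
                      ppi_drug_link = logical(0), tier = character(0),
                      stringsAsFactors = FALSE)
    return(list(table = tab,
                summary = stats::setNames(integer(length(tiers)), tiers)))
  }
  rows <- lapply(evidence, function(e) {
    g <- grade_target(e, tier1_pph4)
    data.frame(protein_id = e$protein_id, outcome_id = e$outcome_id,
               discovery_pass = e$discovery_pass,
               replication_available = e$replication_available,
               replication_pass = e$replication_pass,
               cause_pass = e$cause_pass, pph4 = e$pph4,
               coloc_pass = e$coloc_pass, twas_pass = e$twas_pass,
               steiger_pass = e$steiger_pass,
               ppi_drug_link = e$ppi_drug_link,
               tier = g$tier, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  counts <- stats::setNames(integer(length(tiers)), tiers)
  found <- table(tab$tier)
  counts[names(found)] <- as.integer(found)
  list(table = tab, summary = counts)
}
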