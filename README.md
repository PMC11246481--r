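# cismr

Proteome-wide **cis-Mendelian randomization** for drug-target discovery.

`cismr` is for statistical geneticists and drug-target triage teams who have
GWAS and pQTL *summary statistics* (no individual-level data) and want to
screen circulating proteins for causal effects on a binary disease outcome,
then grade the survivors into an evidence tier a discovery program can act
on. Everything runs from delimited summary tables plus an LD matrix; a
built-in simulator with known ground truth makes the whole pipeline testable
offline.

## What it computes

For each protein, cis-pQTL instruments are selected by four criteria —
within 1 Mb of the encoding gene, p < 5×10⁻⁸, pairwise LD r² < 0.001
(greedy clumping), outside the MHC (chr6 26–34 Mb) — and harmonized to the
outcome GWAS (allele flips, palindromic-SNP handling). The causal effect per
SD of protein is the Wald ratio θ̂ = β̂_Y/β̂_X for one instrument, or the
fixed-effect inverse-variance-weighted pool of per-SNP ratios

  θ̂ = Σ wⱼ θ̂ⱼ / Σ wⱼ,  wⱼ = 1/σⱼ²,  SE = (Σ wⱼ)^(-1/2)

for several, reported as OR per SD with Cochran's Q heterogeneity,
Benjamini–Hochberg FDR, per-instrument R² and first-stage F. Downstream:
Steiger directionality filtering (instruments must explain more variance in
the protein than in the outcome), replication meta-analysis pooled by fixed
effects or DerSimonian–Laird random effects when I² = max(0, (Q−df)/Q)
exceeds 50%, Bayesian colocalization from per-SNP Wakefield approximate
Bayes factors (priors p1 = p2 = 1e-4, p12 = 1e-5; shared-variant evidence at
PPH4 ≥ 0.8), and a four-tier evidence grade combining colocalization,
replication, TWAS, CAUSE and drug-target PPI flags. See the vignette
(`vignettes/cis-mr-pipeline.Rmd`) for the model, assumptions and design
decisions.

## Worked example

Simulate a three-protein study (two true causal proteins with θ = 0.35, one
null), an independent replication study, and grade the candidates:

```r
library(cismr)

cfg <- simulation_config(n_proteins = 3, snps_per_region = 60,
                         causal_effect_theta = c(0.35, 0.35, 0),
                         seed = 20260922)
discovery <- simulate_study(cfg)
replication <- simulate_study(simulation_config(
  n_proteins = 3, snps_per_region = 60,
  causal_effect_theta = c(0.35, 0.35, 0), seed = 20260923))

flags <- data.frame(PROTEIN_ID = c("P001", "P002"), OUTCOME_ID = "outcome",
                    CAUSE_PASS = TRUE, TWAS_PASS = c(TRUE, FALSE),
                    PPI_DRUG_LINK = c(FALSE, TRUE))

report <- run_full(discovery, list(replication), flags,
                   pipeline_config(seed = 20260922))

report$discovery[, c("protein_id", "n_snps", "or", "ci_low", "ci_high",
                     "pval", "fdr_q", "steiger_pass")]
#>   protein_id n_snps    or ci_low ci_high     pval    fdr_q steiger_pass
#> 1       P001      1 1.424  1.333    1.52 7.79e-26 1.17e-25         TRUE
#> 2       P002      1 1.375  1.297    1.46 1.67e-26 5.01e-26         TRUE
#> 3       P003      1 0.976  0.914    1.04 4.64e-01 4.64e-01         TRUE
report$grading$table[, c("protein_id", "replication_pass", "pph4", "tier")]
#>   protein_id replication_pass pph4   tier
#> 1       P001             TRUE    1 Tier 1
#> 2       P002             TRUE    1 Tier 2
```

The two planted proteins come out genome-wide significant with ORs near
exp(0.35) ≈ 1.42, colocalize (PPH4 ≈ 1), replicate, and grade Tier 1
(replication + TWAS + colocalization) and Tier 2 (PPI link + replication,
no TWAS); the null protein is correctly non-significant. `write_report()`
writes the discovery/meta/coloc/grading tables as TSV with a JSON run
manifest (config hash, seed, stage counts).

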