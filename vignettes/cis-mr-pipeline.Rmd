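---
title: "Proteome-wide cis-MR for drug-target discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-wide cis-MR for drug-target discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The problem and the model

Circulating proteins are attractive drug targets because their levels are
measurable, modifiable, and often causally proximal to disease. `cismr`
implements a two-sample Mendelian randomization (MR) screen that treats
cis-acting protein quantitative trait loci (cis-pQTLs) as instrumental
variables for plasma protein levels and estimates each protein's causal
effect on a binary disease outcome from summary statistics alone.

For an instrument SNP $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its
effect on the protein in SD units and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its
log-odds effect on the outcome. The single-instrument Wald ratio is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order SE
$\sigma_{Yj}/|\hat\beta_{Xj}|$; with $k \ge 2$ instruments the fixed-effect
inverse-variance-weighted (IVW) estimate pools the ratios with weights
$w_j = 1/\sigma_j^2$:

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},\qquad
\mathrm{SE}(\hat\theta) = \Big(\sum_j w_j\Big)^{-1/2}.$$

Effects are reported as odds ratios per SD of genetically predicted protein
level. Instrument heterogeneity is summarized by Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2 \sim \chi^2_{k-1}$, and
proteome-wide significance is controlled by Benjamini–Hochberg FDR.

The core assumptions are the usual instrumental-variable ones. Restricting
instruments to the cis region, demanding genome-wide significance, clumping
to pairwise $r^2 < 0.001$ and excluding the MHC are all there to make
relevance strong and horizontal pleiotropy less likely; the downstream
stages (Steiger, colocalization, replication, external flags) each probe a
different residual failure mode.

## Pipeline stages

1. **Instrument selection** (`select_instruments()`): keep SNPs within 1 Mb
   of the gene bounds, with $p < 5\times 10^{-8}$ (strict), outside
   chr6:26–34 Mb (inclusive), then greedy LD clumping: repeatedly emit the
   smallest-$p$ SNP (ties broken by smaller position) and discard everything
   with $r^2 \ge 0.001$ to an emitted SNP. The three filters commute;
   clumping runs last. Per instrument we attach the summary-data
   pseudo-$R^2 = Z^2/(Z^2 + n - 2)$ and the first-stage
   $F = \frac{R^2}{1-R^2}\frac{n-k-1}{k}$.
2. **Harmonization** (`harmonize()`): outcome alleles are aligned to the
   exposure's; swapped labels flip the outcome beta and reflect the EAF.
   Palindromic SNPs (A/T, C/G) with EAF within 0.42–0.58 — or missing — are
   dropped as strand-ambiguous; outside that window they are aligned by
   minor/major-allele frequency. Anything else is an allele mismatch.
3. **Estimation** (`mr_analyze()`): Wald ratio for one instrument, IVW for
   two or more, Cochran's Q when $k \ge 2$, BH-FDR across the proteins
   tested per outcome (the family size is configurable because a screen may
   carry only a subset of the tested family forward).
4. **Directionality** (`mr_steiger()`): the instruments' summed $R^2$ in the
   protein must exceed their summed $R^2$ in the outcome; the comparison
   p-value uses Fisher-transformed correlations,
   $z = \frac{\mathrm{atanh}\,r_X - \mathrm{atanh}\,r_Y}
   {\sqrt{1/(n_X-3) + 1/(n_Y-3)}}$. Candidates failing direction are
   excluded from grading.
5. **Replication meta-analysis** (`meta_auto()`): discovery plus every
   replication combination are pooled on the log-OR scale; DerSimonian–Laird
   random effects replace the fixed-effect model when
   $I^2 = \max(0, (Q - \mathrm{df})/Q)$ strictly exceeds 50% (ties stay
   fixed). A candidate replicates when the pooled replication estimate is
   significant at 0.05 and sign-concordant with discovery.
6. **Colocalization** (`coloc_posteriors()`): single-causal-variant Bayesian
   colocalization from per-SNP Wakefield approximate Bayes factors,
   $\log\mathrm{ABF} = \tfrac12\log\frac{V}{V+W} + \tfrac12 z^2\frac{W}{V+W}$,
   with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and prior effect
   variances $W = 0.15^2$ (continuous) / $0.2^2$ (binary log-odds). The five
   hypothesis posteriors are assembled entirely in log space; evidence of a
   shared causal variant requires $\mathrm{PPH4} \ge 0.8$.
7. **Tier grading** (`grade_target()`): candidates with no replication data
   are Excluded; candidates failing the CAUSE pleiotropy sensitivity flag
   are downgraded to Tier 4 outright; otherwise Tier 1 requires
   $\mathrm{PPH4} > 0.8$ plus replication plus TWAS validation, Tier 2 a
   drug-target PPI link plus replication or TWAS, Tier 3 any single evidence
   stream, Tier 4 none. CAUSE, TWAS and PPI verdicts are external boolean
   inputs (`read_evidence_flags()`); the package does not compute them.

`run_discovery()` and `run_full()` orchestrate the stages; every threshold
above lives in `pipeline_config()` (YAML round-trip, content hash recorded
in the run manifest), so no stage carries hidden constants. The package is
driven from R — the exported functions plus small scripts are the intended
command surface.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_bp` | 1e6 | cis flank around gene bounds (bp) |
| `alpha` | 5e-8 | instrument p-value threshold (strict `<`) |
| `clump_r2` | 0.001 | pairwise LD ceiling among instruments |
| `mhc_*` | chr6:26–34 Mb | exclusion zone, bounds inclusive |
| `eaf_window` | 0.08 | palindromic ambiguity half-window around 0.5 |
| `fdr_alpha`, `fdr_family_m` | 0.05, n tested | BH level and family size |
| `i2_threshold` | 0.5 | random-effects switch, strict `>` |
| `coloc_p1/p2/p12` | 1e-4/1e-4/1e-5 | per-SNP causal priors |
| `pph4_threshold` / `tier1_pph4` | 0.8 / 0.8 | coloc verdict (`>=`) vs tier rule (`>`) |

The two PPH4 thresholds are deliberately separate: the colocalization
verdict is inclusive at 0.8 while the tier wording is strict, and both are
config values.

## The synthetic-data generator

Real pQTL/GWAS inputs are controlled-access, so validation rests on
`simulate_study()`, which generates LD-structured summary statistics with
known ground truth. Defaults are chosen once to mirror the study shape the
pipeline targets: exposure cohort $n = 7213$ (an ARIC-scale proteomic
panel), outcome $n = 275{,}911$ with $16{,}328$ cases (FinnGen-scale basal
cell carcinoma), causal effect $\theta = 0.3$ log-odds per SD (OR $\approx$
1.35, mid-range for credible protein effects), planted cis-pQTLs with
expected marginal $|z| = 10$ (first-stage $F \approx 100$, conservative
relative to strong published cis-pQTLs), LD in exchangeable blocks of 10
SNPs at $\rho = 0.8$, and MAF uniform on (0.05, 0.95).

Per region, marginal pQTL means are the LD projection $R\,b_\mathrm{joint}$
of the planted per-allele effects, observed effects are drawn from
$\mathcal N(R\,b_\mathrm{joint},\, D R D)$ with
$D = \mathrm{diag}(1/\sqrt{2f(1-f)n})$, and binary-outcome SEs use the
effective sample size $4/(1/n_\mathrm{cases} + 1/n_\mathrm{controls})$ —
the standard approximation for heavily imbalanced case-control summary
data. Shared-causal regions place the outcome signal on the exposure's
causal SNP; distinct-causal regions place it in a different LD block at the
same standardized strength (scaled to that SNP's own SE), so the two
colocalization scenarios differ only in position, not power.

What the generator does *not* emulate: realistic allele-frequency spectra,
imputation noise, population structure or cryptic relatedness, sample
overlap between exposure and outcome, strand errors, or the
frequency-scaling cross-terms of a true genotype model in the LD projection
(the simulator works directly on the marginal-summary scale). Passing tests
therefore demonstrate internal statistical correctness and calibration
under the stated model, not robustness to those real-data pathologies.

## Numerical choices

* Normal quantile 1.959964 (the exact `qnorm(0.975)`) everywhere a 95%
  interval is built or inverted, for determinism to full precision.
* Colocalization hypothesis sums use log-sum-exp throughout; the H3 term is
  a log-space difference that returns exactly $-\infty$ (posterior 0) for
  single-SNP regions; posteriors are clipped to $[0,1]$ after
  normalization. Finite posteriors are maintained for $|z|$ at least 50.
* Clumping tie-break: equal p-values resolve to the smaller genomic
  position, making output deterministic; SNPs missing from the LD matrix
  are treated as independent and reported.
* Steiger per-trait $R^2$ sums are capped just below 1 before the
  $\mathrm{atanh}$ transform.
* The summary-data pseudo-$R^2$ ($Z^2/(Z^2+n-2)$) is used for both
  continuous and binary traits — for binary traits on the observed scale,
  a documented approximation; a frequency-based $2f(1-f)\beta^2$
  alternative is available in `variance_explained()`.
* Degenerate inputs fail loudly: zero exposure effects are degenerate
  instruments, `n <= 3` refuses the Steiger test, inverted CI ordering
  refuses `p_from_or_ci()`.

## Design decisions made where the design was open

* **Fixed-effect IVW** is the default estimator (heterogeneity is reported
  separately via Q) — most instrument sets here have $k \le 3$, where
  multiplicative random-effects IVW is poorly identified.
* **First- vs second-order Wald SEs.** The default per-SNP SE is the
  conventional first-order $\sigma_{Yj}/|\hat\beta_{Xj}|$. When the per-SNP
  outcome signal is not small relative to instrument strength, the
  neglected SNP-exposure noise adds roughly $(z_Y/z_X)^2$ relative variance
  to the ratio, and first-order intervals undercover; at the generator's
  defaults ($z_X = 10$, $\theta = 0.3$, study-scale sample sizes) nominal
  95% intervals cover about 86%. `ivw(second_order = TRUE)` and
  `wald_ratio(second_order = TRUE)` propagate that term and restore nominal
  coverage; the test suite checks calibration of both the default's type-I
  error under the null and the second-order intervals' coverage under the
  alternative.
* **CAUSE downgrade.** The tier rules alone do not determine the grade of a
  candidate that fails the CAUSE pleiotropy sensitivity analysis yet
  colocalizes; the grading here downgrades such candidates to Tier 4
  before the tier rules run, which is the only reading consistent with
  every published Tier-4 assignment the package's fixtures reproduce. One
  published Tier-2 label (a candidate failing both replication and TWAS)
  contradicts the literal Tier-2 wording; it is kept as a flagged
  known-discrepancy fixture rather than reverse-engineered.
* **Palindromic policy.** The drop window 0.42–0.58 (and dropping when EAF
  is missing) follows common two-sample-MR practice; outside the window,
  strand is inferred by frequency. The source methodology does not state
  its rule, so this is the package's own documented convention.
* **FDR family size** is configurable (`fdr_family_m`) because a screen's
  multiple-testing family can legitimately exceed the proteins surviving
  instrument selection in a given run.
* **Positions are 1-based inclusive**; the cis window is measured from gene
  start/end, not the TSS alone; MHC bounds are inclusive at both ends.

## Problem sizes used by the tests

The suite validates arithmetic against worked values recomputable from
published summary cells, and calibration by Monte Carlo at desk scale:
1000 replicates for null rejection (type-I error) and for mean recovery of
$\theta = 0.3$; 600 replicates for second-order interval coverage; 200
replicates each for shared- and distinct-causal colocalization on 500-SNP
regions; brute-force oracles (clumping, BH step-up, colocalization
configuration enumeration on regions of up to 6 SNPs) on randomized small
instances. These sizes give Monte-Carlo error well inside the asserted
bands while keeping the default test run at a few minutes on one CPU.

## Known limitations

* Single-causal-variant colocalization only (no SuSiE-style multi-signal
  decomposition); regions with allelic heterogeneity can mis-partition
  mass between H3 and H4.
* No MR-Egger, weighted-median or mode estimators; with $k \le 3$ cis
  instruments those are underpowered, but the package offers no pleiotropy
  *estimator*, only exclusion-based designs plus external CAUSE flags.
* The binary-trait pseudo-$R^2$ and the effective-sample-size SE rule are
  approximations that degrade for balanced case-control designs or very
  rare outcomes.
* LD is an input; the package never estimates it from genotypes, and
  clumping treats SNPs absent from the LD matrix as independent.
* Bidirectional MR is out of scope: reverse causation is addressed by
  Steiger filtering alone.
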