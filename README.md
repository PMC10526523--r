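# xaberr

X-chromosome aberration analysis for breast tumour cohorts.

In female cells, X-chromosome inactivation (XCI) silences one of the two X
chromosomes, maintained largely by promoter methylation on the inactive X
(Xi); 10–15% of genes — the pseudoautosomal regions most consistently —
escape. Breast tumours can break this system in three ways: large deletions
of the Xi, large amplifications of the active X (Xa), and abnormal X
promoter methylation. These aberrations pattern with *TP53* status and with
patient outcome. `xaberr` is for computational biologists who want to
quantify them from standard multi-omic exports (allele-specific copy-number
segments, methylation beta matrices, MAF-like mutation tables with RNA
allele counts, expression matrices, clinical tables, ATAC peaks) — or to
study the method itself on fully synthetic cohorts with known ground truth.

## What it computes

- **Promoter methylation**: gene-level beta as the mean of probes within
  200 bp of the TSS (1500 bp fallback); per-sample mean X promoter
  methylation.
- **Clustering cascade**: Ward clustering (`ward.D2`) on Gower
  dissimilarity, `d(i,j) = mean_c |x_ic − x_jc| / range(c)`, of binned
  allele-specific copy number. Tier 1 splits all samples into
  Xi-large-deletion vs Xi-unaltered on the minor allele; tier 2 splits the
  Xi-unaltered samples on the major allele into Xa-large-amplification vs
  Xa-unaltered; tier 3 clusters the remaining samples by X promoter
  methylation into high / low / unaltered. Samples unaltered everywhere
  form the reference ("selected unaltered") set.
- **RMAF classification**: per somatic mutation, RMAF = alt/(alt+ref);
  *expressed* if RMAF ≥ 0.75, *non.expressed* if ≤ 0.25, *escape*
  otherwise (coverage floor 8 reads).
- **Signatures**: per-gene OLS of log2 expression on the group indicator
  with molecular-subtype covariates, empirical-Bayes variance moderation
  (scaled inverse-chi-square prior fitted on log variances; moderated t
  with d0 + df degrees of freedom), BH-FDR ≤ 0.05 plus strict logFC sign;
  per-sample scores as the ±1-weighted mean of quantile-rescaled
  expression; hypergeometric region enrichment (PAR1/PAR2, gene sets).
- **Survival**: median-split Kaplan–Meier + log-rank, and Cox
  proportional-hazards HRs (continuous score and split factor, Efron
  ties), with administrative censoring at a horizon.
- **Synthetic cohorts**: `generate_cohort()` plants all of the above with
  configurable marginals and retains truth labels; `write_cohort()` /
  `read_cohort()` round-trip the standard file formats.

## Worked example

```r
library(xaberr)

cfg <- sim_config(n_samples = 300, seed = 1)
cmd_simulate(cfg, "demo_cohort")      # writes 8 TSV/BED files
res <- cmd_run("demo_cohort", "demo_results")
cmd_report("demo_results")            # renders demo_results/report.md
```

The report for this seed reads (abridged):

```
## Clustering cascade
- Tier 1 (Xi, n = 300): Xi-large-deletion = 95, Xi-unaltered = 205
- Tier 2 (Xa, n = 205): Xa-large-amplification = 109, Xa-unaltered = 96
- Tier 3 (methylation, n = 96): high = 21, low = 11, unaltered = 64
- Selected unaltered tumours: 64
- Truth recovery ARI: xi = 1.000, xa = 1.000, methylation = 1.000

## Cross-tabulations (percent aberrant)
- xi_by_tp53: mut = 56, wt = 22 (chi-square p = 8.36e-09)

## Survival
- xi_deletion: HR(score) = 1.73 [1.15, 2.61], p = 0.0088; ...
```

Reading it: the cascade recovered every planted group exactly (adjusted
Rand index 1 at all three tiers, possible here because the cohort carries
truth labels); Xi deletions are strongly enriched in TP53-mutant tumours
(56% vs 22%), mirroring the planted conditional probabilities; and the
Xi-deletion signature score is prognostic in this synthetic cohort
(hazard ratio 1.73 per unit score). Signature HRs on full synthetic
cohorts are attenuated by design — opposite aberrations pull the same
dosage-driven scores in opposite directions — see the methods vignette
(`vignettes/xaberr-methods.Rmd`) for why, and for every modelling choice.

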