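---
title: "Methods: quantifying X-chromosome aberrations in breast tumour cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying X-chromosome aberrations in breast tumour cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

In female somatic cells one of the two X chromosomes is transcriptionally
silenced (X-chromosome inactivation, XCI), initiated by the long non-coding
RNA *XIST* and maintained largely through DNA methylation of gene promoters
on the inactive X (Xi). Roughly 10–15% of X genes escape this silencing, the
pseudoautosomal regions (PAR1/PAR2) most consistently. In breast tumours the
integrity of both the Xi and the active X (Xa) can be disrupted — by large
deletions of the Xi, large amplifications of the Xa, or abnormal promoter
methylation — and these disruptions pattern with *TP53* mutation status and
with outcome.

`xaberr` implements a pipeline that quantifies these aberrations from
standard multi-omic inputs and evaluates their downstream consequences:

1. **Promoter methylation** — aggregate CpG probe beta-values to genes by
   TSS proximity; compute per-sample mean X promoter methylation.
2. **Copy-number cascade** — cluster samples by allele-specific copy number
   of chrX into *Xi-large-deletion* vs *Xi-unaltered* (tier 1); cluster the
   Xi-unaltered samples into *Xa-large-amplification* vs *Xa-unaltered*
   (tier 2); cluster the Xa-unaltered samples by X promoter methylation into
   *high / low / unaltered* groups (tier 3). Samples unaltered at all three
   tiers form the *selected unaltered* reference set.
3. **Somatic-mutation expression** — per mutation, the RNA-mutated allele
   frequency RMAF = alt/(alt+ref) classifies expression as *expressed*
   (RMAF ≥ 0.75), *non.expressed* (RMAF ≤ 0.25), or *escape* (in between).
4. **Differential-expression signatures** — covariate-adjusted moderated-t
   contrasts of each aberrant group against the selected unaltered tumours,
   filtered at FDR ≤ 0.05 with a strict sign constraint, yield four directed
   signatures (Xi-deletion down, Xa-amplification up, high-methylation down,
   low-methylation up).
5. **Survival** — per-sample signature scores, median-split Kaplan–Meier
   curves with log-rank tests, and Cox proportional-hazards models.

Because the real cohorts behind this kind of analysis are access-controlled,
the package ships a first-class synthetic cohort generator
(`generate_cohort()`) that emulates the statistical structure of the inputs
and retains the planted ground truth, so the full pipeline is testable
end-to-end offline.

# Promoter methylation

A gene's promoter methylation is the mean beta-value of the probes within
200 bp of its transcription start site; when no probe lies within 200 bp,
the probes within 1500 bp are used; otherwise the gene receives no value.
Distance is strand-agnostic `|position − TSS|`, matching the TSS200/TSS1500
categories of standard 450K annotation; the assignment rule does not
deduplicate probes across genes — a probe inside two genes' windows serves
both, since promoter windows legitimately overlap in gene-dense regions.
Missing beta-values are propagated, never imputed: a gene×sample cell is
`NA` when every assigned probe is missing, and per-sample means skip `NA`s.
This avoids fabricating signal at the cost of slightly unequal effective
gene sets per sample.

# The clustering cascade

Samples are clustered on a fixed-dimension representation of their chrX
allele-specific copy number: the chromosome is tiled into equal bins
(default 100 bins of 1.5 Mb, approximately chrX's 155 Mb), and each bin
takes the length-weighted mean copy number of the chosen allele over the
overlapping segments. Bins with no segment coverage take the sample's modal
covered value and are flagged; this prevents missing telomeric segments
from inflating dissimilarity. Binning conserves copy-number mass: on a
fully covered chromosome the length-weighted bin mean equals the
length-weighted segment mean.

Dissimilarity is the Gower coefficient for numeric data — the mean over
bins of `|x_i − x_j| / range(bin)`, skipping zero-range bins — and
clustering is agglomerative with the Ward criterion
(`stats::hclust(method = "ward.D2")`, which applies the Ward update to
squared dissimilarities), cut at *k* = 2 for the copy-number tiers and
*k* = 3 for methylation.

Cluster labelling is by an aberration statistic rather than size: the
cluster with the larger mean fraction of bins below copy number 0.5 is
*Xi-large-deletion*; the cluster with the larger mean fraction above 1.5 is
*Xa-large-amplification*; methylation clusters are ranked by centroid mean
beta (highest → *high*, lowest → *low*, middle → *unaltered*). Ties on the
labelling statistic conservatively label the larger cluster unaltered. A
degenerate matrix (no variation at all) yields a single unaltered group
with a warning rather than an arbitrary split.

**Interpretive convention.** Allele-specific segment calls do not say which
physical homologue is the Xi. The package proxies the Xi by the *minor*
allele (a large Xi deletion manifests as minor copy number 0, leaving a
hemizygous active X) and Xa amplification by the *major* allele. This is
the central interpretive decision of the copy-number stage; anchoring Xi
identity by methylation phasing would require phased data the standard
inputs do not carry.

# RMAF classification

RMAF is undefined below a coverage floor of 8 reads (configurable): below
~8 reads the 0.25/0.75 boundaries cannot usefully separate bi-allelic
(p = 0.5) from mono-allelic (p = 1) expression. Both boundary values belong
to the outer classes, exactly as the inequalities read. Records annotated
`Silent` are excluded before classification; records lacking usable allele
counts pass through unclassified with a warning rather than being guessed.
When a gene carries several qualifying mutations in one sample (e.g. for
per-sample *TP53* RMAF), their RMAFs are averaged — symmetric and
order-free. At depth 20 the three true expression fractions
{0, 0.5, 1} are each recovered with probability ≥ 0.95, which the test
suite checks against exact binomial tail sums.

# Differential expression and signatures

Per gene, log2 expression is regressed on an intercept, the group
indicator, and treatment-coded molecular-subtype dummies with the most
frequent subtype as reference; the group coefficient is the logFC. The
subtype covariate absorbs the uneven subtype composition of the contrast
groups, which would otherwise masquerade as aberration effects.

Gene-wise residual variances are moderated by an empirical-Bayes scheme
written out in the package rather than delegated: a scaled
inverse-chi-square prior (d₀, s₀²) is fitted by the method of moments on
log variances, using the digamma/trigamma identities of the log-chi-square
distribution (the trigamma inverse is solved by Newton iteration), and each
variance is shrunk to `(d₀·s₀² + df·s²)/(d₀ + df)`. The moderated t uses
d₀ + df degrees of freedom. Two limits anchor the implementation: d₀ = 0
reproduces the ordinary t, and d₀ → ∞ replaces every variance by s₀²; when
the observed log-variance dispersion does not exceed its sampling noise the
prior degrees of freedom are infinite and s₀² is the mean variance. The
test suite cross-checks the fitted prior and the full moderated-t table
against an independent reference implementation.

P-values are adjusted by Benjamini–Hochberg within the tested gene set —
by default the X-chromosome genes, since the contrasts are X-focused;
correcting across the transcriptome instead is a one-argument change
(pass the full matrix). Signatures take the genes at FDR ≤ 0.05 with a
*strictly* negative (down) or positive (up) logFC; logFC = 0 never enters,
so the up- and down-signatures of one contrast are disjoint by
construction. Weights are the sign of logFC.

Signature scores rescale each gene to [−1, 1] via its 2.5% and 97.5%
quantiles with clipping — robust to outliers and bounded — then average
`w·x̃` over genes, normalised by `Σ|w|`. The quantile pair is configurable.

Enrichment of a signature in a region gene set (PAR1, PAR2, XCU,
p53-associated sets) is the upper-tail hypergeometric probability of at
least the observed overlap. Signature overlaps are reported as
nearest-integer percentages of each signature.

# Survival evaluation

Kaplan–Meier curves and the log-rank test compare median-split score
groups; scores at the median go to the *low* group (recorded tie rule).
Cox models maximise the partial likelihood with the Efron approximation
for ties. Because published hazard ratios of this kind often leave
ambiguous whether the covariate was the continuous score or the split
factor, `cox_hr()` reports both. Follow-up is administratively censored at
a horizon — 20 years for signature evaluation, 5 years where subtype
aggressiveness itself is compared. Monotone likelihood (perfect
separation) is flagged and the confidence interval reported unbounded.
The clinical table carries one endpoint column; which endpoint it encodes
(disease-free or disease-specific) is the caller's naming choice.

# The synthetic cohort generator

`sim_config()` fixes the study conditions; `generate_cohort()` draws a
cohort deterministically from the seed. Marginals are taken from the
published cohort structure wherever it states them:

| parameter | default | source |
|---|---|---|
| subtype mix | LumA 0.54, LumB 0.20, Basal 0.18, Her2 0.08 | subtype denominators 545/205/185/80 |
| P(Xi deletion given TP53 mut / wt) | 0.51 / 0.18 | printed prevalences |
| P(Xa amplification given TP53 mut / wt) | 0.68 / 0.41 | printed prevalences |
| P(methylation high / low) | 0.19 / 0.09 | group sizes 54 and 25 of 280 |
| TP53 mutation by subtype | 0.15/0.30/0.80/0.50 | typical cohort rates (non-source value) |

All remaining parameters — read depths, effect sizes, noise levels,
hazards — are declared non-source values chosen once as field-realistic:
mean RNA depth 30 at mutation sites, log2 expression noise 0.5, Beta
concentration 60 for probe values, exponential survival with baseline
hazard log(2)/12 per year (median 12 years for an unaltered tumour; a
Weibull baseline is available by configuration, the exponential default
being the simplest model satisfying proportional hazards so that Cox
recovery is well-posed), censoring probability 0.3, planted log-hazard
log(3) per unit aggressiveness.

chrX is simulated as 100 abstract 1.5 Mb bins with 1-based inclusive
segment coordinates; PAR1 is the first two bins and PAR2 the last two.
Large deletions (minor allele → 0) and amplifications (major allele →
2 or 3 per bin) cover a terminal, contiguous 70–100% of the chromosome —
large events are typically telomere-anchored, and this places the PARs
inside most events. Unaltered samples carry sparse one-bin focal blips,
and a terminal bin occasionally lacks segment coverage to exercise the
modal imputation path.

Expression follows an **expressed-copy dosage model**: a gene's log2 shift
is `log2(active copies / baseline)`, where XCI-subject genes express only
the major-allele copies (baseline 1) and escapees additionally express the
minor (Xi) copy (baseline 2). Hence Xi deletion halves escapee dose but
leaves XCI-subject genes untouched — which is why deletion signatures
concentrate in escapee/PAR genes — while Xa amplification raises all X
genes. Methylation aberrations act through the same model:
hypermethylation silences the escapee Xi copy; hypomethylation reactivates
XCI-subject Xi copies. *XIST* is handled separately (reduced by 2 log2
units under Xi deletion and 1 under TP53 mutation, reflecting its Xi
origin and p53 regulation). Promoter beta-values are drawn from Beta
distributions whose means follow the same logic (XCI-subject 0.45, one
methylated allele of two; 0.80 hypermethylated; 0.15 hypomethylated; 0.25
after Xi deletion; escapees 0.08 in open chromatin, 0.25 otherwise), an
ordering chosen to mimic the qualitative group structure, not fitted to
any dataset. ATAC peaks cover the promoters of the constitutive (open
chromatin) escapees plus a few background positions.

Mutation RNA alt counts are Binomial(depth, p) with true p = 1 (expressed:
hemizygous or silenced wild type), 0.5 (bi-allelic/escape) or 0 (silenced
mutant); the expressed class is drawn twice as often when Xi is deleted
(0.5 vs 0.25). TP53-mutant samples carry a TP53 record with p = 1 under Xi
deletion (loss of heterozygosity) and 0.5 otherwise.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-level spatial correlation and batch
structure in methylation; tumour purity, subclonal copy-number mixtures
and intermediate clonality; genome-wide copy-number background beyond
chrX; expression covariance networks; informative censoring. One emergent
property deserves emphasis: because the dosage model sends Xi deletion and
Xa amplification in opposite directions through overlapping gene sets, a
signature's score in the *full* synthetic cohort mixes aggressive groups
at both ends of its range, so whole-cohort signature hazard ratios are
attenuated relative to contrasts restricted to the signature's own groups.
The tests therefore validate survival machinery by direct
parameter-recovery simulation (a planted per-unit hazard ratio of 3) and
validate the cascade, classification and signature machinery by
ground-truth recovery — they do not, and cannot, reproduce
cohort-specific hazard-ratio magnitudes.

# Numerical conventions and degenerate inputs

- Segments are 1-based inclusive; BED peaks are 0-based half-open and
  converted on read/write.
- Overlapping segments within a sample are an error naming the offending
  rows, not silently averaged.
- Zero-range Gower columns are skipped; an all-constant matrix errors (or,
  inside the cascade, collapses to a single unaltered group with warning).
- `cutree` on the Ward tree is deterministic for a fixed input ordering;
  the generator fixes sample order, making whole runs reproducible from
  one seed.
- Percentages round to the nearest integer (`round()`), matching the
  printed style of cohort reports.
- All randomness flows through one seed; `generate_cohort()` restores the
  caller's RNG state.

# Problem sizes

The shipped tests and the acceptance script use cohorts of 60–500 samples
(300 for the end-to-end run), 100 chrX bins, 100 X genes plus 40 autosomal
genes, 2000 genes for prior recovery, and 100 replicates of n = 1000 for
Cox recovery — sizes at which every planted property is comfortably
identifiable while a full simulate → run → report cycle stays in the tens
of seconds on a single CPU.

# Known limitations

- The Xi/minor-allele correspondence is a convention, not an inference;
  cohorts with phased methylation could resolve it properly.
- k = 2 / k = 3 cluster counts are fixed by design, not selected from the
  data; the cascade reports sizes, not cluster-number diagnostics.
- The DE stage consumes log-scale expression; count-level modelling
  (voom-style precision weights) is out of scope.
- Survival models are score-only, mirroring the analysis they implement;
  multivariable adjustment for clinical covariates is deliberately not
  provided.
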