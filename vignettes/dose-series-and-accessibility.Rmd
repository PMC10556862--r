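---
title: "Methods: dose-series expression and window-based accessibility analysis"
author: "toxseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-series expression and window-based accessibility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxseq)
```

# Scope

`toxseq` implements the statistical core of a low-dose toxicogenomics
screen on in vitro thyroid models: endocrine-disrupting phthalates are
applied over a five-dose series to thyroid organoids (bulk RNA-seq of
mRNA, miRNA and snoRNA together), and two of the compounds are separately
profiled for chromatin accessibility in a thyroid epithelial cell line
(ATAC-seq, 6 vs 6 against solvent control). The package covers everything
downstream of count matrices and deduplicated fragment intervals: biotype
quality control, per-gene dose-response regression with profile
clustering, removal of unwanted variation, pooled-dose differential
expression with a spurious-spike post-filter, preranked gene set
enrichment, and sliding-window differential accessibility with
region-level FDR. Read trimming, alignment and quantification are
upstream concerns and out of scope.

Because the real deposited dataset is not required for development or
validation, the package ships seeded generators that emulate the count
and fragment structure of such an experiment with known ground truth;
every stage is validated by parameter recovery against that truth.

# The count model

One negative-binomial convention is used everywhere: mean $\mu$ and
dispersion $\alpha > 0$ with variance $\mu + \alpha\mu^2$; the size
parameter is $\theta = 1/\alpha$. This removes the classic
$\theta$-versus-$\alpha$ ambiguity between tools.

All GLMs use the log link with log size-factor offsets. Size factors are
median-of-ratios: for each sample the median ratio of its counts to the
per-gene geometric mean over genes expressed in all samples, rescaled to
geometric mean one. When no gene is expressed everywhere the code falls
back to total-count ratios with a warning.

Dispersion estimation (`estimate_dispersions`) is gene-wise maximum
adjusted profile likelihood with a Cox–Reid correction (without it the
estimates are biased low at a dozen samples, which in turn inflates Wald
type-I error), followed by a mean–dispersion trend
$\alpha_{tr}(\mu) = a_0 + a_1/\mu$ fitted across genes and shrinkage of
each gene-wise estimate toward the trend by a weighted geometric mean
(equal weights by default). Estimates are clipped to $[10^{-8}, 10]$.
With fewer than ten genes the trend is skipped.

# Biotype QC

Biotype percentages are computed per sample directly on counted reads:
$100 \cdot \sum_{g \in b} y_{gs} / \sum_g y_{gs}$, with unmapped genes in
an explicit `unannotated` bucket so rows always total 100. A biotype is
retained when it reaches at least 1% in at least one sample (boundary
inclusive). snoRNA genes are split into their own matrix before further
analysis: their library share depends on the number of PCR cycles used in
library preparation, and leaving them in would bias the library-size
normalization of the protein-coding majority; the snoRNA matrix runs
through the identical differential machinery as a separate dataset with
its own BH family.

Outliers are flagged per treatment group and biotype by the Tukey rule:
strictly below $Q_1 - 1.5\,\mathrm{IQR}$ or strictly above
$Q_3 + 1.5\,\mathrm{IQR}$. The quartile estimator is linear interpolation
(R type 7); the rule's source names no estimator, so the most common
default is fixed and documented to make the tests exact. Flagging is a
report, not a removal: the pipeline-level default removes only samples
flagged in the biotypes that matter most downstream (protein coding,
miRNA), because a control sample aberrant there would distort every
contrast, while flags in minor biotypes (pseudogene, rRNA) are reported
and kept. Groups with fewer than three samples are skipped with a
warning.

# Dose-series regression and profile clustering

For each gene, counts across one compound's series (ordinal dose codes
$d = 0$ for solvent control through 5 for the top dose — the code, not
the molar concentration, even where a compound's absolute doses are
doubled) are fit by an NB GLM with covariates $1, d, d^2, d^3$ and fixed
$\theta = 10$, and tested by likelihood ratio against the intercept-only
model ($\chi^2$, 3 df). The FDR threshold is 0.05. Defaults follow the
reference dose-series methodology (`theta = 10`, `degree = 3`,
`fdr = 0.05`); the reference tool's second-stage stepwise selection and
$R^2$ cutoff are not part of the documented procedure, so the full cubic
fit is kept and per-coefficient Wald $z$ statistics are reported as
supplementary output instead. Whether the original analysis used
size-factor offsets is unstated; median-of-ratios offsets are used here
and documented. Non-convergence falls back to successively lower degrees
with a flag; all-zero genes get $p = 1$.

Significant genes are clustered on their *fitted* (not raw) mean
profiles, standardized per gene to zero mean and unit variance across
dose codes, with correlation distance and average-linkage hierarchical
clustering cut at nine clusters (fitted profiles match the
fitted-curve presentation this analysis is known for; raw profiles
would cluster on noise). Singletons are allowed; constant profiles get
zero correlation to everything. The characteristic phenomenon this
stage should expose — expression diverging only at the top dose — is
verified in the tests by planting a spike-at-top-dose shape and checking
that its cluster's mean profile is flat through code 4 and jumps at 5.

Because the dose model fixes $\theta = 10$, its null p-values are
uniform only when the data's dispersion matches $1/\theta$; the
calibration simulations therefore use $\alpha = 0.1$ for this stage
(a model-matched null). With the package-default $\alpha = 0.05$ the
test is mildly conservative, which costs a little power but never
inflates the FDR.

# Removal of unwanted variation

Two factor-analytic estimators return $k$ orthonormal sample-space
factors $W$ to be used as GLM covariates — never to produce "corrected
counts", because covariate adjustment preserves the count distributions
the downstream tests assume.

* **Control genes** (`ruv_control_genes`, $k = 2$ for expression): the
  first $k$ left singular vectors of the per-gene-centered
  $\log(y + 1)$ matrix restricted to genes assumed unaffected by
  condition. The original analysis does not name its control set, so the
  default is empirical: the least-significant half of genes from a
  first-pass unadjusted test.
* **Replicate sets** (`ruv_replicates`, $k = 5$ for accessibility): log
  counts centered within condition-homogeneous replicate sets, then the
  SVD of the stacked centered matrix. Sets must not mix conditions —
  centering a mixed set would subtract the condition effect into the
  factors and destroy the signal (the function warns if asked to do
  this). Singleton sets are excluded with a warning.

Both recovery guarantees are tested: a planted expression confounder and
planted ATAC batch offsets are each recovered with $|r| \ge 0.9$, and
including $W$ in the null design does not inflate type-I error.

# Pooled-dose differential expression

The dose-series stage consistently shows the top dose diverging from the
rest of the series, so the expression contrast pools dose codes 1–4 of a
compound as "treatment" versus the solvent control, excluding code 5
(configurable via `pool_doses`). The stage is, in order:

1. **Relevance filter**: keep genes with CPM $\ge 1$ in at least 75% of
   the samples of either group, both boundaries inclusive.
2. **Size factors and dispersions** as above.
3. **NB Wald test** with condition plus the RUV covariates: the Wald
   statistic is the condition coefficient over its standard error, and
   $\log_2\mathrm{FC} = \hat\beta/\ln 2$. The two-sided p-value uses a
   t reference with residual degrees of freedom ($n - p$). This is a
   deliberate small-sample choice: with sixteen samples and
   trend-shrunk dispersions, null simulations show the large-sample
   normal reference is well calibrated in the bulk but roughly an
   order of magnitude anti-conservative beyond $4.5\sigma$ — exactly
   where BH decides FDR-0.01 calls — so a normal reference produces
   spurious genome-wide-significant calls in a non-negligible fraction
   of null datasets, while the t tail closely tracks the exact NB
   small-sample tail. The cost is mild bulk conservatism (null
   $p < 0.05$ fraction $\approx 0.04$) and reduced power for effects
   near one log2. The Wald statistic itself is unchanged and remains
   the GSEA ranking score. BH across converged genes, FDR 0.01;
   non-converged genes get `NA` and leave the BH family.
4. **Spurious-spike filter**: a DE gene passes for a group iff its
   largest single-replicate share of the group total is strictly below
   $1.4\,n^{-0.66}$; the rule is applied to both treatment and control
   groups. Failures are *flagged* (`final_call = "spike_filtered"`),
   not silently dropped, mirroring the manual-review step this rule
   feeds in practice. BH precedes the filter, matching the documented
   order (test first, then "an additional filtering step").

No independent filtering beyond the CPM rule is applied. The
pipeline-level guarantee, tested on synthetic data: with 10% true
effects the empirical false discovery proportion among final calls stays
within twice the nominal FDR, planted $\log_2\mathrm{FC} = 1$ effects
are recovered with mean bias $\le 0.2$, and $20\times$ single-replicate
spikes are flagged at $\ge 90\%$.

# Preranked GSEA

Genes are ranked by the Wald statistic, descending, ties broken by gene
id so the order is deterministic. The enrichment score is the classic
weighted running sum: hits increment by $|s|^p / \sum_{hits} |s|^p$
(default $p = 1$), misses decrement by $1/(N - N_{hits})$, and ES is the
signed maximum deviation; the sum starts and ends at zero. The null is
gene-label permutation (the only scheme available for a preranked list),
sharing draws across sets of equal size. NES divides ES by the mean
$|$null ES$|$ of matching sign; the permutation p-value is the
sign-matched exceedance with $+1$ smoothing so it is never zero; q is BH
within sign strata (the referenced tool's FDR is a hybrid, so this
standard signed variant is documented as an explicit choice).
`n_perm` defaults to 10,000; the analysis scripts use 1,000–2,000, which
bounds the smallest attainable p at $\sim 10^{-3}$ and is sufficient at
a q threshold of 0.05. NES $< 0$ means enrichment in the control
condition. Sets significant in every contrast are reported by a simple
intersection (`gsea_intersection`).

# Window-based differential accessibility

Fragment intervals (0-based half-open BED) are converted to Tn5 cut
sites: the transposase duplicates 9 bp at insertion, so the plus-strand
end is shifted $+4$ and the minus-strand end $-5$. When the BED stores
whole fragments (the default mode) both ends yield one cut site each;
single-end mode uses the record's strand. Off-chromosome sites are
clipped and counted.

Cut sites are counted in non-overlapping 50 bp windows; windows with
fewer than 50 total counts across samples are discarded. The "50 total"
reading (rather than per-sample) is deliberate: a per-sample floor would
contradict the subsequent abundance filtering and would scale with
replicate number. The global background is the median log2 CPM of 10 kb
bins over the whole genome (empty bins included; pseudo-count 0.5 in all
log-CPM computations), rescaled to window width by subtracting
$\log_2(10000/50)$. Windows at least $3\times$ above background
(boundary inclusive) count as signal. The fold-change filter is applied
to windows before merging — the source procedure is ambiguous between
windows and pre-merged regions, and window-level filtering is the
standard order.

Each signal window is tested by an NB likelihood-ratio test (1 df) with
condition plus $k = 5$ replicate-set RUV factors, sharing the dispersion
machinery of the expression stage; size factors default to cut-site
library sizes. Signal windows at most 500 bp apart are chained into
regions; a chain spanning more than 5 kbp is split into
$\lceil \mathrm{span}/5000 \rceil$ contiguous sub-chains of near-equal
window count, recursively, so no region ever exceeds the cap (greedy
left-to-right splitting would instead produce a ragged last region).
Multiple-testing correction happens at region level, never window level:
the region p-value is the Simes combination of its member windows
(the companion combination for this windowing strategy; the source
names only the BH step), BH across regions at FDR 0.01, and the region's
logFC and direction come from its most significant window. The
descriptive report counts regions below unadjusted p of 0.001 and 0.01
with $|\mathrm{logFC}| > 1$ by direction, plus the FDR-passing count —
on the matched null that last count is zero in $\ge 95\%$ of seeds,
reproducing the qualitative outcome of the original screen (a general
accessibility increase, nothing surviving correction).

Annotation assigns each region the gene with the nearest TSS (distance
from region midpoint, ties toward the smaller coordinate), a feature
class — TSS or TTS when the region overlaps the site $\pm 1$ kb, else
exon (when an exon map is supplied), intron, or intergenic — and a
regulatory flag for any-bp overlap with a supplied regulatory interval
set (e.g. candidate cis-regulatory elements).

# The synthetic-data generators

`simulate_rna_counts` draws NB counts for the full design: four
compounds $\times$ dose codes 1–5 in triplicate, DMSO solvent control
($n = 5$) and untreated control ($n = 3$). Per-gene log2 means are
baseline + planted dose profile + confounder terms; baselines are
$N(5, 2)$ on the log2 scale, library sizes uniform on [1, 2] million
and dispersion $\alpha = 0.05$ — the source experiment reports neither
library-size nor dispersion magnitudes, so these are fixed once at
values typical of clonal in vitro bulk RNA-seq and documented here
rather than inferred. Effect profiles are polynomials in the raw dose
code (the same covariates the dose model fits; the default cubic
coefficient 0.008 gives one log2 at the top dose) or arbitrary
functions of the code for non-polynomial shapes (step effects for the
pooled contrast, spike-at-top for the clustering phenomenon). Means are
scaled against a fixed baseline normalizer — deliberately
non-compositional, so a planted effect never distorts other genes — and
capped at the library size. Confounders are additive log2 factors with
Gaussian loadings, matching the linear-factor assumption of the removal
method. Spikes multiply one replicate's count in a seeded subset of
gene $\times$ group cells by `spike_multiplier`.

`simulate_atac_fragments` plants non-overlapping peaks on a small
synthetic genome (default 2 Mb over two chromosomes, 200 peaks of
300–800 bp), splits each sample's fragments between uniform background
(30%) and peaks, scales differential peaks by $2^{\pm 2}$ in the treated
condition, and draws fragment lengths from a sub-nucleosomal/
mono-nucleosomal normal mixture (60 ± 10 / 200 ± 25 bp, equal weights —
the weights are free parameters of the generator). Replicate-set batch
offsets multiply a seeded half of the peaks by $2^{\mathrm{shift}}$: a
whole-library offset would be removed by CPM normalization and
unrecoverable by any factor method, so batch structure is planted where
factor analysis can actually see it.

Both generators are bit-reproducible under a fixed seed and return
ground-truth records (planted genes and profiles, confounder loadings
and scores, spiked cells, differential peaks with direction) whose
completeness is itself tested.

What the generators deliberately do not emulate: read-level errors and
sequence content, GC or mappability bias, compositional interaction
between genes, peak shape heterogeneity, and correlated (non-factor)
batch structure. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artifact of real libraries.

# Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere; boundary conventions are stated per
  filter (retention and relevance inclusive, outlier fences and the
  spike rule strict as displayed).
* All-zero genes: $p = 1$, zero coefficients. Non-convergence: lower
  polynomial degree (dose series) or `NA` excluded from the BH family
  (Wald), always flagged.
* Dispersion clipped to $[10^{-8}, 10]$; log-CPM pseudo-count 0.5 in the
  accessibility stage, $\log(y+1)$ in the RUV stage.
* The scale invariance of the LRT under count rescaling with matching
  offsets is asymptotic (the $1/\mu$ variance term breaks it exactly),
  and is tested at high counts with a 2% tolerance.
* Ties: gene-id order in rankings, smaller-coordinate in nearest-TSS
  assignment, both deterministic.

# Problem sizes used in validation

The shipped tests and the acceptance script run: null expression
calibration at 2,000 genes, 12 vs 4 samples, across 10–20 seeds;
fold-change recovery at 2,000 genes (10% planted); dose-series power at
1,000 genes and clustering recovery at 600; the accessibility stage at
the generator's full default (2 Mb genome, 200 peaks, 6 vs 6 with batch
offsets) with a 5–20-seed matched null; GSEA against 20 sets of 30 genes
with 500–1,000 permutations. These sizes give stable Monte-Carlo
estimates for every tested tolerance while keeping a full run in the
minutes range on a single core.

# Known limitations

* The t-referenced Wald p-values are conservative in the bulk at the
  shipped sample sizes (null $p<0.05$ fraction $\approx 0.04$, not
  0.05); uniformity holds on the statistic's large-sample scale. This
  trades a little power for robust FDR-level behaviour, as the null
  simulations verify.
* Fixed $\theta = 10$ in the dose stage trades per-gene dispersion
  estimation for robustness at triplicate dose groups; genes with much
  larger true dispersion will be anticonservative there.
* Region-level Simes combination is valid under positive dependence of
  member windows, which adjacent windows sharing fragments satisfy in
  practice but which is not formally guaranteed.
* The empirical-control default for the control-gene RUV variant can
  leak weak signal into the factors when effects are pervasive;
  supplying known negative controls is preferable when available.
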