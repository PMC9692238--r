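---
title: "Population-level allele-specific expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-level allele-specific expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical models behind `dasepipe`, the
reasoning behind its defaults, and what its synthetic cohorts do and do not
demonstrate about real data.

## The measurement model

In an F1 produced by crossing an outbred paternal parent to a common inbred
maternal tester, every locus carries exactly one tester allele, which
phases all heterozygous SNPs by design. RNA-seq reads overlapping
heterozygous exonic SNPs can be assigned to a parental origin, and summing
assigned reads within a gene gives two allelic counts per gene per sample.
The per-gene statistic is

$$\mathrm{log2ASE}_{gs} = \log_2(\text{parental reads}_{gs}) -
  \log_2(\text{tester reads}_{gs}).$$

Because both alleles share one cellular environment, *trans* effects cancel
and log2ASE responds only to *cis*-regulatory differences between the two
alleles. The quantity of scientific interest is the average difference
$\delta_g$ in log2ASE between samples whose paternal parent comes from the
highland versus lowland class, estimated separately for each source
population, in each site:tissue condition.

### SNP filters

Three per-sample filters protect the ratio from systematic bias:

* **Both alleles detected.** Loci where only the parental allele is seen
  are almost certainly heterozygous, but keeping them while discarding
  tester-only loci (indistinguishable from homozygous) would inflate the
  parental side of the ratio. Dropping all single-allele loci keeps the
  error symmetric.
* **Total coverage ≥ 10 reads** (`snp_min_total`). Below this, allele
  dropout by sampling is likely.
* **|log2(ALT) − log2(REF)| < 2** (`snp_log2_cap`, strict). At high
  coverage, sequencing errors masquerade as rare non-reference alleles;
  extreme SNP-level ratios are predominantly such artifacts and would bias
  gene ratios toward the reference allele.

The boundary semantics are exact: a SNP with counts (2, 8) has
$|\log_2 8 - \log_2 2| = 2$ and is dropped; (4, 6) is kept.

### Aggregation and missingness

Gene-level counts are obtained either from per-read allele assignments
(`mode = "read_assignment"`, each read counted once per gene) or by
summing SNP-level counts (`mode = "snp_sum"`). The second mode
double-counts reads spanning several SNPs of one gene; totals are inflated
but the ratio is nearly unaffected. The read-assignment mode is preferred
when a read table exists; SNP summing is the fallback when only
ASEReadCounter-style tables are available. Cells where either allele has
zero reads are *missing*, never zero: a log2ASE of 0 asserts equal allelic
expression, whereas a zero count carries no information about the ratio.
Such cells receive exactly zero weight in all model fits.

Gene inclusion for the ASE analysis requires at least `min_samples = 10`
samples with at least `min_reads = 32` ASE-informative reads in *every*
population-by-elevation group; the total-expression analysis requires this
in *at least one* group. The ASE filter is deliberately stronger: a low
count is informative about expression but uninformative about the ratio.

## The variance model (ASE-adapted voom)

The precision of log2ASE varies over orders of magnitude with the
ASE-informative coverage. As with counting noise in RNA-seq, ignoring this
heteroskedasticity wastes power. The adaptation mirrors voom:

1. fit the design to each gene's log2ASE by OLS (missing cells excluded)
   and extract residual SDs $s_g$;
2. lowess-smooth $\sqrt{s_g}$ against the gene's mean log2 normalized
   total ASE count (span 0.5, 3 robustifying iterations — voom's
   defaults; the method is not sensitive to the smoother settings);
3. predict each observation's $\sqrt{\mathrm{SD}}$ by linear interpolation
   of the trend at that observation's own log2 normalized total, clamped
   at the endpoints;
4. weight = predicted$^{-4}$ (i.e., inverse predicted variance), and
   exactly 0 for missing cells.

Normalization uses each sample's total ASE-informative library size, a
$\times 10^6$ scale and a $+0.5$ offset before log2 (the count-mode path
normalizes by TMM-scaled library sizes via `limma::voom` and
`edgeR::calcNormFactors`).

The weighted fit is per-gene weighted least squares; genes with fewer than
rank + 2 positively weighted observations, or with a needed design column
entirely zero-weighted, are dropped rather than fitted. Residual variances
are then moderated by empirical Bayes: a scaled-F prior is fitted to the
$s^2_g$ by moment matching on $\log s^2_g$ (via `limma::squeezeVar`), and
$s^2_{\mathrm{post}} = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ with moderated
$t = \hat\beta / (\sqrt{s^2_{\mathrm{post}}}\,\mathrm{stdev.unscaled})$ on
$d_0 + d_g$ degrees of freedom. A negative moment target yields
$d_0 = \infty$ and full shrinkage to $s_0^2$.

### The design

Per site:tissue: intercept; block (only where the site has two blocks);
sampling team; a cubic *orthogonal* polynomial of field sampling order fit
separately within each team (orthogonality avoids collinearity among the
raw powers; teams with too few distinct order values get a reduced
degree); a population main effect; one highland-vs-lowland contrast per
population; and a within-population-centered latitude slope per
population. Centering latitude within population keeps the latitude and
elevation columns well conditioned. The per-population elevation contrast
is directly readable from the named columns `elev_<population>`.
Cell-composition scores can be appended as covariates.

## Multivariate shrinkage across conditions

Effects and standard errors from the per-tissue fits form matrices over
$R$ conditions (2 populations × 3 site:tissues = 6 by default; the fit is
joint over all six, and per-population calls read that population's
columns — a joint fit shares the scale grid and residual correlation
across populations while still letting singleton and population-specific
covariances carry population-specific signal). The prior on the true
effect vector is a mixture of multivariate normals
$\sum_{k,\omega} \pi_{k\omega}\, N(0, \omega U_k)$ plus a point mass at
zero, with:

* canonical shapes: identity, one singleton per condition, equal effects,
  heterogeneous shared effects (off-diagonal 0.25/0.5/0.75);
* data-driven shapes: SVD of the z-scores of strong genes
  ($|z| > 3.3$ in some condition — a first-pass proxy, since lfsr is not
  available before fitting), one rank-1 shape per leading component plus
  the low-rank reconstruction; extreme-deconvolution refinement is
  deliberately omitted (PCA shapes have proven adequate on the synthetic
  cohorts and keep the fit fast and deterministic);
* a geometric scale grid from $(\min \hat s/10)^2$ to
  $(4 \max|\hat b|)^2$ with ratio 2.

Measurement error is $N(0, V_j)$ with
$V_j = \mathrm{diag}(\hat s_j)\, C\, \mathrm{diag}(\hat s_j)$; the residual
correlation $C$ is the empirical correlation of z-scores over near-null
genes ($|z| < 2$ everywhere), shrunk 5% toward the identity — a moment
simplification of the EM residual-correlation estimator. Missing
conditions are imputed as $\hat b = 0$, $\hat s = 10^6$ (no information)
and masked back to `NA` in all outputs.

Mixture weights maximize the null-biased penalized likelihood (Dirichlet
pseudo-count 10 on the null). EM handles the bulk of the optimization but
moves vanishingly slowly along directions where components are
near-duplicates (the null versus the smallest grid scales), so a pairwise
Frank-Wolfe refinement with exact line search follows until the
Frank-Wolfe gap is below tolerance. Posterior summaries are the standard
mixture-of-conditionals: posterior means, SDs, and the local false sign
rate $\mathrm{lfsr}_r = \min\{P(b_r \le 0 \mid \cdot), P(b_r \ge 0 \mid
\cdot)\}$ with the point mass counted in both terms. The per-gene overall
lfsr is the minimum over that gene's observed conditions — the natural
reading of "significant in at least one condition"; the lfsr of the
average effect is a stricter alternative that would miss
condition-specific signals. The per-population effect summary is the mean
posterior effect over the population's conditions, which is stable
because the per-tissue true effects are nearly perfectly correlated in
both the motivating data and the simulations.

## Convergence between populations

A gene is *convergent* iff lfsr < α in both populations and the posterior
mean effects share a nonzero sign ("same size in both populations" is read
as same *sign*, consistent with classifying by identical directional
change; genes significant in both populations with opposite signs are
reported separately as discordant). The overlap between the two
populations' significant lists is tested against the upper tail of the
hypergeometric distribution (computed in log space), with the background
N equal to the number of genes assayed in the relevant analysis union.
Effect concordance reports Pearson correlations over all genes and over
the convergent subset.

## IBD classification

Sibling plants of one family share the same paternal haplotype over a
chromosome segment (IBD) or not, and shared haplotypes show as shared
heterozygous-SNP patterns in RNA-seq. Heterozygous calls are taken to be
the SNPs passing the per-sample ASE filters. Each chromosome is split into
20 bins with equal SNP counts from the genome-wide panel (half-open
position boundaries); per bin the statistic is
$f = |A \cap B| / \min(|A|, |B|)$ over the two samples' het sets, missing
when either set is empty. Fractions are pooled across chromosomes per
sample pair (one mixture fit per pair; pooling gives the mixture enough
points and the two modes are global properties of the pair), a
two-component Gaussian mixture is fitted by EM (means initialized at the
25th/75th percentiles, equal variances at the overall variance, equal
weights, tolerance $10^{-8}$, 1000 iterations maximum), and bins are
called IBD when the posterior of the *higher-mean* component is strictly
above 0.9, not-IBD strictly below 0.1, otherwise ambiguous. Degenerate
inputs (all fractions identical) flag the fit and return split posteriors,
leaving every bin ambiguous.

In synthetic validation, a bin that straddles a simulated segment boundary
is genuinely part-IBD and part-not, so no binary truth label exists for
it; classification accuracy is therefore judged on uniformly inherited
bins (about 90% of bins under the default 5-segment, 20-bin geometry).

## Cell-composition scores

For marker set $c$ with weights $w_{gc}$, a sample's score is the weighted
sum of mean-centered log2 expression,
$\mathrm{score}_{sc} = \sum_g w_{gc}(x_{gs} - \bar x_{g\cdot})$. This is
relative, not a deconvolution: it does not assume the reference marker
sets cover all cell populations present. Reliability is assessed by
re-computing the scores after randomly reassigning marker identities to
expressed genes (weights retained, 200 permutations by default); the
statistic is the total variance of the score matrix across samples
(variance explained in expression space is a plausible alternative; the
score variance was chosen as the direct measure of the quantity actually
used downstream), and the empirical p-value is
$(1 + \#\{\text{null} \ge \text{observed}\})/(n_{\mathrm{perm}} + 1)$.
The packaged marker table is synthetic and illustrative; real reference
markers are user-supplied.

## The synthetic cohorts

`simulate_cohort()` emulates the full study design: 108 F1 families by
default, split between two populations and two elevation classes; three
plants per family (two at the two-block highland site, one at the lowland
site) and three site:tissue conditions; three sampling teams with
round-robin field order per tissue; latitude uniform within population.
Per gene and paternal haplotype, the cis effect is
$\theta_{g,h} \sim N(\delta_g \cdot \mathrm{highland}, \tau^2)$ with
$\delta_g = \delta$ for the designated DASE genes and 0 otherwise. Totals
are negative binomial with the maternal allele constant and the paternal
allele scaled by $2^\theta$ (so cis shifts also move total expression, as
the cross design implies); the allelic split is beta-binomial with
intra-class correlation $\rho$ (parameterized
$\alpha = p(1-\rho)/\rho$, $\beta = (1-p)(1-\rho)/\rho$; $\rho = 0$ is
binomial); SNP counts arise by multinomial thinning of the gene's allelic
reads over its exonic SNPs; haplotypes segregate independently in five
fixed-length segments per chromosome (simpler than a recombination map and
sufficient to exercise the IBD classifier); and sequencing errors flip
each read's allele call at rate `seq_error_rate`, creating spurious
minor-allele counts at homozygous loci.

What the simulator does *not* emulate: read-level alignment artifacts and
mapping bias beyond the scalar error rate, reference bias, linked SNPs
with correlated errors, spatial field gradients beyond the order
polynomial, true diel expression dynamics, and real maize genome
structure. Passing tests therefore demonstrate the statistical machinery
under the stated generative assumptions — correct filters, weights,
shrinkage, calibration — not robustness to every artifact of real
sequencing data.

### Problem sizes used by the test suite

The unit suite uses cohorts of 20 families × 300 genes; the end-to-end
recovery checks use 40 families × 2,000 genes with 200 DASE genes at
$\delta = 1$, $\tau = 0.3$, $\rho = 0.01$; the shrinkage calibration uses
5,000 genes × 6 conditions; the IBD checks use 4 families × 500 genes
with 8 SNPs per gene. These sizes were chosen to make every stage's
behavior measurable with comfortable statistical margins while keeping a
full run of the suite fast enough for routine development.

## Known limitations

* `snp_sum` aggregation double-counts multi-SNP reads; totals (and hence
  variance-trend abscissae) are slightly inflated when reads span SNPs.
* The residual-correlation estimator is a moment simplification; with few
  near-null genes it falls back to the identity.
* The penalized-likelihood mixture fit can legitimately assign a small
  share of weight to small-scale singleton components on finite null data
  (absorbing per-condition variance sampling noise of order
  $\sqrt{2/J}$); lfsr-based calls remain calibrated, but the reported
  $\pi_0$ is not a sharp null-proportion estimate.
* The hypergeometric overlap test treats gene calls as exchangeable; it
  ignores detection-probability bias (expression level, gene length),
  which dedicated enrichment machinery would model.
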