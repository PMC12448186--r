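---
title: "Methods: detecting parallel latitudinal transcriptome differentiation"
author: "parallelCline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting parallel latitudinal transcriptome differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parallelCline)
```

# Overview

`parallelCline` asks whether species that independently colonised the
same latitudinal gradient show *parallel* gene expression responses:
shared differentially expressed (DE) orthologs beyond the independence
expectation, concordant directions of change, correlated log fold
changes, and asymmetric expression divergence along the lineage leading
to one focal population. This vignette is the package's own account of
the statistical machinery, the choices behind it, and what its
validation does and does not establish.

The pipeline consumes gene-by-sample read-count matrices with gene
lengths, sample metadata (species, population, tissue, replicate),
one-to-one ortholog maps, and gene-class files. It starts at counts:
alignment, quantification and ortholog inference are upstream of this
package.

# Differential expression engine

## Normalisation and filtering

Counts are converted to transcripts per million,
$\mathrm{TPM}_{gs} = 10^6 \frac{c_{gs}/\ell_g}{\sum_{g'} c_{g's}/\ell_{g'}}$
with $\ell$ in kilobases; every non-degenerate sample column sums to
$10^6$ by construction (the identity is asserted to relative tolerance
$10^{-6}$ in the validity checks). A gene is *expressed* in a species ×
tissue cell when its median TPM strictly exceeds 1 in at least one of
the two focal populations; medians use the standard midpoint rule for
even replicate counts. The strict inequality matters at the boundary: a
gene at exactly 1 TPM in both populations is excluded.

## The moderated t-statistic

DE between the low- and high-latitude populations is tested on
log2-CPM, $\log_2\!\big((c + p)/(N + 2p)\cdot 10^6\big)$ with prior
count $p = 0.5$ (configurable; the prior stabilises zeros at the cost
of a slight shrinkage of extreme fold changes). For each gene the
pooled two-group variance $s_g^2$ with $d_g = n_1 + n_2 - 2$ degrees of
freedom is shrunk towards a prior variance:

$$\tilde s^2_g = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
  t_g = \frac{\bar x_{g,\text{low}} - \bar x_{g,\text{high}}}
             {\sqrt{\tilde s^2_g (1/n_1 + 1/n_2)}} \sim t_{d_0 + d_g}.$$

The hyperparameters $(d_0, s_0^2)$ are the method-of-moments fit of a
scaled inverse-chi-square prior to the observed variances on the log
scale: $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(\log s^2) - \psi'(d_g/2)$ (via a Newton
inversion of the trigamma function, relative tolerance $10^{-10}$),
clamped to $+\infty$ when the observed spread of log variances does not
exceed what sampling alone explains — in which case every gene is
tested against the common variance with a normal reference
distribution. Two limits anchor the implementation and are tested
exactly: with $d_0 = 0$ the statistic *is* the ordinary pooled
two-sample t (checked against `t.test` to $10^{-10}$ on random
matrices), and with $d_0 = \infty$ it is the global-variance z-like
statistic.

Raw p-values are Benjamini–Hochberg adjusted (the step-up rule; the
suite checks the implementation against a hand-rolled oracle), and DE
is called at adjusted P ≤ 0.1 — deliberately more liberal than the
conventional 0.05, because downstream parallelism statistics compare DE
sets *between* species and a moderate false-discovery rate does not
manufacture cross-species sharing.

The sign convention throughout: `log_fc` is low-latitude minus
high-latitude, so negative values mean lower expression in the
low-latitude ("Panama"-role) population.

**Deliberate simplification.** The engine fits no mean–variance trend
and no observation-level precision weights. With three replicates per
group, a trend fit is poorly identified; the cost is that
low-expression genes carry extra Poisson noise that the global prior
under-shrinks, so the extreme tail of the null statistic is slightly
heavy. In the package's own null simulations the raw p-values are
uniform to within Monte-Carlo error at the 0.05 and 0.01 levels, and
the fraction of genes falsely flagged at adjusted P ≤ 0.1 stays far
below the nominal rate, but the familywise chance of *at least one*
false call exceeds 0.1. Analyses that need strict familywise control
should tighten `alpha`.

# Parallelism statistics

All cross-species statements are restricted to ortholog rows whose
genes are expressed in every species of the comparison (1:1 for pairs,
1:1:1 for the triple). With $N$ jointly-expressed orthologs and
per-species DE counts $n_i$:

* **Expected shared DE.** Under independence the expected number of
  orthologs DE in every species is $N\prod_i (n_i/N)$ — the
  hypergeometric/permutation mean. The test suite verifies the formula
  against the empirical mean of shared counts over label shuffles.
* **Enrichment test.** One-sided upper-tail exact binomial
  $P(X \ge k_{obs})$, $X \sim \mathrm{Bin}(N, \prod_i n_i/N)$. The
  upper tail is used because the scientific question is an *excess* of
  sharing. The binomial treats per-species DE flags as independent
  across orthologs; the planted-signal experiments below confirm the
  test's operating characteristics under that regime.
* **Directionality.** An ortholog is concordant when its log fold
  changes share a sign in all species. Concordance among shared-DE
  orthologs is tested (again upper-tail binomial) against the
  concordant fraction of *all* expressed orthologs — the natural null
  that absorbs transcriptome-wide directionality skew. Genes with a log
  fold change of exactly 0 are ties; they are excluded from numerator
  and denominator with a warning (a measure-zero event for continuous
  estimates, reachable only with degenerate inputs).
* **Correlation.** Spearman's ρ of log fold changes (average ranks for
  ties, t-approximation p-value) over all jointly-expressed orthologs
  of a species pair. Rank correlation is used because fold-change
  distributions are heavy-tailed and the comparison spans species with
  different dynamic ranges.

# Tissue bias

τ is computed on log2(TPM+1) over a multi-tissue reference,
$\tau = \sum_i (1 - x_i/x_{max})/(n-1)$, with genes of zero maximal
expression flagged undefined. τ is scale-invariant and monotone in the
dominant tissue's expression (both are property-tested). Genes with
τ ≥ 0.9 are called biased in their maximal tissue.

Because a multi-tissue reference typically exists for only one species,
the package carries a *calibrated organ-vs-whole-male classifier* that
applies uniformly across species. Both contrasts are oriented as (whole
male − organ), so organ-enriched genes are strongly **negative**; this
is the only orientation under which the calibrated accessory-gland
cutoff (−3.59) and testis cutoff (−0.46) select organ-enriched genes
while the companion requirement — (whole male − other organ) ≥ 1 —
depletes genes enriched in the other organ. The accessory-gland rule
additionally requires adjusted P ≤ 0.01, organ median TPM ≥ 1 and
average expression strictly > 0; the testis rule uses TPM ≥ 5 and
average expression ≥ 0 (the strict/non-strict distinction is kept
exactly as calibrated). The minimum TPM is evaluated on the organ's
median TPM across all focal samples — the reference data do not
resolve per-population evaluation, and the pooled median is the least
noisy choice with three replicates.

`calibrateThresholds()` reproduces the calibration procedure itself:
a grid search maximising the Jaccard overlap with the τ-based set, ties
broken towards stricter thresholds (more negative organ logFC first,
then higher TPM, lower adjusted-P bound, higher other-organ bound), so
the selected rule is the most conservative among equally good ones.

# Gene-class enrichment

Class × DE and class × logFC-sign tables are built over the expressed
universe; the direction table drops exact-zero fold changes with a
warning and a correspondingly reduced total. Fisher's exact test is
two-sided by summation of hypergeometric probabilities not exceeding
that of the observed table (the classical convention; a table with
identical row proportions gives p = 1 exactly), with the
conditional-MLE odds ratio. The suite cross-checks the test against a
full enumeration oracle on random tables to $10^{-12}$, and the
acceptance script reproduces published accessory-gland contingency
tables to three significant figures. Zero-margin tables return p = 1
with an undefined, flagged odds ratio.

# Lineage-specific expression divergence

Per gene, the four populations (two focal, two outgroup) are summarised
as log2(median TPM + 1); the pseudo-count of 1 matches the rest of the
pipeline and bounds the profile below. A gene's expression distance
between populations is the absolute difference of these values — for a
one-dimensional trait the only freedom is the scale, and the log scale
makes branch lengths comparable across expression levels.

On the fixed topology ((out1, out2), (focal1, focal2)) the terminal
branch to focal population 1 is the three-point estimate
$b_1 = \tfrac12\big(d(f_1,o) + d(f_1,f_2) - d(f_2,o)\big)$, computed
per outgroup, floored at 0 (branch lengths are non-negative by
definition; the flooring is a small positive bias under noise and is
documented as such), and averaged over the two outgroups — a symmetric
use of both rooting populations rather than a min or max. For rooted
collinear profiles this estimator provably coincides with the
brute-force minimal-total-length embedding of the quartet on the real
line, and the suite checks equality to $10^{-12}$ over a grid of $10^4$
profiles. When the outgroups straddle the focal pair the minimal
embedding is non-unique (an interval of equally short trees), so no
estimator is identified there; the package's estimator degrades
gracefully by averaging the two rootings.

Gene-set contrasts (DE vs not, tissue-biased vs not, focal population 1
vs 2) use Welch's unequal-variance t-test — the comparisons involve
differently-sized, differently-dispersed gene sets, and the same test
is applied to the population contrast for uniformity. Zero-variance
comparisons are flagged with `p = NA` rather than a fabricated value.

# The synthetic generator

`simulateDataset()` emulates the study design: 2–3 species × 1–2
tissues × two focal populations × `n_replicates` (default 3) replicate
pools, plus two outgroup populations for rooting. Defaults are fixed
once as the package's reference conditions:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 8000 | expressed-gene scale of a male reproductive tissue |
| `baseline_log_mean_range` | (0, 8) log2 | spans ~3 orders of magnitude of TPM |
| `dispersion` (NB φ) | 0.005 | replicate pools of ~36 flies: near-technical variability (CV ≈ 7%); also the regime in which estimated log fold changes are faithful enough that the cross-species correlation is recovered within its stated ±0.07 band (see below) |
| `effect_sd` | 0.5 log2 | planted latitudinal effects large enough to be individually detectable at 3 vs 3 |
| `cross_species_corr` | 0.46 | the flagship accessory-gland estimate between the two distantly related species |
| `shared_outlier_fraction`, `outlier_effect` | 0.02, 2 | a thin layer of strong, shared-direction outliers |
| `de_direction_bias` | 0.5 | truth-level sign symmetry; the observed skew towards lower low-latitude expression is an *outcome* to detect, not a planted condition — set it above 0.5 to plant the skew |
| `ortholog_coverage` | 0.8 | one-to-one maps never cover the genome |
| `outgroup_drift_sd` | 0.3 log2 | outgroup populations drift independently from the ancestral mean |
| `library_size_range` | 5–15 M reads | bulk RNA-seq depth |

Counts are negative-binomial with mean
$\mu_{gs} = L_s \cdot a_g \ell_g / \sum_{g'} a_{g'} \ell_{g'}$ where
$a_g = 2^{\text{baseline} + \text{effect} \cdot [\text{low latitude}]}$
and variance $\mu + \phi\mu^2$; effects enter the low-latitude
population only. True effects are equicorrelated across species over
ortholog rows. The correlation is implemented by drawing a fixed
n × 3 standard-normal block from a dedicated cross-species stream and
mixing it through the *nested* Cholesky factor of the equicorrelation
matrix, while every other draw comes from a per-species stream at a
fixed seed offset — so adding a third species changes nothing about the
first two species' data. A three-species equicorrelation below −0.5 is
rejected as non-positive-semidefinite. Gene-class memberships are
planted with a configurable relative risk among *affected* genes
(those whose largest absolute planted effect reaches `effect_sd`).

What the generator does **not** emulate: batch effects, a
mean–dispersion trend, isoform structure, correlated gene–gene
expression, compositional shifts from a few dominant transcripts, and
mapping artefacts. Passing the validation suite therefore demonstrates
the statistical machinery is correct under the stated model, not that
real tissue data satisfy that model.

## Calibration and recovery experiments

The suite's simulation experiments (also re-run by
`scripts/acceptance.R`) are designed as follows; sizes were chosen to
keep the full suite within a few minutes on one CPU while leaving the
Monte-Carlo error well inside each acceptance band.

* **Correlation recovery** — 20 seeds, 8000 orthologs, deep (10⁷-read)
  libraries, planted ρ = 0.46 with outliers disabled: the estimated
  Spearman ρ must fall in [0.39, 0.53] in ≥ 90% of seeds. Outliers are
  disabled because a layer of forced common-sign effects adds a shared
  variance component and would bias the recovered correlation upward by
  design. Two attenuation mechanisms act downward: the normal-score
  rank shrink ($\rho_S = \tfrac{6}{\pi}\arcsin(\rho/2)$) and estimation
  noise ($\approx 2.08\,\phi \cdot 2/3$ on the log2FC variance), which
  is why the generator's dispersion default sits at 0.005 — at larger
  φ the estimated correlation is attenuated out of its own recovery
  band regardless of data volume.
* **Null calibration** — 20 null seeds (no effects) for the DE engine:
  per-seed flagged fraction within [0, 0.15] and pooled false-call
  fraction below α; 200 independent-effect seeds for the enrichment
  test: p ≤ 0.05 in at most 8% of seeds; 100 symmetric-drift seeds for
  the branch lengths: the mean focal branch-length difference is
  centred at 0 (within 3 standard errors of its own spread).
* **Planted-signal detection** — 2% shared outliers on an otherwise
  null background must drive the enrichment p below 0.01 in ≥ 90% of
  seeds at N = 5000. The null background isolates the sharing signal:
  against a dense background of independent effects, a 2% layer of
  shared genes shifts the shared count by less than one binomial
  standard deviation and is undetectable by construction — a power
  fact, not an implementation defect. Similarly, effects planted in
  the low-latitude population must lengthen that population's mean
  branch in ≥ 95% of seeds.
* **Engine limits** — the d₀ → 0 pooled-t identity (10⁻¹⁰ on 100
  random matrices) and recovery of (d₀ = 4, s₀² = 0.05) within ±15%
  from 20 000 prior-simulated variances.

# Degenerate inputs and tie-breaks

* All-zero samples yield all-zero TPM columns (no division by zero).
* Genes with zero expression in every reference tissue get undefined τ.
* Exactly-zero log fold changes are excluded from sign-based statistics
  with a warning, shrinking the relevant totals.
* Identical gene variances clamp the variance prior to $d_0 = \infty$.
* Threshold-calibration ties resolve towards the strictest cell.
* Negative three-point branch estimates floor at 0 per outgroup before
  averaging.
* Binomial tests are exact tail sums; nothing is approximated by a
  normal unless the t reference itself has infinite df.

# Known limitations

* No mean–variance trend or precision weights (see above); familywise
  null behaviour is liberal at the margins even though per-gene and
  FDR-scale behaviour is calibrated.
* The independence-product expectation and binomial enrichment test
  ignore correlation between species induced by shared library
  artefacts; use the permutation oracle in the tests as a template if
  that matters.
* Branch lengths inherit the flooring bias at low signal; comparisons
  between gene sets share the bias and are less affected than absolute
  values.
* Tissue-bias comparisons across species with very different body and
  organ sizes are structurally cautious: the classifier is uniform, but
  organ-to-whole ratios are not biologically equivalent across such
  species.
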