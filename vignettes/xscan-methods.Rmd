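---
title: "Methods: discovering autosomal loci with female-specific effects on X-chromosome methylation"
author: "xscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering autosomal loci with female-specific effects on X-chromosome methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xscan)
```

## The scientific problem

X-chromosome inactivation (XCI) silences one of the two female X
chromosomes, but a substantial minority of X-linked genes escape this
silencing, some of them variably between individuals. Because escape
status is mirrored in DNA methylation of X-chromosomal CpG islands,
autosomal regulators of XCI can be searched for genetically: an
autosomal variant that modulates the XCI machinery should produce
*female-specific*, chromosome-wide shifts in X methylation. `xscan`
implements that search as a reusable pipeline and ships a synthetic-data
generator with planted, recoverable ground truth so that every stage can
be validated end to end.

## The statistical model

For variant $i$ with dosage $x_i$ and CpG $j$ with (transformed)
methylation $y_j$, the discovery model is the mass-univariate linear
model

$$y_j = \beta_{ij} x_i + \gamma M + \delta U + \varepsilon$$

with known covariates $M$ (age, six blood cell counts, cohort,
technical batch) and estimated latent confounders $U$. Each variant
yields one two-sided Wald p-value per CpG, $p_{ij}$, from the $t$
distribution with $n - k$ residual degrees of freedom. The per-variant
family of $m$ p-values is combined with the **Simes procedure**,

$$P_i = \min_j \; \frac{m \, p_{(j)}}{j},$$

a valid global test of "variant $i$ affects methylation anywhere on the
chromosome" under independence or positive dependence. This reduces the
whole scan to one genome-wide association study with threshold
$P_i < 5 \times 10^{-8}$.

Computationally, the per-variant coefficient and Wald $t$ are obtained
through the Frisch–Waugh–Lovell identity: both the dosage panel and the
trait matrix are residualized on the covariate design once (QR), after
which a single cross-product yields every $t_{ij}$ exactly equal to the
full-model fit, with the degrees of freedom of the full design. The
equivalence is tested against an explicit normal-equations oracle to
1e-10.

### Iterative conditional discovery

Independent loci are separated by conditioning: the strongest sentinel
(lowest $P_i$) is added to the covariates and the scan repeated until no
variant passes the threshold. Conditioning on the sentinel removes the
signal of all its LD proxies (their partial association given the
sentinel is zero), so a locus is reported once. A hard cap of 100
iterations guarantees termination; variants whose residual dosage
variance vanishes after conditioning are dropped from the ranking
rather than tested.

### Female-specificity and interaction

A locus discovered in females is validated in the male stratum: the
sentinel *and every proxy* (dosage $r^2 \ge 0.8$ within 1 Mb, computed
in males) are scanned in males, and the locus is called female-specific
only if the minimum male overall $P$ exceeds 0.05. Separately, the
per-CpG minimum male Wald p is compared against a reporting threshold of
$1.1 \times 10^{-6}$ to list loci that replicate in males; the two
thresholds serve different claims (exclusion vs replication) and are
both configurable. Note that the exclusion rule takes a minimum over
$1 + n_\text{proxies}$ approximately uniform null p-values, so a truly
female-specific locus with $k$ proxies is retained with probability
about $0.95^{\,1+k}$ — a deliberate property of the conservative rule,
visible in the synthetic confusion matrices.

The genotype-by-sex interaction model
$y = \beta_1 x + \beta_2 \text{sex} + \beta_3 (x \cdot \text{sex}) +
\gamma M + \delta U$ is fitted on the combined sample; per-CpG Wald
p-values for $\beta_3$ are Simes-combined, with a default significance
threshold of $5.9 \times 10^{-4}$.

### Replication meta-analysis

Each sentinel is re-tested in independent replication cohorts with the
plain per-cohort regression $y_{jk} = \beta_{ijk} x_{ik}$ (traits
inverse-normal transformed within cohort; no further covariates by
default, with an option to add them). Per CpG, cohort $t$ statistics are
combined by **Stouffer's weighted Z**,

$$Z_{ij} = \frac{\sum_k w_k t_{ijk}}{\sqrt{\sum_k w_k^2}}, \qquad
w_k = n_k,$$

treating $t$ as $z$ (accurate at the cohort sizes the method targets;
the package's own tests use $n \ge 100$ per cohort). Cohorts with a
missing statistic (e.g. monomorphic dosage) are excluded from both
sums, preserving the weight normalization. Per-CpG $z$ becomes a
two-sided normal p, Simes combines CpGs per variant, and Bonferroni
across the number of sentinels carried to replication gives the
adjusted replication P.

### QTL mapping and the epistasis check

* **cis-eQTL**: genes whose interval lies within 250 kb of the sentinel
  (distance measured to the interval, zero inside; the window is closed,
  so a gene at exactly 250,000 bp is tested), Bonferroni within the
  genes actually tested.
* **CpG–expression coupling**: the same window anchored on the CpG,
  with methylation predicting expression and known covariates only.
* **trans-meQTL**: autosomal CpGs on other chromosomes, or more than
  5 Mb away on the sentinel's chromosome, on the combined-sex sample
  (sex is a covariate); Benjamini–Hochberg within each variant's
  p-vector.
* **Epistasis check**: each associated X CpG is first mapped for its
  strongest X-chromosomal cis-meQTL (250 kb, Bonferroni, ties broken
  toward the lower position), and the autosomal effect is re-estimated
  with that cis-SNP as an additional covariate. With no cis-SNP the
  adjusted estimate equals the unadjusted one exactly.

### Annotation and enrichment

CpGs are classified as CpG-island (inside a CGI interval), shore
(within a closed 2 kb band of an island boundary), or non-CGI; interval
tracks follow the "any dataset of the mark" overlap rule; XCI escape
class is the class of the nearest TSS within 10 kb (ties toward the
smaller position), else unannotated. Enrichment of an associated CpG
set uses **Fisher's exact test** (two-sided, summing table probabilities
at most the observed) against the chromosome-wide CpG background. The
reported *fold* is the ratio of annotation proportions — not the odds
ratio — because only the proportion ratio reports enrichment and
depletion on one reciprocal scale; depletion is reported as the
reciprocal with `direction = "depleted"`.

### Direction-consistency sign test

Effect-sign consistency among an associated CpG set is tested with the
exact two-sided sign test,
$p = \min\!\big(1,\, 2\min(P(X \le k), P(X \ge k))\big)$ under
$\mathrm{Binomial}(n, 1/2)$. For example, 10 of 10 consistent signs give
$2/2^{10}$, and 56 of 57 give $2 \cdot 58/2^{57} \approx 8.0 \times
10^{-16}$. Published analyses of this design sometimes print values for
such counts computed under unstated conventions that do not reproduce
under any exact two-sided binomial variant; this package deliberately
fixes and documents the convention above rather than reverse-engineering
printed numbers.

## Preprocessing choices

* **Variant QC** retains variants with imputation info $\ge 0.5$, exact
  Hardy–Weinberg $P \ge 10^{-4}$ (Wigginton-style conditional
  enumeration), call rate $\ge 95\%$ and MAF $\ge 1\%$; all boundaries
  inclusive, filter idempotent.
* **Inverse-normal transformation** uses the Blom offset,
  $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, within each cohort
  independently, with ties averaged. Within-cohort transformation also
  removes additive cohort intercepts, which is why the generator plants
  them.
* **Latent confounders** are defined in this package as the leading
  principal-component scores of the feature-standardized,
  covariate-residualized trait matrix, with the factor count chosen by
  the eigenvalue-difference rule
  $q = \arg\max_{k \le q_\text{max}} (\lambda_k - \lambda_{k+1})$
  (default $q_\text{max} = 10$). Estimating from residuals makes the
  scores orthogonal to the known covariates by construction. This is a
  deliberately simple, fully specified estimator; it does not implement
  negative-control or iteratively reweighted confounder models.
* Factors are estimated **within each analysis stratum** (females,
  males, combined), since a stratum-specific scan should be adjusted
  for stratum-specific structure; the choice is recorded in the run
  manifest's latent-factor counts.
* Missing dosages are mean-imputed per variant (and counted) before
  modelling, because OLS needs complete predictors and imputed dosage
  panels are effectively complete.
* Categorical covariates are reference-coded. Batch is nested inside
  cohort, so batch indicators alias the cohort block; aliased indicator
  columns are dropped automatically (and reported), whereas a collinear
  *numeric* covariate — for instance a dosage conditioned on twice — is
  an error naming the column.

## The synthetic-data generator

The generator draws, per variant, Hardy–Weinberg dosages at a
configurable MAF; per CpG, a baseline methylation level uniform on
2.6–55% (the observed dynamic range of affected CpGs in blood);
cell-count, latent-factor and per-cohort confounding with Gaussian
per-CpG loadings; and Gaussian noise on the beta scale (default SD
0.02), truncated to $[0,1]$. Planted loci add a per-allele beta-scale
effect (defaults in the 0.3–4% range typical of blood meQTLs) at a
configured CpG set, applied to females only when the locus is
female-specific; each target CpG keeps the planted sign with probability
`direction_consistency`, the others flip. Long-range (trans) autosomal
effects are applied in both sexes. LD proxies are synthesized by
copy-with-probability $\sqrt{r^2}$, giving the target dosage
correlation at matched MAF. Variants, CpGs and genes live on a
miniature genome (four 50-Mb autosomes, one 150-Mb X) so that the
250 kb / 1 Mb / 5 Mb / 10 kb window logic is exercised with realistic
arithmetic but desk-scale cost.

Annotation tracks are built so that planted target CpGs fall into CGI
and variable-escape intervals with probability elevated by a
configurable enrichment factor over a 5% background; the recorded truth
assignment is re-derived from the constructed tracks, so it is exactly
consistent with downstream annotation.

What the generator does **not** emulate: realistic LD beyond the
explicit proxy blocks, 450k probe density or probe chemistry, beta-value
heteroscedasticity (noise is truncated Gaussian, not Beta-distributed),
read- or intensity-level artefacts, imputation uncertainty (info scores
default to 1), or relatedness. Passing tests therefore demonstrate the
statistical machinery under the model's own assumptions, not robustness
to every failure mode of real cohort data.

Noise defaults were chosen once for desk-scale power: the residual SD of
methylation at affected CpGs is not an empirically pinned quantity, and
0.02 beta makes a 1.5% per-allele effect detectable at $n = 1000$
without making the scan trivial.

## Numerical and design details

* Two-sided p-values are fixed as $2(1 - F_t(|t|))$.
* The Simes statistic needs no tie correction; ranking uses a stable
  sort, and the reported `argmin_feature` is the CpG attaining the
  minimum.
* Residual dosage variance below $10^{-10}$ of the raw sum of squares
  marks a variant collinear with the design (e.g. a conditioned-on
  sentinel); such variants get `overall_p = NA`.
* Sentinel selection breaks ties by overall P, then variant id.
* Per-CpG effect sizes are re-estimated on the raw beta scale with the
  same design, so effects are reported as % methylation per allele even
  though inference runs on the inverse-normal scale.
* Seeds: one master seed; every generator stage derives its own stream
  (`seed*1000 + stage`), so stages are independently reproducible and
  the whole pipeline is byte-identical under a fixed config and seed.
* The run manifest records config hash, thresholds, per-stage counts
  and output file hashes; a re-run with `resume = TRUE` and unchanged
  hashes reuses the completed outputs (the skip is whole-run, since
  stages exchange in-memory objects rather than files).

## Reference problem sizes

The package's tests run the method at deliberately chosen desk-scale
conditions: discovery 1,000 females + 600 males across 3 cohorts, 2,000
autosomal variants, 500 X-chromosomal CpGs, 300 autosomal CpGs, 50
genes; a type-I study of 1,000 null variants x 200 CpGs x 10 seeds with
confounding present and adjusted; power, conditional-separation and
replication studies of 20 seeds each; and enrichment recovery at 50
target / 10,000 background CpGs. These sizes are the package's own
reference conditions for validating the statistics; chromosome-scale
inputs run through exactly the same code paths.

## Known limitations

* When a planted locus affects a large fraction of the trait panel
  (roughly: when its eigenvalue rivals the confounder eigenvalues),
  PCA-based latent factors can absorb genuine genetic signal. At the
  reference conditions (50 of 500 CpGs, 1.5% effects) the genetic
  component stays well below the confounder spectrum and the
  eigenvalue-difference rule selects only the true factors, but
  aggressive factor counts on small panels will cost power — the
  classic bias–power trade-off of confounder adjustment.
* The male-exclusion rule's retention probability decays with the
  number of proxies (see above).
* Stouffer combination treats per-cohort $t$ as $z$; with very small
  cohorts this is anticonservative.
* The Fisher fold is a ratio of proportions with the target included in
  the background (matching the chromosome-wide background definition);
  with small backgrounds this differs visibly from the odds ratio.
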