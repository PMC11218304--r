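---
title: "Rare-variant collapsing burden analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant collapsing burden analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecollapse)
library(dplyr)
```

## The analysis in one paragraph

`rarecollapse` implements a case/control rare-variant collapsing (burden)
analysis for sequenced cohorts. Each gene's rare *qualifying variants* are
reduced to a single dominant carrier indicator per sample (a sample is a
carrier if it holds at least one qualifying allele in the unit). Carrier
frequencies are then compared between cases and controls with an **exact
two-sided Cochran–Mantel–Haenszel (CMH) test** stratified by ancestry
cluster, so that cohorts mixing ancestries with very different
case:control ratios are not confounded. Units can be whole genes, the
intolerant-domain subset of a gene (subRVIS percentile < 25), or curated
gene sets. Calibration is assessed with within-cluster label permutations
rather than a uniform reference, because collapsing p-values are discrete.

## The exact stratified CMH test

For unit $u$ and cluster $i$ the data form a $2\times 2$ table with cells
$a_i$ (case carriers), $b_i$ (case non-carriers), $c_i$, $d_i$ (control
carriers / non-carriers). Conditioning on all margins, under the null of a
common odds ratio of 1 each $a_i$ follows a central hypergeometric
distribution, and the total $S = \sum_i a_i$ follows their convolution.
`exact_cmh()` computes this convolution directly — no asymptotic
$\chi^2$ approximation — and reports the **probability-mass two-sided
p-value**:

$$p = \Pr\!\left(\,\{s : \Pr(S=s) \le \Pr(S=s_{\mathrm{obs}})\,(1+10^{-7})\}\,\right).$$

This is the same two-sided definition used by `fisher.test()` and the
exact mode of `mantelhaen.test()` in R, which the test suite uses as
independent cross-checks (together with a brute-force enumeration over all
margin-consistent cell configurations). A doubled-one-tail variant is
available behind `alternative = "doubled"` for comparison; mid-p variants
are deliberately not offered.

Numerical choices:

* The convolution is accumulated **in log space** (`dhyper(log = TRUE)`
  plus a vectorised log-sum-exp). Burden signals of interest sit at
  p-values far below $10^{-30}$, where naive probability products
  underflow; log-space accumulation keeps the full support exact.
* Ties at the observed point probability are admitted with a relative
  tolerance factor $1 + 10^{-7}$, matching the convention of the exact
  tests in base R.
* Strata whose conditional support is a single point (no carriers, or
  margins that force the table) contribute nothing and are retained; a
  table whose whole support is one point is reported untestable with
  $p = 1$.

The effect estimate is the Mantel–Haenszel pooled odds ratio
$\widehat{OR}_{MH} = \sum_i (a_i d_i/n_i) \,/\, \sum_i (b_i c_i/n_i)$ with a
Robins–Breslow–Greenland variance for the 95% interval on the log scale.
A zero denominator with a positive numerator is reported as $+\infty$ with
an undefined interval; an all-zero ratio is undefined and flagged.

## Qualifying-variant models

A variant qualifies for a sample under a model when **all** predicates
hold:

| predicate | default | notes |
|---|---|---|
| effect class | model-specific | PTV = stop gained, frameshift, canonical splice acceptor/donor |
| gnomAD AF, each population | $< 0.1\%$ | a single population at or above the bound disqualifies |
| internal AF | $< 0.1\%$ | alternate alleles / (2 × called samples), full cohort, no leave-one-out |
| genotype | dominant | at least one alternate allele |
| subRVIS percentile (domain models) | $< 25$ | strict; unannotated positions never qualify and are audited |

`model_registry()` ships the six nonsynonymous models — `ptv`,
`missense`, `ptv_missense`, each with and without the intolerant-domain
restriction — plus the `synonymous` negative control. Start/stop-loss and
in-frame indels are excluded from the default effect sets (the
conventional protein-truncating definition in collapsing studies); both
the effect sets and the thresholds are plain `model_spec()` fields, so
membership can be changed without touching code. Study-wide significance
uses $\alpha = 4.9\times 10^{-7}$, the multiplicity adjustment for six
nonsynonymous models.

Interpretation decisions worth knowing:

* **Genotype-level QC failures remove the single genotype, not the
  site.** A low-GQ carrier disappears; other carriers at the site remain.
* The internal AF is computed once on the QC-retained cohort (cases and
  controls pooled). When a VCF is read, the called denominator is the
  per-site number of non-missing genotypes; for in-memory cohorts it is
  the retained sample count.
* All inequality directions are exactly as printed in the QC table of
  defaults (`qc_thresholds()`): e.g. Fisher strand bias 60 passes and 61
  fails for SNVs, heterozygous allele balance 0.30 passes and 0.29 fails,
  mapping-quality rank sum must be strictly greater than −10. A boundary
  grid test pins every threshold at value and value ± ε.

## Quality control and harmonization

Sample QC removes contamination > 2% and CCDS coverage < 90%, then prunes
relatedness: from every related pair up to second degree exactly one
member is removed, preferring to retain cases. The pruning is a greedy
vertex cover on the degree-≤2 relatedness graph — repeatedly drop the
sample maximising (is-control, number of remaining close partners,
sample id) — which is deterministic and resolves chains with the fewest
exclusions consistent with the case preference. Third-degree pairs are
unrestricted.

Coverage harmonization operates per cluster: a site is removed in a
cluster when the percentage of cases and of controls with ≥ 10× depth
differs by strictly more than 7 points. A site removed in one cluster can
remain testable in the others; removal masks all genotypes at that site
within the cluster. Clusters with fewer than 5 participants or fewer than
3 cases are dropped before any testing and the survivors become the CMH
strata.

## Permutation-based expected distributions

Exact CMH p-values on rare-carrier tables are discrete and conservative:
under the null a large share of units sits exactly at $p = 1$, so a
uniform QQ reference would fake deflation. `empirical_qq()` therefore
permutes phenotype labels **within clusters** (stratum margins are
preserved exactly) and recomputes every unit's p-value per permutation.
Because the conditional null distribution of a unit depends only on its
margins — which permutations never change — the support and its two-sided
p-values are computed once per unit and permutations reduce to sparse
matrix–vector products plus table lookups; 1,000 permutations at fixture
scale run in seconds.

The expected value at rank $r$ is the mean over permutations of the
$r$-th smallest p-value; the plotted band is the pointwise 2.5–97.5
percentile range of that order statistic (a simultaneous envelope is not
attempted). The inflation factor is

$$\lambda = \frac{\mathrm{median}\,\chi^2_1(\text{observed } p)}{\mathrm{median}\,\chi^2_1(\text{permuted } p)},$$

an empirical-null version of the usual median-based $\lambda$. When more
than half of all permuted p-values equal 1 the denominator is zero and
$\lambda$ is reported as `NA` with a warning — that is a statement about
carrier sparsity at the attempted scale, not about inflation. The default
of 1,000 permutations stabilises the percentile bands; $\lambda$ is
already stable at around 100.

## The cohort simulator

`simulate_cohort()` generates the inputs the analysis consumes — VCF,
manifest, kinship pairs, domain table, truth table — with the statistical
structure the method assumes, so every stage is testable without any
external data. What it emulates:

* a multi-cluster case/control cohort with configurable per-cluster
  case:control imbalance (the confounding CMH is for); the bundled
  `als_cohort_config()` uses 6,970 cases / 22,524 controls in 12 clusters
  dominated by one large cluster;
* per-gene dominant carriers drawn as independent Bernoulli events per
  sample, implemented as binomial counts per (gene, class, cluster,
  phenotype) plus uniform assignment — an exact equivalence that scales;
* planted case- or control-enriched genes via per-arm carrier rates;
  planted signal is **allelically heterogeneous**: the number of
  planted-class sites grows with the expected carrier count (about two
  carriers per site), as in real rare-variant architecture, which also
  keeps per-site internal AFs below the 0.1% gate;
* optional concentration of case signal in intolerant domains
  (`domain_concentration`), the situation in which the domain-restricted
  model beats the whole-gene model;
* differential-coverage artifact sites, variants common in exactly one
  gnomAD population, and variants violating exactly one QC threshold, to
  exercise the corresponding filters;
* the background per-gene carrier rate defaults to 0.005, matching the
  per-gene carrier counts visible in large exome collapsing cohorts
  (on the order of 100–200 carriers among ~30,000 samples).

What it deliberately does not model: read-level noise, linkage and
haplotype structure (negligible for dominant indicators in the MAF <
0.1% regime), ancestry admixture (clusters are labels), genotype-derived
kinship (pairs are planted labels), and subRVIS score derivation
(percentiles are inputs). Passing tests on simulated cohorts therefore
validate the *statistical machinery* — filters applied exactly as
specified, exact conditional inference, calibration under confounded
cluster structure — not the upstream bioinformatics of a real cohort.

The simulator-calibration property is checked against the permutation
null (a two-sample comparison), not against Uniform(0,1): discreteness
makes the uniform reference unattainable by construction, which is
precisely why the pipeline carries a permutation-based expected
distribution.

## Validation scale

The shipped tests run the full statistical validation at these problem
sizes, chosen to give stable Monte-Carlo estimates while keeping the
default suite fast: 500 random stratified tables against the enumeration
oracle; a null cohort of 2,000 cases / 5,000 controls × 5,000 genes for
type-I calibration and synonymous-model $\lambda$; 20 replicates of the
full-size cohort (1,000 genes) for power and OR recovery of an OR ≈ 16
planted gene; 50 replicates for the domain-restriction gain; 1,000
permutations for the permutation contract. `scripts/acceptance.R`
recomputes the same quantities from scratch with a caller-supplied seed.

## Known limitations

* The MH odds ratio on simulated cohorts is mildly attenuated relative to
  the planted marginal odds ratio because nonsynonymous background
  carriers (equal rates in both arms) join the planted carriers in the
  collapsed indicator — visible as a few-percent downward shift, well
  inside the tolerance the validation asserts.
* `ci95` is Wald-type on the log scale (RBG variance); it is undefined for
  tables with empty carrier cells rather than bootstrapped.
* The one-tailed control-depletion z-test between gene- and domain-level
  qualifying counts uses pooled variance and no continuity correction;
  its gene- and domain-level counts overlap (the domain set is a subset),
  and the test treats them as independent samples, exactly as the
  published caption values imply.
* Recessive or allele-count-weighted coding, covariate-adjusted
  regression burden tests, and Breslow–Day homogeneity checks are out of
  scope.
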