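---
title: "Methods: the type 1 diabetes genetic risk score and its evaluation"
author: "t1dgrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the type 1 diabetes genetic risk score and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dgrs)
```

## The model

The score is log-additive in risk-allele dosage with a categorical HLA
term:

$$\mathrm{GRS} \;=\; \frac{\sum_{i=1}^{n}\beta_i\,s_i \;+\; H_l}{(n+1)\times 2}$$

* $\beta_i = \ln(\mathrm{OR}_i)$, dimensionless, one per $\beta$-weighted
  locus: the non-HLA SNPs plus three HLA haplotype loci (non-DQ6, A24,
  non-B57). All weights are configuration, not code (`readWeights()`).
* $s_i \in \{0,1,2\}$ counts risk alleles. X-linked loci in males are
  counted 0 or 2, a dominant-risk reading of hemizygosity; a heterozygous
  X call in a male (possible only as assay noise) is promoted to 2 rather
  than dropped.
* $H_l = \ln(\mathrm{OR})$ of the subject's six-category HLA-DR-DQ
  diplotype. The HLA region violates per-allele additivity — the DR3/DR4
  heterozygote carries more risk than either homozygote — so it enters as
  one categorical term, and contributes the $+1$ in the denominator.
* $n$ counts the $\beta$-weighted loci *tested*. By default $n$ is
  per-sample (only called loci count; `missingPolicy = "per_sample_n"`),
  which avoids deflating the scores of samples with a few missing calls;
  `"panel_n"` fixes $n$ at the configured panel size for strict
  cross-sample comparability of the denominator. Both are implemented
  because the convention is genuinely ambiguous for samples below full
  call rate; with the default QC (below) the two differ by at most ~10%
  of non-HLA loci.

Component scores (`grs_hla_only`, `grs_nonhla_only`) split the numerator
but share the full score's denominator, so the decomposition is exact:
the two component numerators add to the full numerator at machine
precision (summation is fixed in panel order for bit-reproducibility).

### HLA imputation

Two tag SNPs determine the diplotype category: the DR3-DQ2 tag dosage
$d_3$ and DR4-DQ8 tag dosage $d_4$ map to DR3/DR4 when both are $\ge 1$,
to the corresponding homozygote at $(2,0)$/$(0,2)$, heterozygote-with-X
at $(1,0)$/$(0,1)$, and X/X at $(0,0)$. Only two haplotypes exist, so
$d_3 + d_4 > 2$ — the pairs $(2,1), (1,2), (2,2)$ — is biologically
impossible; no published rule covers this, so the package's explicit
policy is to assign the highest-risk compatible category (DR3/DR4) and
set a conflict flag that propagates into scored output, rather than drop
the sample. The protective DR15-DQ6 and B57 haplotypes are re-oriented to
risk once, at imputation time ($2 - d$), so scoring code only ever sees
risk-oriented dosages. Which rsID tags which haplotype is part of the
weight configuration, since array dialects differ.

### Quality control

Samples are excluded when any HLA tag SNP is uncalled, or when fewer
than 90% of non-HLA panel SNPs are called. The boundary is inclusive
(exactly 90% is retained), reading the rule as "*below* 90% excluded".
A sample failing both rules is attributed to the HLA rule, making the QC
report a deterministic partition of the input.

## Default configuration

The shipped weight configuration (`defaultWeights()`) uses the published
per-locus case-control odds ratios of the Caucasian reference cohort
(`table2Reference()`) for all 28 non-HLA SNPs, the three haplotype loci
and the six diplotype categories. Two consequences are worth stating:

* Absolute score levels are configuration-dependent. Under these weights
  simulated patients and controls average roughly 0.18 and 0.14; a
  configuration with externally derived weights (e.g. from a consortium
  reference model) shifts the scale. Thresholds are meaningful only
  relative to their configuration.
* A24 carries a weight below 1 here because that is its measured odds
  ratio in the reference cohort, even though the haplotype is reported
  as susceptible when conditioned on class II elsewhere. The weight
  file, not the code, decides.

## Statistical conventions

Conventions differ across software, so the package pins these down:

* **2×2 odds ratios**: cross-product $(ad)/(bc)$ with the table framed as
  {category vs rest} × {outcome vs rest}. This convention reproduces
  every published diplotype-by-age contingency value to two decimals.
  Zero cross-product cells give an *undefined* OR (`NA`, matching the
  "—" convention in published tables); an optional Haldane–Anscombe
  $+0.5$ mode exists but is off by default.
* **Woolf CI**: $\exp(\ln\mathrm{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$.
  For frequency-only inputs, counts are reconstructed as
  $\mathrm{round}(freq \times n)$ — approximate when per-locus
  missingness altered true denominators — while the interval stays
  centred on the frequency-ratio OR.
* **Fisher's exact test**: two-sided by summing hypergeometric
  probabilities no larger than the observed table's (the "small-p"
  rule).
* **AUROC**: midrank pair statistic, $P(\text{case} > \text{control}) +
  \tfrac12 P(\text{tie})$, identical to trapezoidal integration over all
  distinct thresholds and invariant under strictly increasing score
  transforms. Direction is fixed — higher score predicts disease — with
  no automatic flip.
* **Balanced accuracy**: $[\mathrm{sens}(t) + \mathrm{spec}(t)]/2$ with
  $score \ge t$ predicting a case, scanned over midpoints between
  consecutive distinct scores plus $\pm\infty$ sentinels. No threshold
  strictly between two adjacent scores can change a prediction, so the
  midpoint grid is exhaustive; peak ties break toward the lower
  threshold.
* **Centiles**: linear interpolation between order statistics
  (`quantile` type 7).
* **Prediction band**: $\hat y \pm t_{(1+\gamma)/2,\,n-2}\; s\,
  \sqrt{1 + 1/n + (x-\bar x)^2/S_{xx}}$ at $\gamma = 0.99$; patients
  below the lower band are flagged as low-score outliers (the flag used
  to revisit clinical diagnoses).
* **Group comparison**: Kruskal–Wallis omnibus plus Dunn's pairwise
  z-tests on shared ranks with tie correction. The multiplicity
  adjustment is a parameter (default Bonferroni, the usual
  multiple-comparison post-test convention; `adjust = "none"` is
  available because published post-test variants differ).

## The synthetic-data generator

No subject-level data accompany the published analysis, so the generator
produces cohorts with the statistical structure the analysis assumes.

**Group-frequency mode** (`simulateCohort()`): each group draws its
diplotype category from a group-specific categorical distribution, each
haplotype locus as two independent haplotype draws, and each autosomal
SNP as Binomial(2, p) — Hardy–Weinberg equilibrium per locus. X-linked
SNPs in males are a single draw recorded as 0/2. Defaults
(`defaultGroupModels()`) are the published case and control frequencies,
taken verbatim; at-risk relatives (≥2 autoantibodies) reuse case
frequencies, since their published mean score is essentially the
patients'. No frequencies are published for unaffected relatives, so the
relative models interpolate control → case frequencies with weight equal
to the coefficient of relationship: 1/2 for first-degree, 1/4 for
second-degree relatives. Patient age at diagnosis is log-normal with
geometric mean 8.94 years and geometric SD 2.18; with
`age_by_diplotype = TRUE`, ages are instead drawn per diplotype from the
published three-bin proportions (uniform within bins of 0.5–8, 8–16 and
16–40 years), which ties age to HLA *only* — the construction used to
test that the non-HLA score component shows no age association while the
HLA component carries all of it. Ages for non-patients are uniform on a
configurable donation window; autoantibody counts are labels (at-risk
fixed at 2), with no serology model behind them.

**Liability-family mode** (`simulateLiabilityFamily()`): genotypes come
from population (control) frequencies; disease is Bernoulli with
$P(\text{case}\mid g) = \mathrm{logit}^{-1}(\alpha + \sum_i\beta_i s_i +
H_l)$, with $\alpha$ calibrated by root-finding on a 20,000-genotype
Monte-Carlo pool to hit a target prevalence within 2%. Cases are
accepted by thinning; first-degree relatives are siblings drawn from the
case's simulated parents by per-locus Mendelian transmission (class II
is transmitted as one of three haplotypes, X-linked loci respect
sex-specific transmission); second-degree relatives add one meiosis
(a sibling's child with a random population mate). This mode produces
the dilution of risk in relatives mechanistically rather than by
assumption, and the simulated mean-score ordering case > sibling >
population is verified in tests.

**What the generator does not emulate**: linkage disequilibrium between
loci (all loci independent — the main simplification relative to real
genomes, where the HLA region especially is one long haplotype block),
ancestry admixture (race/ethnicity are sampled labels used for
stratification plumbing only), genotyping error, and autoantibody
serology. Tests passing on these cohorts therefore validate the
*computational pipeline* — scoring, statistics, threshold selection —
not the biological claims; in particular, discrimination measured on
synthetic cohorts reflects the configured frequency separation, not an
estimate of clinical performance.

## Problem sizes and tolerances in the test suite

The suite exercises exact oracles at small n (all-pairs AUC for n ≤ 12,
exhaustive threshold evaluation for n ≤ 10, full hypergeometric
enumeration for table totals ≤ 12, tolerance 1e−12/1e−9) and sampling
properties at moderate n chosen to keep a full run under a minute:
allele-frequency and Hardy–Weinberg recovery at n = 5,000 per group
(3σ / χ² at α = 0.001), age-model recovery at n = 10,000 (3 standard
errors), odds-ratio coverage at n = 5,000 per group (≥90% of loci inside
their Woolf CIs), and ordering/age-association constructions at
n = 2,000 per group. Seeds are fixed in the tests; the acceptance script
takes its seed on the command line.

## Known limitations

* The six-category diplotype model omits population-specific HLA
  haplotypes (e.g. African-derived risk haplotypes the tag SNPs do not
  capture); scores computed with Caucasian-derived configurations are
  expected to discriminate less well in other populations, and the
  package makes no correction for this.
* `oddsRatioFromFreqs()` CIs from reconstructed counts inherit the
  rounding of the input frequencies; odds ratios at frequencies near 0
  or 1 are highly leveraged and reproduce published values only to ~1%.
* The VCF reader handles unphased diploid genotypes matched on rsID
  only: no liftover, no phasing, half-calls become missing.
* No covariate-adjusted (logistic regression) odds ratios and no
  multiple-testing correction across loci are provided — the reference
  tables report unadjusted values.
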