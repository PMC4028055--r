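---
title: "Variance-component heritability and eQTL mapping in structured populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component heritability and eQTL mapping in structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heritex)
```

## The model

heritex estimates the narrow-sense heritability of replicated
gene-expression traits measured on individuals sampled from several
geographically separated populations. For gene expression value $y_{ij}$ of
individual $i$ on replicate array $j$, the mixed model is

$$ y_{ij} = \mu + \mathbf{S}_i \beta + u_i + e_{ij}, $$

where $\mathbf{S}_i$ holds population-indicator covariates (one level
omitted against the intercept), $u \sim N(0, \sigma_g^2 \mathbf{K})$ is the
polygenic effect with $\mathbf{K}$ the kinship matrix, and
$e \sim N(0, \sigma_e^2 \mathbf{I})$. With $\mathbf{Z}$ the incidence
matrix mapping arrays to individuals, the phenotypic covariance is
$\mathbf{V} = \sigma_g^2 \mathbf{Z K Z'} + \sigma_e^2 \mathbf{I}$ and
narrow-sense heritability is $h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$.

The kinship matrix is estimated by method-of-moments IBD within each
population separately (on an LD-pruned SNP subset) and merged
block-diagonally: coefficients between individuals from different
populations are set to exactly zero, reflecting the assumption that
geographically isolated populations are unrelated. The within-population
estimator counts identity-by-state sharing per pair and solves for the
probabilities of sharing 0, 1 or 2 alleles identical by descent, using
unbiased factorial-moment estimators of the allele-frequency polynomials to
correct small-sample bias; each probability is truncated to $[0,1]$ and the
triple renormalised, so $\hat\pi = P(\text{IBD}=2) + P(\text{IBD}=1)/2$.
Truncation means $\hat\pi$ for unrelated pairs is positively biased by an
amount that shrinks with marker count; with tens of thousands of pruned
markers the noise standard deviation is below 0.01, comparable to values
reported for dense human SNP panels.

## REML by 1-D profiling

No closed form exists for the variance components, and a key requirement is
that estimates never go negative. We profile the restricted likelihood over
the single ratio $\lambda = \sigma_g^2/\sigma_e^2$: eigendecomposing
$\mathbf{ZKZ'}$ rotates the model so $\mathbf{V}$ is diagonal in $\lambda$,
after which the restricted log-likelihood (including the log-determinant of
the rotated fixed-design cross-product) is a cheap 1-D function. Because
the replicate design is balanced, only the $n \times n$ kinship needs
decomposing: the non-null eigenvalues of $\mathbf{ZKZ'}$ are $r$ times those
of $\mathbf{K}$, and the $n(r-1)$ within-individual directions enter only
through the within-individual sum of squares. The decomposition is shared
across genes (`kinship_eigen()`), so a panel of thousands of genes costs one
eigendecomposition plus an $O(n)$ likelihood evaluation per candidate
$\lambda$ per gene.

The maximiser uses an 81-point log-spaced grid on
$\lambda \in [10^{-5}, 10^5]$, plus the boundary $\lambda = 0$, refined by
golden-section search; boundary hits are flagged. $\sigma_e^2$ is recovered
in closed form, so $\sigma_g^2 = \hat\lambda \sigma_e^2 \ge 0$ and
$h^2 \in [0,1]$ by construction. The acceptance suite verifies the profiled
optimum against a 10,000-point grid to $10^{-6}$ in log-likelihood.
Convergence tolerance is $10^{-10}$ on the profile argument; a fit with one
replicate per individual and an identity-like kinship is flagged
`flat_likelihood` because $\sigma_g^2$ and $\sigma_e^2$ are then poorly
separated. Negative kinship eigenvalues (possible after truncated
method-of-moments estimation) are clipped at zero so $\mathbf{V}$ stays
positive semi-definite; a matrix whose most negative eigenvalue exceeds a
quarter of its largest is rejected as corrupt rather than silently clipped.

The full (ML) likelihood is maximised over the same profile and reported
alongside. AIC comparisons use the ML, not the REML, log-likelihood,
because the models compared (additive versus interaction) differ in their
fixed effects and REML likelihoods are not comparable across fixed-effect
structures. The parameter count is the number of fixed-effect columns plus
the two variance components.

## The eQTL scan and eQTL heritability

The association scan is deliberately ordinary least squares, not a mixed
model: replicate-averaged expression is regressed on intercept, population
indicators and the SNP dosage (0/1/2), with a two-sided $t$-test on the
dosage coefficient. Population indicators absorb the mean expression and
allele-frequency differences between populations that would otherwise
inflate the test; the kinship enters only the heritability machinery. SNPs
whose dosage is collinear with the population indicators (fixed differences)
carry no within-population information and are skipped. Significance uses a
Bonferroni threshold over the number of SNPs only — genes are not counted,
a deliberately conservative and simple choice whose expected chance-discovery
fraction the package reports (`expected_false_positive_fraction()`).

Significant SNPs are merged per chromosome by single-linkage clustering with
a 5 Mb gap: consecutive significant SNPs at most 5 Mb apart form one peak.
"A region of 5 Mb" is ambiguous between a gap and a total-span reading; the
gap reading was chosen because it is the standard single-linkage rule and
does not depend on where a long peak started. A peak is *cis* when its lead
SNP (minimum P, ties broken to the smaller position) lies within 500 kb
upstream of the transcript start or 500 kb downstream of the 3' end —
since one window extends each side, the interval is simply the gene span
± 500 kb and strand does not alter it. The lead SNP, not any member,
decides the label, so a wide peak straddling the window boundary is
classified by its strongest signal.

The phenotypic variance explained by a detected eQTL is estimated by
refitting the mixed model with the lead SNP as a fixed covariate and
differencing the variance-component sums:

$$ h^2_{QTL} = \frac{(\hat\sigma_g^2 + \hat\sigma_e^2)_{\text{free}} -
  (\hat\sigma_g^2 + \hat\sigma_e^2)_{\text{SNP}}}
  {(\hat\sigma_g^2 + \hat\sigma_e^2)_{\text{free}}}. $$

The denominator is the SNP-free total — the quantity is the proportion of
the trait's phenotypic variance, not of the SNP-adjusted remainder. The
difference is floored at zero (optimizer noise can push it slightly
negative) and the component-wise changes are reported so a user can verify
that the decrease comes from the genetic component rather than the residual.
Because the difference is floored, adding an irrelevant SNP produces a
small non-negative bias; under the acceptance conditions it stays below
0.02. The ratio $\pi = h^2_{QTL}/h^2$ — the fraction of the gene's
heritability captured by its detected eQTLs — is capped into $[0,1]$.
Multi-eQTL genes aggregate their peak lead SNPs in one SNP-inclusive fit.

## Trio heritability

For trio families, heritability is the least-squares slope of offspring
expression on the midparent value. The estimator's unbiasedness requires
offspring-on-midparent; a `literal = TRUE` switch provides the reversed
regression (midparent-on-offspring) for comparison with analyses worded that
way, which we read as a probable wording slip since the reversed slope
estimates $\mathrm{cov}/\mathrm{var}(\text{offspring})$, not $h^2$.
Negative slopes are reported as-is — with tens of families they are common
under environmental noise — and "non-negative heritability" downstream means
slope $\ge 0$ exactly. Fisher's exact test (two-sided, conditional on
margins) tests whether eQTL genes are enriched for non-negative estimates;
the sample odds ratio $ad/bc$ is reported rather than the conditional MLE.

## The synthetic-data generator

The generator exists so that every stage is testable against known truth
without any external data, and its defaults mirror the study design it
emulates: four populations, on the order of a hundred individuals each,
four replicate arrays per individual, and SNP filters at call rate 0.90,
MAF 0.05, Hardy-Weinberg $\alpha$ 0.001, pruning $r^2 < 0.05$, relatedness
cutoff 0.05, a 5 Mb merge window and a 500 kb cis window.

* **Structure** follows the Balding-Nichols model: per SNP an ancestral
  frequency $p$ is drawn uniformly from `maf_range`, and each population's
  frequency from $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, giving
  allele-frequency divergence with $E[F_{ST}] \approx F$. SNPs are
  independent — there is no linkage disequilibrium beyond chance sample
  correlation, which suffices to exercise pruning (planted duplicate columns
  provide deterministic LD).
* **Expression** is simulated directly on the normalised (log-like) scale
  with baseline 8, population shifts $N(0, \texttt{pop\_effect\_sd}^2)$, QTL
  dosage effects, an optional multiplicative interaction, a polygenic value
  drawn with covariance $\sigma_g^2 \mathbf{K}_{true}$ (the realized
  standardized-genotype relationship within population, zero across — the
  analysis assumption), and iid per-array noise. Effects are scaled against
  realized dosage variances so per-gene variance fractions decompose
  exactly; the interaction column is orthogonalised against its two dosage
  columns for the same reason. Because QTL effects are scaled by the pooled
  dosage variance, a QTL whose frequency differs strongly between
  populations loses part of its apparent effect to the population
  covariates in the scan — as it would in the real analysis.
* **Trios** transmit one allele per parent per SNP (genotypes are exactly
  Mendelian), but phenotypes follow the infinitesimal midparent model: the
  offspring's additive value is the midparent value, with residual noise
  scaled so the replicate-averaged phenotype has residual variance $1-h^2$.
  Omitting the Mendelian-sampling deviation from the phenotype does not
  change the expectation of the offspring-on-midparent slope (the deviation
  is independent of the midparent) and makes the degenerate $h^2 = 1$ case
  exact; it does understate offspring phenotypic variance, which no
  estimator here consumes.
* The raw-intensity scale exists only to exercise the probe filter
  (a raw-layer `expression_panel` with per-array background); the expression
  scale of the emulated platform is not asserted — the generator works on
  the normalised scale and leaves raw-scale modelling to the user.

What passing tests on this generator do **not** show: robustness to linkage
disequilibrium between causal and typed SNPs, to batch structure beyond
per-array noise, to non-normal expression distributions, or to admixed
individuals (the generator draws each individual from exactly one
population).

## Numerical and design choices

* Hardy-Weinberg testing is the 1-df chi-square goodness-of-fit test —
  adequate at the per-population sample sizes the design targets (~45-90);
  an exact test is a documented extension point. Monomorphic SNPs return
  P = 1 and fall to the MAF filter instead.
* Genotypic $r^2$ uses pairwise-complete dosage correlations; MAF uses
  non-missing alleles. Pruning windows default to 50 SNPs advancing by 5;
  within a window the member of the worst pair with the lower call rate is
  dropped (ties: higher position).
* Per-population QC requires a SNP to pass every filter in **all**
  populations (the consensus reading of independent per-population
  checking).
* Quantile normalisation ties receive the mean reference value of their
  tied ranks, making the chain deterministic and rank-preserving; median
  normalisation is an additive shift, appropriate on a log-like scale.
  Probes below the array background on *all* replicates for strictly more
  than half the individuals are dropped; if no background estimate is
  supplied, each array's 5th percentile is the fallback.
* Related-pair exclusion iterates greedily from the highest pi-hat pair,
  dropping the member with more missing genotypes (ties: later in sort
  order) until no pair exceeds the cutoff.
* The per-population simplified model (intercept-only fixed design with that
  population's kinship block) is the same REML machinery via the `X`
  argument.
* Model diagnostics correlate the fixed-effect predictions with the
  random-plus-residual estimates ($y - X\hat\beta$); a significant
  correlation indicates fixed effects missing from the model. With an
  identity-like kinship and a balanced design the GLS solution makes the two
  exactly orthogonal, so the check has power only when the kinship carries
  real structure — which is exactly the situation where omitted fixed
  effects masquerade as genetic signal.

## Problem sizes

The test and acceptance suites run the generator at the scale the design
targets where the property needs it (400 individuals in 4 populations, 4
replicates, 50-200 genes; 20,000-50,000 markers where relatedness noise
matters) and smaller elsewhere. The end-to-end pipeline fixture uses 2
populations of 100 with 50,000 SNPs: method-of-moments pi-hat noise scales
as $1/\sqrt{m}$, and below roughly 20,000 pruned markers the 0.05
relatedness cutoff begins excluding genuinely unrelated pairs, which is a
property of the method, not of the implementation.
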