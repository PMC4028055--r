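# heritex

Heritability and eQTL mapping of gene expression in structured populations.

Gene expression is itself a heritable quantitative trait. Given replicated
expression measurements (microarray-style, several arrays per individual)
and dense SNP genotypes on individuals drawn from several geographically
separated populations, heritex estimates, for every gene, how much of the
expression variance is genetic, where the controlling variants sit, and how
much of the genetic variance those detected variants explain. It is aimed
at quantitative geneticists analysing population-based expression panels —
and at anyone who needs a transparent, testable implementation of the
variance-component machinery behind such analyses.

## The model

For expression $y_{ij}$ of a gene in individual $i$ on replicate array $j$:

$$y_{ij} = \mu + \mathbf{S}_i\beta + u_i + e_{ij}, \qquad
u \sim N(0, \sigma_g^2\mathbf{K}), \quad e \sim N(0, \sigma_e^2\mathbf{I}),$$

with population indicators $\mathbf{S}_i$ correcting for structure and
$\mathbf{K}$ a merged kinship matrix: method-of-moments IBD estimated
within each population on an LD-pruned SNP subset, zero between
populations. REML estimation profiles the restricted likelihood over
$\lambda = \sigma_g^2/\sigma_e^2$ after one shared eigendecomposition of
the kinship, so both components are non-negative by construction and
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2) \in [0,1]$ always.

Around that core: the four standard SNP filters (call rate ≥ 0.90,
MAF ≥ 0.05, Hardy–Weinberg P ≥ 0.001, autosomes only) applied per
population; greedy sliding-window LD pruning at $r^2 < 0.05$;
close-relative exclusion above pi-hat 0.05; MDS for structure inspection;
within-individual quantile normalisation, across-individual median
normalisation, probe→gene collapsing and replicate averaging; an OLS
genome-wide scan with population covariates and Bonferroni threshold
$\alpha/m$; 5 Mb peak merging and a ±500 kb cis window; eQTL heritability
$h^2_{QTL}$ by variance-component differencing between SNP-free and
SNP-inclusive fits, with $\pi = h^2_{QTL}/h^2$; SNP×SNP multiplicative
epistasis compared against the additive model by AIC; and
midparent–offspring regression heritability for trio families with a
Fisher exact enrichment test. A synthetic-data generator (Balding–Nichols
structure, configurable polygenic/QTL/epistatic architecture, Mendelian
trios) makes the whole chain testable end to end with known truth.

## Worked example

```r
library(heritex)

cfg <- sim_config(n_populations = 2, n_per_pop = 100, n_snps = 1000,
                  fst = 0.1, missing_rate = 0, n_genes = 3,
                  h2_list = c(0.1, 0.8, 0.4),
                  qtl_specs = data.frame(gene = 3, role = "cis", frac = 0.2),
                  seed = 42)
panel <- simulate_genotypes(cfg)
sim   <- simulate_expression(panel, cfg)

Keig  <- kinship_eigen(realized_grm(panel))
X     <- model.matrix(~factor(panel$samples$population))
indiv <- sim$expression$samples$sample
for (g in 1:3) print(reml_fit(sim$expression$values[g, ], indiv, Keig, X = X))
#> REML variance components: sigma_g2 = 0.09339, sigma_e2 = 0.8704, h2 = 0.097
#> REML variance components: sigma_g2 = 0.7815, sigma_e2 = 0.2042, h2 = 0.793
#> REML variance components: sigma_g2 = 0.517, sigma_e2 = 0.3757, h2 = 0.579
```

The three genes were simulated with polygenic fractions 0.1, 0.8 and 0.4 —
the estimates recover them, except that gene 3's cis QTL (20% of variance)
is partly absorbed into $\sigma_g^2$ when no SNP is in the model. The scan
finds it:

```r
means <- collapse_and_average(sim$expression)$means
rec   <- scan_gene(means[3, ], panel,
                   threshold = bonferroni_threshold(0.05, ncol(panel$geno)))
peaks <- classify_cis_trans(merge_peaks(rec), sim$genes[3, ])
peaks[, c("chrom", "lead_snp", "lead_pos", "lead_p", "n_snps", "label")]
#>   chrom  lead_snp lead_pos       lead_p n_snps label
#> 1  chr1 snp000384 19200000 8.162886e-17      1   cis

free <- reml_fit(sim$expression$values[3, ], indiv, Keig, X = X)
snp  <- fit_snp_model(sim$expression$values[3, ], indiv, Keig,
                      snps = panel$geno[, peaks$lead_snp, drop = FALSE], X = X)
eh   <- eqtl_heritability(free, snp)
#> h2_qtl = 0.211, pi = 0.365 (delta sigma_g2 = 0.188, delta sigma_e2 = 0.001)
```

The lead SNP explains an estimated 21% of the gene's phenotypic variance
(truth: 20%), the drop comes from the genetic component
($\Delta\sigma_g^2 = 0.188$) and not the residual, and the detected eQTL
accounts for $\pi = 37\%$ of the gene's heritability — the rest is
polygenic background.

`run_pipeline(pipeline_config(...))` chains every stage (QC → relatedness →
normalisation → heritability → scan → eQTL heritability → epistasis) and
writes per-stage TSVs plus a JSON manifest; `summarize_results()` builds the
report tables and histograms.

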