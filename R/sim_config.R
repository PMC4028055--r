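#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-data generator: a
#' structured genotype panel (Balding-Nichols allele-frequency divergence
#' between populations), replicated expression phenotypes with a configurable
#' polygenic/QTL/epistatic architecture, and trio families.
#'
#' Per-gene variance fractions are specified on the per-array phenotypic scale
#' (total variance 1): `h2_list[g]` is the polygenic fraction, each row of
#' `qtl_specs` adds a fixed-effect QTL fraction, and each row of
#' `epistasis_specs` a multiplicative SNP-SNP interaction fraction.  The
#' residual fraction is whatever remains; the fractions for a gene must
#' therefore sum to at most 1.
#'
#' @param n_populations number of geographically separated populations.
#' @param n_per_pop individuals per population.
#' @param n_snps number of independent SNPs.
#' @param fst Balding-Nichols divergence parameter, in (0, 1).
#' @param maf_range range of the ancestral allele frequency, within (0, 0.5].
#' @param missing_rate probability that a genotype call is missing.
#' @param n_genes number of expression traits.
#' @param n_replicates arrays hybridised per individual (default 4, the
#'   replicated-microarray design the model assumes).
#' @param h2_list per-gene polygenic variance fraction in \[0, 1\]; recycled to
#'   `n_genes`.
#' @param qtl_specs `NULL` or data frame with columns `gene` (index), `role`
#'   (`"cis"` or `"trans"`) and `frac` (variance fraction).
#' @param epistasis_specs `NULL` or data frame with columns `gene` and `frac`
#'   (interaction variance fraction); optional columns `snp1`, `snp2` name the
#'   interacting SNPs, otherwise the gene's first two QTLs are used.
#' @param pop_effect_sd standard deviation of the per-population fixed shift in
#'   expression units.
#' @param n_chromosomes number of synthetic chromosomes the SNPs are laid on.
#' @param snp_spacing distance in bp between adjacent SNPs.
#' @param n_families number of trio families for [simulate_trios()].
#' @param seed integer seed fixing every generated output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_populations = 2, n_per_pop = 20, n_snps = 100,
#'                   n_genes = 5, h2_list = 0.5, seed = 1)
#' @export
sim_config <- function(n_populations = 4, n_per_pop = 50, n_snps = 5000,
                       fst = 0.1, maf_range = c(0.05, 0.5),
                       missing_rate = 0.01, n_genes = 100, n_replicates = 4,
                       h2_list = 0.5, qtl_specs = NULL, epistasis_specs = NULL,
                       pop_effect_sd = 0.25, n_chromosomes = 2,
                       snp_spacing = 5e4, n_families = 50, seed = 1) {
  if (!is.numeric(fst) || length(fst) != 1 || fst <= 0 || fst >= 1)
    stop_config("`fst` must be a single value in (0, 1), got %s", fst)
  counts <- c(n_populations = n_populations, n_per_pop = n_per_pop,
              n_snps = n_snps, n_genes = n_genes, n_replicates = n_replicates,
              n_chromosomes = n_chromosomes, n_families = n_families)
  if (any(counts < 1) || any(counts != round(counts)))
    stop_config("all counts must be positive integers")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_config("`maf_range` must be an increasing interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_config("`missing_rate` must be in [0, 1)")
  h2 <- rep_len(as.numeric(h2_list), n_genes)
  if (any(h2 < 0 | h2 > 1)) stop_config("heritabilities must lie in [0, 1]")

  frac_tot <- h2
  if (!is.null(qtl_specs)) {
    qtl_specs <- as.data.frame(qtl_specs)
    stopifnot(all(c("gene", "role", "frac") %in% names(qtl_specs)))
    if (!all(qtl_specs$role %in% c("cis", "trans")))
      stop_config("QTL role must be 'cis' or 'trans'")
    if (any(qtl_specs$gene < 1 | qtl_specs$gene > n_genes))
      stop_config("QTL gene index out of range")
    agg <- tapply(qtl_specs$frac, qtl_specs$gene, sum)
    frac_tot[as.integer(names(agg))] <- frac_tot[as.integer(names(agg))] + agg
  }
  if (!is.null(epistasis_specs)) {
    epistasis_specs <- as.data.frame(epistasis_specs)
    stopifnot(all(c("gene", "frac") %in% names(epistasis_specs)))
    agg <- tapply(epistasis_specs$frac, epistasis_specs$gene, sum)
    frac_tot[as.integer(names(agg))] <- frac_tot[as.integer(names(agg))] + agg
  }
  if (any(frac_tot > 1 + 1e-12))
    stop_config("per-gene variance fractions sum to > 1 (max %.3f)",
                max(frac_tot))

  structure(list(
    n_populations = as.integer(n_populations),
    n_per_pop = as.integer(n_per_pop), n_snps = as.integer(n_snps),
    fst = fst, maf_range = maf_range, missing_rate = missing_rate,
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    h2_list = h2, qtl_specs = qtl_specs, epistasis_specs = epistasis_specs,
    pop_effect_sd = pop_effect_sd, n_chromosomes = as.integer(n_chromosomes),
    snp_spacing = snp_spacing, n_families = as.integer(n_families),
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d pops x %d, %d SNPs (Fst %.3g), %d genes x %d replicates\n",
    x$n_populations, x$n_per_pop, x$n_snps, x$fst, x$n_genes, x$n_replicates))
  invisible(x)
}
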