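#' Simulate trio families with expression phenotypes
#'
#' Draws `n_families` father/mother pairs as unrelated individuals from a
#' single population (allele frequencies uniform in `maf_range`) and one
#' offspring per family by Mendelian transmission (one allele sampled from
#' each parent per SNP).  Expression phenotypes follow the infinitesimal
#' midparent model: parental additive values are `N(0, h2)`, the offspring's
#' additive value is the midparent value, and residual noise is scaled so the
#' *replicate-averaged* phenotype has residual variance `1 - h2`.  The
#' expected slope of offspring on midparent expression therefore equals the
#' configured narrow-sense `h2` exactly; with `h2 = 1` offspring expression
#' equals the midparent value.  (Omitting the Mendelian-sampling term from
#' the phenotype leaves the regression slope's expectation unchanged;
#' genotypes are still transmitted Mendelian for pedigree-level checks.)
#'
#' @param config a [sim_config()]; uses `n_families`, `n_snps`, `maf_range`,
#'   `n_genes`, `h2_list`, `n_replicates`, `missing_rate` and `seed`.
#' @return A list with `panel` (a [genotype_panel()] of all family members),
#'   `expression` (a normalized-layer [expression_panel()]) and `families`
#'   (data frame `family`, `father`, `mother`, `child`).
#' @export
simulate_trios <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nf <- config$n_families
  if (nf < 2) stop_config("at least 2 trio families are required")
  m <- config$n_snps
  r <- config$n_replicates
  ng <- config$n_genes
  with_seed(substream_seed(config$seed, "trios"), {
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    draw <- function(k) matrix(rbinom(k * m, 2L, rep(p, each = k)), k, m)
    fa <- draw(nf)
    mo <- draw(nf)
    transmit <- function(g) ifelse(g == 0, 0,
                            ifelse(g == 2, 1,
                                   rbinom(length(g), 1, 0.5)))
    ch <- matrix(transmit(fa), nf, m) + matrix(transmit(mo), nf, m)
    geno <- rbind(fa, mo, ch)
    ids <- c(sprintf("fam%03d_father", seq_len(nf)),
             sprintf("fam%03d_mother", seq_len(nf)),
             sprintf("fam%03d_child", seq_len(nf)))
    if (config$missing_rate > 0)
      geno[runif(length(geno)) < config$missing_rate] <- NA
    per_chrom <- ceiling(m / config$n_chromosomes)
    chrom_idx <- rep(seq_len(config$n_chromosomes), each = per_chrom)[seq_len(m)]
    pos <- unlist(lapply(split(seq_len(m), chrom_idx), function(ix)
      seq_along(ix) * config$snp_spacing), use.names = FALSE)
    panel <- genotype_panel(
      geno,
      data.frame(snp = sprintf("snp%06d", seq_len(m)),
                 chrom = paste0("chr", chrom_idx), pos = pos,
                 a1 = "A", a2 = "G"),
      data.frame(sample = ids, population = "TRIO"))

    h2 <- rep_len(config$h2_list, ng)
    n_tot <- 3L * nf
    y <- matrix(0, ng, n_tot * r)
    for (g in seq_len(ng)) {
      a_fa <- rnorm(nf, 0, sqrt(h2[g]))
      a_mo <- rnorm(nf, 0, sqrt(h2[g]))
      a_ch <- (a_fa + a_mo) / 2
      indiv <- c(a_fa, a_mo, a_ch) + 8
      # per-array noise scaled so the replicate mean has variance 1 - h2
      e_sd <- sqrt((1 - h2[g]) * r)
      y[g, ] <- rep(indiv, each = r) + rnorm(n_tot * r, 0, e_sd)
    }
    rownames(y) <- sprintf("gene%04d", seq_len(ng))
    samples <- data.frame(sample = rep(ids, each = r),
                          replicate = rep(seq_len(r), n_tot))
    families <- data.frame(family = sprintf("fam%03d", seq_len(nf)),
                           father = ids[seq_len(nf)],
                           mother = ids[nf + seq_len(nf)],
                           child = ids[2L * nf + seq_len(nf)])
    list(panel = panel,
         expression = expression_panel(y, samples, layer = "normalized"),
         families = families)
  })
}
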