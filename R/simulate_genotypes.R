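#' Simulate a structured genotype panel
#'
#' Draws, for each SNP, an ancestral allele frequency uniformly from
#' `maf_range` and, for each population, a population-specific frequency from
#' the Balding-Nichols distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)` with
#' divergence parameter `F = fst`.  Genotypes are `Binomial(2, p_pop)`
#' dosages; calls are masked missing independently at `missing_rate`.  SNPs
#' are laid on `n_chromosomes` synthetic chromosomes at ascending positions
#' spaced `snp_spacing` bp apart.
#'
#' The latent population frequencies are kept in attribute `pop_freq`
#' (populations x SNPs); [plant_relatives()] and tests use them as ground
#' truth.
#'
#' @param config a [sim_config()].
#' @return A [genotype_panel()] with samples `pop<i>_ind<j>`.
#' @examples
#' panel <- simulate_genotypes(sim_config(n_populations = 2, n_per_pop = 10,
#'                                        n_snps = 50, seed = 7))
#' dim(panel)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "genotypes"), {
    np <- config$n_populations
    n <- config$n_per_pop
    m <- config$n_snps
    p_anc <- runif(m, config$maf_range[1], config$maf_range[2])
    f <- config$fst
    pop_freq <- matrix(NA_real_, np, m)
    for (k in seq_len(np)) {
      pf <- rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      # keep SNPs segregating: Beta draws can collapse to 0/1 numerically
      pop_freq[k, ] <- pmin(pmax(pf, 1e-6), 1 - 1e-6)
    }
    geno <- matrix(NA_real_, np * n, m)
    for (k in seq_len(np)) {
      rows <- (k - 1L) * n + seq_len(n)
      geno[rows, ] <- matrix(
        rbinom(n * m, 2L, rep(pop_freq[k, ], each = n)), n, m)
    }
    if (config$missing_rate > 0) {
      geno[runif(length(geno)) < config$missing_rate] <- NA
    }
    per_chrom <- ceiling(m / config$n_chromosomes)
    chrom_idx <- rep(seq_len(config$n_chromosomes), each = per_chrom)[seq_len(m)]
    pos <- unlist(lapply(split(seq_len(m), chrom_idx), function(ix)
      seq_along(ix) * config$snp_spacing), use.names = FALSE)
    snps <- data.frame(snp = sprintf("snp%06d", seq_len(m)),
                       chrom = paste0("chr", chrom_idx), pos = pos,
                       a1 = "A", a2 = "G")
    samples <- data.frame(
      sample = sprintf("pop%d_ind%03d", rep(seq_len(np), each = n),
                       rep(seq_len(n), np)),
      population = sprintf("POP%d", rep(seq_len(np), each = n)))
    panel <- genotype_panel(geno, snps, samples)
    attr(panel, "pop_freq") <- pop_freq
    panel
  })
}

#' Plant related individuals in a simulated panel
#'
#' Overwrites the genotypes of the second member of each pair so the pair has
#' a known relationship, to exercise relatedness estimation and the
#' close-relative exclusion rule.  For `"duplicate"` the genotypes are copied
#' verbatim; for `"parent_offspring"` one allele per SNP is transmitted from
#' the first member and the other drawn from the population allele frequency.
#' Missing calls in the donor propagate to the recipient.
#'
#' @param panel a panel from [simulate_genotypes()].
#' @param pairs data frame with columns `id1`, `id2`, `relationship`
#'   (`"duplicate"` or `"parent_offspring"`); both members must belong to the
#'   same population.
#' @param seed integer seed for the transmitted/untransmitted allele draws.
#' @return The panel with modified genotypes and a `relatives` attribute
#'   recording the pairs with their true kinship (1 for duplicates, 0.5 for
#'   parent-offspring).
#' @export
plant_relatives <- function(panel, pairs, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("id1", "id2", "relationship") %in% names(pairs)))
  pop_freq <- attr(panel, "pop_freq")
  with_seed(substream_seed(seed, "relatives"), {
    for (i in seq_len(nrow(pairs))) {
      i1 <- match(pairs$id1[i], panel$samples$sample)
      i2 <- match(pairs$id2[i], panel$samples$sample)
      if (is.na(i1) || is.na(i2)) stop_config("unknown individual in pair")
      if (panel$samples$population[i1] != panel$samples$population[i2])
        stop_config("planted relatives must belong to one population (populations are assumed unrelated)")
      rel <- pairs$relationship[i]
      if (rel == "duplicate") {
        panel$geno[i2, ] <- panel$geno[i1, ]
      } else if (rel == "parent_offspring") {
        g1 <- panel$geno[i1, ]
        transmitted <- ifelse(g1 == 0, 0, ifelse(g1 == 2, 1, rbinom(length(g1), 1, 0.5)))
        popk <- match(panel$samples$population[i1],
                      sort(unique(panel$samples$population)))
        pf <- if (!is.null(pop_freq)) pop_freq[popk, ]
              else allele_freq(panel$geno)
        other <- rbinom(length(g1), 1, pf)
        g2 <- transmitted + other
        g2[is.na(g1)] <- NA
        panel$geno[i2, ] <- g2
      } else stop_config("unknown relationship '%s'", rel)
    }
  })
  truth <- data.frame(pairs,
                      kinship = ifelse(pairs$relationship == "duplicate", 1, 0.5))
  attr(panel, "relatives") <- rbind(attr(panel, "relatives"), truth)
  panel
}
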