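#' Realized genomic relationship matrix
#'
#' Standardized-genotype relationship matrix computed within each population
#' (dosages centred and scaled by that population's allele frequency) and set
#' to exactly zero between populations, mirroring the analysis assumption
#' that geographically separated populations are unrelated.  Missing dosages
#' are mean-imputed, i.e. contribute zero after centring.
#'
#' @param panel a [genotype_panel()].
#' @return Symmetric matrix, individuals x individuals, block-diagonal by
#'   population, with sample ids as dimnames.
#' @export
realized_grm <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$geno)
  K <- matrix(0, n, n, dimnames = list(panel$samples$sample,
                                       panel$samples$sample))
  for (pop in unique(panel$samples$population)) {
    rows <- which(panel$samples$population == pop)
    g <- panel$geno[rows, , drop = FALSE]
    p <- allele_freq(g)
    keep <- which(p > 0 & p < 1 & !is.na(p))
    g <- g[, keep, drop = FALSE]
    p <- p[keep]
    w <- sweep(g, 2, 2 * p)
    w[is.na(w)] <- 0
    w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
    K[rows, rows] <- tcrossprod(w) / length(keep)
  }
  K
}

# Block-diagonal square root of a kinship-like matrix via per-population
# eigendecomposition with negative eigenvalues clipped at zero.
kinship_sqrt <- function(K, populations) {
  n <- nrow(K)
  L <- matrix(0, n, n)
  for (pop in unique(populations)) {
    rows <- which(populations == pop)
    e <- eigen(K[rows, rows, drop = FALSE], symmetric = TRUE)
    d <- pmax(e$values, 0)
    L[rows, rows] <- e$vectors %*% (t(e$vectors) * sqrt(d))
  }
  L
}

#' Simulate replicated expression phenotypes on a genotype panel
#'
#' For gene *g* and array *j* of individual *i*,
#' `y_ij = mu + pop_i + sum_k alpha_k x_ik (+ gamma z_i) + u_i + e_ij`:
#' a population fixed shift, optional cis/trans QTL dosage effects, an
#' optional multiplicative SNP-SNP interaction, a polygenic value `u` drawn
#' multivariate normal with covariance `sigma_g^2 * K_true` (the realized
#' within-population GRM, zero across populations), and independent per-array
#' noise.  Replicates of an individual share `u_i` and all fixed parts.
#' Effects are scaled against realized dosage variances so the per-array
#' variance fractions match the configuration (polygenic `h2_list`, QTL
#' `frac`, interaction `frac`; residual is the remainder).  The interaction
#' column is orthogonalised against the two dosage columns so the configured
#' fractions decompose exactly.
#'
#' Genes are laid on the panel's chromosomes; a gene with a cis QTL is placed
#' within 400 kb of its QTL SNP, a trans QTL SNP is drawn from another
#' chromosome (or at least 6 Mb away when there is only one).
#'
#' @param panel a [genotype_panel()].
#' @param config the [sim_config()] used to build `panel`.
#' @return A list with `expression` (a normalized-layer [expression_panel()]),
#'   `genes` (annotation: `gene`, `chrom`, `start`, `end`, `strand`) and
#'   `truth` (per-gene true `h2`, `sigma_g2`, `sigma_e2`; QTL and epistasis
#'   tables with the SNPs actually used).
#' @export
simulate_expression <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  n <- nrow(panel$geno)
  r <- config$n_replicates
  ng <- config$n_genes
  pops <- panel$samples$population
  K <- realized_grm(panel)
  L <- kinship_sqrt(K, pops)

  with_seed(substream_seed(config$seed, "expression"), {
    # gene placement and QTL SNP assignment
    qtl <- config$qtl_specs
    chroms <- unique(panel$snps$chrom)
    genes <- data.frame(gene = sprintf("gene%04d", seq_len(ng)),
                        chrom = sample(chroms, ng, replace = TRUE),
                        start = NA_real_, end = NA_real_, strand = "+")
    span <- tapply(panel$snps$pos, panel$snps$chrom, max)
    genes$start <- floor(runif(ng, 1, pmax(span[genes$chrom] - 1e4, 2)))
    genes$end <- genes$start + 1e4
    poly <- which(maf(panel$geno) >= 0.05)
    qtl_rows <- list()
    if (!is.null(qtl)) {
      for (i in seq_len(nrow(qtl))) {
        g <- qtl$gene[i]
        if (qtl$role[i] == "cis") {
          s <- sample(poly, 1)
          genes$chrom[g] <- panel$snps$chrom[s]
          genes$start[g] <- max(1, panel$snps$pos[s] + round(runif(1, -4e5, 4e5)))
          genes$end[g] <- genes$start[g] + 1e4
        } else {
          far <- poly[panel$snps$chrom[poly] != genes$chrom[g]]
          if (!length(far))
            far <- poly[abs(panel$snps$pos[poly] - genes$start[g]) > 6e6]
          if (!length(far)) stop_config("no SNP far enough for a trans QTL")
          s <- sample(far, 1)
        }
        qtl_rows[[i]] <- data.frame(gene = genes$gene[g], gene_idx = g,
                                    role = qtl$role[i], snp = panel$snps$snp[s],
                                    snp_idx = s, frac = qtl$frac[i])
      }
    }
    qtl_truth <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else NULL

    epi <- config$epistasis_specs
    epi_rows <- list()
    if (!is.null(epi)) {
      for (i in seq_len(nrow(epi))) {
        g <- epi$gene[i]
        gq <- if (!is.null(qtl_truth))
          qtl_truth$snp_idx[qtl_truth$gene_idx == g] else integer()
        pair <- if (!is.null(epi$snp1) && !is.na(epi$snp1[i]))
          match(c(epi$snp1[i], epi$snp2[i]), panel$snps$snp)
        else if (length(gq) >= 2) gq[1:2]
        else sample(poly, 2)
        epi_rows[[i]] <- data.frame(gene = genes$gene[g], gene_idx = g,
                                    snp1 = panel$snps$snp[pair[1]],
                                    snp2 = panel$snps$snp[pair[2]],
                                    snp1_idx = pair[1], snp2_idx = pair[2],
                                    frac = epi$frac[i])
      }
    }
    epi_truth <- if (length(epi_rows)) do.call(rbind, epi_rows) else NULL

    dosage_imputed <- function(s) {
      x <- panel$geno[, s]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    }

    pop_levels <- sort(unique(pops))
    y <- matrix(0, ng, n * r)
    h2 <- config$h2_list
    sigma_e2 <- numeric(ng)
    mu <- 8
    for (g in seq_len(ng)) {
      fixed <- rep(mu, n)
      pe <- rnorm(length(pop_levels), 0, config$pop_effect_sd)
      fixed <- fixed + pe[match(pops, pop_levels)]
      frac_used <- h2[g]
      if (!is.null(qtl_truth)) {
        for (i in which(qtl_truth$gene_idx == g)) {
          x <- dosage_imputed(qtl_truth$snp_idx[i])
          fixed <- fixed + sqrt(qtl_truth$frac[i]) * (x - mean(x)) / sd(x)
          frac_used <- frac_used + qtl_truth$frac[i]
        }
      }
      if (!is.null(epi_truth)) {
        for (i in which(epi_truth$gene_idx == g)) {
          x1 <- dosage_imputed(epi_truth$snp1_idx[i])
          x2 <- dosage_imputed(epi_truth$snp2_idx[i])
          z <- stats::lm.fit(cbind(1, x1, x2), x1 * x2)$residuals
          fixed <- fixed + sqrt(epi_truth$frac[i]) * z / sd(z)
          frac_used <- frac_used + epi_truth$frac[i]
        }
      }
      sigma_e2[g] <- max(1 - frac_used, 1e-8)
      u <- if (h2[g] > 0) sqrt(h2[g]) * as.vector(L %*% rnorm(n)) else numeric(n)
      indiv <- fixed + u
      y[g, ] <- rep(indiv, each = r) + rnorm(n * r, 0, sqrt(sigma_e2[g]))
    }
    rownames(y) <- genes$gene
    samples <- data.frame(sample = rep(panel$samples$sample, each = r),
                          replicate = rep(seq_len(r), n))
    truth <- list(
      genes = data.frame(gene = genes$gene, h2 = h2, sigma_g2 = h2,
                         sigma_e2 = sigma_e2),
      qtl = qtl_truth, epistasis = epi_truth,
      population = setNames(pops, panel$samples$sample))
    list(expression = expression_panel(y, samples, layer = "normalized"),
         genes = genes, truth = truth)
  })
}
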