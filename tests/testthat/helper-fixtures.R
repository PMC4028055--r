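# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files.

# Small two-population panel for QC/relatedness unit tests.
small_panel <- function(seed = 42, n_per_pop = 50, n_snps = 1000, fst = 0.1,
                        n_populations = 2, missing_rate = 0.01) {
  simulate_genotypes(sim_config(
    n_populations = n_populations, n_per_pop = n_per_pop, n_snps = n_snps,
    fst = fst, missing_rate = missing_rate, n_genes = 1, seed = seed))
}

# A panel built directly from a dosage matrix (one population).
panel_from_matrix <- function(geno, chrom = NULL, pos = NULL, pop = NULL) {
  m <- ncol(geno)
  n <- nrow(geno)
  genotype_panel(
    geno,
    data.frame(snp = sprintf("s%03d", seq_len(m)),
               chrom = chrom %||% rep("chr1", m),
               pos = pos %||% seq_len(m) * 1000,
               a1 = "A", a2 = "G"),
    data.frame(sample = sprintf("i%03d", seq_len(n)),
               population = pop %||% rep("POP1", n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replicated phenotype with known variance components on a given kinship.
simulate_vc_trait <- function(K, pops, sigma_g2, sigma_e2, r = 4,
                              beta_pop = NULL, seed = 1) {
  set.seed(seed)
  n <- nrow(K)
  e <- eigen(K, symmetric = TRUE)
  L <- e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
  u <- sqrt(sigma_g2) * as.vector(L %*% rnorm(n))
  shift <- if (is.null(beta_pop)) rep(0, n)
           else beta_pop[match(pops, sort(unique(pops)))]
  indiv <- shift + u
  y <- rep(indiv, each = r) + rnorm(n * r, 0, sqrt(sigma_e2))
  list(y = y, indiv = rep(rownames(K), each = r), u = u)
}

# Random small mixed-model instance on a block kinship.
random_instance <- function(seed, n_max = 60) {
  set.seed(seed)
  n <- sample(20:n_max, 1)
  r <- sample(1:4, 1)
  npop <- sample(1:2, 1)
  pops <- sort(rep_len(paste0("P", seq_len(npop)), n))
  # a valid PSD block kinship: scaled Wishart per block
  K <- matrix(0, n, n)
  for (p in unique(pops)) {
    rows <- which(pops == p)
    W <- matrix(rnorm(length(rows) * 80), length(rows), 80)
    K[rows, rows] <- tcrossprod(W) / 80
  }
  dimnames(K) <- list(sprintf("i%02d", 1:n), sprintf("i%02d", 1:n))
  sg <- runif(1, 0, 2); se <- runif(1, 0.2, 2)
  sim <- simulate_vc_trait(K, pops, sg, se, r = r, seed = seed + 1000)
  X <- if (npop > 1) stats::model.matrix(~factor(pops)) else NULL
  list(y = sim$y, indiv = sim$indiv, K = K, X = X, sg = sg, se = se, r = r)
}

pop_design <- function(panel) {
  pf <- factor(panel$samples$population)
  if (nlevels(pf) > 1) model.matrix(~pf) else matrix(1, nrow(panel$geno), 1)
}
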