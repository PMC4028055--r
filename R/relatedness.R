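# Pairwise identity-by-state counts via indicator-matrix cross-products.
# Returns n x n matrices of IBS0/IBS1/IBS2 counts and the number of SNPs
# non-missing in both members.
ibs_counts <- function(geno) {
  M <- !is.na(geno); storage.mode(M) <- "double"
  G0 <- (geno == 0) & M; G1 <- (geno == 1) & M; G2 <- (geno == 2) & M
  storage.mode(G0) <- storage.mode(G1) <- storage.mode(G2) <- "double"
  G0[is.na(G0)] <- 0; G1[is.na(G1)] <- 0; G2[is.na(G2)] <- 0
  N0 <- tcrossprod(G0, G2); N0 <- N0 + t(N0)
  N2 <- tcrossprod(G0) + tcrossprod(G1) + tcrossprod(G2)
  S <- tcrossprod(M)
  list(N0 = N0, N1 = S - N0 - N2, N2 = N2, S = S, nonmissing = M)
}

# Per-SNP expected P(IBS = s | IBD = z) with the small-sample bias
# correction: powers of the allele frequency are replaced by their unbiased
# factorial-moment estimators from the sample allele counts.
ibs_expectations <- function(geno) {
  X <- colSums(geno, na.rm = TRUE)              # alt allele count
  T <- 2 * colSums(!is.na(geno))                # total alleles
  Y <- T - X
  ok <- T >= 4
  ff <- function(a, k) {
    out <- a
    for (i in seq_len(k - 1)) out <- out * (a - i)
    out
  }
  d4 <- ff(T, 4); d3 <- ff(T, 3)
  p2q2 <- ff(X, 2) * ff(Y, 2) / d4
  p3q1 <- ff(X, 3) * Y / d4
  p1q3 <- X * ff(Y, 3) / d4
  p4 <- ff(X, 4) / d4
  q4 <- ff(Y, 4) / d4
  p2q1 <- ff(X, 2) * Y / d3
  p1q2 <- X * ff(Y, 2) / d3
  p3 <- ff(X, 3) / d3
  q3 <- ff(Y, 3) / d3
  list(ok = ok,
       e00 = 2 * p2q2,
       e10 = 4 * p3q1 + 4 * p1q3,
       e20 = p4 + q4 + 4 * p2q2,
       e11 = 2 * p2q1 + 2 * p1q2,
       e21 = p3 + q3 + p2q1 + p1q2)
}

#' Method-of-moments IBD estimation within one population
#'
#' For every pair of individuals in a population, counts identity-by-state
#' (IBS) 0/1/2 sharing across the pruned SNPs non-missing in both members,
#' compares the counts with their expectations given IBD state 0/1/2 computed
#' from the population's allele frequencies (with small-sample bias
#' corrections based on unbiased factorial moments of the allele counts), and
#' solves for the IBD-state probabilities.  Each probability is truncated to
#' \[0, 1\] and the triple renormalised; the kinship coefficient is
#' `pi-hat = P(IBD=2) + P(IBD=1)/2`.
#'
#' @param panel a [genotype_panel()].
#' @param population population label to analyse (`NULL` if the panel holds a
#'   single population).
#' @param pruned_snps SNP ids to use (a set in approximate linkage
#'   equilibrium from [ld_prune()]); `NULL` uses all SNPs.
#' @param min_informative pairs sharing fewer non-missing SNPs than this are
#'   flagged `unreliable`.
#' @return Data frame with one row per pair: `id1`, `id2`, IBS counts,
#'   `n_snps`, IBD state probabilities `p0`, `p1`, `p2`, `pihat`,
#'   `unreliable`.  Sample ids are kept in attribute `samples`.
#' @export
estimate_ibd <- function(panel, population = NULL, pruned_snps = NULL,
                         min_informative = 100L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(population))
    panel <- subset_panel(panel, samples = panel$samples$population == population)
  if (!is.null(pruned_snps)) panel <- subset_panel(panel, snps = pruned_snps)
  n <- nrow(panel$geno)
  if (n < 2) stop_config("at least two individuals are required")
  ex <- ibs_expectations(panel$geno)
  geno <- panel$geno[, ex$ok, drop = FALSE]
  ib <- ibs_counts(geno)
  M <- ib$nonmissing
  pairsum <- function(e) {
    Me <- M * matrix(e[ex$ok], nrow(M), ncol(M), byrow = TRUE)
    tcrossprod(Me, M)
  }
  E00 <- pairsum(ex$e00); E10 <- pairsum(ex$e10); E20 <- pairsum(ex$e20)
  E11 <- pairsum(ex$e11); E21 <- pairsum(ex$e21)
  ut <- upper.tri(ib$S)
  i1 <- row(ib$S)[ut]; i2 <- col(ib$S)[ut]
  P0 <- ib$N0[ut] / E00[ut]
  P1 <- (ib$N1[ut] - P0 * E10[ut]) / E11[ut]
  P2 <- (ib$N2[ut] - P0 * E20[ut] - P1 * E21[ut]) / ib$S[ut]
  P0 <- pmin(pmax(P0, 0), 1)
  P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmin(pmax(P2, 0), 1)
  tot <- P0 + P1 + P2
  zero <- tot == 0
  P0[zero] <- 1; P1[zero] <- 0; P2[zero] <- 0; tot[zero] <- 1
  P0 <- P0 / tot; P1 <- P1 / tot; P2 <- P2 / tot
  out <- data.frame(
    id1 = panel$samples$sample[i1], id2 = panel$samples$sample[i2],
    ibs0 = ib$N0[ut], ibs1 = ib$N1[ut], ibs2 = ib$N2[ut], n_snps = ib$S[ut],
    p0 = P0, p1 = P1, p2 = P2, pihat = P2 + P1 / 2,
    unreliable = ib$S[ut] < min_informative)
  attr(out, "samples") <- panel$samples$sample
  attr(out, "population") <- population %||% panel$samples$population[1]
  out
}

#' Merge per-population IBD tables into a block-diagonal kinship matrix
#'
#' Relationship coefficients between individuals from different populations
#' are set to exactly zero (geographically separated populations are assumed
#' unrelated); the diagonal is fixed at 1.
#'
#' @param tables list of pi-hat tables from [estimate_ibd()], one per
#'   population.
#' @return Symmetric kinship matrix with sample ids as dimnames and a
#'   `populations` attribute; class `kinship_matrix`.
#' @export
merge_kinship <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  ids <- unlist(lapply(tables, attr, "samples"), use.names = FALSE)
  if (anyDuplicated(ids))
    stop_config("duplicate individual ids across populations")
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  pops <- character(n)
  for (tb in tables) {
    s <- attr(tb, "samples")
    pops[match(s, ids)] <- as.character(attr(tb, "population"))
    if (nrow(tb)) {
      K[cbind(match(tb$id1, ids), match(tb$id2, ids))] <- tb$pihat
      K[cbind(match(tb$id2, ids), match(tb$id1, ids))] <- tb$pihat
    }
  }
  diag(K) <- 1
  attr(K, "populations") <- setNames(pops, ids)
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' Exclude one member of each closely related pair
#'
#' Iterates greedily from the pair with the highest kinship coefficient above
#' `threshold` and drops the member with the greater number of missing
#' genotypes (ties: the individual later in sort order), until no remaining
#' pair exceeds the threshold.
#'
#' @param kinship a [merge_kinship()] matrix.
#' @param panel the [genotype_panel()] the kinship was estimated from (used
#'   for per-individual missingness).
#' @param threshold pi-hat above which a pair counts as related (default
#'   0.05).
#' @return Character vector of individual ids to drop (possibly empty).
#' @export
exclude_related <- function(kinship, panel, threshold = 0.05) {
  ids <- rownames(kinship)
  miss <- colSums(is.na(t(panel$geno[match(ids, panel$samples$sample), ,
                                     drop = FALSE])))
  K <- unclass(kinship)
  diag(K) <- 0
  drop <- character()
  repeat {
    mx <- max(K)
    if (mx <= threshold) break
    w <- which(K == mx, arr.ind = TRUE)[1, ]
    a <- ids[w[1]]; b <- ids[w[2]]
    victim <- if (miss[w[1]] > miss[w[2]]) a
              else if (miss[w[2]] > miss[w[1]]) b
              else sort(c(a, b))[2]
    vi <- match(victim, ids)
    K[vi, ] <- 0; K[, vi] <- 0
    drop <- c(drop, victim)
  }
  drop
}

#' Classical MDS of genotype panel individuals
#'
#' Classical (metric) multidimensional scaling on the allele-sharing distance
#' `1 - mean(IBS)/2`, where mean IBS is the average identity-by-state sharing
#' (0-2) per non-missing SNP for the pair.  Used to inspect population
#' structure.
#'
#' @param panel a [genotype_panel()].
#' @param k number of coordinates to return.
#' @return Data frame with `sample`, `population` and coordinates
#'   `PCo1..PCok`.
#' @export
mds_coords <- function(panel, k = 2) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$geno)
  if (k >= n) stop_config("k must be smaller than the number of individuals")
  ib <- ibs_counts(panel$geno)
  mean_ibs <- (ib$N1 + 2 * ib$N2) / ib$S
  D <- 1 - mean_ibs / 2
  diag(D) <- 0
  coords <- cmdscale(as.dist(D), k = k)
  out <- data.frame(sample = panel$samples$sample,
                    population = panel$samples$population)
  colnames(coords) <- paste0("PCo", seq_len(k))
  cbind(out, coords)
}
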