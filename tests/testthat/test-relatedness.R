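test_that("duplicates and parent-offspring pairs are recovered by pi-hat", {
  cfg <- sim_config(n_populations = 1, n_per_pop = 60, n_snps = 20000,
                    fst = 0.1, missing_rate = 0.01, n_genes = 1, seed = 30)
  panel <- simulate_genotypes(cfg)
  panel <- plant_relatives(panel, data.frame(
    id1 = c("pop1_ind001", "pop1_ind003"),
    id2 = c("pop1_ind002", "pop1_ind004"),
    relationship = c("duplicate", "parent_offspring")), seed = 31)
  tab <- estimate_ibd(panel)
  pick <- function(a, b) tab$pihat[(tab$id1 == a & tab$id2 == b) |
                                   (tab$id1 == b & tab$id2 == a)]
  expect_gte(pick("pop1_ind001", "pop1_ind002"), 0.95)
  expect_lt(abs(pick("pop1_ind003", "pop1_ind004") - 0.5), 0.1)
})

test_that("unrelated individuals have near-zero mean pi-hat and duplicates dominate", {
  cfg <- sim_config(n_populations = 1, n_per_pop = 100, n_snps = 20000,
                    missing_rate = 0, n_genes = 1, seed = 32)
  panel <- simulate_genotypes(cfg)
  tab <- estimate_ibd(panel)
  expect_lt(mean(tab$pihat), 0.02)
  # a planted duplicate stands clear of the unrelated background
  planted <- plant_relatives(panel, data.frame(
    id1 = "pop1_ind010", id2 = "pop1_ind011", relationship = "duplicate"),
    seed = 33)
  tab2 <- estimate_ibd(planted)
  dup <- tab2$pihat[tab2$id1 == "pop1_ind010" & tab2$id2 == "pop1_ind011"]
  expect_gt(dup, 0.9)
  others <- tab2$pihat[!(tab2$id1 == "pop1_ind010" & tab2$id2 == "pop1_ind011")]
  expect_lt(quantile(others, 0.99), 0.05)
})

test_that("pi-hat is invariant to SNP order", {
  panel <- small_panel(seed = 34, n_per_pop = 30, n_snps = 2000,
                       n_populations = 1)
  tab <- estimate_ibd(panel)
  set.seed(35)
  perm <- sample(ncol(panel$geno))
  tab_perm <- estimate_ibd(subset_panel(panel, snps = perm))
  expect_equal(tab$pihat, tab_perm$pihat, tolerance = 1e-12)
})

test_that("pairs with too few informative SNPs are flagged unreliable", {
  set.seed(36)
  geno <- matrix(rbinom(10 * 120, 2, 0.3), 10, 120)
  geno[1, 1:80] <- NA  # leaves < 100 shared SNPs for pairs with indiv 1
  panel <- panel_from_matrix(geno)
  tab <- estimate_ibd(panel)
  expect_true(all(tab$unreliable[tab$id1 == "i001" | tab$id2 == "i001"]))
  expect_false(any(tab$unreliable[tab$id1 != "i001" & tab$id2 != "i001"]))
})

test_that("merged kinship is block-diagonal with unit diagonal", {
  panel <- small_panel(seed = 37, n_per_pop = 20, n_snps = 3000,
                       n_populations = 2)
  tabs <- lapply(c("POP1", "POP2"), function(p)
    estimate_ibd(panel, population = p))
  K <- merge_kinship(tabs)
  expect_equal(dim(K), c(40L, 40L))
  expect_equal(unname(diag(K)), rep(1, 40))
  expect_true(isSymmetric(unclass(K)))
  pops <- attr(K, "populations")
  cross <- outer(pops, pops, "!=")
  expect_true(all(K[cross] == 0))
  # clipped eigenvalues are all non-negative
  expect_gte(min(kinship_eigen(K)$values), 0)
  # single population: merged matrix reproduces its own table
  K1 <- merge_kinship(tabs[1])
  expect_equal(K1["pop1_ind001", "pop1_ind002"],
               tabs[[1]]$pihat[tabs[[1]]$id1 == "pop1_ind001" &
                               tabs[[1]]$id2 == "pop1_ind002"])
})

test_that("duplicate ids across populations are rejected", {
  t1 <- data.frame(id1 = "a", id2 = "b", pihat = 0)
  attr(t1, "samples") <- c("a", "b"); attr(t1, "population") <- "P1"
  t2 <- data.frame(id1 = "b", id2 = "c", pihat = 0)
  attr(t2, "samples") <- c("b", "c"); attr(t2, "population") <- "P2"
  expect_error(merge_kinship(list(t1, t2)), "duplicate")
})

test_that("relative exclusion drops the member with more missing genotypes", {
  set.seed(38)
  geno <- matrix(rbinom(4 * 500, 2, 0.4), 4, 500)
  geno[2, 1:15] <- NA  # second individual has more missing calls
  panel <- panel_from_matrix(geno)
  K <- diag(4); K[1, 2] <- K[2, 1] <- 0.5
  dimnames(K) <- list(panel$samples$sample, panel$samples$sample)
  expect_equal(exclude_related(K, panel), "i002")
  # no related pair: empty drop list
  expect_length(exclude_related(diag(4) -> K0, panel), 0)
})

test_that("a related triangle is broken until no pair exceeds the threshold", {
  set.seed(39)
  geno <- matrix(rbinom(5 * 500, 2, 0.4), 5, 500)
  panel <- panel_from_matrix(geno)
  K <- diag(5)
  K[1, 2] <- K[2, 1] <- 0.5
  K[1, 3] <- K[3, 1] <- 0.3
  K[2, 3] <- K[3, 2] <- 0.4
  dimnames(K) <- list(panel$samples$sample, panel$samples$sample)
  drops <- exclude_related(K, panel, threshold = 0.05)
  keep <- setdiff(rownames(K), drops)
  Kk <- K[keep, keep]; diag(Kk) <- 0
  expect_true(all(Kk <= 0.05))  # brute-force post-state check
  expect_lt(length(drops), 3)   # greedy exclusion is economical
})

test_that("MDS separates populations and identical individuals coincide", {
  cfg <- sim_config(n_populations = 2, n_per_pop = 40, n_snps = 2000,
                    fst = 0.2, missing_rate = 0, n_genes = 1, seed = 40)
  panel <- simulate_genotypes(cfg)
  panel <- plant_relatives(panel, data.frame(
    id1 = "pop1_ind001", id2 = "pop1_ind002", relationship = "duplicate"),
    seed = 41)
  co <- mds_coords(panel, k = 2)
  a <- co$PCo1[co$population == "POP1"]
  b <- co$PCo1[co$population == "POP2"]
  expect_true(max(a) < min(b) || max(b) < min(a))  # no overlap on PCo1
  dup <- co[co$sample %in% c("pop1_ind001", "pop1_ind002"), ]
  expect_equal(dup$PCo1[1], dup$PCo1[2], tolerance = 1e-8)
  expect_equal(dup$PCo2[1], dup$PCo2[2], tolerance = 1e-8)
  expect_error(mds_coords(panel, k = 100), "smaller")
})
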