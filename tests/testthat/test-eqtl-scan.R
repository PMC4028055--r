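test_that("Bonferroni threshold arithmetic", {
  expect_equal(signif(bonferroni_threshold(0.05, 1299240), 3), 3.85e-8)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
})

test_that("scan coefficients match an lm() oracle over random instances", {
  for (s in 1:50) {
    set.seed(100 + s)
    n <- sample(30:80, 1)
    npop <- sample(1:3, 1)
    pops <- rep_len(paste0("P", seq_len(npop)), n)
    geno <- matrix(rbinom(n * 5, 2, runif(5, 0.2, 0.5)), n, 5)
    if (s %% 2 == 0) geno[sample(length(geno), n %/% 4)] <- NA
    panel <- panel_from_matrix(geno, pop = pops)
    y <- rnorm(n) + geno[, 1] %*% cbind(0.3) * (s %% 3 == 0)
    y <- as.vector(y); y[is.na(y)] <- 0
    names(y) <- panel$samples$sample
    rec <- scan_gene(y, panel)
    for (i in seq_len(nrow(rec))) {
      j <- match(rec$snp[i], panel$snps$snp)
      x <- geno[, j]
      fit <- if (npop > 1) lm(y ~ factor(pops) + x) else lm(y ~ x)
      sm <- summary(fit)$coefficients["x", ]
      expect_equal(rec$beta[i], unname(sm["Estimate"]), tolerance = 1e-8)
      expect_equal(rec$t[i], unname(sm["t value"]), tolerance = 1e-8)
      expect_equal(rec$p[i], unname(sm["Pr(>|t|)"]), tolerance = 1e-8)
    }
  }
})

test_that("a noiseless dosage-equal trait is maximally significant", {
  set.seed(130)
  geno <- matrix(rbinom(60 * 3, 2, 0.5), 60, 3)
  panel <- panel_from_matrix(geno)
  y <- as.numeric(geno[, 2])
  names(y) <- panel$samples$sample
  rec <- scan_gene(y, panel, threshold = 1e-10)
  hit <- rec[rec$snp == "s002", ]
  expect_equal(hit$beta, 1, tolerance = 1e-8)
  expect_lt(hit$p, 1e-100)
})

test_that("monomorphic SNPs are skipped and missing genotypes use complete cases", {
  set.seed(131)
  geno <- matrix(rbinom(50 * 3, 2, 0.4), 50, 3)
  geno[, 2] <- 1
  geno[1:5, 3] <- NA
  panel <- panel_from_matrix(geno)
  y <- rnorm(50); names(y) <- panel$samples$sample
  rec <- scan_gene(y, panel)
  expect_false("s002" %in% rec$snp)
  expect_equal(rec$n[rec$snp == "s003"], 45)
})

test_that("type-I error is calibrated with covariates and inflated without", {
  cfg <- sim_config(n_populations = 4, n_per_pop = 100, n_snps = 250,
                    fst = 0.15, missing_rate = 0, n_genes = 1, seed = 132)
  panel <- simulate_genotypes(cfg)
  pops <- panel$samples$population
  shifts <- c(POP1 = 0, POP2 = 0.6, POP3 = -0.4, POP4 = 0.9)
  set.seed(133)
  p_with <- p_without <- c()
  intercept_only <- matrix(1, 400, 1)
  for (g in 1:40) {
    y <- shifts[pops] + rnorm(400)
    names(y) <- panel$samples$sample
    p_with <- c(p_with, scan_gene(y, panel)$p)
    p_without <- c(p_without, scan_gene(y, panel,
                                        covariates = intercept_only)$p)
  }
  expect_lt(abs(mean(p_with < 0.05) - 0.05), 0.01)
  expect_gt(mean(p_without < 0.05), 0.10)
})

test_that("significant SNPs merge into peaks by the 5 Mb gap rule", {
  rec <- data.frame(snp = c("a", "b"), chrom = "chr1",
                    pos = c(10e6, 13e6), beta = 1, t = 10,
                    p = c(1e-10, 1e-12), n = 100)
  expect_equal(nrow(merge_peaks(rec)), 1)
  rec$pos <- c(10e6, 16e6)
  pk2 <- merge_peaks(rec)
  expect_equal(nrow(pk2), 2)
  # exactly 5 Mb apart still merges (gap rule is inclusive)
  rec$pos <- c(10e6, 15e6)
  expect_equal(nrow(merge_peaks(rec)), 1)
  # single significant SNP is its own peak and lead
  one <- merge_peaks(rec[1, ])
  expect_equal(one$lead_snp, "a")
  expect_equal(one$n_snps, 1)
})

test_that("peaks partition the significant SNPs of a gene", {
  set.seed(134)
  pos <- sort(sample(1:2e8, 60))
  rec <- data.frame(snp = sprintf("s%02d", 1:60),
                    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
                    pos = pos, beta = 1, t = 8, p = runif(60, 0, 1e-9),
                    n = 100)
  pk <- merge_peaks(rec)
  members <- unlist(pk$members)
  expect_setequal(members, rec$snp)
  expect_equal(length(members), length(unique(members)))
  # lead SNP is the minimum-P member of its peak
  for (i in seq_len(nrow(pk))) {
    sub <- rec[rec$snp %in% pk$members[[i]], ]
    expect_equal(pk$lead_p[i], min(sub$p))
  }
})

test_that("cis/trans classification respects the 500 kb window to the base pair", {
  gene <- data.frame(gene = "g", chrom = "chr1", start = 1e6, end = 1.01e6)
  mk_peak <- function(chrom, pos)
    data.frame(chrom = chrom, lead_snp = "s", lead_pos = pos, lead_p = 1e-10,
               n_snps = 1L, start = pos, end = pos)
  lab <- function(p) classify_cis_trans(p, gene)$label
  expect_equal(lab(mk_peak("chr1", 6e5)), "cis")     # upstream inside
  expect_equal(lab(mk_peak("chr2", 6e5)), "trans")   # other chromosome
  expect_equal(lab(mk_peak("chr1", 1510000)), "cis")  # 3' boundary, inclusive
  expect_equal(lab(mk_peak("chr1", 1510001)), "trans")  # 1 bp outside
  expect_equal(lab(mk_peak("chr1", 500000)), "cis")   # 5' boundary
  expect_equal(lab(mk_peak("chr1", 499999)), "trans")
  expect_equal(classify_cis_trans(mk_peak("chr1", 6e5), NULL)$label,
               "unknown")
})

test_that("a planted cis QTL at 25% variance is detected at the genome-wide threshold", {
  qtl <- data.frame(gene = 1, role = "cis", frac = 0.25)
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_populations = 4, n_per_pop = 100, n_snps = 300,
                      n_genes = 1, h2_list = 0.3, qtl_specs = qtl,
                      missing_rate = 0, seed = 140 + s)
    panel <- simulate_genotypes(cfg)
    se <- simulate_expression(panel, cfg)
    means <- collapse_and_average(se$expression)$means
    rec <- scan_gene(means[1, ], panel,
                     threshold = bonferroni_threshold(0.05, 1299240))
    se$truth$qtl$snp[1] %in% rec$snp
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the expected chance-discovery fraction follows alpha * genes / discoveries", {
  expect_equal(round(100 * expected_false_positive_fraction(0.05, 10720, 11290), 1),
               4.7)
  expect_equal(expected_false_positive_fraction(0.05, 100, 50), 0.1)
})
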