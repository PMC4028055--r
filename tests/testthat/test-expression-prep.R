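raw_fixture <- function(values, n_rep = 4, background = NULL) {
  n_arrays <- ncol(values)
  samples <- data.frame(sample = rep(sprintf("s%02d", seq_len(n_arrays / n_rep)),
                                     each = n_rep),
                        replicate = rep(seq_len(n_rep), n_arrays / n_rep))
  expression_panel(values, samples, layer = "raw",
                   background = background %||% rep(1, n_arrays))
}

test_that("the low-expression probe filter follows the all-replicates rule", {
  n_ind <- 10; n_rep <- 4
  vals <- matrix(10, 3, n_ind * n_rep,
                 dimnames = list(c("pA", "pB", "pC"), NULL))
  # pA: below background on all 4 replicates for 6/10 individuals -> removed
  vals["pA", 1:(6 * n_rep)] <- 0.5
  # pB: below background on only 3 of 4 replicates for every individual -> kept
  vals["pB", seq(1, n_ind * n_rep) %% n_rep != 0] <- 0.5
  raw <- raw_fixture(vals, n_rep)
  kept <- rownames(filter_probes(raw)$values)
  expect_false("pA" %in% kept)
  expect_true(all(c("pB", "pC") %in% kept))
  # exactly half of individuals below background is not "more than half"
  vals2 <- matrix(10, 1, n_ind * n_rep, dimnames = list("pD", NULL))
  vals2[1, 1:(5 * n_rep)] <- 0.5
  expect_true("pD" %in% rownames(filter_probes(raw_fixture(vals2, n_rep))$values))
})

test_that("the whitelist restricts probes before the intensity rule", {
  vals <- matrix(10, 2, 8, dimnames = list(c("pA", "pB"), NULL))
  raw <- raw_fixture(vals, n_rep = 4)
  expect_equal(rownames(filter_probes(raw, whitelist = "pA")$values), "pA")
})

test_that("quantile normalisation replaces sorted values by their cross-replicate mean", {
  out <- quantile_normalize_replicates(cbind(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out[, 1], c(2.5, 3.5, 4.5))
  expect_equal(out[, 2], c(2.5, 3.5, 4.5))
  # identical replicates are unchanged
  x <- c(5, 1, 3)
  expect_equal(quantile_normalize_replicates(cbind(x, x)), cbind(x, x),
               ignore_attr = TRUE)
  # after normalisation all replicates share one sorted vector
  set.seed(50)
  m <- matrix(rnorm(400), 100, 4)
  qn <- quantile_normalize_replicates(m)
  ref <- sort(qn[, 1])
  for (j in 2:4) expect_equal(sort(qn[, j]), ref, tolerance = 1e-12)
  # ranks are preserved within each replicate
  for (j in 1:4) expect_equal(rank(qn[, j]), rank(m[, j]))
})

test_that("tied entries receive the mean reference value of their tied ranks", {
  out <- quantile_normalize_replicates(cbind(c(1, 1, 5), c(2, 4, 6)))
  ref <- rowMeans(cbind(c(1, 1, 5), c(2, 4, 6)))  # both already sorted
  expect_equal(out[, 1], c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("median normalisation aligns every individual's median to the global median", {
  set.seed(51)
  vals <- matrix(rnorm(5 * 12, mean = rep(c(7, 8, 9), each = 4 * 5)), 5, 12)
  panel <- raw_fixture(vals, n_rep = 4)
  panel$layer <- "normalized"
  out <- median_normalize_individuals(panel)
  g <- median(out$values)
  for (s in unique(out$samples$sample)) {
    cols <- out$samples$sample == s
    expect_lt(abs(median(out$values[, cols]) - g), 1e-12)
  }
  # an individual 1 above the global median is shifted down by exactly 1
  v2 <- matrix(8, 1, 8); v2[1, 5:8] <- 9
  p2 <- raw_fixture(v2, n_rep = 4); p2$layer <- "normalized"
  o2 <- median_normalize_individuals(p2)
  expect_equal(unname(o2$values[1, 5]), 9 + (median(o2$values) - 9) + 0,
               tolerance = 1e-12)
  expect_equal(unname(o2$values[1, 5] - v2[1, 5]),
               median(o2$values) - 9, tolerance = 1e-12)
})

test_that("probe collapsing and replicate averaging are unweighted means", {
  vals <- rbind(p1 = rep(2, 8), p2 = rep(4, 8), p3 = 1:8)
  samples <- data.frame(sample = rep(c("a", "b"), each = 4),
                        replicate = rep(1:4, 2))
  panel <- expression_panel(vals, samples, layer = "normalized",
                            probe_map = data.frame(
                              probe = c("p1", "p2", "p3"),
                              gene = c("g1", "g1", "g2")))
  res <- collapse_and_average(panel)
  expect_equal(unname(res$gene_panel$values["g1", ]), rep(3, 8))
  expect_equal(unname(res$means["g2", ]), c(a = 2.5, b = 6.5),
               ignore_attr = TRUE)
  # brute-force replicate means oracle
  set.seed(52)
  vals2 <- matrix(rnorm(3 * 12), 3, 12,
                  dimnames = list(paste0("g", 1:3), NULL))
  samples2 <- data.frame(sample = rep(c("a", "b", "c"), each = 4),
                         replicate = rep(1:4, 3))
  p <- expression_panel(vals2, samples2, layer = "normalized")
  m <- collapse_and_average(p)$means
  for (g in 1:3) for (s in c("a", "b", "c"))
    expect_equal(m[g, s], mean(vals2[g, samples2$sample == s]),
                 tolerance = 1e-12)
})

test_that("the normalisation chain is invariant to individual order", {
  set.seed(53)
  vals <- matrix(rlnorm(20 * 12, 2, 0.4), 20, 12,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  samples <- data.frame(sample = rep(c("a", "b", "c"), each = 4),
                        replicate = rep(1:4, 3))
  p <- expression_panel(vals, samples, layer = "raw")
  res1 <- normalize_expression(p)
  perm <- c(9:12, 1:8)  # swap individual order
  p2 <- expression_panel(vals[, perm], samples[perm, ], layer = "raw")
  res2 <- normalize_expression(p2)
  expect_equal(res1$means[, c("a", "b", "c")], res2$means[, c("a", "b", "c")],
               tolerance = 1e-12)
})
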