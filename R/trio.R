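#' Midparent-offspring regression heritability
#'
#' Least-squares slope of offspring expression on the midparent value (the
#' mean of the two parents), the classical trio estimator of narrow-sense
#' heritability.  Negative slopes are reported as-is — with small family
#' counts the regression is vulnerable to environmental noise, and the sign
#' carries information downstream (see [fisher_enrichment()]).
#'
#' By convention the regression is offspring on midparent, which makes the
#' slope an unbiased estimator of `h2`; `literal = TRUE` regresses midparent
#' on offspring instead, for comparison with analyses worded that way.
#'
#' @param offspring numeric vector, one replicate-averaged value per family.
#' @param parents two-column matrix (father, mother) of replicate-averaged
#'   values, rows aligned with `offspring`.
#' @param literal regress midparent on offspring instead of offspring on
#'   midparent.
#' @return List of class `trio_h2`: `slope` (the h2 estimate), `se`,
#'   `n_families`, `flag` (`"zero_midparent_variance"` when undefined,
#'   `"few_families"` when fewer than 3 complete families).
#' @export
midparent_regression <- function(offspring, parents, literal = FALSE) {
  parents <- as.matrix(parents)
  stopifnot(ncol(parents) == 2, nrow(parents) == length(offspring))
  mid <- rowMeans(parents)
  ok <- complete.cases(offspring, mid)
  nf <- sum(ok)
  if (nf < 3)
    return(structure(list(slope = NA_real_, se = NA_real_, n_families = nf,
                          flag = "few_families"), class = "trio_h2"))
  x <- if (literal) offspring[ok] else mid[ok]
  yv <- if (literal) mid[ok] else offspring[ok]
  if (var(x) == 0)
    return(structure(list(slope = NA_real_, se = NA_real_, n_families = nf,
                          flag = "zero_midparent_variance"), class = "trio_h2"))
  sxy <- sum((x - mean(x)) * (yv - mean(yv)))
  sxx <- sum((x - mean(x))^2)
  slope <- sxy / sxx
  resid <- yv - mean(yv) - slope * (x - mean(x))
  se <- sqrt(sum(resid^2) / (nf - 2) / sxx)
  structure(list(slope = slope, se = se, n_families = nf, flag = "ok"),
            class = "trio_h2")
}

#' Trio heritability for every gene of an expression matrix
#'
#' @param means gene x individual matrix of replicate-averaged expression
#'   values (e.g. from [collapse_and_average()]).
#' @param families data frame with columns `father`, `mother`, `child`
#'   naming columns of `means`.
#' @param literal see [midparent_regression()].
#' @return Data frame: `gene`, `slope`, `se`, `n_families`, `flag`.
#' @export
trio_heritability <- function(means, families, literal = FALSE) {
  stopifnot(all(c("father", "mother", "child") %in% names(families)))
  need <- c(families$father, families$mother, families$child)
  if (!all(need %in% colnames(means)))
    stop_config("expression values missing for some family members")
  res <- lapply(seq_len(nrow(means)), function(g) {
    fit <- midparent_regression(
      means[g, families$child],
      cbind(means[g, families$father], means[g, families$mother]),
      literal = literal)
    data.frame(gene = rownames(means)[g], slope = fit$slope, se = fit$se,
               n_families = fit$n_families, flag = fit$flag)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for enrichment of non-negative trio heritability
#'
#' Two-sided Fisher's exact test on the 2x2 table of gene class (eQTL gene /
#' non-eQTL gene) against the sign of the trio heritability estimate
#' (non-negative: slope >= 0; negative otherwise).  Returns the sample odds
#' ratio `ad / bc` alongside the exact P computed by conditioning on the
#' table margins (hypergeometric enumeration, as implemented in
#' [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts, rows = gene
#'   class, columns = `h2 >= 0` / `h2 < 0`.
#' @return List: `odds_ratio` (sample odds ratio; `NA` with flag
#'   `"zero_margin"` when a margin is empty, in which case P = 1),
#'   `p_value`, `flag`.
#' @export
fisher_enrichment <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1, flag = "zero_margin"))
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  p <- fisher.test(table, alternative = "two.sided")$p.value
  list(odds_ratio = or, p_value = min(p, 1), flag = "ok")
}
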