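#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (SNPs; following the study design the number of
#'   genes is not included in the correction).
#' @return The per-test P-value threshold `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 1299240)  # 3.85e-8
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Expected fraction of chance discoveries
#'
#' With a Bonferroni threshold `alpha / m` applied to `m` SNPs for each of
#' `n_genes` genes, about `alpha * n_genes` gene-SNP models are expected to
#' be significant by chance genome-wide.  Dividing by the observed number of
#' discoveries gives the expected false-positive fraction among them.
#'
#' @param alpha family-wise rate used per gene.
#' @param n_genes number of genes scanned.
#' @param n_discoveries number of significant gene-SNP models observed.
#' @return Expected false-positive fraction (0-1).
#' @export
expected_false_positive_fraction <- function(alpha, n_genes, n_discoveries) {
  stopifnot(alpha > 0, alpha < 1, n_genes >= 1, n_discoveries >= 1)
  alpha * n_genes / n_discoveries
}

# Population-indicator covariate matrix (one level omitted; intercept
# included), the structure correction of the association model.
population_covariates <- function(panel) {
  pop <- factor(panel$samples$population)
  if (nlevels(pop) > 1) model.matrix(~pop)
  else matrix(1, nrow(panel$geno), 1, dimnames = list(NULL, "(Intercept)"))
}

#' Structure-corrected association scan for one gene
#'
#' For each SNP, ordinary least squares of the replicate-averaged expression
#' value on an intercept, the population-indicator covariates and the
#' genotype dosage (0/1/2), followed by a two-sided t-test of the dosage
#' coefficient with `n - p` degrees of freedom.  Monomorphic SNPs are
#' skipped; SNPs with missing genotypes are tested on their complete cases.
#'
#' @param y named numeric vector of replicate-averaged expression values, one
#'   per individual (names = sample ids of `panel`).
#' @param panel a [genotype_panel()] of the same individuals.
#' @param covariates covariate matrix including intercept (default: intercept
#'   plus population indicators from the panel).  Pass a 1-column intercept
#'   matrix to scan without structure correction.
#' @param threshold P-value threshold (e.g. [bonferroni_threshold()]); only
#'   records at or below it are returned.  `NULL` returns every test.
#' @return Data frame: `snp`, `chrom`, `pos`, `beta`, `t`, `p`, `n`.
#' @export
scan_gene <- function(y, panel, covariates = NULL, threshold = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(names(y))) {
    ix <- match(panel$samples$sample, names(y))
    if (anyNA(ix)) stop_config("expression values missing for some individuals")
    y <- y[ix]
  } else stopifnot(length(y) == nrow(panel$geno))
  C <- covariates %||% population_covariates(panel)
  C <- as.matrix(C)
  n <- length(y)
  p <- ncol(C)
  if (n <= p + 2)
    stop_config("too few individuals (%d) for a scan with %d covariate column(s)",
                n, p)
  Q <- qr.Q(qr(C))
  ry <- y - Q %*% crossprod(Q, y)
  G <- panel$geno
  has_na <- colSums(is.na(G)) > 0
  m <- ncol(G)
  beta <- tstat <- pval <- rep(NA_real_, m)
  nn <- rep(n, m)
  complete <- which(!has_na)
  if (length(complete)) {
    Gc <- G[, complete, drop = FALSE]
    sds <- apply(Gc, 2, sd)
    poly <- sds > 0
    if (any(poly)) {
      Gp <- Gc[, poly, drop = FALSE]
      rG <- Gp - Q %*% crossprod(Q, Gp)
      sxx <- colSums(rG^2)
      # dosages collinear with the covariates carry no testable signal
      testable <- sxx > 1e-8
      sxy <- as.vector(crossprod(rG, ry))
      syy <- sum(ry^2)
      b <- ifelse(testable, sxy / sxx, NA_real_)
      df <- n - p - 1
      rss <- syy - b * sxy
      se <- sqrt(pmax(rss, 0) / df / sxx)
      tv <- b / se
      idx <- complete[poly]
      beta[idx] <- b
      tstat[idx] <- tv
      pval[idx] <- ifelse(testable, 2 * pt(-abs(tv), df), NA_real_)
    }
  }
  for (j in which(has_na)) {
    x <- G[, j]
    ok <- !is.na(x)
    if (sum(ok) <= p + 1 || sd(x[ok]) == 0) next
    Qok <- qr.Q(qr(C[ok, , drop = FALSE]))
    ryk <- y[ok] - Qok %*% crossprod(Qok, y[ok])
    rxk <- x[ok] - Qok %*% crossprod(Qok, x[ok])
    sxx <- sum(rxk^2)
    if (sxx < 1e-12) next
    b_j <- sum(rxk * ryk) / sxx
    df_j <- sum(ok) - ncol(Qok) - 1
    rss <- sum(ryk^2) - b_j * sum(rxk * ryk)
    se_j <- sqrt(max(rss, 0) / df_j / sxx)
    beta[j] <- b_j
    tstat[j] <- b_j / se_j
    pval[j] <- 2 * pt(-abs(tstat[j]), df_j)
    nn[j] <- sum(ok)
  }
  out <- data.frame(snp = panel$snps$snp, chrom = panel$snps$chrom,
                    pos = panel$snps$pos, beta = beta, t = tstat, p = pval,
                    n = nn)
  out <- out[!is.na(out$p), , drop = FALSE]
  if (!is.null(threshold)) out <- out[out$p <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge significant SNPs into eQTL peaks
#'
#' Per chromosome, single-linkage positional clustering of the significant
#' SNPs of one gene: consecutive SNPs at most `window` apart join the same
#' peak, so each cluster is an independent peak in the P-value profile.  The
#' lead SNP of a peak is its minimum-P member (ties: the smaller position).
#'
#' @param records significant [scan_gene()] records for one gene.
#' @param window maximum gap, in bp, between consecutive member SNPs of a
#'   peak (default 5 Mb).
#' @return Data frame with one row per peak: `chrom`, `lead_snp`, `lead_pos`,
#'   `lead_p`, `n_snps`, `start`, `end`, and a list column `members` of member
#'   SNP ids.
#' @export
merge_peaks <- function(records, window = 5e6) {
  if (nrow(records) == 0)
    return(data.frame(chrom = character(), lead_snp = character(),
                      lead_pos = numeric(), lead_p = numeric(),
                      n_snps = integer(), start = numeric(), end = numeric()))
  peaks <- list()
  for (chrom in unique(records$chrom)) {
    rc <- records[records$chrom == chrom, , drop = FALSE]
    rc <- rc[order(rc$pos), , drop = FALSE]
    gap <- c(0, diff(rc$pos))
    cluster <- cumsum(gap > window)
    for (cl in unique(cluster)) {
      sub <- rc[cluster == cl, , drop = FALSE]
      lead <- sub[order(sub$p, sub$pos), ][1, ]
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom, lead_snp = lead$snp, lead_pos = lead$pos,
        lead_p = lead$p, n_snps = nrow(sub),
        start = min(sub$pos), end = max(sub$pos),
        members = I(list(sub$snp)))
    }
  }
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Classify an eQTL peak as cis or trans
#'
#' A peak is *cis* when its lead SNP lies on the gene's chromosome within
#' 500 kb upstream of the transcript start or 500 kb downstream of the 3'
#' end, i.e. within `[start - cis_window, end + cis_window]` (the window is
#' symmetric about the gene span, so the strand does not change it);
#' otherwise *trans*.  Unannotated genes are labelled `"unknown"`.
#'
#' @param peaks a [merge_peaks()] data frame.
#' @param gene_annot one-row data frame (or list) with `chrom`, `start`,
#'   `end` for the gene (1-based inclusive); `NULL`/`NA` fields give
#'   `"unknown"`.
#' @param cis_window half-width of the cis window in bp (default 500 kb).
#' @return The `peaks` data frame with a `label` column (`"cis"`, `"trans"`
#'   or `"unknown"`).
#' @export
classify_cis_trans <- function(peaks, gene_annot, cis_window = 5e5) {
  if (is.null(gene_annot) || anyNA(c(gene_annot$chrom, gene_annot$start,
                                     gene_annot$end))) {
    peaks$label <- "unknown"
    return(peaks)
  }
  lo <- gene_annot$start - cis_window
  hi <- gene_annot$end + cis_window
  peaks$label <- ifelse(peaks$chrom == gene_annot$chrom &
                        peaks$lead_pos >= lo & peaks$lead_pos <= hi,
                        "cis", "trans")
  peaks
}
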