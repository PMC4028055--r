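#' SNP quality-control thresholds
#'
#' Defaults are the standard population-genetics filters: SNPs are removed if
#' called in less than 90% of individuals, with minor allele frequency below
#' 0.05, or departing from Hardy-Weinberg equilibrium at P < 0.001; only
#' autosomes are retained; LD pruning targets pairwise genotypic r^2 < 0.05.
#'
#' @param min_call_rate minimum fraction of individuals genotyped.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_alpha Hardy-Weinberg chi-square P-value below which a SNP is
#'   removed.
#' @param autosomes_only drop SNPs on chromosomes named `X`, `Y`, `MT`
#'   (case-insensitive, with or without a `chr` prefix).
#' @param prune_r2 squared-correlation threshold for LD pruning.
#' @param prune_window,prune_step sliding-window size and step, in SNPs.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_maf = 0.05,
                          hwe_alpha = 0.001, autosomes_only = TRUE,
                          prune_r2 = 0.05, prune_window = 50L,
                          prune_step = 5L) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5,
            hwe_alpha > 0, hwe_alpha <= 1,
            prune_r2 > 0, prune_r2 <= 1,
            prune_window >= 2, prune_step >= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, autosomes_only = autosomes_only,
                 prune_r2 = prune_r2, prune_window = as.integer(prune_window),
                 prune_step = as.integer(prune_step)),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed genotype
#' counts against the Hardy-Weinberg expectation at the sample allele
#' frequency.  Monomorphic SNPs return P = 1.  Vectorised over SNPs.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote).
#' @return P-value(s) in (0, 1].
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions -> 1
#' hwe_test(50, 0, 50)    # complete heterozygote deficit -> ~0
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_config("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (any(n == 0)) stop_config("at least one genotype call is required")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  exp_counts <- cbind(n * p^2, n * 2 * p * q, n * q^2)
  obs <- cbind(n_AA, n_Aa, n_aa)
  mono <- p == 0 | p == 1
  chisq <- rowSums(ifelse(exp_counts > 0, (obs - exp_counts)^2 / exp_counts, 0))
  pval <- pchisq(chisq, df = 1, lower.tail = FALSE)
  pval[mono] <- 1
  unname(pval)
}

hwe_test_panel <- function(geno) {
  n_AA <- colSums(geno == 0, na.rm = TRUE)
  n_Aa <- colSums(geno == 1, na.rm = TRUE)
  n_aa <- colSums(geno == 2, na.rm = TRUE)
  ok <- (n_AA + n_Aa + n_aa) > 0
  out <- rep(1, ncol(geno))
  out[ok] <- hwe_test(n_AA[ok], n_Aa[ok], n_aa[ok])
  out
}

is_autosome <- function(chrom) {
  !grepl("^(chr)?(x|y|mt|m)$", tolower(chrom))
}

#' Filter SNPs on call rate, MAF, Hardy-Weinberg and chromosome
#'
#' Applies the four filters of [qc_thresholds()].  With
#' `per_population = TRUE` (the default) every filter is evaluated
#' independently within each population and a SNP failing any filter in any
#' population is removed, leaving the consensus set that passes everywhere.
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @param per_population evaluate filters within each population.
#' @return A list with `panel` (the filtered [genotype_panel()]) and `report`
#'   (data frame of removal counts per criterion; a SNP is counted under
#'   every criterion it fails).
#' @export
filter_snps <- function(panel, thresholds = qc_thresholds(),
                        per_population = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(thresholds, "qc_thresholds"))
  m <- ncol(panel$geno)
  fail_auto <- if (thresholds$autosomes_only) !is_autosome(panel$snps$chrom)
               else rep(FALSE, m)
  groups <- if (per_population) {
    if (is.null(panel$samples$population))
      stop_config("population labels required for per-population QC")
    split(seq_len(nrow(panel$geno)), panel$samples$population)
  } else list(all = seq_len(nrow(panel$geno)))
  fail_call <- fail_maf <- fail_hwe <- rep(FALSE, m)
  for (rows in groups) {
    g <- panel$geno[rows, , drop = FALSE]
    fail_call <- fail_call | (call_rate(g) < thresholds$min_call_rate)
    fail_maf <- fail_maf | (maf(g) < thresholds$min_maf) | is.na(maf(g))
    fail_hwe <- fail_hwe | (hwe_test_panel(g) < thresholds$hwe_alpha)
  }
  keep <- !(fail_auto | fail_call | fail_maf | fail_hwe)
  if (!any(keep))
    stop_config("no SNP survives quality control; check thresholds")
  report <- data.frame(
    criterion = c("input", "non_autosomal", "call_rate", "maf", "hwe",
                  "retained"),
    n_snps = c(m, sum(fail_auto), sum(fail_call), sum(fail_maf),
               sum(fail_hwe), sum(keep)))
  list(panel = subset_panel(panel, snps = keep), report = report)
}

# Pairwise-complete genotypic correlation between two dosage vectors.
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  sx <- sd(x[ok]); sy <- sd(y[ok])
  if (sx == 0 || sy == 0) return(0)
  cor(x[ok], y[ok])^2
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `prune_window` SNPs (per chromosome, positions
#' ascending), while any retained pair has genotypic r^2 at or above
#' `prune_r2`, the member of the worst pair with the lower call rate is
#' dropped (ties: the SNP at the higher position); the window then advances
#' by `prune_step` SNPs.  The retained set has no within-window pair at or
#' above the threshold.
#'
#' @param panel a QC'd [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @return Character vector of retained SNP ids, in panel order.
#' @export
ld_prune <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (thresholds$prune_window < 2) stop_config("pruning window must be >= 2")
  cr <- call_rate(panel$geno)
  keep <- rep(TRUE, ncol(panel$geno))
  for (chrom in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == chrom)
    idx <- idx[order(panel$snps$pos[idx])]
    start <- 1L
    repeat {
      win <- idx[seq(start, min(start + thresholds$prune_window - 1L,
                                length(idx)))]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2 <- suppressWarnings(
          cor(panel$geno[, win, drop = FALSE],
              use = "pairwise.complete.obs")^2)
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        while (length(win) >= 2 && max(r2) >= thresholds$prune_r2) {
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          a <- win[worst[1]]; b <- win[worst[2]]
          drop <- if (cr[a] < cr[b]) a
                  else if (cr[b] < cr[a]) b
                  else if (panel$snps$pos[a] > panel$snps$pos[b]) a else b
          keep[drop] <- FALSE
          di <- match(drop, win)
          win <- win[-di]
          r2 <- r2[-di, -di, drop = FALSE]
        }
      }
      if (start + thresholds$prune_window - 1L >= length(idx)) break
      start <- start + thresholds$prune_step
    }
  }
  panel$snps$snp[keep]
}
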