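#' Construct a genotype panel
#'
#' The container shared by all genotype-facing operations: an individuals x
#' SNPs dosage matrix (0/1/2 copies of the alternate allele, `NA` = missing)
#' with SNP metadata and population labels.
#'
#' @param geno numeric matrix, individuals in rows, SNPs in columns; rownames
#'   are sample ids, colnames SNP ids.
#' @param snps data frame with columns `snp`, `chrom`, `pos` (1-based), `a1`
#'   (reference), `a2` (alternate), one row per column of `geno`.
#' @param samples data frame with columns `sample`, `population`, one row per
#'   row of `geno`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, snps, samples) {
  geno <- as.matrix(geno)
  snps <- as.data.frame(snps)
  samples <- as.data.frame(samples)
  stopifnot(nrow(snps) == ncol(geno), nrow(samples) == nrow(geno),
            all(c("snp", "chrom", "pos") %in% names(snps)),
            all(c("sample", "population") %in% names(samples)))
  if (anyDuplicated(samples$sample))
    stop_config("duplicate sample ids in panel")
  if (!all(geno %in% c(0, 1, 2, NA)))
    stop_config("dosages must be 0, 1, 2 or NA")
  rownames(geno) <- samples$sample
  colnames(geno) <- snps$snp
  structure(list(geno = geno, snps = snps, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs, %d population(s)\n",
              nrow(x$geno), ncol(x$geno),
              length(unique(x$samples$population))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missingness %.2f%%; chromosomes: %s\n", 100 * miss,
              paste(unique(x$snps$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param samples,snps character ids or logical/integer indices; `NULL` keeps
#'   all.
#' @return A `genotype_panel` restricted to the selection.
#' @export
subset_panel <- function(panel, samples = NULL, snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  ri <- seq_len(nrow(panel$geno))
  ci <- seq_len(ncol(panel$geno))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, panel$samples$sample)
          else ri[samples]
    if (anyNA(ri)) stop_config("unknown sample id in selection")
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, panel$snps$snp) else ci[snps]
    if (anyNA(ci)) stop_config("unknown SNP id in selection")
  }
  out <- panel
  out$geno <- panel$geno[ri, ci, drop = FALSE]
  out$snps <- panel$snps[ci, , drop = FALSE]
  out$samples <- panel$samples[ri, , drop = FALSE]
  rownames(out$snps) <- rownames(out$samples) <- NULL
  out
}

# Per-SNP alternate-allele frequency from non-missing calls.
allele_freq <- function(geno) {
  colMeans(geno, na.rm = TRUE) / 2
}

# Minor allele frequency.
maf <- function(geno) {
  p <- allele_freq(geno)
  pmin(p, 1 - p)
}

call_rate <- function(geno) colMeans(!is.na(geno))
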