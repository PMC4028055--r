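#' Write a genotype panel as an uncompressed VCF
#'
#' Minimal VCFv4.2 with a GT FORMAT field (`0/0`, `0/1`, `1/1`, `./.`) and
#' 1-based positions; dosage is the count of the alternate allele.
#' Population labels travel in the companion TSV written by
#' [write_dosage_tsv()] or can be re-supplied on read.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=heritex",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples$sample),
                     collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(panel$geno), ncol(panel$geno))
  ok <- !is.na(panel$geno)
  gt[ok] <- gt_map[panel$geno[ok] + 1]
  lines <- paste(panel$snps$chrom, panel$snps$pos, panel$snps$snp,
                 panel$snps$a1, panel$snps$a2, ".", "PASS", ".", "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Parses the GT field of a (possibly gzipped) VCF via the vcfR package into
#' alternate-allele dosages.
#'
#' @param path VCF file.
#' @param populations named character vector mapping sample id to population
#'   label (unnamed samples get `"POP1"`).
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, populations = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_config("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    out[x %in% c("1/1", "1|1")] <- 2
    out
  }
  geno <- t(apply(gt, 1, count_alt))
  geno <- t(geno)  # individuals x SNPs
  ids <- colnames(gt)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- data.frame(snp = fix$ID, chrom = fix$CHROM,
                     pos = as.numeric(fix$POS), a1 = fix$REF, a2 = fix$ALT)
  pop <- if (is.null(populations)) rep("POP1", length(ids))
         else unname(populations[ids])
  genotype_panel(geno, snps, data.frame(sample = ids, population = pop))
}

#' Write / read a dosage TSV
#'
#' Wide TSV: columns `snp`, `chrom`, `pos`, `a1`, `a2`, then one column per
#' individual holding 0/1/2 dosage (`NA` = missing).  Population labels go
#' in a two-column sidecar written next to the matrix.
#'
#' @param panel a [genotype_panel()].
#' @param path output TSV path; the sidecar is `<path>.populations.tsv`.
#' @export
write_dosage_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  out <- cbind(panel$snps, as.data.frame(t(panel$geno)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel$samples, paste0(path, ".populations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param populations optional named vector overriding the sidecar labels.
#' @return `read_dosage_tsv()`: a [genotype_panel()].
#' @export
read_dosage_tsv <- function(path, populations = NULL) {
  tab <- read.delim(path, check.names = FALSE)
  meta_cols <- c("snp", "chrom", "pos", "a1", "a2")
  stopifnot(all(meta_cols %in% names(tab)))
  ids <- setdiff(names(tab), meta_cols)
  geno <- t(as.matrix(tab[, ids, drop = FALSE]))
  side <- paste0(path, ".populations.tsv")
  pop <- if (!is.null(populations)) unname(populations[ids])
         else if (file.exists(side)) {
           s <- read.delim(side)
           s$population[match(ids, s$sample)]
         } else rep("POP1", length(ids))
  genotype_panel(geno, tab[, meta_cols], data.frame(sample = ids, population = pop))
}

#' Write / read an expression panel TSV
#'
#' Long-by-array TSV: columns `sample_id`, `replicate`, then one column per
#' feature (gene or probe).
#'
#' @param panel an [expression_panel()].
#' @param path output TSV path.
#' @export
write_expression_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "expression_panel"))
  out <- cbind(data.frame(sample_id = panel$samples$sample,
                          replicate = panel$samples$replicate),
               as.data.frame(t(panel$values)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param layer layer tag for the panel read back.
#' @return `read_expression_tsv()`: an [expression_panel()].
#' @export
read_expression_tsv <- function(path, layer = "normalized") {
  tab <- read.delim(path, check.names = FALSE)
  stopifnot(all(c("sample_id", "replicate") %in% names(tab)))
  feats <- setdiff(names(tab), c("sample_id", "replicate"))
  expression_panel(t(as.matrix(tab[, feats, drop = FALSE])),
                   data.frame(sample = tab$sample_id,
                              replicate = tab$replicate),
                   layer = layer)
}

#' Write / read a kinship matrix TSV
#'
#' Square TSV with a header row and a leading id column.
#'
#' @param K a [merge_kinship()] matrix.
#' @param path output TSV path.
#' @export
write_kinship_tsv <- function(K, path) {
  out <- cbind(data.frame(id = rownames(K)), as.data.frame(unclass(K)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @return `read_kinship_tsv()`: the kinship matrix.
#' @export
read_kinship_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  K <- as.matrix(tab[, -1, drop = FALSE])
  rownames(K) <- tab$id
  class(K) <- c("kinship_matrix", class(K))
  K
}
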