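#' Pipeline configuration
#'
#' Collects the simulation settings and every analysis threshold (defaulting
#' to the standard values: call rate 0.90, MAF 0.05, Hardy-Weinberg alpha
#' 0.001, pruning r^2 0.05, relatedness cutoff 0.05, Bonferroni alpha 0.05,
#' 5 Mb peak-merge window, 500 kb cis window) for [run_pipeline()].
#'
#' @param sim a [sim_config()] describing the synthetic data set (or `NULL`
#'   when `genotypes`/`expression` point at input files).
#' @param genotypes,expression optional input paths (VCF or dosage TSV;
#'   expression TSV) used instead of simulation.
#' @param thresholds a [qc_thresholds()].
#' @param relatedness_cutoff pi-hat above which one member of a pair is
#'   excluded.
#' @param bonferroni_alpha family-wise rate for the eQTL scan.
#' @param merge_window peak-merge window in bp.
#' @param cis_window cis-classification half-window in bp.
#' @param run_epistasis fit additive-vs-interaction models for genes with two
#'   eQTL peaks.
#' @param out_dir output directory (created if absent).
#' @param seed master seed for all stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), genotypes = NULL,
                            expression = NULL, thresholds = qc_thresholds(),
                            relatedness_cutoff = 0.05,
                            bonferroni_alpha = 0.05, merge_window = 5e6,
                            cis_window = 5e5, run_epistasis = TRUE,
                            out_dir = tempfile("heritex_run_"), seed = 1) {
  stopifnot(inherits(thresholds, "qc_thresholds"),
            relatedness_cutoff > 0, bonferroni_alpha > 0, bonferroni_alpha < 1,
            merge_window > 0, cis_window > 0)
  structure(list(sim = sim, genotypes = genotypes, expression = expression,
                 thresholds = thresholds,
                 relatedness_cutoff = relatedness_cutoff,
                 bonferroni_alpha = bonferroni_alpha,
                 merge_window = merge_window, cis_window = cis_window,
                 run_epistasis = run_epistasis, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full heritability / eQTL analysis
#'
#' Executes the stages in order — simulate (or load) genotypes and
#' expression, SNP quality control, LD pruning and IBD estimation per
#' population, kinship merging and close-relative exclusion, MDS, expression
#' normalisation, per-gene REML heritability, the structure-corrected eQTL
#' scan with peak merging and cis/trans classification, eQTL heritability by
#' variance-component differencing (aggregating peak lead SNPs for
#' multi-eQTL genes), and optional epistasis fits for two-peak genes —
#' writing every intermediate table as TSV plus a JSON manifest into
#' `config$out_dir`.  Rerunning with the same config and seed reproduces all
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all stage results (`panel`, `kinship`,
#'   `mds`, `heritability`, `associations`, `peaks`, `eqtl_h2`, `epistasis`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  manifest <- list(package = "heritex",
                   version = as.character(utils::packageVersion("heritex")),
                   seed = config$seed, stages = list())
  finish <- function(status) {
    manifest$status <- status
    jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  # --- inputs -------------------------------------------------------------
  sim <- config$sim
  truth <- NULL
  genes_annot <- NULL
  if (!is.null(config$genotypes)) {
    panel <- if (grepl("\\.vcf(\\.gz)?$", config$genotypes))
      read_vcf(config$genotypes) else read_dosage_tsv(config$genotypes)
    expr <- read_expression_tsv(config$expression)
  } else {
    panel <- simulate_genotypes(sim)
    se <- simulate_expression(panel, sim)
    expr <- se$expression
    truth <- se$truth
    genes_annot <- se$genes
    write_dosage_tsv(panel, outp("genotypes.tsv"))
    write_expression_tsv(expr, outp("expression_raw.tsv"))
    write.table(se$genes, outp("gene_annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(se$truth$genes, outp("truth_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  manifest$stages$input <- list(n_individuals = nrow(panel$geno),
                                n_snps = ncol(panel$geno),
                                n_genes = nrow(expr$values))

  # --- genotype QC --------------------------------------------------------
  qc <- filter_snps(panel, config$thresholds, per_population = TRUE)
  write.table(qc$report, outp("qc_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  panel_qc <- qc$panel
  manifest$stages$genotype_qc <- as.list(setNames(qc$report$n_snps,
                                                  qc$report$criterion))

  # --- relatedness --------------------------------------------------------
  pops <- unique(panel_qc$samples$population)
  tables <- lapply(pops, function(pp) {
    sub <- subset_panel(panel_qc, samples = panel_qc$samples$population == pp)
    pruned <- ld_prune(sub, config$thresholds)
    estimate_ibd(sub, pruned_snps = pruned)
  })
  kin <- merge_kinship(tables)
  write_kinship_tsv(kin, outp("kinship.tsv"))
  drops <- exclude_related(kin, panel_qc, config$relatedness_cutoff)
  writeLines(drops, outp("excluded_individuals.txt"))
  keep_ids <- setdiff(rownames(kin), drops)
  panel_final <- subset_panel(panel_qc, samples = keep_ids)
  kin <- kin[keep_ids, keep_ids]
  class(kin) <- c("kinship_matrix", class(kin))
  mds <- mds_coords(panel_final, k = min(3, nrow(panel_final$geno) - 1))
  write.table(mds, outp("mds.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$relatedness <- list(n_excluded = length(drops),
                                      n_retained = length(keep_ids))

  # --- expression normalisation -------------------------------------------
  norm <- normalize_expression(expr)
  means <- norm$means[, keep_ids, drop = FALSE]
  gene_panel <- norm$gene_panel
  keep_cols <- gene_panel$samples$sample %in% keep_ids
  gene_panel$values <- gene_panel$values[, keep_cols, drop = FALSE]
  gene_panel$samples <- gene_panel$samples[keep_cols, , drop = FALSE]
  write_expression_tsv(gene_panel, outp("expression_normalized.tsv"))

  # --- heritability per gene ----------------------------------------------
  Keig <- kinship_eigen(kin)
  pops_f <- factor(panel_final$samples$population)
  X <- if (nlevels(pops_f) > 1) model.matrix(~pops_f)
       else matrix(1, nrow(panel_final$geno), 1)
  indiv <- gene_panel$samples$sample
  h2_tab <- do.call(rbind, lapply(rownames(gene_panel$values), function(g) {
    fit <- reml_fit(gene_panel$values[g, ], indiv, Keig, X = X)
    data.frame(gene = g, sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
               h2 = fit$h2, loglik_reml = fit$loglik_reml,
               loglik_ml = fit$loglik_ml, converged = fit$converged,
               flags = paste(fit$flags, collapse = ";"))
  }))
  write.table(h2_tab, outp("heritability.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$heritability <- list(n_genes = nrow(h2_tab),
                                       mean_h2 = mean(h2_tab$h2))

  # --- eQTL scan ----------------------------------------------------------
  thr <- bonferroni_threshold(config$bonferroni_alpha, ncol(panel_final$geno))
  covs <- population_covariates(panel_final)
  assoc <- do.call(rbind, lapply(rownames(means), function(g) {
    rec <- scan_gene(means[g, ], panel_final, covariates = covs,
                     threshold = thr)
    if (nrow(rec)) cbind(gene = g, rec) else NULL
  }))
  if (is.null(assoc))
    assoc <- data.frame(gene = character(), snp = character(),
                        chrom = character(), pos = numeric(),
                        beta = numeric(), t = numeric(), p = numeric(),
                        n = integer())
  write.table(assoc, outp("associations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$scan <- list(threshold = thr,
                               n_significant = nrow(assoc),
                               n_genes_hit = length(unique(assoc$gene)))

  # --- peaks, cis/trans, eQTL heritability --------------------------------
  peak_list <- list()
  eqtl_h2_list <- list()
  epi_list <- list()
  for (g in unique(assoc$gene)) {
    rec <- assoc[assoc$gene == g, , drop = FALSE]
    pk <- merge_peaks(rec, window = config$merge_window)
    ga <- if (!is.null(genes_annot)) genes_annot[genes_annot$gene == g, ]
          else NULL
    pk <- classify_cis_trans(pk, ga, cis_window = config$cis_window)
    lead_snps <- panel_final$geno[, pk$lead_snp, drop = FALSE]
    fit_free <- reml_fit(gene_panel$values[g, ], indiv, Keig, X = X)
    fit_snp <- fit_snp_model(gene_panel$values[g, ], indiv, Keig,
                             snps = lead_snps, X = X)
    eh <- eqtl_heritability(fit_free, fit_snp)
    per_peak <- vapply(seq_len(nrow(pk)), function(i) {
      f1 <- fit_snp_model(gene_panel$values[g, ], indiv, Keig,
                          snps = lead_snps[, i, drop = FALSE], X = X)
      eqtl_heritability(fit_free, f1)$h2_qtl
    }, numeric(1))
    pk <- cbind(gene = g, pk[, setdiff(names(pk), "members")],
                h2_qtl = per_peak)
    peak_list[[g]] <- pk
    eqtl_h2_list[[g]] <- data.frame(
      gene = g, n_peaks = nrow(pk), h2_qtl_aggregate = eh$h2_qtl,
      delta_sigma_g2 = eh$delta_sigma_g2, delta_sigma_e2 = eh$delta_sigma_e2,
      pi_ratio = eh$pi_ratio, h2_free = eh$h2_free)
    if (config$run_epistasis && nrow(pk) == 2) {
      ef <- fit_epistasis(gene_panel$values[g, ], indiv, Keig,
                          snp1 = lead_snps[, 1], snp2 = lead_snps[, 2],
                          X = X)
      epi_list[[g]] <- data.frame(
        gene = g, aic_additive = ef$aic["additive"],
        aic_interaction = if ("interaction" %in% names(ef$aic))
          ef$aic["interaction"] else NA_real_,
        preferred = ef$preferred, delta_explained = ef$delta_explained)
    }
  }
  peaks <- if (length(peak_list)) do.call(rbind, peak_list) else NULL
  eqtl_h2 <- if (length(eqtl_h2_list)) do.call(rbind, eqtl_h2_list) else NULL
  epistasis <- if (length(epi_list)) do.call(rbind, epi_list) else NULL
  for (nm in c("peaks", "eqtl_h2", "epistasis")) {
    obj <- get(nm)
    if (!is.null(obj)) {
      rownames(obj) <- NULL
      write.table(obj, outp(paste0(nm, ".tsv")), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  manifest$stages$eqtl <- list(
    n_peaks = if (is.null(peaks)) 0L else nrow(peaks),
    n_cis = if (is.null(peaks)) 0L else sum(peaks$label == "cis"),
    n_trans = if (is.null(peaks)) 0L else sum(peaks$label == "trans"))
  finish("complete")
  invisible(list(panel = panel_final, kinship = kin, mds = mds,
                 heritability = h2_tab, associations = assoc, peaks = peaks,
                 eqtl_h2 = eqtl_h2, epistasis = epistasis, truth = truth,
                 genes = genes_annot, means = means, manifest = manifest))
}

#' Summary tables (and optional plots) for a pipeline run
#'
#' Builds the report tables: a histogram of heritability estimates (overall
#' and per gene group), the stacked cis/trans distribution of per-peak
#' `h2_qtl`, and the distribution of `pi` (fraction of heritability explained
#' by detected eQTLs).  Tables come first; if ggplot2 is available a list of
#' plots is attached.
#'
#' @param results the list returned by [run_pipeline()].
#' @param gene_groups optional named list of gene-id vectors (e.g.
#'   housekeeping genes); unknown ids are reported with a warning.
#' @param bins number of histogram bins on \[0, 1\].
#' @return List with `h2_histogram`, `group_histograms`, `eqtl_h2_by_class`,
#'   `pi_summary` and (optionally) `plots`.
#' @export
summarize_results <- function(results, gene_groups = NULL, bins = 20) {
  h2 <- results$heritability
  brk <- seq(0, 1, length.out = bins + 1)
  hist_tab <- function(x) {
    ct <- table(cut(x, breaks = brk, include.lowest = TRUE))
    data.frame(bin = names(ct), count = as.integer(ct))
  }
  out <- list(h2_histogram = hist_tab(h2$h2))
  if (!is.null(gene_groups)) {
    out$group_histograms <- lapply(gene_groups, function(ids) {
      missing <- setdiff(ids, h2$gene)
      if (length(missing))
        warning("gene group names ", length(missing),
                " gene(s) absent from results: ",
                paste(head(missing, 5), collapse = ", "))
      found <- intersect(ids, h2$gene)
      if (!length(found)) return(NULL)
      hist_tab(h2$h2[h2$gene %in% found])
    })
  }
  if (!is.null(results$peaks)) {
    out$eqtl_h2_by_class <- aggregate(h2_qtl ~ label, data = results$peaks,
                                      FUN = function(v)
                                        c(n = length(v), mean = mean(v)))
  }
  if (!is.null(results$eqtl_h2)) {
    pi_v <- results$eqtl_h2$pi_ratio
    out$pi_summary <- data.frame(n = length(pi_v), mean = mean(pi_v),
                                 median = median(pi_v), min = min(pi_v),
                                 max = max(pi_v))
  }
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    df <- data.frame(h2 = h2$h2)
    out$plots <- list(
      h2 = ggplot2::ggplot(df, ggplot2::aes(x = h2)) +
        ggplot2::geom_histogram(breaks = brk) +
        ggplot2::labs(x = expression(h^2), y = "genes"))
    if (!is.null(results$peaks))
      out$plots$eqtl_h2 <- ggplot2::ggplot(
        results$peaks, ggplot2::aes(x = h2_qtl, fill = label)) +
        ggplot2::geom_histogram(breaks = brk, position = "stack") +
        ggplot2::labs(x = "phenotypic variance explained by eQTL",
                      y = "eQTLs")
  }
  out
}
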