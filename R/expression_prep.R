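#' Filter probes by whitelist and background intensity
#'
#' Keeps probes that are on the whitelist (the precomputed probe-to-cDNA
#' mapping screen is consumed as a list of acceptable probe ids) and that are
#' *not* lowly expressed, where lowly expressed means: raw intensity below
#' the array's background on **all** replicate arrays for strictly more than
#' half of the individuals.
#'
#' @param raw a raw-layer [expression_panel()] with per-array `background`
#'   estimates (if absent, the 5th percentile of each array is used as a
#'   fallback and a warning is issued).
#' @param whitelist character vector of probe ids to consider (`NULL` keeps
#'   all).
#' @return The panel restricted to surviving probes.
#' @export
filter_probes <- function(raw, whitelist = NULL) {
  stopifnot(inherits(raw, "expression_panel"))
  if (raw$layer != "raw") stop_config("probe filtering applies to the raw layer")
  bg <- raw$background
  if (is.null(bg)) {
    warning("no background estimates supplied; using each array's 5th percentile")
    bg <- apply(raw$values, 2, quantile, probs = 0.05, names = FALSE)
  }
  keep <- rep(TRUE, nrow(raw$values))
  if (!is.null(whitelist)) keep <- rownames(raw$values) %in% whitelist
  below <- sweep(raw$values, 2, bg, "<")
  samples <- unique(raw$samples$sample)
  # per individual: TRUE when the probe is below background on every replicate
  all_below <- vapply(samples, function(s) {
    cols <- which(raw$samples$sample == s)
    rowSums(below[, cols, drop = FALSE]) == length(cols)
  }, logical(nrow(raw$values)))
  all_below <- matrix(all_below, nrow = nrow(raw$values))
  low <- rowMeans(all_below) > 0.5
  keep <- keep & !low
  out <- raw
  out$values <- raw$values[keep, , drop = FALSE]
  if (!is.null(raw$probe_map))
    out$probe_map <- raw$probe_map[raw$probe_map$probe %in%
                                   rownames(out$values), , drop = FALSE]
  out
}

#' Quantile normalisation across the replicates of one individual
#'
#' Each replicate's sorted values are replaced by the mean of the sorted
#' values across replicates, written back in rank order.  Tied entries
#' receive the mean of the reference values at their tied ranks, so the
#' result is deterministic and rank-preserving.
#'
#' @param values numeric matrix, features x replicates, for one individual.
#' @return Matrix of the same shape; after normalisation all replicates have
#'   identical sorted vectors.
#' @export
quantile_normalize_replicates <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop_config("at least two replicates are required")
  if (anyNA(values)) stop_config("missing intensities are not supported")
  ref <- rowMeans(apply(values, 2, sort))
  out <- values
  for (j in seq_len(ncol(values))) {
    o <- order(values[, j])
    xs <- values[o, j]
    grp <- cumsum(c(TRUE, xs[-1] != xs[-length(xs)]))
    # tied entries get the mean reference value of their tied ranks
    out[o, j] <- stats::ave(ref, grp, FUN = mean)
  }
  out
}

#' Median normalisation across individuals
#'
#' Shifts every array of each individual additively so the individual's
#' median (over all its arrays' values) equals the global median, aligning
#' the location of the per-individual intensity distributions.
#'
#' @param panel a normalized-layer [expression_panel()].
#' @return The panel with shifted values.
#' @export
median_normalize_individuals <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  global <- median(panel$values)
  for (s in unique(panel$samples$sample)) {
    cols <- which(panel$samples$sample == s)
    shift <- global - median(panel$values[, cols])
    panel$values[, cols] <- panel$values[, cols] + shift
  }
  panel
}

#' Collapse probes to genes and average replicates
#'
#' Gene values are unweighted means over the gene's surviving probes; the
#' per-individual value is the unweighted mean over its replicate arrays.
#' Genes with no surviving probe are dropped (with a message).
#'
#' @param panel a normalized-layer [expression_panel()] with a `probe_map`
#'   (if `NULL`, rows are taken to be genes already).
#' @return List with `gene_panel` (gene x array, normalized layer) and
#'   `means` (gene x individual matrix of replicate-averaged values).
#' @export
collapse_and_average <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  vals <- panel$values
  if (!is.null(panel$probe_map)) {
    pm <- panel$probe_map
    missing_map <- setdiff(rownames(vals), pm$probe)
    if (length(missing_map))
      stop_config("probe map does not cover probe(s): %s",
                  paste(head(missing_map, 3), collapse = ", "))
    gene <- pm$gene[match(rownames(vals), pm$probe)]
    vals <- rowsum(vals, gene) / as.vector(table(gene)[sort(unique(gene))])
    dropped <- setdiff(unique(pm$gene), rownames(vals))
    if (length(dropped))
      message(length(dropped), " gene(s) without surviving probes dropped")
  }
  gene_panel <- expression_panel(vals, panel$samples, layer = "normalized")
  sample_f <- factor(panel$samples$sample, levels = unique(panel$samples$sample))
  means <- t(rowsum(t(vals), sample_f) / as.vector(table(sample_f)))
  colnames(means) <- levels(sample_f)
  list(gene_panel = gene_panel, means = means)
}

#' Full expression normalisation chain
#'
#' Within-individual quantile normalisation of replicate arrays, followed by
#' across-individual median normalisation, probe-to-gene collapsing and
#' replicate averaging — the preprocessing the heritability model expects.
#'
#' @param panel a raw- or normalized-layer [expression_panel()] (raw layers
#'   should be probe-filtered with [filter_probes()] first).
#' @return As [collapse_and_average()].
#' @export
normalize_expression <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  for (s in unique(panel$samples$sample)) {
    cols <- which(panel$samples$sample == s)
    panel$values[, cols] <- quantile_normalize_replicates(
      panel$values[, cols, drop = FALSE])
  }
  panel$layer <- "normalized"
  panel <- median_normalize_individuals(panel)
  collapse_and_average(panel)
}
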