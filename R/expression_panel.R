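#' Construct an expression panel
#'
#' Features (probes or genes) x arrays intensity matrix with per-array sample
#' and replicate labels.  A panel carries a `layer` tag recording where it
#' sits in the normalisation chain: `"raw"` intensities (with per-array
#' background estimates), `"normalized"` values, or `"averaged"`
#' (replicate-averaged, one column per individual).
#'
#' @param values numeric matrix, features in rows, arrays in columns.
#' @param samples data frame with columns `sample` and `replicate`, one row
#'   per column of `values` (`replicate` is `NA` for the averaged layer).
#' @param layer `"raw"`, `"normalized"` or `"averaged"`.
#' @param probe_map `NULL` (rows are genes) or data frame with columns
#'   `probe`, `gene` mapping every row to a gene.
#' @param background per-array background intensity (raw layer only).
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, samples, layer = "normalized",
                             probe_map = NULL, background = NULL) {
  values <- as.matrix(values)
  samples <- as.data.frame(samples)
  layer <- match.arg(layer, c("raw", "normalized", "averaged"))
  stopifnot(nrow(samples) == ncol(values),
            all(c("sample", "replicate") %in% names(samples)))
  if (layer != "averaged") {
    reps <- table(samples$sample)
    if (length(unique(reps)) != 1)
      stop_config("replicate count must be equal across individuals")
  }
  if (!is.null(probe_map)) {
    probe_map <- as.data.frame(probe_map)
    stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  }
  if (!is.null(background) && length(background) != ncol(values))
    stop_config("one background value per array is required")
  colnames(values) <- if (layer == "averaged") samples$sample
                      else paste0(samples$sample, ":", samples$replicate)
  structure(list(values = values, samples = samples, layer = layer,
                 probe_map = probe_map, background = background),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("expression_panel (%s): %d features x %d arrays (%d individuals)\n",
              x$layer, nrow(x$values), ncol(x$values),
              length(unique(x$samples$sample))))
  invisible(x)
}

n_replicates <- function(panel) {
  if (panel$layer == "averaged") return(1L)
  as.integer(table(panel$samples$sample)[1])
}
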