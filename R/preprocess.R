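# Probe-level preprocessing: log2 + quantile normalization, variance-based
# probe-to-gene collapse, detection-p expressed universe, sample QC.

#' Log2-transform and quantile-normalize a probe-level experiment
#'
#' Signals are log2-transformed, then every column is mapped onto the
#' across-column mean of sorted log2 values, preserving within-column ranks
#' (the standard quantile-normalization reference distribution). Ties within
#' a column receive the mean of the reference values spanned by their ranks.
#'
#' @param x a linear-scale [timecourse()].
#' @return The same experiment with `signal` replaced by normalized log2
#'   values (`log2 = TRUE`). Detection p-values are carried unchanged.
#' @export
log2_quantile_normalize <- function(x) {
  stopifnot(inherits(x, "timecourse"))
  if (x$log2) stop("experiment is already on the log2 scale")
  bad <- which(x$signal <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive signal at feature '%s', sample '%s' (%g)",
                 rownames(x$signal)[bad[1, 1]],
                 colnames(x$signal)[bad[1, 2]],
                 x$signal[bad[1, , drop = FALSE]]))
  }
  norm <- limma::normalizeQuantiles(log2(x$signal), ties = TRUE)
  dimnames(norm) <- dimnames(x$signal)
  out <- x
  out$signal <- norm
  out$log2 <- TRUE
  out
}

#' Collapse probes to genes by maximal variance
#'
#' For genes measured by several probes, keeps the probe with the largest
#' sample variance of the (normalized log2) signal across all samples; its
#' detection-p row is carried along. Variance ties are broken by the
#' lexicographically smallest probe ID. Probes absent from the map are
#' dropped with a message.
#'
#' @param x a probe-level [timecourse()].
#' @param probe_map data frame with columns `probe` and `gene`.
#' @return A gene-level [timecourse()].
#' @export
collapse_probes <- function(x, probe_map) {
  stopifnot(inherits(x, "timecourse"))
  if (x$level != "probe") stop("experiment is already gene level")
  probe_map <- tibble::as_tibble(probe_map)
  if (!all(c("probe", "gene") %in% names(probe_map)) || !nrow(probe_map)) {
    stop("probe_map must be a non-empty table with columns probe, gene")
  }
  if (anyDuplicated(probe_map$probe)) {
    stop("each probe must map to exactly one gene")
  }
  present <- rownames(x$signal)
  unmapped <- setdiff(present, probe_map$probe)
  if (length(unmapped)) {
    message(length(unmapped), " unmapped probe(s) dropped")
  }
  keep <- probe_map %>%
    dplyr::filter(.data$probe %in% present) %>%
    dplyr::mutate(variance = apply(
      x$signal[.data$probe, , drop = FALSE], 1L, stats::var)) %>%
    dplyr::arrange(.data$gene, dplyr::desc(.data$variance), .data$probe) %>%
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  out <- x
  out$signal <- x$signal[keep$probe, , drop = FALSE]
  rownames(out$signal) <- keep$gene
  if (!is.null(x$detection)) {
    out$detection <- x$detection[keep$probe, , drop = FALSE]
    rownames(out$detection) <- keep$gene
  }
  out$level <- "gene"
  out
}

#' Expressed-gene universe from detection p-values
#'
#' A gene belongs to the expressed set when its detection p-value is below
#' `alpha` in every sample (the strictest reading of "expressed above
#' background in all replicates"). This set is the analysis universe for the
#' differential-expression, warping, component and network stages; the full
#' platform universe is kept separately for enrichment.
#'
#' @param x a gene-level [timecourse()] with detection p-values.
#' @param alpha detection-p threshold (default 0.05).
#' @return Character vector of expressed gene IDs.
#' @export
expressed_set <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "timecourse"))
  if (is.null(x$detection)) stop("detection p-values are required")
  rownames(x$signal)[rowSums(x$detection >= alpha) == 0]
}

#' Sample-level quality control
#'
#' Hierarchical clustering of samples (distance 1 - Pearson correlation,
#' average linkage) over the `n_top` most variable genes, plus sample PCA
#' scores. A sample is flagged as a candidate outlier when the height at
#' which it first merges into the tree exceeds `median + 3 IQR` of all merge
#' heights.
#'
#' @param x a log2-scale [timecourse()].
#' @param n_top number of top-variance genes used (default 2000); capped at
#'   the gene count with a warning.
#' @return A list: `tree` (hclust), `flags` (tibble with columns `sample`,
#'   `merge_height`, `outlier`) and `pca` (tibble of PC scores).
#' @export
qc_samples <- function(x, n_top = 2000) {
  stopifnot(inherits(x, "timecourse"))
  if (ncol(x$signal) < 3) stop("need at least 3 samples")
  if (n_top > nrow(x$signal)) {
    warning("n_top exceeds gene count; using all ", nrow(x$signal), " genes")
    n_top <- nrow(x$signal)
  }
  v <- apply(x$signal, 1L, stats::var)
  top <- x$signal[order(v, decreasing = TRUE)[seq_len(n_top)], , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(top, method = "pearson"))
  tree <- stats::hclust(d, method = "average")
  # height at which each leaf first merges
  first_merge <- vapply(seq_len(ncol(top)), function(i) {
    tree$height[which(apply(tree$merge == -i, 1L, any))[1]]
  }, numeric(1))
  cut <- stats::median(tree$height) + 3 * stats::IQR(tree$height)
  pca <- stats::prcomp(t(top), center = TRUE, scale. = FALSE)
  flags <- tibble::tibble(
    sample = colnames(top),
    merge_height = first_merge,
    outlier = first_merge > cut
  )
  list(tree = tree,
       flags = flags,
       pca = dplyr::bind_cols(x$samples,
                              tibble::as_tibble(pca$x[, 1:min(4, ncol(pca$x)),
                                                      drop = FALSE])))
}
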