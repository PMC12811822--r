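# Expression filtering and normalisation ahead of network construction.

#' Filter genes by CPM and transform counts
#'
#' Counts-per-million filtering (CPM > `cpm_min` in at least
#' `ceiling(min_frac * n_samples)` samples) followed by a log2(CPM + 1)
#' transform of the retained genes. The log-CPM transform is this package's
#' variance-stabilising step; the network statistics downstream are
#' rank-robust (biweight midcorrelation), so they are insensitive to the
#' precise monotone transform used.
#'
#' @param counts non-negative integer matrix, genes x samples (rownames =
#'   gene ids).
#' @param cpm_min CPM threshold (strict `>`).
#' @param min_frac minimum fraction of samples above threshold.
#' @return Numeric matrix (retained genes x samples) of log2(CPM + 1)
#'   values, with attribute `provenance = "log2cpm"`.
#' @export
filter_and_transform <- function(counts, cpm_min = 1, min_frac = 0.2) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop_input("filter_and_transform: need >= 2 samples")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_input("filter_and_transform: counts must be non-negative integers")
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop_input("filter_and_transform: zero library size in sample(s) %s",
               paste(colnames(counts)[libsize == 0], collapse = ", "))
  cpm <- sweep(counts, 2, libsize, "/") * 1e6
  keep <- rowSums(cpm > cpm_min) >= ceiling(min_frac * ncol(counts))
  expr <- log2(cpm[keep, , drop = FALSE] + 1)
  attr(expr, "provenance") <- "log2cpm"
  expr
}

#' Remove outlier samples by hierarchical clustering
#'
#' Average-linkage clustering of samples on Euclidean distance, cut at
#' `height_cutoff`; the largest resulting branch is retained.
#'
#' @param expr genes x samples matrix.
#' @param height_cutoff tree cut height.
#' @return The matrix restricted to retained samples; removed sample ids in
#'   attribute `removed_samples`.
#' @export
remove_outlier_samples <- function(expr, height_cutoff) {
  if (ncol(expr) < 3L)
    stop_input("remove_outlier_samples: need >= 3 samples")
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  cl <- stats::cutree(hc, h = height_cutoff)
  sizes <- table(cl)
  if (max(sizes) < 2L)
    stop_input("remove_outlier_samples: cutoff %g leaves only singleton branches",
               height_cutoff)
  biggest <- as.integer(names(sizes)[which.max(sizes)])
  keep <- cl == biggest
  out <- expr[, keep, drop = FALSE]
  attr(out, "removed_samples") <- colnames(expr)[!keep]
  attr(out, "provenance") <- attr(expr, "provenance")
  out
}

#' Select the most variable genes
#'
#' Ranks genes by variance (ties broken lexicographically by gene id for
#' reproducibility) and keeps the top `n`.
#'
#' @param expr genes x samples matrix with rownames.
#' @param n number of genes to keep; if `n` >= available genes, all are
#'   kept with a warning.
#' @return Restricted matrix.
#' @export
top_variable <- function(expr, n = 5000L) {
  v <- apply(expr, 1, stats::var)
  if (n >= nrow(expr)) {
    if (n > nrow(expr))
      warning(sprintf("top_variable: only %d genes available", nrow(expr)))
    return(expr)
  }
  o <- order(-v, rownames(expr))
  expr[sort(o[seq_len(n)]), , drop = FALSE]
}
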