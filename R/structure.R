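#' All-vs-all sample Spearman correlation
#'
#' Rank correlation (mid-ranks for ties) between every pair of samples,
#' plus an average-linkage hierarchical ordering of the samples on the
#' distance `1 - rho` — the layout used for correlation heat maps. Run on
#' the expressed-filtered expression matrix.
#'
#' @param em an [expression_matrix()] with at least 2 samples.
#' @return list of class `SampleCorrelation`: `rho` (symmetric matrix,
#'   unit diagonal), `order` (dendrogram leaf order), `hclust` (the
#'   average-linkage tree).
#' @export
sample_spearman <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  x <- em$values
  if (ncol(x) < 2) stop("need at least 2 samples")
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant expression column(s), correlation undefined: ",
         paste(colnames(x)[const], collapse = ", "))
  rho <- stats::cor(x, method = "spearman")
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  structure(list(rho = rho, order = hc$order, hclust = hc),
            class = "SampleCorrelation")
}

#' Sample-level PCA
#'
#' Principal components of the samples on log2 RPKM values: genes are
#' centered across samples, no unit-variance scaling. A deterministic
#' sign convention is applied (the largest-magnitude gene loading of each
#' component is made positive).
#'
#' @param em an [expression_matrix()] on the `log2rpkm` scale, >= 3 samples.
#' @return list of class `PcaResult`: `scores` (samples x components),
#'   `variance_explained` (percentages, non-increasing, summing to 100),
#'   `rotation` (gene loadings).
#' @export
pca_samples <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale != "log2rpkm") stop("PCA expects the log2rpkm scale")
  if (ncol(em$values) < 3) stop("need at least 3 samples for PCA")
  pr <- stats::prcomp(t(em$values), center = TRUE, scale. = FALSE)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, "*")
  rotation <- sweep(pr$rotation, 2, flip, "*")
  ve <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, variance_explained = ve,
                 rotation = rotation),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  k <- min(3, length(x$variance_explained))
  cat(sprintf("PcaResult: %d samples; first %d components explain %.1f%%\n",
              nrow(x$scores), k, sum(x$variance_explained[seq_len(k)])))
  invisible(x)
}
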