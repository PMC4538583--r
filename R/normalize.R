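#' Filter to expressed genes
#'
#' Keeps exactly the genes whose raw count is greater than zero in every
#' sample; gene order is preserved. This per-sample criterion guarantees
#' strictly positive RPKM, so downstream log2 transforms need no
#' pseudocount. Pre-filter library sizes are retained for RPKM
#' denominators.
#'
#' @param cm a [count_matrix()].
#' @return the filtered `CountMatrix` (warns, but does not error, if no
#'   gene survives).
#' @export
filter_expressed <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (nrow(cm$counts) == 0) stop("empty count matrix")
  keep <- rowSums(cm$counts > 0) == ncol(cm$counts)
  if (!any(keep)) warning("no gene has positive counts in every sample")
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  out$gene_lengths <- cm$gene_lengths[keep]
  out$lib_sizes <- cm$lib_sizes   # depth measured before filtering
  out
}

#' Compute RPKM
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm_ij = 1e9 * k_ij / (length_i * N_j)`, with `N_j` the pre-filter
#' column sum of raw counts for sample j (the counted-read proxy for
#' total mapped reads).
#'
#' @param cm a [count_matrix()] (typically after [filter_expressed()]).
#' @return an [expression_matrix()] on the `rpkm` scale.
#' @export
compute_rpkm <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  N <- cm$lib_sizes
  if (any(N <= 0))
    stop("zero library size for sample(s): ",
         paste(names(N)[N <= 0], collapse = ", "))
  vals <- 1e9 * sweep(cm$counts / cm$gene_lengths, 2, N, "/")
  expression_matrix(vals, cm$sample_meta, scale = "rpkm")
}

#' log2-transform an RPKM matrix
#'
#' Elementwise log2. Requires an expressed-filtered RPKM matrix (all
#' values strictly positive); no pseudocount is applied.
#'
#' @param em an [expression_matrix()] on the `rpkm` scale.
#' @return an `ExpressionMatrix` on the `log2rpkm` scale.
#' @export
log2_transform <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale != "rpkm") stop("input must be on the rpkm scale")
  if (any(em$values <= 0))
    stop("non-positive RPKM present; run filter_expressed() before log2")
  expression_matrix(log2(em$values), em$sample_meta, scale = "log2rpkm")
}
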