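#' Relative qPCR expression (2^-dCT)
#'
#' Converts threshold cycles to reference-normalized relative abundance:
#' `dCT = CT_target - CT_reference`, value `2^-dCT`. Wells with a missing
#' CT yield `NA` and are excluded pairwise downstream.
#'
#' @param qpcr long data.frame with columns `gene_id`, `sample_id`,
#'   `ct_target`, `ct_reference`.
#' @return data.frame `gene_id`, `sample_id`, `value` (`2^-dCT`).
#' @export
delta_ct_expression <- function(qpcr) {
  req <- c("gene_id", "sample_id", "ct_target", "ct_reference")
  miss <- setdiff(req, names(qpcr))
  if (length(miss)) stop("qpcr table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(stats::na.omit(c(qpcr$ct_target, qpcr$ct_reference)) <= 0))
    stop("CT values must be positive")
  data.frame(gene_id = qpcr$gene_id, sample_id = qpcr$sample_id,
             value = 2^-(qpcr$ct_target - qpcr$ct_reference))
}

#' Welch two-sample t-test on replicate intensities
#'
#' Unequal-variance t-test used to annotate significant protein (or
#' qPCR) differences between the first and last PD.
#'
#' @param a,b numeric replicate vectors (typically n = 3 each).
#' @return two-sided p-value.
#' @export
protein_t_test <- function(a, b) {
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Cross-platform fold-change concordance
#'
#' For each assayed gene of one cell line: the log2 fold change between
#' the first and last PD on each platform (RNA-seq group-mean RPKM with
#' pseudocount 0.5; qPCR as `-ddCT` where `ddCT = mean dCT_last - mean
#' dCT_first`; protein as log2 of the supplied expression ratio), the
#' Spearman correlation between RPKM and `2^-dCT` across all samples
#' assayed on both platforms, and a flag for sign agreement of all
#' available platform fold changes.
#'
#' @param em RPKM-scale [expression_matrix()].
#' @param qpcr long CT table as in [delta_ct_expression()].
#' @param line cell-line label.
#' @param first_pd,last_pd the two PDs compared.
#' @param protein_ratio optional named numeric vector of protein
#'   last/first expression ratios per gene (linear scale).
#' @return data.frame of class `ConcordanceResult`: `gene_id`,
#'   `spearman_rho`, `n_pairs`, `rho_reliable` (>= 3 paired samples),
#'   `log2fc_rnaseq`, `log2fc_qpcr`, `log2fc_protein`, `sign_concordant`.
#' @export
platform_fold_changes <- function(em, qpcr, line, first_pd, last_pd,
                                  protein_ratio = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"), em$scale == "rpkm")
  sm <- em$sample_meta
  rel <- delta_ct_expression(qpcr)
  genes <- unique(rel$gene_id)
  genes <- genes[genes %in% rownames(em$values)]
  if (!length(genes)) stop("no qPCR gene found in the expression matrix")
  line_samples <- sm$sample_id[sm$cell_line == line]
  s_first <- sm$sample_id[sm$cell_line == line & sm$pd == first_pd]
  s_last <- sm$sample_id[sm$cell_line == line & sm$pd == last_pd]
  if (!length(s_first) || !length(s_last))
    stop("no samples at the requested PDs for line ", line)
  out <- lapply(genes, function(g) {
    q <- rel[rel$gene_id == g, ]
    qv <- stats::setNames(q$value, q$sample_id)
    common <- intersect(line_samples, names(qv)[!is.na(qv)])
    rho <- NA_real_
    if (length(common) >= 2) {
      xg <- em$values[g, common]; yg <- qv[common]
      if (stats::sd(xg) > 0 && stats::sd(yg) > 0)   # constant series: rho undefined
        rho <- stats::cor(xg, yg, method = "spearman")
    }
    dct <- -log2(qv)                      # dCT recovered from 2^-dCT
    fc_q <- -(mean(dct[intersect(s_last, names(dct))], na.rm = TRUE) -
              mean(dct[intersect(s_first, names(dct))], na.rm = TRUE))
    fc_r <- log2((mean(em$values[g, s_last]) + 0.5) /
                 (mean(em$values[g, s_first]) + 0.5))
    fc_p <- if (!is.null(protein_ratio) && g %in% names(protein_ratio))
      log2(protein_ratio[[g]]) else NA_real_
    fcs <- c(fc_r, fc_q, fc_p)
    fcs <- fcs[!is.na(fcs)]
    data.frame(gene_id = g, spearman_rho = rho, n_pairs = length(common),
               rho_reliable = length(common) >= 3,
               log2fc_rnaseq = fc_r, log2fc_qpcr = fc_q,
               log2fc_protein = if (is.null(protein_ratio) ||
                                    !(g %in% names(protein_ratio))) NA_real_
                                else log2(protein_ratio[[g]]),
               sign_concordant = length(unique(sign(fcs))) == 1)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ConcordanceResult", "data.frame")
  res
}
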