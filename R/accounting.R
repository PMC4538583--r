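#' Recurrence partition of ordered DEG sets
#'
#' For an ordered list of DEG sets (one per comparison, e.g. the bars of
#' an intersection barplot), labels every gene of every comparison by the
#' earliest comparison in which it appeared as a DEG. Genes first seen in
#' the current comparison are "new"; recurring genes keep the label of
#' their first appearance, so identical colors across bars mean the same
#' recurring set.
#'
#' @param deg_sets named list of character vectors, in comparison order.
#' @return list of class `RecurrencePartition`: `labels` (per comparison,
#'   a named-by-gene vector of first-appearance indices), `counts`
#'   (matrix comparisons x origin-labels; row sums equal the DEG totals).
#' @export
recurrence_partition <- function(deg_sets) {
  if (!length(deg_sets)) stop("need a nonempty list of DEG sets")
  if (is.null(names(deg_sets)))
    names(deg_sets) <- sprintf("comparison_%d", seq_along(deg_sets))
  n <- length(deg_sets)
  first_seen <- integer(0)
  labels <- vector("list", n)
  names(labels) <- names(deg_sets)
  for (t in seq_len(n)) {
    genes <- unique(deg_sets[[t]])
    new <- setdiff(genes, names(first_seen))
    first_seen <- c(first_seen, stats::setNames(rep(t, length(new)), new))
    labels[[t]] <- first_seen[genes]
  }
  counts <- matrix(0L, n, n, dimnames = list(names(deg_sets),
                                             names(deg_sets)))
  for (t in seq_len(n)) {
    tab <- table(factor(labels[[t]], levels = seq_len(n)))
    counts[t, ] <- as.integer(tab)
  }
  structure(list(labels = labels, counts = counts),
            class = "RecurrencePartition")
}

#' Common regulation between two cell lines
#'
#' Splits the intersection of two DEG sets by fold-change sign agreement:
#' genes up in both lines, down in both, or changing in opposite
#' directions.
#'
#' @param deg1,deg2 character vectors of DEG ids (typically strict
#'   first-vs-last DEG of each line).
#' @param sign1,sign2 named numeric vectors giving the fold-change sign
#'   (or the log2 fold change itself) per gene for each line; must cover
#'   the intersection.
#' @return list: `intersection`, `common_up`, `common_down`, `discordant`
#'   (the three subsets partition the intersection).
#' @export
crossline_common <- function(deg1, deg2, sign1, sign2) {
  inter <- intersect(deg1, deg2)
  miss <- inter[!(inter %in% names(sign1)) | !(inter %in% names(sign2))]
  if (length(miss))
    stop("missing fold-change sign for gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  s1 <- sign(sign1[inter]); s2 <- sign(sign2[inter])
  list(intersection = inter,
       common_up = inter[s1 > 0 & s2 > 0],
       common_down = inter[s1 < 0 & s2 < 0],
       discordant = inter[s1 * s2 <= 0])
}

#' Select genes for wet-lab validation
#'
#' Genes that are strict DEG in both cell lines and either show strong
#' expression (maximum per-group mean RPKM above a threshold, i.e. a
#' strong signal in at least one condition) or belong to a curated list
#' of established senescence/cell-cycle genes.
#'
#' @param genes character vector of candidate gene ids (strict DEG in
#'   both lines).
#' @param max_rpkm named numeric vector: per gene, the maximum group-mean
#'   RPKM over all (line, PD) groups.
#' @param threshold RPKM cutoff, strict `>`.
#' @param curated character vector of curated gene ids (may be empty).
#' @return character vector of selected genes, in input order.
#' @export
select_validation_genes <- function(genes, max_rpkm, threshold = 50,
                                    curated = character()) {
  if (threshold <= 0) stop("threshold must be > 0")
  strong <- genes %in% names(max_rpkm)[max_rpkm > threshold]
  genes[strong | genes %in% curated]
}

#' Per-group mean RPKM
#'
#' Mean RPKM per gene within every (cell line, PD) group — the per-PD
#' expression profiles used for clustering, validation-gene selection and
#' reporting.
#'
#' @param em an RPKM-scale [expression_matrix()].
#' @return list: `means` (genes x groups matrix), `groups` (data.frame
#'   `cell_line`, `pd` per column, PD-ascending within line).
#' @export
group_mean_rpkm <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"), em$scale == "rpkm")
  sm <- em$sample_meta
  key <- paste(sm$cell_line, sm$pd, sep = "|")
  grp <- unique(data.frame(cell_line = sm$cell_line, pd = sm$pd, key = key))
  grp <- grp[order(grp$cell_line, grp$pd), ]
  means <- sapply(grp$key, function(k)
    rowMeans(em$values[, key == k, drop = FALSE]))
  colnames(means) <- sprintf("%s_PD%g", grp$cell_line, grp$pd)
  list(means = means,
       groups = data.frame(cell_line = grp$cell_line, pd = grp$pd,
                           row.names = colnames(means)))
}
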