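#' Construct a CountMatrix
#'
#' Bundles a raw gene-level count matrix with its per-sample metadata and
#' per-gene lengths. This is the entry container for the whole pipeline;
#' all downstream stages consume it or the [ExpressionMatrix] derived from
#' it. Library sizes (per-sample column sums) are computed at construction
#' time and carried along, so that RPKM denominators survive gene filtering.
#'
#' @param counts integer matrix, genes x samples, non-negative. Must have
#'   rownames (gene ids) and colnames (sample ids).
#' @param sample_meta data.frame with one row per sample and columns
#'   `sample_id`, `cell_line`, `pd` (numeric population doubling) and
#'   `replicate` (integer). Rows are matched to `colnames(counts)`.
#' @param gene_lengths numeric vector of gene lengths in bp, named by gene
#'   id or in row order of `counts`; all > 0.
#' @return An object of class `CountMatrix`: a list with elements `counts`,
#'   `sample_meta`, `gene_lengths` and `lib_sizes` (pre-filter column sums).
#' @export
count_matrix <- function(counts, sample_meta, gene_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must contain non-negative integers")
  storage.mode(counts) <- "double"   # keep exact integers, avoid overflow in sums
  sample_meta <- as.data.frame(sample_meta)
  req <- c("sample_id", "cell_line", "pd", "replicate")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    stop("sample_meta is missing column(s): ", paste(miss, collapse = ", "))
  if (!setequal(sample_meta$sample_id, colnames(counts)))
    stop("sample_meta$sample_id does not match colnames(counts)")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- sample_meta$sample_id
  if (anyNA(sample_meta$cell_line) || anyNA(sample_meta$pd))
    stop("every sample needs a cell_line and a pd")
  gene_lengths <- unlist(gene_lengths)
  if (is.null(names(gene_lengths))) {
    if (length(gene_lengths) != nrow(counts))
      stop("gene_lengths length does not match number of genes")
    names(gene_lengths) <- rownames(counts)
  }
  if (!all(rownames(counts) %in% names(gene_lengths)))
    stop("gene_lengths missing for some genes")
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  structure(
    list(counts = counts,
         sample_meta = sample_meta,
         gene_lengths = gene_lengths,
         lib_sizes = colSums(counts)),
    class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("cell lines:",
      paste(sprintf("%s (%d)", names(table(x$sample_meta$cell_line)),
                    table(x$sample_meta$cell_line)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Construct an ExpressionMatrix
#'
#' Normalized expression values (RPKM or log2 RPKM) plus the sample
#' metadata needed to interpret columns.
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param sample_meta as in [count_matrix()].
#' @param scale either `"rpkm"` or `"log2rpkm"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, sample_meta, scale = c("rpkm", "log2rpkm")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have dimnames")
  if (scale == "rpkm" && any(values < 0))
    stop("RPKM values must be non-negative")
  sample_meta <- as.data.frame(sample_meta)
  if (!setequal(sample_meta$sample_id, colnames(values)))
    stop("sample_meta does not match columns of 'values'")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- sample_meta$sample_id
  structure(list(values = values, sample_meta = sample_meta, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d genes x %d samples\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read a CountMatrix from TSV files
#'
#' Reads the three plain-text tables that define a dataset: the count
#' matrix (gene id rows x sample columns), the sample sheet and the gene
#' length table. The same schemas are written by [write_dataset()].
#'
#' @param counts_file TSV, first column `gene_id`, remaining columns one
#'   per sample.
#' @param samples_file TSV with columns `sample_id`, `cell_line`, `pd`,
#'   `replicate`.
#' @param lengths_file TSV with columns `gene_id`, `length_bp`.
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(counts_file, samples_file, lengths_file) {
  for (f in c(counts_file, samples_file, lengths_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  cnt <- utils::read.delim(counts_file, check.names = FALSE)
  if (names(cnt)[1] != "gene_id") stop(counts_file, ": first column must be 'gene_id'")
  m <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(m) <- cnt$gene_id
  sm <- utils::read.delim(samples_file, colClasses = c(sample_id = "character",
                                                       cell_line = "character"))
  lg <- utils::read.delim(lengths_file)
  if (!all(c("gene_id", "length_bp") %in% names(lg)))
    stop(lengths_file, ": needs columns gene_id, length_bp")
  count_matrix(m, sm, stats::setNames(lg$length_bp, lg$gene_id))
}

#' Write a dataset to TSV files
#'
#' Writes `counts.tsv`, `samples.tsv`, `lengths.tsv` and, when ground
#' truth is supplied, `truth.tsv` into `dir`.
#'
#' @param cm a [count_matrix()] object.
#' @param dir output directory, created if needed.
#' @param truth optional ground-truth data.frame (from [generate_dataset()]).
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(cm, dir, truth = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("counts.tsv", "samples.tsv", "lengths.tsv"))
  utils::write.table(data.frame(gene_id = rownames(cm$counts), cm$counts,
                                check.names = FALSE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$sample_meta, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(cm$gene_lengths),
                                length_bp = unname(cm$gene_lengths)),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    p <- file.path(dir, "truth.tsv")
    utils::write.table(truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
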