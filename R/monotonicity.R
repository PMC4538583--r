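#' Monotonicity test configuration
#'
#' @param n_resamples number of replicate-resampled profiles per gene.
#' @param alpha significance level of the class rule.
#' @param seed RNG seed for the resampling.
#' @param sided `"two.sided"` (default) or `"greater"` (one-sided on rho).
#' @param exhaustive when TRUE and the number of distinct resample paths
#'   `r^5` is at most 1024, enumerate every path instead of sampling.
#' @return list of class `monotony_config`.
#' @export
monotony_config <- function(n_resamples = 100, alpha = 0.05, seed = 1L,
                            sided = c("two.sided", "greater"),
                            exhaustive = FALSE) {
  sided <- match.arg(sided)
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_resamples = as.integer(n_resamples), alpha = alpha,
                 seed = as.integer(seed), sided = sided,
                 exhaustive = exhaustive),
            class = "monotony_config")
}

# cache of permutation matrices (n! x n index matrices) per n
.perm_cache <- new.env(parent = emptyenv())

.all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  P <- perms(seq_len(n))
  .perm_cache[[key]] <- P
  P
}

# exact permutation null of Spearman's rho between the mid-ranks `rx`
# (a fixed multiset) and the target ranks 1..n: rho for all n! orderings
.rho_perm_dist <- function(rx) {
  n <- length(rx)
  P <- .all_perms(n)
  RX <- matrix(rx[P], nrow(P), n)
  s <- seq_len(n)
  sx <- stats::sd(rx)
  if (sx == 0) return(rep(0, nrow(P)))
  as.vector((RX %*% (s - mean(s))) / ((n - 1) * sx * stats::sd(s)))
}

#' Exact Spearman correlation test for short series
#'
#' Spearman's rho (mid-ranks for ties) between a series and a target
#' (default: the linearly increasing curve f(x) = x, i.e. the series
#' index), with the p-value obtained by full enumeration of all n!
#' orderings of the observed values — exact also under ties, because the
#' enumeration permutes the observed mid-ranks themselves. Series longer
#' than 8 points fall back to the large-sample t approximation.
#'
#' @param x numeric series, length >= 3.
#' @param y target series (default `seq_along(x)`).
#' @param sided `"two.sided"`: `p = P(|rho_perm| >= |rho_obs|)`;
#'   `"greater"`: `p = P(rho_perm >= rho_obs)`.
#' @return list: `rho`, `p`, `constant` (TRUE with `rho = 0, p = 1` when
#'   either series is constant).
#' @export
exact_spearman_p <- function(x, y = seq_along(x),
                             sided = c("two.sided", "greater")) {
  sided <- match.arg(sided)
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (length(y) != n) stop("x and y lengths differ")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = 0, p = 1, constant = TRUE))
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    # enumeration is against orderings of x relative to y; when y is not
    # already in rank order, permute rx against ry directly
    P <- .all_perms(n)
    RX <- matrix(rx[P], nrow(P), n)
    ryc <- ry - mean(ry)
    null <- as.vector((RX %*% ryc) / ((n - 1) * stats::sd(rx) * stats::sd(ry)))
    p <- if (sided == "two.sided") mean(abs(null) >= abs(rho) - 1e-12)
         else mean(null >= rho - 1e-12)
  } else {
    t <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- if (sided == "two.sided") 2 * stats::pt(-abs(t), n - 2)
         else stats::pt(-t, n - 2)
    p <- min(1, p)
  }
  list(rho = rho, p = p, constant = FALSE)
}

# ---- fast per-gene resampling core (n = 5 time points) ----

# tail-probability lookup for the tie-free n=5 null: for each achievable
# |rho| value, P(|rho_perm| >= |rho|)
.null5_table <- function(sided) {
  key <- paste0("null5_", sided)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  null <- .rho_perm_dist(1:5)
  v <- if (sided == "two.sided") abs(null) else null
  uq <- sort(unique(v))
  tail <- vapply(uq, function(u) mean(v >= u - 1e-12), 0)
  tab <- list(values = uq, tail = tail)
  .perm_cache[[key]] <- tab
  tab
}

.null5_lookup <- function(stat, tab) {
  # p = tail prob at the largest table value <= stat + 1e-12
  idx <- findInterval(stat + 1e-12, tab$values)
  idx[idx < 1] <- 1
  tab$tail[idx]
}

# mat: 5 x r matrix (PD-ascending rows, replicates in columns);
# draws resampled profiles, returns c(i) = mean rho, p(i) = median p
.monotony_gene <- function(mat, config) {
  r <- ncol(mat)
  npd <- nrow(mat)
  stopifnot(npd == 5)
  if (config$exhaustive && r^npd <= 1024) {
    idx <- as.matrix(expand.grid(rep(list(seq_len(r)), npd)))
    B <- nrow(idx)
  } else {
    B <- config$n_resamples
    idx <- matrix(sample.int(r, B * npd, replace = TRUE), B, npd)
  }
  M <- matrix(0, B, npd)
  for (j in seq_len(npd)) M[, j] <- mat[j, idx[, j]]
  # row-wise mid-ranks via pairwise comparisons
  Rk <- matrix(0.5, B, npd)
  for (j in seq_len(npd)) {
    acc <- numeric(B)
    for (k in seq_len(npd))
      acc <- acc + (M[, k] < M[, j]) + 0.5 * (M[, k] == M[, j])
    Rk[, j] <- Rk[, j] + acc
  }
  ss <- rowSums((Rk - 3)^2)                  # 10 when tie-free
  num <- as.vector(Rk %*% (1:5 - 3))
  sd_s <- stats::sd(1:5)
  rho <- ifelse(ss > 0, num / (4 * sqrt(ss / 4) * sd_s), 0)
  p <- rep(1, B)
  tab <- .null5_table(config$sided)
  stat <- if (config$sided == "two.sided") abs(rho) else rho
  free <- abs(ss - 10) < 1e-9
  p[free] <- .null5_lookup(stat[free], tab)
  tied <- which(!free & ss > 0)
  for (i in tied) {
    null <- .rho_perm_dist(Rk[i, ])
    p[i] <- if (config$sided == "two.sided")
      mean(abs(null) >= abs(rho[i]) - 1e-12)
    else mean(null >= rho[i] - 1e-12)
  }
  c(ci = mean(rho), pi = stats::median(p))
}

.monotony_class <- function(ci, pi, alpha) {
  ifelse(pi < alpha & ci > 0, "up",
  ifelse(pi < alpha & ci < 0, "down", "nonuniform"))
}

#' Classify one gene's monotonic behaviour
#'
#' Resamples one replicate per PD, correlates each resampled 5-point
#' profile with the linearly increasing curve f(x) = x by exact Spearman
#' ([exact_spearman_p()]), and aggregates: `c(i)` is the mean resampled
#' rho and `p(i)` the median resampled exact p-value. The gene is
#' classified `up` when `c(i) > 0` and `p(i) < alpha`, `down` when
#' `c(i) < 0` and `p(i) < alpha`, otherwise `nonuniform`.
#'
#' @param mat numeric matrix, 5 PDs (ascending, rows) x replicates
#'   (columns) of expression values (RPKM).
#' @param config a [monotony_config()]; seeds the resampling.
#' @return list: `ci`, `pi`, `class`.
#' @export
classify_gene <- function(mat, config = monotony_config()) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing values in replicate matrix")
  if (nrow(mat) != 5) stop("expected 5 PDs in rows")
  set.seed(config$seed)
  z <- .monotony_gene(mat, config)
  list(ci = unname(z["ci"]), pi = unname(z["pi"]),
       class = unname(.monotony_class(z["ci"], z["pi"], config$alpha)))
}

#' Classify every gene of a cell line
#'
#' Runs [classify_gene()]'s resampling procedure over all genes of one
#' cell line. The configured seed fixes the entire run (genes consume
#' the RNG stream in row order).
#'
#' @param em RPKM-scale [expression_matrix()].
#' @param line cell-line label to analyse.
#' @param config a [monotony_config()].
#' @return data.frame of class `MonotonicityResult`: `gene_id`, `ci`
#'   (mean resampled rho), `pi` (median exact p), `class` in
#'   `{up, down, nonuniform}`.
#' @export
classify_monotonic <- function(em, line, config = monotony_config()) {
  stopifnot(inherits(em, "ExpressionMatrix"), em$scale == "rpkm")
  sm <- em$sample_meta
  sel <- sm$cell_line == line
  if (!any(sel)) stop("unknown cell line: ", line)
  pds <- sort(unique(sm$pd[sel]))
  if (length(pds) != 5) stop("cell line ", line, " must have 5 PDs")
  cols <- lapply(pds, function(p) which(sel & sm$pd == p))
  r <- lengths(cols)
  if (any(r == 0)) stop("PD without replicates")
  if (length(unique(r)) != 1)
    stop("unequal replicate numbers across PDs are not supported")
  X <- em$values[, unlist(cols), drop = FALSE]
  G <- nrow(X)
  set.seed(config$seed)
  out <- matrix(0, G, 2)
  r1 <- r[1]
  for (g in seq_len(G)) {
    m <- matrix(X[g, ], nrow = 5, ncol = r1, byrow = TRUE)
    out[g, ] <- .monotony_gene(m, config)
  }
  res <- data.frame(gene_id = rownames(X), ci = out[, 1], pi = out[, 2],
                    class = .monotony_class(out[, 1], out[, 2], config$alpha),
                    row.names = NULL)
  class(res) <- c("MonotonicityResult", "data.frame")
  res
}

#' Compare monotonicity calls between two cell lines
#'
#' Venn-style bookkeeping of the three-class labels: genes monotone in
#' the same direction in both lines, in opposite directions, or neither.
#'
#' @param res1,res2 `MonotonicityResult` data.frames over the same gene
#'   universe.
#' @return list: `common_up`, `common_down`, `opposite`, `rest` (gene id
#'   vectors, disjoint, covering the universe) and `counts`.
#' @export
compare_lines <- function(res1, res2) {
  if (!setequal(res1$gene_id, res2$gene_id)) {
    bad <- c(setdiff(res1$gene_id, res2$gene_id),
             setdiff(res2$gene_id, res1$gene_id))
    stop("gene universes differ; offending ids: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  r2 <- res2[match(res1$gene_id, res2$gene_id), ]
  c1 <- res1$class; c2 <- r2$class
  g <- res1$gene_id
  common_up <- g[c1 == "up" & c2 == "up"]
  common_down <- g[c1 == "down" & c2 == "down"]
  opposite <- g[(c1 == "up" & c2 == "down") | (c1 == "down" & c2 == "up")]
  rest <- setdiff(g, c(common_up, common_down, opposite))
  list(common_up = common_up, common_down = common_down,
       opposite = opposite, rest = rest,
       counts = c(common_up = length(common_up),
                  common_down = length(common_down),
                  opposite = length(opposite), rest = length(rest)))
}
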