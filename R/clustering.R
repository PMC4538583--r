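#' Fuzzy c-means configuration
#'
#' Settings of the temporal-profile clustering: fuzzifier `m = 1.2`,
#' at most 500 iterations, objective-change tolerance `1e-8`, 30 random
#' starts, candidate cluster numbers 2..10.
#'
#' @param m fuzzifier (> 1). Close to 1 gives near-hard partitions.
#' @param max_iter maximum alternating-minimization iterations per start.
#' @param tol stop when the objective decreases by less than this.
#' @param n_starts random restarts; the best (lowest objective) is kept.
#' @param c_range integer vector of candidate cluster numbers.
#' @param seed RNG seed.
#' @return list of class `fcm_config`.
#' @export
fcm_config <- function(m = 1.2, max_iter = 500, tol = 1e-8, n_starts = 30,
                       c_range = 2:10, seed = 1L) {
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (tol <= 0) stop("tolerance must be > 0")
  if (n_starts < 1) stop("need at least 1 start")
  structure(list(m = m, max_iter = as.integer(max_iter), tol = tol,
                 n_starts = as.integer(n_starts),
                 c_range = as.integer(c_range), seed = as.integer(seed)),
            class = "fcm_config")
}

#' Build concatenated two-line temporal profiles
#'
#' For each gene of a subset, the five per-PD replicate-mean RPKM values
#' of the first cell line followed by the five of the second, z-scored
#' per gene over all 10 entries jointly (so the between-line expression
#' offset survives scaling). Genes with a constant raw profile carry no
#' shape information and are dropped with a warning.
#'
#' @param em RPKM-scale [expression_matrix()] covering both lines.
#' @param genes gene ids to profile.
#' @param lines the two cell-line labels, in concatenation order
#'   (default: sorted unique lines of the metadata).
#' @return list of class `ProfileMatrix`: `values` (genes x 10 z-scored),
#'   `raw_means` (genes x 10 mean RPKM), `lines`, `pds` (per column).
#' @export
build_profiles <- function(em, genes,
                           lines = sort(unique(em$sample_meta$cell_line))) {
  stopifnot(inherits(em, "ExpressionMatrix"), em$scale == "rpkm")
  if (!length(genes)) stop("empty gene subset")
  if (length(lines) != 2) stop("profiles concatenate exactly 2 cell lines")
  gm <- group_mean_rpkm(em)
  cols <- unlist(lapply(lines, function(ln) {
    ix <- which(gm$groups$cell_line == ln)
    if (length(ix) != 5) stop("cell line ", ln, " does not have 5 PDs")
    ix[order(gm$groups$pd[ix])]
  }))
  raw <- gm$means[genes, cols, drop = FALSE]
  mu <- rowMeans(raw)
  sdv <- apply(raw, 1, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning(sum(const), " gene(s) with constant profiles dropped")
    raw <- raw[!const, , drop = FALSE]
    mu <- mu[!const]; sdv <- sdv[!const]
  }
  if (!nrow(raw)) stop("no non-constant profile left")
  z <- (raw - mu) / sdv
  structure(list(values = z, raw_means = raw, lines = lines,
                 pds = gm$groups$pd[cols]),
            class = "ProfileMatrix")
}

# squared Euclidean distances points (n x d) -> centers (c x d)
.sqdist <- function(X, V) {
  d2 <- outer(rowSums(X^2), rowSums(V^2), "+") - 2 * X %*% t(V)
  pmax(d2, 0)
}

# membership update; zero-distance points get crisp membership
.fcm_membership <- function(d2, m) {
  pw <- d2^(-1 / (m - 1))
  zero <- !is.finite(pw)
  if (any(zero)) {
    rows <- which(rowSums(zero) > 0)
    pw[rows, ] <- 0
    pw[cbind(rows, max.col(zero[rows, , drop = FALSE]))] <- 1
  }
  pw / rowSums(pw)
}

.fcm_once <- function(X, c, m, max_iter, tol) {
  n <- nrow(X)
  # flat-simplex initial memberships (Dirichlet(1,...,1) rows)
  U <- matrix(stats::rexp(n * c), n, c)
  U <- U / rowSums(U)
  J_prev <- Inf
  J_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Um <- U^m
    V <- (t(Um) %*% X) / colSums(Um)
    d2 <- .sqdist(X, V)
    U <- .fcm_membership(d2, m)
    J <- sum(U^m * d2)
    J_trace <- c(J_trace, J)
    if (abs(J_prev - J) < tol) break
    J_prev <- J
  }
  list(U = U, V = V, J = J, J_trace = J_trace, iterations = it)
}

#' Fuzzy c-means clustering
#'
#' Standard FCM with Euclidean distance: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`, centers
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`, objective
#' `J = sum u^m d^2`, iterated until the objective changes by less than
#' the tolerance or `max_iter` is reached. The best of `n_starts` random
#' restarts (lowest final objective) is returned; deterministic given
#' the config seed.
#'
#' @param X a [build_profiles()] result or a plain numeric matrix
#'   (points x dimensions).
#' @param c number of clusters, `2 <= c < n`.
#' @param config an [fcm_config()].
#' @return list of class `ClusteringResult`: `membership` (n x c, rows
#'   sum to 1), `centers` (c x d), `cluster` (hard assignment = argmax
#'   membership), `J` (final objective), `J_trace` (objective per
#'   iteration of the winning start), `c`.
#' @export
fcm <- function(X, c, config = fcm_config()) {
  M <- if (inherits(X, "ProfileMatrix")) X$values else as.matrix(X)
  n <- nrow(M)
  if (c < 2) stop("c must be >= 2")
  if (c >= n) stop("c must be smaller than the number of points")
  set.seed(config$seed)
  best <- NULL
  for (s in seq_len(config$n_starts)) {
    run <- .fcm_once(M, c, config$m, config$max_iter, config$tol)
    if (is.null(best) || run$J < best$J) best <- run
  }
  hard <- max.col(best$U, ties.method = "first")
  rownames(best$U) <- rownames(M)
  names(hard) <- rownames(M)
  structure(list(membership = best$U, centers = best$V, cluster = hard,
                 J = best$J, J_trace = best$J_trace, c = c),
            class = "ClusteringResult")
}

# fuzzy-partition validity indexes; `opt` says which direction is better
.validity_indexes <- function(res, M) {
  U <- res$membership; V <- res$centers
  n <- nrow(U)
  d2 <- .sqdist(M, V)
  Um <- U^res_m_guess(res)
  pc <- sum(U^2) / n
  eps_u <- pmax(U, .Machine$double.xmin)
  pe <- -sum(U * log(eps_u)) / n
  dv2 <- .sqdist(V, V); diag(dv2) <- Inf
  xb <- sum(Um * d2) / (n * min(dv2))
  xbar <- colMeans(M)
  fs <- sum(Um * d2) - sum(Um * matrix(rowSums(sweep(V, 2, xbar)^2),
                                       n, nrow(V), byrow = TRUE))
  c(partition_coefficient = pc, partition_entropy = pe,
    xie_beni = xb, fukuyama_sugeno = fs)
}

# the fuzzifier used when a result was produced (stored by choose_c path)
res_m_guess <- function(res) if (!is.null(res$m)) res$m else 1.2

#' Choose the number of clusters
#'
#' Runs FCM for every candidate c and scores each partition with four
#' fuzzy validity indexes: partition coefficient (maximize), partition
#' entropy (minimize), Xie-Beni (minimize) and Fukuyama-Sugeno
#' (minimize). Each index votes for the candidate it ranks best; the
#' chosen c is the modal vote, ties resolved toward the smallest c.
#'
#' @param X profiles or matrix as in [fcm()].
#' @param config an [fcm_config()]; candidates come from `config$c_range`.
#' @return list: `chosen_c`, `votes` (per index), `validity`
#'   (data.frame of index values per candidate), `results` (the
#'   `ClusteringResult` per candidate, named by c).
#' @export
choose_c <- function(X, config = fcm_config()) {
  M <- if (inherits(X, "ProfileMatrix")) X$values else as.matrix(X)
  cand <- config$c_range[config$c_range >= 2 & config$c_range < nrow(M)]
  if (!length(cand)) stop("empty candidate range")
  results <- list()
  vals <- NULL
  for (ci in cand) {
    cfg_i <- config
    cfg_i$seed <- config$seed + ci   # independent, reproducible per candidate
    res <- fcm(M, ci, cfg_i)
    res$m <- config$m
    results[[as.character(ci)]] <- res
    vals <- rbind(vals, .validity_indexes(res, M))
  }
  validity <- data.frame(c = cand, vals, row.names = NULL)
  votes <- c(
    partition_coefficient = cand[which.max(validity$partition_coefficient)],
    partition_entropy = cand[which.min(validity$partition_entropy)],
    xie_beni = cand[which.min(validity$xie_beni)],
    fukuyama_sugeno = cand[which.min(validity$fukuyama_sugeno)])
  tab <- table(votes)
  top <- as.integer(names(tab)[tab == max(tab)])
  chosen <- min(top)
  list(chosen_c = chosen, votes = votes, validity = validity,
       results = results)
}

#' Per-cluster mean and SD profiles
#'
#' For each cluster and each cell line, the 5-point mean and standard
#' deviation of the member genes' z-scored profiles — the summary shown
#' in cluster line plots.
#'
#' @param res a [fcm()] result.
#' @param X the [build_profiles()] object that was clustered.
#' @return data.frame: `cluster`, `cell_line`, `pd_index` (1..5), `mean`,
#'   `sd`, `n_genes`. Empty clusters yield NaN rows with a warning.
#' @export
summarize_clusters <- function(res, X) {
  stopifnot(inherits(res, "ClusteringResult"), inherits(X, "ProfileMatrix"))
  out <- NULL
  for (k in seq_len(res$c)) {
    members <- X$values[res$cluster == k, , drop = FALSE]
    if (!nrow(members)) warning("cluster ", k, " is empty")
    for (li in 1:2) {
      cols <- ((li - 1) * 5 + 1):(li * 5)
      mn <- if (nrow(members)) colMeans(members[, cols, drop = FALSE]) else rep(NaN, 5)
      sdv <- if (nrow(members) > 1) apply(members[, cols, drop = FALSE], 2, stats::sd)
             else if (nrow(members) == 1) rep(0, 5) else rep(NaN, 5)
      out <- rbind(out, data.frame(cluster = k, cell_line = X$lines[li],
                                   pd_index = 1:5, mean = mn, sd = sdv,
                                   n_genes = nrow(members)))
    }
  }
  rownames(out) <- NULL
  out
}
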