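#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors by the median-of-ratios
#' convention: each sample's counts are divided by the per-gene geometric
#' mean across samples, and the factor is the median of those ratios over
#' the genes with all-positive counts. Factors are reported as-is
#' (not re-scaled to unit geometric mean).
#'
#' @param counts a counts matrix (genes x samples) or a [count_matrix()].
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "CountMatrix")) counts <- counts$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene with all-positive counts; cannot estimate size factors")
  lg <- log(counts[pos, , drop = FALSE])
  gm <- rowMeans(lg)                       # log geometric means
  apply(exp(lg - gm), 2, stats::median)
}

#' Estimate negative-binomial dispersion
#'
#' Method-of-moments dispersion on size-factor-normalized counts. For each
#' gene the within-group moment estimate
#' `MoM = max(0, (var - mean) / mean^2)` is computed per group and
#' averaged. Two model flavors are fit, standing for the two differing
#' dispersion treatments whose agreement defines a consensus DEG call:
#' \describe{
#'   \item{common}{a single `alpha` = mean of the raw (unfloored)
#'     per-gene MoM values, floored at 0 and applied to every gene; the
#'     raw mean is unbiased for a shared dispersion, whereas flooring
#'     per gene before averaging biases it downward.}
#'   \item{trended}{least-squares fit of MoM against `1/mean`, giving
#'     `alpha(mu) = a0 + a1/mu`; each gene then uses
#'     `max(MoM_i, a0 + a1/mean_i)` (floored at 0).}
#' }
#'
#' @param counts counts matrix or [count_matrix()] restricted to the
#'   comparison's samples.
#' @param sf size factors from [estimate_size_factors()].
#' @param groups factor/vector of group labels per sample; every group
#'   must have >= 2 replicates. If omitted, all samples form one group.
#' @param flavor `"common"` or `"trended"`.
#' @return list of class `DispersionModel`: `flavor`, `alpha` (scalar for
#'   common), `coef` (`c(a0, a1)`, trended only), `alpha_gene` (per-gene
#'   dispersions actually used by the test), `mom`, `mean` (diagnostics).
#' @export
estimate_dispersion <- function(counts, sf, groups = NULL,
                                flavor = c("common", "trended")) {
  flavor <- match.arg(flavor)
  if (inherits(counts, "CountMatrix")) counts <- counts$counts
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  groups <- as.factor(groups)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 replicates to estimate dispersion")
  q <- sweep(counts, 2, sf, "/")
  mom_g <- sapply(levels(groups), function(g) {
    qg <- q[, groups == g, drop = FALSE]
    m <- rowMeans(qg)
    v <- rowSums((qg - m)^2) / (ncol(qg) - 1)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  })
  mom_raw <- rowMeans(as.matrix(mom_g))       # unfloored; NA if a group mean is 0
  mom <- pmax(0, ifelse(is.finite(mom_raw), mom_raw, 0))
  mu <- rowMeans(q)
  out <- list(flavor = flavor, mom = mom, mean = mu)
  if (flavor == "common") {
    # the raw (unfloored) mean is unbiased for a shared alpha; flooring
    # before averaging would bias it downward
    ok <- is.finite(mom_raw)
    out$alpha <- if (any(ok)) max(0, mean(mom_raw[ok])) else 0
    out$alpha_gene <- rep(out$alpha, length(mom))
  } else {
    ok <- mu > 0 & is.finite(mom_raw)
    fit <- stats::lsfit(1 / mu[ok], mom_raw[ok])
    co <- unname(fit$coefficients)            # (a0, a1)
    out$coef <- co
    fit_a <- ifelse(mu > 0, co[1] + co[2] / mu, 0)
    out$alpha_gene <- pmax(0, pmax(mom, fit_a))
  }
  names(out$alpha_gene) <- rownames(counts)
  class(out) <- "DispersionModel"
  out
}

# window half-width in conditional SDs used when the enumeration total is
# large; truncation error is < 1e-8 at 8 SDs
.NB_EXACT_FULL_T <- 5000
.NB_EXACT_SDS <- 8

# core of the exact test on already depth-matched, rounded counts
.nb_exact_p <- function(KA, mA, KB, mB, alpha) {
  T <- KA + KB
  if (T == 0) return(1)
  muhat <- T / (mA + mB)
  meanA <- mA * muhat
  meanB <- mB * muhat
  if (T <= .NB_EXACT_FULL_T) {
    a <- 0:T
  } else {
    # conditional variance of the group-A sum given the total
    vA <- mA * (muhat + alpha * muhat^2)
    vB <- mB * (muhat + alpha * muhat^2)
    cv <- vA * vB / (vA + vB)
    w <- ceiling(.NB_EXACT_SDS * sqrt(cv))
    ctr <- round(T * mA / (mA + mB))
    a <- max(0, min(KA, ctr - w)):min(T, max(KA, ctr + w))
  }
  if (alpha <= 0) {
    lp <- stats::dpois(a, meanA, log = TRUE) +
      stats::dpois(T - a, meanB, log = TRUE)
  } else {
    lp <- stats::dnbinom(a, mu = meanA, size = mA / alpha, log = TRUE) +
      stats::dnbinom(T - a, mu = meanB, size = mB / alpha, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pobs <- pr[match(KA, a)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]) / sum(pr))
}

#' Exact negative-binomial two-group test
#'
#' Conditional exact test for a difference in expression between two
#' groups of count samples. Counts are scaled to a common depth (the
#' geometric mean of the size factors) and rounded; conditioning on the
#' total `T = K_A + K_B`, each split `(a, T - a)` is scored by the product
#' of group-sum negative-binomial probabilities with per-group mean
#' `m_g * muhat` and variance `m_g * (muhat + alpha * muhat^2)` (i.e. the
#' sum of `m_g` iid NB(muhat, alpha) draws), and the two-sided p-value is
#' the probability mass of splits no more probable than the observed one,
#' normalized over all splits. At `alpha = 0` the NB degenerates to
#' Poisson and the test reduces to the conditional binomial exact test.
#' For totals above 5000 the sum is restricted to splits within 8
#' conditional SDs of the expected split (truncation error < 1e-8).
#'
#' @param counts_a,counts_b non-negative count vectors for the two groups.
#' @param sf_a,sf_b size factors for the samples of each group.
#' @param alpha NB dispersion (>= 0).
#' @return list: `p` (two-sided p-value in [0, 1]) and `untestable`
#'   (`TRUE` with `p = 1` when the common-scale total is zero).
#' @export
exact_nb_test <- function(counts_a, counts_b, sf_a, sf_b, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (any(c(counts_a, counts_b) < 0)) stop("counts must be non-negative")
  sf <- c(sf_a, sf_b)
  stopifnot(length(sf) == length(counts_a) + length(counts_b), all(sf > 0))
  s_common <- exp(mean(log(sf)))
  ka <- round(counts_a * s_common / sf_a)
  kb <- round(counts_b * s_common / sf_b)
  KA <- sum(ka); KB <- sum(kb)
  list(p = .nb_exact_p(KA, length(counts_a), KB, length(counts_b), alpha),
       untestable = (KA + KB) == 0)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' monotone in rank and capped at 1.
#'
#' @param pvalues numeric vector in [0, 1] (NAs preserved).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Consensus DEG calls
#'
#' A gene is differentially expressed only when both dispersion flavors
#' agree: `deg_standard` requires both FDRs < 0.05; `deg_strict` requires
#' both FDRs < 0.01 and |log2 fold-change| strictly greater than 1.
#'
#' @param fdr_common,fdr_trended adjusted p-values from the two flavors.
#' @param log2fc per-gene log2 fold-changes.
#' @param standard_fdr,strict_fdr,strict_lfc thresholds.
#' @return data.frame with logical columns `deg_standard`, `deg_strict`.
#' @export
call_deg <- function(fdr_common, fdr_trended, log2fc,
                     standard_fdr = 0.05, strict_fdr = 0.01, strict_lfc = 1) {
  std <- fdr_common < standard_fdr & fdr_trended < standard_fdr
  strict <- fdr_common < strict_fdr & fdr_trended < strict_fdr &
    abs(log2fc) > strict_lfc
  data.frame(deg_standard = std & !is.na(std),
             deg_strict = strict & !is.na(strict))
}

#' Differential expression between two PD groups
#'
#' Runs the full consensus pipeline for one comparison: size factors from
#' the comparison's samples, both dispersion flavors, the exact NB test
#' per gene under each, BH adjustment per flavor, fold changes on
#' normalized group means (pseudocount 0.5 in the fold change only), and
#' consensus DEG flags.
#'
#' @param cm a [count_matrix()] (expressed-filtered recommended).
#' @param samples_a,samples_b sample ids of the two groups (>= 2 each).
#' @param standard_fdr,strict_fdr,strict_lfc DEG thresholds, see [call_deg()].
#' @return data.frame of class `ComparisonResult`, one row per gene:
#'   `gene_id`, `mean_a`, `mean_b` (normalized group means), `log2fc`,
#'   `p_common`, `p_trended`, `fdr_common`, `fdr_trended`,
#'   `deg_standard`, `deg_strict`, `untestable`.
#' @export
run_comparison <- function(cm, samples_a, samples_b,
                           standard_fdr = 0.05, strict_fdr = 0.01,
                           strict_lfc = 1) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each group needs at least 2 replicates")
  all_s <- c(samples_a, samples_b)
  if (!all(all_s %in% colnames(cm$counts))) stop("unknown sample id(s)")
  sub <- cm$counts[, all_s, drop = FALSE]
  grp <- rep(c("a", "b"), c(length(samples_a), length(samples_b)))
  sf <- estimate_size_factors(sub)
  disp_c <- estimate_dispersion(sub, sf, grp, "common")
  disp_t <- estimate_dispersion(sub, sf, grp, "trended")

  # pre-scale all counts to the common depth once
  s_common <- exp(mean(log(sf)))
  k <- round(sweep(sub, 2, s_common / sf, "*"))
  KA <- rowSums(k[, grp == "a", drop = FALSE])
  KB <- rowSums(k[, grp == "b", drop = FALSE])
  mA <- sum(grp == "a"); mB <- sum(grp == "b")
  G <- nrow(sub)
  p_c <- p_t <- numeric(G)
  a_c <- disp_c$alpha_gene
  a_t <- disp_t$alpha_gene
  for (i in seq_len(G)) {
    p_c[i] <- .nb_exact_p(KA[i], mA, KB[i], mB, a_c[i])
    p_t[i] <- if (a_t[i] == a_c[i]) p_c[i] else
      .nb_exact_p(KA[i], mA, KB[i], mB, a_t[i])
  }
  q <- sweep(sub, 2, sf, "/")
  mean_a <- rowMeans(q[, grp == "a", drop = FALSE])
  mean_b <- rowMeans(q[, grp == "b", drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  fdr_c <- bh_adjust(p_c)
  fdr_t <- bh_adjust(p_t)
  flags <- call_deg(fdr_c, fdr_t, log2fc, standard_fdr, strict_fdr, strict_lfc)
  res <- data.frame(gene_id = rownames(sub), mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2fc, p_common = p_c, p_trended = p_t,
                    fdr_common = fdr_c, fdr_trended = fdr_t,
                    deg_standard = flags$deg_standard,
                    deg_strict = flags$deg_strict,
                    untestable = (KA + KB) == 0,
                    row.names = NULL)
  class(res) <- c("ComparisonResult", "data.frame")
  res
}

#' Comparison plan for a time course
#'
#' For each cell line, the four consecutive-PD comparisons plus
#' first-vs-last (5 per line, 10 for the default two-line design).
#'
#' @param sample_meta sample sheet with `cell_line` and `pd`.
#' @return data.frame of class `ComparisonPlan`: `cell_line`, `pd_from`,
#'   `pd_to`, `name`; `pd_from < pd_to` throughout.
#' @export
comparison_plan <- function(sample_meta) {
  out <- do.call(rbind, lapply(unique(sample_meta$cell_line), function(ln) {
    pds <- sort(unique(sample_meta$pd[sample_meta$cell_line == ln]))
    n <- length(pds)
    if (n < 2) stop("cell line ", ln, " has fewer than 2 PDs")
    from <- c(pds[-n], pds[1])
    to <- c(pds[-1], pds[n])
    data.frame(cell_line = ln, pd_from = from, pd_to = to,
               name = sprintf("%s_%g_vs_%g", ln, from, to))
  }))
  rownames(out) <- NULL
  class(out) <- c("ComparisonPlan", "data.frame")
  out
}

#' Run every comparison of a plan
#'
#' @param cm a [count_matrix()].
#' @param plan a [comparison_plan()] (default: derived from `cm`).
#' @param ... thresholds forwarded to [run_comparison()].
#' @return named list of `ComparisonResult` data.frames, in plan order.
#' @export
run_comparisons <- function(cm, plan = comparison_plan(cm$sample_meta), ...) {
  sm <- cm$sample_meta
  res <- lapply(seq_len(nrow(plan)), function(i) {
    sa <- sm$sample_id[sm$cell_line == plan$cell_line[i] & sm$pd == plan$pd_from[i]]
    sb <- sm$sample_id[sm$cell_line == plan$cell_line[i] & sm$pd == plan$pd_to[i]]
    run_comparison(cm, sa, sb, ...)
  })
  names(res) <- plan$name
  res
}
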