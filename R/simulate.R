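#' Simulation configuration
#'
#' Defines the synthetic study design: two fibroblast-like cell lines
#' sampled at five population doublings (PDs) in triplicate, with
#' negative-binomial counts whose means follow one of six temporal
#' archetypes. Defaults mirror the study design the package targets:
#' line A at PDs 32/42/52/62/72 and line B at PDs 16/26/46/64/74,
#' three replicates each, ~20k genes.
#'
#' @param n_genes number of genes.
#' @param cell_lines character vector of cell-line labels.
#' @param pd_labels named list (one entry per cell line) of 5 numeric PD
#'   labels each.
#' @param n_replicates replicates per (line, PD); >= 2.
#' @param archetype_fractions named numeric vector over
#'   `c("flat","monotone_up","monotone_down","late_step","early_step","parabolic")`,
#'   summing to 1.
#' @param shared_fraction probability that a regulated (non-flat) gene has
#'   the same archetype in both cell lines.
#' @param effect_size log2 change per PD step for monotone archetypes; step
#'   and parabolic archetypes use a total amplitude of `2 * effect_size`
#'   in log2.
#' @param dispersion_params `c(alpha0, alpha1)` of the mean-dispersion
#'   relation `alpha(mu) = alpha0 + alpha1 / mu`.
#' @param library_size_spread sigma of the log-normal per-sample library
#'   size factor (exercises size-factor estimation).
#' @param length_range bp interval gene lengths are drawn uniformly from.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline expected counts.
#' @param line_offset_sdlog sdlog of the per-gene log-normal cell-line
#'   offset separating the two lines (drives their separation in PCA).
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000,
                       cell_lines = c("A", "B"),
                       pd_labels = list(A = c(32, 42, 52, 62, 72),
                                        B = c(16, 26, 46, 64, 74)),
                       n_replicates = 3,
                       archetype_fractions = c(flat = 0.70,
                                               monotone_up = 0.08,
                                               monotone_down = 0.08,
                                               late_step = 0.05,
                                               early_step = 0.05,
                                               parabolic = 0.04),
                       shared_fraction = 0.8,
                       effect_size = 0.5,
                       dispersion_params = c(0.05, 2),
                       library_size_spread = 0.2,
                       length_range = c(500, 10000),
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1.2,
                       line_offset_sdlog = 0.5,
                       seed = 1L) {
  arche <- c("flat", "monotone_up", "monotone_down", "late_step",
             "early_step", "parabolic")
  if (!setequal(names(archetype_fractions), arche))
    stop("archetype_fractions must be named over: ", paste(arche, collapse = ", "))
  archetype_fractions <- archetype_fractions[arche]
  if (any(archetype_fractions < 0) || any(archetype_fractions > 1))
    stop("archetype fractions must lie in [0, 1]")
  if (abs(sum(archetype_fractions) - 1) > 1e-9)
    stop("archetype fractions must sum to 1 (got ",
         format(sum(archetype_fractions)), ")")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  if (!setequal(names(pd_labels), cell_lines))
    stop("pd_labels must be named by cell line")
  if (any(vapply(pd_labels, length, 1L) != 5L))
    stop("each cell line needs exactly 5 PD labels")
  structure(list(n_genes = as.integer(n_genes), cell_lines = cell_lines,
                 pd_labels = pd_labels, n_replicates = as.integer(n_replicates),
                 archetype_fractions = archetype_fractions,
                 shared_fraction = shared_fraction, effect_size = effect_size,
                 dispersion_params = dispersion_params,
                 library_size_spread = library_size_spread,
                 length_range = length_range,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 line_offset_sdlog = line_offset_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Temporal archetype multiplier
#'
#' Fold-change multiplier applied to a gene's baseline mean at PD index
#' `pd_index` (0-based, 0..4). Shapes, in log2 units `g(i)`:
#' flat `0`; monotone_up `e*i`; monotone_down `-e*i`; early_step `0` at
#' i=0 then `2e`; late_step `0` up to i=3 then `2e`; parabolic
#' `2e * (1 - ((i-2)/2)^2)` (symmetric rise-fall peaking at i=2).
#'
#' @param archetype one of the six archetype names.
#' @param pd_index integer in 0..4 (vectorized).
#' @param effect_size log2 change per PD step, `e` above.
#' @return positive multiplier(s) `2^g(pd_index)`.
#' @export
archetype_multiplier <- function(archetype, pd_index, effect_size) {
  if (any(pd_index < 0 | pd_index > 4)) stop("pd_index must be in 0..4")
  e <- effect_size
  g <- switch(archetype,
    flat          = 0 * pd_index,
    monotone_up   =  e * pd_index,
    monotone_down = -e * pd_index,
    early_step    = ifelse(pd_index >= 1, 2 * e, 0),
    late_step     = ifelse(pd_index >= 4, 2 * e, 0),
    parabolic     = 2 * e * (1 - ((pd_index - 2) / 2)^2),
    stop("unknown archetype: ", archetype))
  2^g
}

.sim_archetypes <- c("flat", "monotone_up", "monotone_down", "late_step",
                     "early_step", "parabolic")

# per-gene log2 profile over the 5 PDs, including direction sign for the
# step/parabolic shapes (monotone shapes carry their sign in the name)
.profile_log2 <- function(archetype, direction, effect_size) {
  base <- log2(archetype_multiplier(archetype, 0:4, effect_size))
  if (archetype %in% c("late_step", "early_step", "parabolic")) base * direction
  else base
}

#' Generate a synthetic senescence time-course dataset
#'
#' Draws a gene x sample count matrix with negative-binomial noise,
#' `variance = mu + alpha(mu) * mu^2`, around per-gene temporal mean
#' profiles, together with the ground truth needed to score every
#' downstream stage. Deterministic given `config$seed`.
#'
#' Gene means factorize as
#' `mu_ij = baseline_i(line) * archetype_multiplier(PD) * lib_j`, with the
#' per-sample library factor `lib_j` log-normal so sequencing depths are
#' unequal. Regulated genes share their archetype between the two lines
#' with probability `shared_fraction`; otherwise the second line redraws
#' an independent archetype (possibly flat).
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]) and `truth`
#'   (data.frame, one row per gene x cell line: `gene_id`, `cell_line`,
#'   `archetype`, `direction`, `monotone_class`, `mu_pd1..mu_pd5` true
#'   reads-scale means at unit library factor, `deg_12..deg_45`,
#'   `deg_15` true DEG status per consecutive pair and first-vs-last).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  lines <- config$cell_lines
  R <- config$n_replicates
  gene_ids <- sprintf("gene%05d", seq_len(G))

  lengths <- stats::setNames(
    round(stats::runif(G, config$length_range[1], config$length_range[2])),
    gene_ids)
  baseline <- stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
  offset2 <- stats::rlnorm(G, 0, config$line_offset_sdlog)  # line 2 vs line 1

  fr <- config$archetype_fractions
  arch1 <- sample(names(fr), G, replace = TRUE, prob = fr)
  shared <- stats::runif(G) < config$shared_fraction
  arch2 <- ifelse(arch1 == "flat", "flat",
           ifelse(shared, arch1,
                  sample(names(fr), G, replace = TRUE, prob = fr)))
  dir1 <- sample(c(-1, 1), G, replace = TRUE)
  dir2 <- ifelse(arch2 == arch1 & shared, dir1, sample(c(-1, 1), G, TRUE))

  arch <- cbind(arch1, arch2)[, seq_along(lines), drop = FALSE]
  dirs <- cbind(dir1, dir2)[, seq_along(lines), drop = FALSE]

  # sample layout: line-major, PD-major, replicate-minor
  meta <- do.call(rbind, lapply(lines, function(ln) {
    pds <- config$pd_labels[[ln]]
    data.frame(sample_id = sprintf("%s_PD%g_R%d", ln, rep(pds, each = R),
                                   rep(seq_len(R), 5)),
               cell_line = ln, pd = rep(pds, each = R),
               replicate = rep(seq_len(R), 5))
  }))
  nS <- nrow(meta)
  libf <- stats::rlnorm(nS, 0, config$library_size_spread)
  a0 <- config$dispersion_params[1]; a1 <- config$dispersion_params[2]

  counts <- matrix(0, G, nS, dimnames = list(gene_ids, meta$sample_id))
  truth <- vector("list", length(lines))
  # log2 profile shapes cached per (archetype, direction)
  shapes <- list()
  shape_of <- function(a, d) {
    key <- paste0(a, d)
    if (is.null(shapes[[key]]))
      shapes[[key]] <<- .profile_log2(a, d, config$effect_size)
    shapes[[key]]
  }

  for (li in seq_along(lines)) {
    ln <- lines[li]
    base_l <- if (li == 1) baseline else baseline * offset2
    prof <- t(vapply(seq_len(G),
                     function(g) shape_of(arch[g, li], dirs[g, li]),
                     numeric(5)))                      # G x 5 log2 multipliers
    mu_pd <- base_l * 2^prof                           # G x 5 true means
    cols <- which(meta$cell_line == ln)
    for (j in cols) {
      pdi <- match(meta$pd[j], config$pd_labels[[ln]])
      mu <- mu_pd[, pdi] * libf[j]
      alpha <- a0 + a1 / mu
      counts[, j] <- stats::rnbinom(G, mu = mu, size = 1 / alpha)
    }
    lg2 <- prof
    ddeg <- function(i, k) abs(lg2[, k] - lg2[, i]) > 1e-9
    truth[[li]] <- data.frame(
      gene_id = gene_ids, cell_line = ln,
      archetype = arch[, li], direction = dirs[, li],
      monotone_class = ifelse(arch[, li] == "monotone_up", "up",
                       ifelse(arch[, li] == "monotone_down", "down",
                              "nonuniform")),
      stats::setNames(as.data.frame(mu_pd), paste0("mu_pd", 1:5)),
      deg_12 = ddeg(1, 2), deg_23 = ddeg(2, 3), deg_34 = ddeg(3, 4),
      deg_45 = ddeg(4, 5), deg_15 = ddeg(1, 5))
  }
  cm <- count_matrix(counts, meta, lengths)
  list(counts = cm, truth = do.call(rbind, truth))
}

#' Simulate a qPCR CT table coupled to an expression matrix
#'
#' Produces target/reference threshold-cycle (CT) pairs whose implied
#' `2^-dCT` abundances are a noisy monotone transform of the supplied
#' RPKM values — the structure assumed by the cross-platform concordance
#' stage. CT noise is Gaussian on the cycle scale.
#'
#' @param em RPKM-scale [expression_matrix()].
#' @param genes gene ids to assay.
#' @param samples sample ids to assay (default: all).
#' @param ct_ref reference-gene CT (constant across samples before noise).
#' @param ct_sd per-well Gaussian CT noise SD, in cycles.
#' @param seed RNG seed.
#' @return long data.frame: `gene_id`, `sample_id`, `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(em, genes, samples = colnames(em$values),
                          ct_ref = 20, ct_sd = 0.25, seed = 1L) {
  stopifnot(inherits(em, "ExpressionMatrix"), em$scale == "rpkm")
  if (!all(genes %in% rownames(em$values))) stop("unknown gene ids")
  set.seed(seed)
  x <- em$values[genes, samples, drop = FALSE]
  # target CT: high expression -> low cycle number; offset keeps CTs positive
  ct_t <- ct_ref + 8 - log2(x + 0.25) +
    stats::rnorm(length(x), 0, ct_sd)
  data.frame(gene_id = rep(genes, times = length(samples)),
             sample_id = rep(samples, each = length(genes)),
             ct_target = as.vector(ct_t),
             ct_reference = ct_ref + stats::rnorm(length(x), 0, ct_sd))
}
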