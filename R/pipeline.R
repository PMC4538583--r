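#' Pipeline configuration
#'
#' One configuration object for the whole analysis. Either the three
#' input TSV paths are given (`counts_file`, `samples_file`,
#' `lengths_file`) or a synthetic dataset is generated from `sim`.
#' The global `seed` is fanned out to the stage seeds by fixed offsets
#' (simulation +0, clustering +101, monotonicity +211, qPCR simulation
#' +307), so stages can be re-run individually yet reproducibly.
#'
#' @param outdir output directory.
#' @param counts_file,samples_file,lengths_file input TSVs (optional when
#'   simulating).
#' @param sim a [sim_config()] or list of its arguments; used when input
#'   files are not given.
#' @param standard_fdr,strict_fdr,strict_lfc DEG thresholds.
#' @param fcm a [fcm_config()] or list of its arguments.
#' @param monotony a [monotony_config()] or list of its arguments.
#' @param qpcr_file optional CT TSV for the concordance stage; when
#'   absent and the data is simulated, a coupled qPCR table is simulated
#'   for the validation genes.
#' @param validation_rpkm_threshold RPKM cutoff of validation-gene
#'   selection.
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            counts_file = NULL, samples_file = NULL,
                            lengths_file = NULL, sim = list(),
                            standard_fdr = 0.05, strict_fdr = 0.01,
                            strict_lfc = 1,
                            fcm = list(), monotony = list(),
                            qpcr_file = NULL,
                            validation_rpkm_threshold = 50,
                            seed = 1L) {
  if (standard_fdr <= 0 || strict_fdr <= 0 || strict_lfc <= 0)
    stop("thresholds must be positive")
  seed <- as.integer(seed)
  as_cfg <- function(x, ctor, cls, seed_off) {
    if (inherits(x, cls)) return(x)
    x$seed <- if (is.null(x$seed)) seed + seed_off else x$seed
    do.call(ctor, x)
  }
  structure(list(
    outdir = outdir,
    counts_file = counts_file, samples_file = samples_file,
    lengths_file = lengths_file,
    sim = if (is.null(counts_file))
      as_cfg(sim, sim_config, "sim_config", 0L) else NULL,
    standard_fdr = standard_fdr, strict_fdr = strict_fdr,
    strict_lfc = strict_lfc,
    fcm = as_cfg(fcm, fcm_config, "fcm_config", 101L),
    monotony = as_cfg(monotony, monotony_config, "monotony_config", 211L),
    qpcr_file = qpcr_file,
    validation_rpkm_threshold = validation_rpkm_threshold,
    seed = seed), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' simulate/load -> filter + RPKM -> sample structure -> consensus NB
#' differential expression over the 10-comparison plan -> DEG recurrence
#' and cross-line accounting -> fuzzy c-means profile clustering with
#' automatic cluster-number selection -> monotonic-trend classification
#' per line -> (optional) qPCR concordance. All stage outputs are TSVs
#' under `config$outdir`; a JSON manifest (`manifest.json`) records the
#' seeds, thresholds and per-stage gene counts. Reruns with an identical
#' configuration reproduce identical outputs.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return the manifest, invisibly (a nested list, also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # fail fast on inputs before any computation
  for (f in c(config$counts_file, config$samples_file, config$lengths_file,
              config$qpcr_file))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("fibrosen")),
                   r_version = R.version.string,
                   seed = config$seed,
                   thresholds = list(standard_fdr = config$standard_fdr,
                                     strict_fdr = config$strict_fdr,
                                     strict_lfc = config$strict_lfc),
                   stages = list())

  # -- data --------------------------------------------------------------
  truth <- NULL
  if (is.null(config$counts_file)) {
    sim <- generate_dataset(config$sim)
    cm <- sim$counts
    truth <- sim$truth
    write_dataset(cm, config$outdir, truth)
    manifest$stages$simulate <- list(n_genes = nrow(cm$counts),
                                     n_samples = ncol(cm$counts),
                                     seed = config$sim$seed)
  } else {
    cm <- read_count_matrix(config$counts_file, config$samples_file,
                            config$lengths_file)
    manifest$stages$load <- list(n_genes = nrow(cm$counts),
                                 n_samples = ncol(cm$counts))
  }

  # -- normalize ---------------------------------------------------------
  cmf <- filter_expressed(cm)
  rpkm <- compute_rpkm(cmf)
  lrpkm <- log2_transform(rpkm)
  .write_tsv(data.frame(gene_id = rownames(rpkm$values), rpkm$values,
                        check.names = FALSE),
             file.path(config$outdir, "rpkm.tsv"))
  manifest$stages$normalize <- list(n_expressed = nrow(cmf$counts))

  # -- sample structure --------------------------------------------------
  sc <- sample_spearman(lrpkm)
  pca <- pca_samples(lrpkm)
  .write_tsv(data.frame(sample_id = rownames(sc$rho), sc$rho,
                        check.names = FALSE),
             file.path(config$outdir, "sample_correlation.tsv"))
  .write_tsv(data.frame(sample_id = rownames(pca$scores),
                        pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                   drop = FALSE], check.names = FALSE),
             file.path(config$outdir, "pca_scores.tsv"))
  .write_tsv(data.frame(component = seq_along(pca$variance_explained),
                        variance_explained = pca$variance_explained),
             file.path(config$outdir, "pca_variance.tsv"))
  manifest$stages$structure <- list(
    variance_first3 = sum(pca$variance_explained[1:3]))

  # -- differential expression ------------------------------------------
  plan <- comparison_plan(cmf$sample_meta)
  de <- run_comparisons(cmf, plan, standard_fdr = config$standard_fdr,
                        strict_fdr = config$strict_fdr,
                        strict_lfc = config$strict_lfc)
  de_dir <- file.path(config$outdir, "de")
  dir.create(de_dir, showWarnings = FALSE)
  for (nm in names(de)) .write_tsv(de[[nm]], file.path(de_dir, paste0(nm, ".tsv")))
  manifest$stages$diffexp <- list(
    comparisons = names(de),
    deg_standard = vapply(de, function(d) sum(d$deg_standard), 0),
    deg_strict = vapply(de, function(d) sum(d$deg_strict), 0))

  # -- DEG accounting ----------------------------------------------------
  lines <- unique(plan$cell_line)
  std_sets <- lapply(de, function(d) d$gene_id[d$deg_standard])
  rec <- recurrence_partition(std_sets)
  .write_tsv(data.frame(comparison = rownames(rec$counts), rec$counts,
                        check.names = FALSE),
             file.path(config$outdir, "recurrence_counts.tsv"))
  fl_names <- vapply(lines, function(ln) {
    i <- which(plan$cell_line == ln)
    plan$name[i[length(i)]]             # first-vs-last is last in plan order
  }, "")
  strict_fl <- lapply(fl_names, function(nm) {
    d <- de[[nm]]; stats::setNames(d$log2fc, d$gene_id)[d$deg_strict]
  })
  common <- crossline_common(names(strict_fl[[1]]), names(strict_fl[[2]]),
                             strict_fl[[1]], strict_fl[[2]])
  .write_tsv(data.frame(
    gene_id = common$intersection,
    direction = ifelse(common$intersection %in% common$common_up, "up",
                ifelse(common$intersection %in% common$common_down, "down",
                       "discordant"))),
    file.path(config$outdir, "common_first_last_deg.tsv"))
  manifest$stages$accounting <- list(
    strict_first_last = lengths(strict_fl),
    intersection = length(common$intersection),
    common_up = length(common$common_up),
    common_down = length(common$common_down),
    discordant = length(common$discordant))

  # -- profile clustering ------------------------------------------------
  strict_union <- lapply(lines, function(ln) {
    nms <- plan$name[plan$cell_line == ln]
    unique(unlist(lapply(de[nms], function(d) d$gene_id[d$deg_strict])))
  })
  clust_genes <- Reduce(intersect, strict_union)
  manifest$stages$clustering <- list(n_genes = length(clust_genes))
  if (length(clust_genes) > max(config$fcm$c_range)) {
    prof <- build_profiles(rpkm, clust_genes, lines)
    sel <- choose_c(prof, config$fcm)
    res <- sel$results[[as.character(sel$chosen_c)]]
    .write_tsv(data.frame(gene_id = rownames(prof$raw_means),
                          prof$raw_means, cluster = res$cluster,
                          check.names = FALSE),
               file.path(config$outdir, "clusters.tsv"))
    .write_tsv(sel$validity, file.path(config$outdir, "cluster_validity.tsv"))
    .write_tsv(summarize_clusters(res, prof),
               file.path(config$outdir, "cluster_profiles.tsv"))
    manifest$stages$clustering$chosen_c <- sel$chosen_c
    manifest$stages$clustering$cluster_sizes <-
      as.integer(table(factor(res$cluster, levels = seq_len(res$c))))
  } else {
    warning("too few strict DEG shared by both lines; clustering skipped")
  }

  # -- monotonicity ------------------------------------------------------
  mono <- lapply(lines, function(ln) classify_monotonic(rpkm, ln, config$monotony))
  names(mono) <- lines
  for (ln in lines)
    .write_tsv(mono[[ln]], file.path(config$outdir,
                                     sprintf("monotony_%s.tsv", ln)))
  venn <- compare_lines(mono[[1]], mono[[2]])
  manifest$stages$monotonicity <- list(
    counts_per_line = lapply(mono, function(m) as.list(table(m$class))),
    venn = as.list(venn$counts))

  # -- concordance (optional) -------------------------------------------
  val_genes <- character()
  gm <- group_mean_rpkm(rpkm)
  max_rpkm <- apply(gm$means, 1, max)
  both_strict <- intersect(names(strict_fl[[1]]), names(strict_fl[[2]]))
  val_genes <- select_validation_genes(both_strict, max_rpkm,
                                       config$validation_rpkm_threshold)
  manifest$stages$validation_genes <- list(n = length(val_genes))
  qpcr <- NULL
  if (!is.null(config$qpcr_file)) {
    qpcr <- utils::read.delim(config$qpcr_file,
                              colClasses = c(gene_id = "character",
                                             sample_id = "character"))
  } else if (is.null(config$counts_file) && length(val_genes)) {
    qpcr <- do.call(rbind, lapply(lines, function(ln) {
      s <- rpkm$sample_meta$sample_id[rpkm$sample_meta$cell_line == ln]
      simulate_qpcr(rpkm, utils::head(val_genes, 12), s,
                    seed = config$seed + 307L)
    }))
  }
  if (!is.null(qpcr) && nrow(qpcr)) {
    conc <- do.call(rbind, lapply(lines, function(ln) {
      pds <- sort(unique(rpkm$sample_meta$pd[rpkm$sample_meta$cell_line == ln]))
      sub <- qpcr[qpcr$sample_id %in%
                    rpkm$sample_meta$sample_id[rpkm$sample_meta$cell_line == ln], ]
      if (!nrow(sub)) return(NULL)
      cbind(cell_line = ln,
            platform_fold_changes(rpkm, sub, ln, pds[1], pds[length(pds)]))
    }))
    .write_tsv(conc, file.path(config$outdir, "concordance.tsv"))
    manifest$stages$concordance <- list(
      n_gene_line = nrow(conc),
      mean_rho = mean(conc$spearman_rho, na.rm = TRUE),
      frac_sign_concordant = mean(conc$sign_concordant, na.rm = TRUE))
  }

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
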