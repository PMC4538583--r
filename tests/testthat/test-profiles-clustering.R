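test_that("profiles are per-gene z-scores of concatenated PD means", {
  d <- generate_dataset(sim_config(n_genes = 80, seed = 14))
  rpkm <- compute_rpkm(filter_expressed(d$counts))
  genes <- rownames(rpkm$values)[1:10]
  prof <- build_profiles(rpkm, genes)
  expect_equal(rowMeans(prof$values), setNames(rep(0, 10), genes),
               tolerance = 1e-9)
  expect_equal(apply(prof$values, 1, sd), setNames(rep(1, 10), genes),
               tolerance = 1e-9)
  # matches hand-computed means and z-scores for one gene
  gm <- group_mean_rpkm(rpkm)
  g <- genes[3]
  raw <- gm$means[g, c(paste0("A_PD", c(32, 42, 52, 62, 72)),
                       paste0("B_PD", c(16, 26, 46, 64, 74)))]
  expect_equal(prof$raw_means[g, ], raw)
  expect_equal(prof$values[g, ], (raw - mean(raw)) / sd(raw),
               tolerance = 1e-12)
})

test_that("constant profiles are dropped and slope scale is factored out", {
  sm <- data.frame(sample_id = paste0("s", 1:20),
                   cell_line = rep(c("A", "B"), each = 10),
                   pd = rep(rep(1:5, each = 2), 2),
                   replicate = rep(1:2, 10))
  v <- rbind(const = rep(5, 20),
             slope1 = rep(rep(1:5, each = 2), 2),
             slope9 = rep(rep(1:5, each = 2), 2) * 9)
  colnames(v) <- sm$sample_id
  em <- expression_matrix(v, sm, "rpkm")
  expect_warning(prof <- build_profiles(em, rownames(v)), "constant")
  expect_false("const" %in% rownames(prof$values))
  expect_equal(prof$values["slope1", ], prof$values["slope9", ],
               tolerance = 1e-12)
})

test_that("FCM resolves well-separated clumps with crisp memberships", {
  p <- planted_profiles(60, noise_sd = 0.05, seed = 15)
  res <- fcm(p$X, 5, fcm_config(n_starts = 10, seed = 16))
  expect_equal(rowSums(res$membership), rep(1, 60), tolerance = 1e-9)
  expect_equal(ari(res$cluster, p$truth), 1)
  expect_true(all(apply(res$membership, 1, max) >= 0.99))
  # objective from returned (U, V) equals J recomputed from definitions
  d2 <- as.matrix(dist(rbind(p$X, res$centers)))[1:60, 61:65]^2
  expect_equal(sum(res$membership^1.2 * d2), res$J, tolerance = 1e-9)
})

test_that("FCM objective is non-increasing and a further update stalls", {
  p <- planted_profiles(80, noise_sd = 0.3, seed = 17)
  cfg <- fcm_config(n_starts = 5, seed = 18)
  res <- fcm(p$X, 4, cfg)
  expect_true(all(diff(res$J_trace) <= 1e-9))
  # first-order stationarity: one more alternating step barely moves J
  U <- res$membership^cfg$m
  V <- (t(U) %*% p$X) / colSums(U)
  d2 <- as.matrix(dist(rbind(p$X, V)))[1:80, 81:84]^2
  Unew <- (d2^(-1 / (cfg$m - 1))) / rowSums(d2^(-1 / (cfg$m - 1)))
  expect_lt(abs(sum(Unew^cfg$m * d2) - res$J), 1e-6)
})

test_that("FCM agrees with an independent implementation on separated data", {
  skip_if_not_installed("e1071")
  p <- planted_profiles(100, noise_sd = 0.1, seed = 19)
  res <- fcm(p$X, 5, fcm_config(n_starts = 10, seed = 20))
  # cmeans is single-start; give it restarts too and keep its best run
  set.seed(20)
  runs <- lapply(1:10, function(i) e1071::cmeans(p$X, 5, m = 1.2,
                                                 iter.max = 500))
  cm <- runs[[which.min(vapply(runs, function(r) r$withinerror, 0))]]
  expect_equal(ari(res$cluster, cm$cluster), 1)
  expect_equal(res$J / 100, cm$withinerror, tolerance = 1e-6)  # cmeans reports J/n
})

test_that("zero-distance points receive crisp membership", {
  X <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10), c(5, 0))
  res <- fcm(X, 2, fcm_config(n_starts = 3, seed = 21))
  # duplicated points coincide with their center
  expect_true(all(apply(res$membership[1:4, ], 1, max) > 0.99))
  expect_error(fcm(X, 5, fcm_config()), "smaller")
  expect_error(fcm(X, 1, fcm_config()), ">= 2")
})

test_that("validity-index voting picks the planted cluster number", {
  p <- planted_profiles(150, noise_sd = 0.2, seed = 22)
  sel <- choose_c(p$X, fcm_config(c_range = 2:7, n_starts = 10, seed = 23))
  expect_equal(sel$chosen_c, 5)
  expect_equal(nrow(sel$validity), 6)
  # single candidate chosen trivially
  one <- choose_c(p$X, fcm_config(c_range = 5, n_starts = 5, seed = 24))
  expect_equal(one$chosen_c, 5)
})

test_that("vote ties resolve to the smallest candidate", {
  # forced tie via direct vote arithmetic on a synthetic validity table:
  # two indexes prefer 4, two prefer 5 -> modal set {4, 5} -> 4
  votes <- c(pc = 4, pe = 4, xb = 5, fs = 5)
  tab <- table(votes)
  top <- as.integer(names(tab)[tab == max(tab)])
  expect_equal(min(top), 4)
})

test_that("cluster summaries follow group-by arithmetic", {
  p <- planted_profiles(60, noise_sd = 0.1, seed = 25)
  sm <- data.frame(sample_id = paste0("s", 1:10),
                   cell_line = rep(c("A", "B"), each = 5),
                   pd = rep(1:5, 2), replicate = 1)
  prof <- structure(list(values = p$X, raw_means = p$X,
                         lines = c("A", "B"), pds = rep(1:5, 2)),
                    class = "ProfileMatrix")
  res <- fcm(p$X, 5, fcm_config(n_starts = 10, seed = 26))
  s <- summarize_clusters(res, prof)
  k <- res$cluster[1]
  members <- p$X[res$cluster == k, 1:5, drop = FALSE]
  ref_mean <- colMeans(members)
  got <- s[s$cluster == k & s$cell_line == "A", ]
  expect_equal(got$mean, unname(ref_mean), tolerance = 1e-12)
  expect_equal(got$sd, unname(apply(members, 2, sd)), tolerance = 1e-12)
  # identical profiles -> SD 0; mirrored pair in one cluster -> mean 0
  # (summary arithmetic checked on a hand-made assignment)
  X2 <- rbind(rep(c(-1, 1), 5), rep(c(-1, 1), 5),
              c(rep(1, 5), rep(-1, 5)), c(rep(-1, 5), rep(1, 5)))
  res2 <- structure(list(cluster = c(1, 1, 2, 2), c = 2),
                    class = "ClusteringResult")
  prof2 <- structure(list(values = X2, raw_means = X2,
                          lines = c("A", "B"), pds = rep(1:5, 2)),
                     class = "ProfileMatrix")
  s2 <- summarize_clusters(res2, prof2)
  expect_equal(s2$sd[s2$cluster == 1], rep(0, 10))
  expect_equal(s2$mean[s2$cluster == 2], rep(0, 10), tolerance = 1e-9)
})
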