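test_that("exact Spearman p comes from full enumeration", {
  s <- exact_spearman_p(1:5)
  expect_equal(s$rho, 1)
  expect_equal(s$p, 2 / 120)
  s2 <- exact_spearman_p(c(1, 2, 3, 5, 4))
  expect_equal(s2$rho, 0.9)
  o <- spearman_perm_oracle(c(1, 2, 3, 5, 4))
  expect_equal(s2$p, o$p)
  # random series, including ties, against the literal enumeration oracle
  set.seed(51)
  for (i in 1:8) {
    x <- sample(1:4, 5, replace = TRUE)
    got <- exact_spearman_p(x)
    ref <- spearman_perm_oracle(x)
    if (sd(rank(x)) == 0) {
      expect_equal(got$p, 1)
    } else {
      expect_equal(got$rho, ref$rho, tolerance = 1e-12)
      expect_equal(got$p, ref$p, tolerance = 1e-12)
    }
  }
  # agrees with cor.test in the tie-free case
  ct <- cor.test(c(2, 1, 4, 3, 5), 1:5, method = "spearman")
  got <- exact_spearman_p(c(2, 1, 4, 3, 5))
  expect_equal(got$rho, unname(ct$estimate))
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})

test_that("constant series return rho 0, p 1 with a flag", {
  s <- exact_spearman_p(rep(3, 5))
  expect_true(s$constant)
  expect_equal(s$rho, 0)
  expect_equal(s$p, 1)
  expect_error(exact_spearman_p(1:2), "3 points")
})

test_that("noise-free trends classify up/down; constants are nonuniform", {
  inc <- matrix(rep(c(1, 2, 4, 8, 16), 3), 5, 3)
  r <- classify_gene(inc, monotony_config(seed = 1))
  expect_equal(r$class, "up")
  expect_equal(r$ci, 1)
  expect_equal(r$pi, 2 / 120)
  dec <- classify_gene(inc[5:1, ], monotony_config(seed = 1))
  expect_equal(dec$class, "down")
  expect_equal(dec$ci, -1)
  flat <- classify_gene(matrix(5, 5, 3), monotony_config(seed = 1))
  expect_equal(flat$class, "nonuniform")
  expect_equal(flat$pi, 1)
})

test_that("reversing PD order flips up and down and preserves p", {
  set.seed(52)
  m <- matrix(2^(0:4) + rnorm(15, 0, 0.01), 5, 3)
  up <- classify_gene(m, monotony_config(seed = 3))
  down <- classify_gene(m[5:1, ], monotony_config(seed = 3))
  expect_equal(up$class, "up")
  expect_equal(down$class, "down")
  expect_equal(down$ci, -up$ci, tolerance = 1e-12)
  expect_equal(down$pi, up$pi, tolerance = 1e-12)
})

test_that("c(i) is invariant under strictly monotone transforms", {
  set.seed(53)
  m <- matrix(rlnorm(15, 2, 1), 5, 3)
  a <- classify_gene(m, monotony_config(seed = 7))
  b <- classify_gene(exp(m / 10), monotony_config(seed = 7))
  expect_equal(a$ci, b$ci, tolerance = 1e-12)
  expect_equal(a$pi, b$pi, tolerance = 1e-12)
})

test_that("exhaustive path enumeration is deterministic and seed-free", {
  set.seed(54)
  m <- matrix(rnorm(15, rep(1:5, 1)), 5, 3)
  cfgs <- lapply(c(1, 2), function(s)
    monotony_config(seed = s, exhaustive = TRUE))
  r1 <- classify_gene(m, cfgs[[1]])
  r2 <- classify_gene(m, cfgs[[2]])
  expect_equal(r1, r2)
})

test_that("classify_monotonic matches truth on clearly planted genes", {
  # low biological noise and a modest per-step effect: orderings are
  # near-deterministic while the monotone genes stay a small share of
  # the library (so RPKM composition drift does not trend flat genes)
  cfg <- sim_config(n_genes = 400,
                    archetype_fractions = c(flat = 0.9, monotone_up = 0.05,
                                            monotone_down = 0.05, late_step = 0,
                                            early_step = 0, parabolic = 0),
                    effect_size = 0.5, dispersion_params = c(0.005, 0.5),
                    baseline_meanlog = log(500), baseline_sdlog = 0.5,
                    seed = 55)
  d <- generate_dataset(cfg)
  rpkm <- compute_rpkm(filter_expressed(d$counts))
  res <- classify_monotonic(rpkm, "A", monotony_config(seed = 56))
  tr <- d$truth[d$truth$cell_line == "A", ]
  tr <- tr[match(res$gene_id, tr$gene_id), ]
  sens <- mean(res$class[tr$monotone_class != "nonuniform"] ==
                 tr$monotone_class[tr$monotone_class != "nonuniform"])
  fpr <- mean(res$class[tr$monotone_class == "nonuniform"] != "nonuniform")
  expect_gt(sens, 0.8)
  expect_lte(fpr, 0.05)
  # classification rule is consistent with (ci, pi)
  expect_true(all((res$class == "up") == (res$ci > 0 & res$pi < 0.05)))
})

test_that("c(i) and class are Monte-Carlo stable as resamples grow", {
  d <- generate_dataset(sim_config(n_genes = 150, seed = 57))
  rpkm <- compute_rpkm(filter_expressed(d$counts))
  a <- classify_monotonic(rpkm, "A", monotony_config(n_resamples = 100, seed = 58))
  b <- classify_monotonic(rpkm, "A", monotony_config(n_resamples = 400, seed = 59))
  # per-path rho has SD at most 1/sqrt(4) = 0.5 (null rank correlation),
  # so independent 100- and 400-draw means differ by < 0.15 (2.7 SE)
  # for ~99% of genes
  expect_gte(mean(abs(a$ci - b$ci) < 0.15), 0.99)
  expect_gte(mean(a$class == b$class), 0.95)
})

test_that("cross-line Venn accounting is a disjoint partition", {
  mk <- function(classes) data.frame(gene_id = paste0("g", seq_along(classes)),
                                     ci = 0, pi = 1, class = classes)
  r1 <- mk(c("up", "up", "down", "down", "up", "nonuniform", "nonuniform",
             "down", "up", "nonuniform"))
  r2 <- mk(c("up", "down", "down", "up", "nonuniform", "up", "nonuniform",
             "down", "up", "nonuniform"))
  v <- compare_lines(r1, r2)
  expect_equal(sort(v$common_up), c("g1", "g9"))
  expect_equal(sort(v$common_down), c("g3", "g8"))
  expect_equal(sort(v$opposite), c("g2", "g4"))
  expect_equal(sum(v$counts), 10)
  expect_length(intersect(v$common_up, v$rest), 0)
  # identical results -> no opposite genes
  same <- compare_lines(r1, r1)
  expect_length(same$opposite, 0)
  expect_error(compare_lines(r1, mk(c("up"))), "universes differ")
})
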