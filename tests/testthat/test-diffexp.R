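test_that("size factors follow the median-of-ratios oracle", {
  m <- rbind(g1 = c(4, 8, 2), g2 = c(10, 22, 5), g3 = c(6, 11, 3),
             g4 = c(100, 180, 60), g5 = c(1, 3, 1))
  sf <- estimate_size_factors(m)
  for (j in 1:3) {
    gm <- apply(m, 1, function(r) exp(mean(log(r))))
    expect_equal(unname(sf[j]), median(m[, j] / gm), tolerance = 1e-12)
  }
  # identical columns -> equal factors; doubled column -> doubled factor
  eq <- cbind(a = c(3, 9), b = c(3, 9))
  rownames(eq) <- c("g1", "g2")
  expect_equal(diff(unname(estimate_size_factors(eq))), 0)
  dbl <- cbind(a = c(3, 9), b = c(6, 18))
  rownames(dbl) <- c("g1", "g2")
  sf2 <- estimate_size_factors(dbl)
  expect_equal(unname(sf2["b"] / sf2["a"]), 2)
  allz <- rbind(g1 = c(0, 1), g2 = c(1, 0))
  expect_error(estimate_size_factors(allz), "all-positive")
})

test_that("dispersion estimation recovers planted alpha and handles edge cases", {
  set.seed(31)
  G <- 2000
  mu <- rlnorm(G, log(100), 1)
  mk <- function(gen) {
    m <- sapply(1:6, function(j) gen())
    dimnames(m) <- list(sprintf("g%04d", 1:G), sprintf("s%d", 1:6))
    m
  }
  grp <- rep(c("a", "b"), each = 3)
  nb <- mk(function() rnbinom(G, mu = mu, size = 1 / 0.2))
  d <- estimate_dispersion(nb, estimate_size_factors(nb), grp, "common")
  expect_gte(d$alpha, 0.15); expect_lte(d$alpha, 0.25)
  pois <- mk(function() rpois(G, mu))
  dp <- estimate_dispersion(pois, estimate_size_factors(pois), grp, "common")
  expect_lte(dp$alpha, 0.02)
  # var == mu exactly gives zero MoM: counts (x, x+2) per group have
  # var 2, mean arranged to 2 by construction
  ex <- rbind(g1 = c(1, 3, 1, 3), g2 = c(1, 3, 1, 3))
  colnames(ex) <- paste0("s", 1:4)
  de <- estimate_dispersion(ex, rep(1, 4), rep(c("a", "b"), each = 2))
  expect_equal(unname(de$mom), c(0, 0))
  expect_error(estimate_dispersion(nb, estimate_size_factors(nb),
                                   c("a", rep("b", 5))), "2 replicates")
})

test_that("trended dispersions are never below the per-gene moment estimate", {
  set.seed(33)
  G <- 500
  mu <- rlnorm(G, log(50), 1)
  m <- sapply(1:6, function(j) rnbinom(G, mu = mu, size = 1 / (0.05 + 2 / mu)))
  dimnames(m) <- list(sprintf("g%03d", 1:G), sprintf("s%d", 1:6))
  sf <- estimate_size_factors(m)
  dt <- estimate_dispersion(m, sf, rep(c("a", "b"), each = 3), "trended")
  expect_true(all(dt$alpha_gene >= dt$mom - 1e-12))
  expect_true(all(dt$alpha_gene >= 0))
  expect_length(dt$coef, 2)
})

test_that("exact NB test equals the full-enumeration oracle", {
  # frozen example: (3,4,5) vs (9,11,10), alpha = 0.1, equal size factors
  p <- exact_nb_test(c(3, 4, 5), c(9, 11, 10), rep(1, 3), rep(1, 3), 0.1)
  expect_equal(p$p, nb_oracle_p(c(3, 4, 5), c(9, 11, 10), 0.1),
               tolerance = 1e-12)
  # balanced groups with identical sums sit at the conditional mode
  expect_equal(exact_nb_test(c(3, 4, 5), c(5, 4, 3),
                             rep(1, 3), rep(1, 3), 0.1)$p, 1)
  # zero total is untestable
  z <- exact_nb_test(c(0, 0), c(0, 0), rep(1, 2), rep(1, 2), 0.1)
  expect_true(z$untestable)
  expect_equal(z$p, 1)
})

test_that("exact test is symmetric for equal-size groups and respects size factors", {
  a <- c(7, 2, 5); b <- c(12, 9, 15)
  p1 <- exact_nb_test(a, b, rep(1, 3), rep(1, 3), 0.2)$p
  p2 <- exact_nb_test(b, a, rep(1, 3), rep(1, 3), 0.2)$p
  expect_equal(p1, p2, tolerance = 1e-12)
  # uniform rescaling of all size factors changes nothing
  p3 <- exact_nb_test(a, b, rep(3, 3), rep(3, 3), 0.2)$p
  expect_equal(p3, p1, tolerance = 1e-12)
  # unequal depths: counts are matched to the geometric-mean common
  # scale and rounded before conditioning
  p4 <- exact_nb_test(a, b * 2, rep(1, 3), rep(2, 3), 0.2)$p
  expect_equal(p4, nb_oracle_p(round(a * sqrt(2)), round(b * sqrt(2)), 0.2),
               tolerance = 1e-12)
})

test_that("large totals use the truncated window without losing accuracy", {
  a <- c(2100, 1900, 2050); b <- c(2500, 2600, 2450)   # T > 5000
  p <- exact_nb_test(a, b, rep(1, 3), rep(1, 3), 0.05)$p
  expect_equal(p, nb_oracle_p(a, b, 0.05), tolerance = 1e-8)
})

test_that("bh_adjust equals the step-up definition and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("consensus DEG flags apply both-flavor and strict-inequality rules", {
  f <- call_deg(fdr_common = c(0.04, 0.005, 0.001, 0.04),
                fdr_trended = c(0.2, 0.008, 0.002, 0.04),
                log2fc = c(3, 1.0, -1.5, 0.2))
  expect_equal(f$deg_standard, c(FALSE, TRUE, TRUE, TRUE))
  # |log2FC| = 1 exactly fails the strict '>' cutoff
  expect_equal(f$deg_strict, c(FALSE, FALSE, TRUE, FALSE))
  # strict implies standard
  expect_true(all(!f$deg_strict | f$deg_standard))
})

test_that("run_comparison output satisfies its structural invariants", {
  d <- generate_dataset(sim_config(n_genes = 300, seed = 43, effect_size = 1))
  cmf <- filter_expressed(d$counts)
  sm <- cmf$sample_meta
  r <- run_comparison(cmf, sm$sample_id[sm$cell_line == "A" & sm$pd == 32],
                      sm$sample_id[sm$cell_line == "A" & sm$pd == 72])
  expect_true(all(r$p_common >= 0 & r$p_common <= 1))
  expect_true(all(r$fdr_common >= r$p_common - 1e-12))
  expect_true(all(r$fdr_trended >= r$p_trended - 1e-12))
  expect_true(all(!r$deg_strict | r$deg_standard))
  # log2FC antisymmetric under group swap
  r2 <- run_comparison(cmf, sm$sample_id[sm$cell_line == "A" & sm$pd == 72],
                       sm$sample_id[sm$cell_line == "A" & sm$pd == 32])
  expect_equal(r2$log2fc, -r$log2fc, tolerance = 1e-12)
  # planted first-vs-last regulation is recovered
  tr <- d$truth[d$truth$cell_line == "A", ]
  tr <- tr[match(r$gene_id, tr$gene_id), ]
  sens <- mean(r$deg_standard[tr$deg_15 & abs(tr$mu_pd5 - tr$mu_pd1) > 20])
  expect_gt(sens, 0.6)
})

test_that("comparison plan lists 4 consecutive pairs plus first-vs-last per line", {
  d <- generate_dataset(sim_config(n_genes = 20, seed = 2))
  plan <- comparison_plan(d$counts$sample_meta)
  expect_equal(nrow(plan), 10)
  expect_true(all(plan$pd_from < plan$pd_to))
  a <- plan[plan$cell_line == "A", ]
  expect_equal(a$pd_from, c(32, 42, 52, 62, 32))
  expect_equal(a$pd_to, c(42, 52, 62, 72, 72))
})
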