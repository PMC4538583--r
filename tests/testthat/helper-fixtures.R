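# shared fixtures and independent oracles (kept deliberately naive:
# plain loops and textbook formulas, no reuse of package internals)

toy_count_matrix <- function(counts, pds = NULL, lines = NULL,
                             lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  n <- ncol(counts)
  if (is.null(pds)) pds <- rep(1, n)
  if (is.null(lines)) lines <- rep("A", n)
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  sm <- data.frame(sample_id = colnames(counts), cell_line = lines,
                   pd = pds, replicate = seq_len(n))
  count_matrix(counts, sm, lengths)
}

# full-enumeration oracle for the conditional NB exact test (unit size
# factors), written directly from the conditioning definition
nb_oracle_p <- function(ka, kb, alpha) {
  KA <- sum(ka); KB <- sum(kb); T <- KA + KB
  if (T == 0) return(1)
  mA <- length(ka); mB <- length(kb)
  mu <- T / (mA + mB)
  pr <- numeric(T + 1)
  for (a in 0:T) {
    pr[a + 1] <- if (alpha <= 0)
      dpois(a, mA * mu) * dpois(T - a, mB * mu)
    else
      dnbinom(a, mu = mA * mu, size = mA / alpha) *
        dnbinom(T - a, mu = mB * mu, size = mB / alpha)
  }
  pobs <- pr[KA + 1]
  sum(pr[pr <= pobs * (1 + 1e-12)]) / sum(pr)
}

# conditional binomial (Poisson-limit) exact test
binom_oracle_p <- function(ka, kb) {
  KA <- sum(ka); T <- KA + sum(kb)
  if (T == 0) return(1)
  mA <- length(ka); mB <- length(kb)
  pr <- dbinom(0:T, T, mA / (mA + mB))
  pobs <- pr[KA + 1]
  sum(pr[pr <= pobs * (1 + 1e-12)])
}

# brute-force BH step-up definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(o == i)                 # rank of p[i]
    adj[i] <- min(1, min(p[o][r:n] * n / (r:n)))
  }
  adj
}

# exact Spearman permutation p by literal enumeration over permutations
spearman_perm_oracle <- function(x, y = seq_along(x)) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  null <- vapply(perms(seq_len(n)), function(p) cor(rx[p], ry), 0)
  list(rho = rho, p = mean(abs(null) >= abs(rho) - 1e-12))
}

# five well-separated 10-point temporal shapes (two concatenated lines)
planted_profile_shapes <- function() {
  shapes <- rbind(0:4, 4:0, c(0, 4, 4, 4, 4), c(0, 0, 0, 0, 4),
                  c(0, 2, 4, 2, 0))
  t(apply(cbind(shapes, shapes), 1, function(v) (v - mean(v)) / sd(v)))
}

planted_profiles <- function(n, noise_sd = 0.15, seed = 1) {
  set.seed(seed)
  z <- planted_profile_shapes()
  truth <- sample(1:5, n, replace = TRUE)
  list(X = z[truth, ] + matrix(rnorm(n * 10, 0, noise_sd), n, 10),
       truth = truth)
}

# adjusted Rand index (chance-corrected partition agreement)
ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(sum(tab), 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
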