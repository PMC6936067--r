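# Shared fixtures and independent oracles, all generated in code.

# LD-block dataset with two regions (columns 1:k1 and k1 + 1:k2).
make_block_dataset <- function(n = 400, k1 = 3, k2 = 3, rho = 0.7,
                               maf = 0.35, seed = 1) {
  spec <- haplotype_block_spec(rep(maf, k1 + k2), block_sizes = c(k1, k2),
                               rho = rho)
  simulate_genotypes(spec, n, seed = seed)
}

# Dataset of independent SNPs (no LD), codes drawn as Binomial(2, maf).
make_indep_dataset <- function(n = 200, k = 4, maf = 0.3, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(n * k, 2, maf), n, k)
  ph <- rbinom(n, 1, 0.5)
  while (sum(ph) < 2 || n - sum(ph) < 2) ph <- rbinom(n, 1, 0.5)
  genotype_dataset(g, ph, orient = FALSE)
}

# Exact moment products (delta4, delta2, sigma2, tau2) of a quadruple
# (X, Y, U, V) defined as a function of three independent Bernoulli
# latents, by enumeration of the 8 latent combinations. Independent
# oracle for the covariance-of-sample-covariances formula.
exact_latent_moments <- function(fun, probs, n) {
  grid <- expand.grid(z1 = 0:1, z2 = 0:1, z3 = 0:1)
  w <- apply(grid, 1, function(z) prod(ifelse(z == 1, probs, 1 - probs)))
  vals <- t(apply(grid, 1, fun)) # 8 x 4: support points of (X, Y, U, V)
  mu <- colSums(vals * w)
  cv <- function(i, j) sum(w * (vals[, i] - mu[i]) * (vals[, j] - mu[j]))
  d4 <- sum(w * (vals[, 1] - mu[1]) * (vals[, 2] - mu[2]) *
              (vals[, 3] - mu[3]) * (vals[, 4] - mu[4]))
  list(delta4 = d4, delta2 = cv(1, 2) * cv(3, 4),
       sigma2 = cv(1, 3) * cv(2, 4), tau2 = cv(1, 4) * cv(2, 3), n = n)
}

# Monte-Carlo covariance of two sample covariances, vectorized over R
# replicates of size n; returns the estimate and its standard error.
mc_cov_sample_cov <- function(draw, R, n, seed) {
  set.seed(seed)
  M <- draw(R, n) # list of R x n matrices X, Y, U, V
  sc <- function(A, B) (rowSums(A * B) - n * rowMeans(A) * rowMeans(B)) / (n - 1)
  a <- sc(M$X, M$Y)
  b <- sc(M$U, M$V)
  list(est = stats::cov(a, b),
       se = stats::sd((a - mean(a)) * (b - mean(b))) / sqrt(R))
}

# Per-replicate vector of pair statistics under a fresh Bernoulli(0.5)
# phenotype on fixed genotypes (null resampling used by several oracles).
null_pair_t <- function(dataset, r1, r2, n_reps, seed) {
  n <- nrow(dataset$genotypes)
  out <- matrix(NA_real_, n_reps, length(r1) * length(r2))
  set.seed(seed)
  d <- dataset
  for (b in seq_len(n_reps)) {
    ph <- rbinom(n, 1, 0.5)
    while (sum(ph) < 2 || n - sum(ph) < 2) ph <- rbinom(n, 1, 0.5)
    d$phenotype <- ph
    out[b, ] <- regionepi:::.region_core(d, r1, r2)$t
  }
  out
}
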