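test_that("central product moment matches its definition on simple inputs", {
  x <- rep(c(1, -1), 10) # symmetric two-point mass, already centered
  expect_equal(central_product_moment(x, x, x, x), 1)
  expect_equal(central_product_moment(x, x, x, rep(3, 20)), 0)
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30); u <- rnorm(30); v <- rnorm(30)
  expect_equal(central_product_moment(a, b, u, v),
               mean((a - mean(a)) * (b - mean(b)) * (u - mean(u)) * (v - mean(v))))
  expect_error(central_product_moment(a, b, u, v[-1]), "equal length")
})

test_that("large-sample product moment approaches cov(x,y)*cov(u,v)", {
  set.seed(3)
  n <- 1e5
  x <- rbinom(n, 2, 0.3); y <- rbinom(n, 2, 0.4) # independent => target 0
  u <- rbinom(n, 2, 0.3); v <- rbinom(n, 2, 0.2)
  expect_lt(abs(central_product_moment(x, y, u, v)), 0.01)
})

test_that("Gaussian closed form: variance of a sample covariance", {
  # For bivariate normal (X,Y)=(U,V): delta4 = sx2*sy2 + 2*sxy^2, and the
  # general formula collapses to (sx2*sy2 + sxy^2)/(n-1).
  cases <- list(c(1, 1, 0.5, 10), c(1.3, 0.7, 0.4, 37), c(2, 5, -1.2, 1000))
  for (cs in cases) {
    sx2 <- cs[1]; sy2 <- cs[2]; sxy <- cs[3]; n <- cs[4]
    got <- cov_sample_cov(list(delta4 = sx2 * sy2 + 2 * sxy^2,
                               delta2 = sxy^2, sigma2 = sx2 * sy2,
                               tau2 = sxy^2, n = n))
    expect_equal(got, (sx2 * sy2 + sxy^2) / (n - 1), tolerance = 1e-12)
  }
})

test_that("independent pairs have zero covariance of sample covariances", {
  got <- cov_sample_cov(list(delta4 = 0.3, delta2 = 0.3, sigma2 = 0,
                             tau2 = 0, n = 50))
  expect_equal(got, 0)
})

test_that("formula matches brute-force Monte-Carlo over distinct distributions", {
  # 2e4 replicates here; the full-scale check runs in the acceptance suite.
  R <- 2e4; n <- 50
  p <- c(0.3, 0.4, 0.2)
  fun_plain <- function(z) c(z[1] + z[2], z[2] + z[3], z[1] + z[3], z[3])
  fun_shared <- function(z) c(z[1] + z[2], z[2] + z[3], z[1] + z[2], z[3])
  draw_plain <- function(R, n) {
    Z1 <- matrix(rbinom(R * n, 1, p[1]), R)
    Z2 <- matrix(rbinom(R * n, 1, p[2]), R)
    Z3 <- matrix(rbinom(R * n, 1, p[3]), R)
    list(X = Z1 + Z2, Y = Z2 + Z3, U = Z1 + Z3, V = Z3)
  }
  draw_shared <- function(R, n) { m <- draw_plain(R, n); m$U <- m$X; m }
  for (case in list(list(f = fun_plain, d = draw_plain, seed = 1),
                    list(f = fun_shared, d = draw_shared, seed = 2))) {
    mom <- exact_latent_moments(case$f, p, n)
    mc <- mc_cov_sample_cov(case$d, R, n, seed = case$seed)
    expect_lt(abs(mc$est - cov_sample_cov(mom)), 3 * mc$se)
  }
})

test_that("delta_ld_cov with itself equals the LD-contrast denominator", {
  d <- make_block_dataset(n = 150, seed = 41)
  res <- ld_contrast_test(d, 2, 5)
  expect_equal(delta_ld_cov(d, c(2, 5), c(2, 5)), res$var_delta)
})

test_that("case/control decomposition is additive for identical groups", {
  set.seed(7)
  half <- matrix(rbinom(60 * 4, 2, 0.35), 60, 4)
  d <- genotype_dataset(rbind(half, half),
                        phenotype = rep(c(1, 0), each = 60), orient = FALSE)
  one_group <- cov_sample_cov(moment_set(half[, 1], half[, 3],
                                         half[, 2], half[, 4]))
  expect_equal(delta_ld_cov(d, c(1, 3), c(2, 4)), 2 * one_group)
})

test_that("pair correlations: identity, argument symmetry, rescaling invariance", {
  d <- make_block_dataset(n = 200, seed = 43)
  expect_equal(pair_corr(d, c(1, 4), c(1, 4)), 1)
  expect_equal(pair_corr(d, c(1, 4), c(4, 1)), 1) # cov symmetric in arguments
  r12 <- pair_corr(d, c(1, 4), c(2, 5))
  d2 <- d; d2$genotypes[, 4] <- 0.5 * d2$genotypes[, 4]
  expect_equal(pair_corr(d2, c(1, 4), c(2, 5)), r12)
})

test_that("flipping one SNP negates exactly the entries of pairs containing it", {
  d <- make_block_dataset(n = 200, seed = 47)
  s1 <- build_sigma(d, 1:2, 4:5)$sigma
  d$genotypes[, 1] <- 2 - d$genotypes[, 1]
  s2 <- build_sigma(d, 1:2, 4:5)$sigma
  has1 <- c(TRUE, TRUE, FALSE, FALSE) # row-major pairs: (1,4) (1,5) (2,4) (2,5)
  sign_flip <- outer(has1, has1, function(a, b) ifelse(xor(a, b), -1, 1))
  expect_equal(s2, s1 * sign_flip)
})

test_that("sigma is a valid correlation matrix on random datasets", {
  for (seed in c(3, 19, 71)) {
    d <- make_block_dataset(n = 120, k1 = 3, k2 = 4, rho = 0.8, seed = seed)
    sg <- build_sigma(d, 1:3, 4:7)
    s <- sg$sigma
    expect_equal(s, t(s))
    expect_equal(diag(s), rep(1, 12), ignore_attr = TRUE)
    expect_true(all(s >= -1 & s <= 1))
    expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("sigma entries agree with the scalar pair_corr path", {
  d <- make_block_dataset(n = 100, seed = 53)
  for (bc in c(FALSE, TRUE)) {
    sg <- build_sigma(d, 1:3, 4:6, bias_correct_delta4 = bc)
    idx <- sg$pair_index
    for (i in c(1, 5, 9)) for (j in c(2, 6)) {
      expect_equal(sg$sigma[i, j],
                   pair_corr(d, c(idx$snp_x[i], idx$snp_y[i]),
                             c(idx$snp_x[j], idx$snp_y[j]),
                             bias_correct_delta4 = bc),
                   tolerance = 1e-12)
    }
  }
})

test_that("duplicated SNP in a region yields identical rows and stays valid", {
  d <- make_block_dataset(n = 150, seed = 59)
  sg <- build_sigma(d, 1:2, c(4, 4))
  s <- sg$sigma # pairs (1,4) (1,4) (2,4) (2,4)
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, ], s[2, ], ignore_attr = TRUE)
  expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("degenerate SNPs are excluded; empty regions error", {
  d <- make_block_dataset(n = 100, seed = 61)
  d$genotypes[, 2] <- 1 # monomorphic everywhere
  expect_message(sg <- build_sigma(d, 1:3, 4:6), "monomorphic")
  expect_equal(sg$region1_snps, c(1L, 3L))
  expect_equal(nrow(sg$sigma), 6)
  d$genotypes[, 4:6] <- 1
  expect_error(suppressMessages(build_sigma(d, 1:3, 4:6)), "degenerate")
})
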