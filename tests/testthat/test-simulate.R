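test_that("haplotype chain produces the requested LD level", {
  spec0 <- haplotype_block_spec(rep(0.3, 5), rho = 0)
  d0 <- simulate_genotypes(spec0, 1e4, seed = 2)
  adj0 <- sapply(1:4, function(j) cor(d0$genotypes[, j], d0$genotypes[, j + 1]))
  expect_lt(max(abs(adj0)), 0.05)

  spec9 <- haplotype_block_spec(rep(0.3, 5), rho = 0.9)
  d9 <- simulate_genotypes(spec9, 1e4, seed = 2)
  adj9 <- sapply(1:4, function(j) cor(d9$genotypes[, j], d9$genotypes[, j + 1]))
  expect_gt(mean(abs(adj9)), 0.5)

  # block boundaries break the correlation
  specb <- haplotype_block_spec(rep(0.3, 4), block_sizes = c(2, 2), rho = 0.9)
  db <- simulate_genotypes(specb, 1e4, seed = 3)
  expect_lt(abs(cor(db$genotypes[, 2], db$genotypes[, 3])), 0.05)
})

test_that("empirical MAFs track the generator settings", {
  maf <- c(0.1, 0.25, 0.4, 0.5)
  spec <- haplotype_block_spec(maf, rho = 0.6)
  d <- simulate_genotypes(spec, 1e4, seed = 7)
  emp <- colMeans(d$genotypes) / 2
  se <- sqrt(maf * (1 - maf) / (2 * 1e4))
  # the maf-0.5 SNP may be re-oriented; compare folded frequencies
  expect_true(all(abs(pmin(emp, 1 - emp) - maf) < 3 * se + 1e-12))
})

test_that("relative risks follow the multiplicative per-allele model", {
  m <- disease_model_spec(0.1, c(1, 2), rr_base = 2, rr_increment = sqrt(2))
  expect_equal(genotype_relative_risk(1, 1, m), 2)
  expect_equal(genotype_relative_risk(1, 2, m), 2 * sqrt(2))
  expect_equal(genotype_relative_risk(2, 1, m), 2 * sqrt(2))
  expect_equal(genotype_relative_risk(2, 2, m), 4)
  expect_equal(genotype_relative_risk(0, 2, m), 1)
  expect_equal(genotype_relative_risk(0, 0, m), 1)
  expect_error(genotype_relative_risk(3, 1, m), "codes")
})

test_that("population disease frequency recovers the prevalence", {
  spec <- haplotype_block_spec(rep(0.3, 4), block_sizes = c(2, 2), rho = 0.5)
  model <- disease_model_spec(0.1, c(1, 3))
  f0 <- solve_baseline(spec, model, pool_size = 2e4, seed = 1)
  set.seed(11)
  g <- regionepi:::.draw_genotypes(spec, 1e5)
  pen <- f0 * genotype_relative_risk(g[, 1], g[, 3], model)
  dis <- rbinom(1e5, 1, pen)
  expect_lt(abs(mean(dis) - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5) + 0.005)
})

test_that("an unreachable prevalence is an infeasible model", {
  spec <- haplotype_block_spec(rep(0.3, 2), rho = 0)
  model <- disease_model_spec(0.9, c(1, 2), rr_base = 50)
  expect_error(solve_baseline(spec, model, seed = 1), "infeasible")
})

test_that("cases are enriched for the interacting risk genotypes", {
  spec <- haplotype_block_spec(rep(0.3, 4), block_sizes = c(2, 2), rho = 0.5)
  model <- disease_model_spec(0.1, c(1, 3), rr_base = 4)
  d <- simulate_case_control(spec, model, 2500, 2500, seed = 13)
  risk <- d$genotypes[, 1] >= 1 & d$genotypes[, 3] >= 1
  expect_gt(mean(risk[d$phenotype == 1]), mean(risk[d$phenotype == 0]))
  # reproducible under the seed
  d2 <- simulate_case_control(spec, model, 2500, 2500, seed = 13)
  expect_identical(d$genotypes, d2$genotypes)
})

test_that("a flat relative-risk model embeds the null: power near alpha", {
  spec <- haplotype_block_spec(rep(0.3, 4), block_sizes = c(2, 2), rho = 0.5)
  null_model <- disease_model_spec(0.1, c(1, 3), rr_base = 1, rr_increment = 1)
  ex <- run_power_experiment(spec, null_model, 1:2, 3:4,
                             sample_sizes = 300, n_reps = 150,
                             alpha = 0.05, seed = 17)
  pw <- ex$power$power[ex$power$method == "region"]
  expect_lt(abs(pw - 0.05), 3 * sqrt(0.05 * 0.95 / 150) + 0.02)
})

test_that("type-I experiment returns calibrated rates on a small design", {
  d <- make_block_dataset(n = 300, k1 = 2, k2 = 2, seed = 19)
  ex <- run_type1_experiment(d, 1:2, 3:4, n_reps = 200,
                             alphas = c(0.05, 1), seed = 21)
  expect_equal(ex$rates$rate[ex$rates$alpha == 1], 1)
  r05 <- ex$rates$rate[ex$rates$alpha == 0.05]
  expect_lt(abs(r05 - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.02)
})
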