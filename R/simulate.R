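#' Haplotype-block specification for the genotype generator
#'
#' Describes the LD structure to simulate: SNPs are grouped into blocks;
#' within a block adjacent haplotype alleles follow a first-order
#' correlated-Bernoulli chain with correlation `rho`, and blocks are
#' independent. Genotypes are the sum of two independently drawn
#' haplotypes, so adjacent-genotype correlation also approaches `rho`.
#'
#' @param maf per-SNP minor-allele frequencies in (0, 0.5].
#' @param block_sizes integer block lengths summing to `length(maf)`
#'   (default: one block holding all SNPs).
#' @param rho within-block adjacent-haplotype correlation in \[0, 1).
#' @return object of class `haplotype_block_spec`.
#' @export
haplotype_block_spec <- function(maf, block_sizes = length(maf), rho = 0.7) {
  maf <- as.numeric(maf)
  if (any(maf <= 0 | maf > 0.5)) stop("minor-allele frequencies must lie in (0, 0.5]")
  if (sum(block_sizes) != length(maf)) stop("block sizes must sum to the number of SNPs")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  structure(list(maf = maf, block_sizes = as.integer(block_sizes), rho = rho),
            class = "haplotype_block_spec")
}

# Draw n_hap haplotypes (rows) for one spec; first-order chain per block:
# P(A_j = 1 | A_{j-1}) = p_j + rho * sqrt(p_j q_j / (p_{j-1} q_{j-1})) *
# (A_{j-1} - p_{j-1}), clamped to [0, 1]. Gives corr(A_{j-1}, A_j) = rho
# exactly when the conditional probabilities stay inside [0, 1].
.draw_haplotypes <- function(spec, n_hap) {
  k <- length(spec$maf)
  H <- matrix(0L, n_hap, k)
  j0 <- 1L
  for (bs in spec$block_sizes) {
    cols <- j0:(j0 + bs - 1L)
    p <- spec$maf[cols]
    H[, cols[1]] <- stats::rbinom(n_hap, 1L, p[1])
    if (bs > 1) for (b in 2:bs) {
      j_prev <- cols[b - 1L]; pj <- p[b]; pp <- p[b - 1L]
      cond <- pj + spec$rho * sqrt(pj * (1 - pj) / (pp * (1 - pp))) *
        (H[, j_prev] - pp)
      cond <- pmin(1, pmax(0, cond))
      H[, cols[b]] <- stats::rbinom(n_hap, 1L, cond)
    }
    j0 <- j0 + bs
  }
  H
}

# Genotype matrix (n x k) from the haplotype model.
.draw_genotypes <- function(spec, n) {
  .draw_haplotypes(spec, n) + .draw_haplotypes(spec, n)
}

#' Simulate LD-structured genotypes with a null phenotype
#'
#' Draws `n_samples` genotypes from the haplotype-block model of `spec`
#' and attaches a Bernoulli(0.5) case/control phenotype (the null
#' phenotype used for type-I-error experiments; redraw or replace it as
#' needed). SNP positions are spaced 1 kbp apart on chromosome "1".
#'
#' @param spec a [haplotype_block_spec()].
#' @param n_samples number of individuals.
#' @param seed RNG seed.
#' @return a [genotype_dataset()].
#' @export
simulate_genotypes <- function(spec, n_samples, seed = 1L) {
  .with_seed(seed, function() {
    g <- .draw_genotypes(spec, n_samples)
    ph <- stats::rbinom(n_samples, 1L, 0.5)
    # guarantee both groups are usable
    while (sum(ph) < 2 || sum(1 - ph) < 2) ph <- stats::rbinom(n_samples, 1L, 0.5)
    k <- ncol(g)
    snps <- data.frame(id = sprintf("snp%d", seq_len(k)), chrom = "1",
                       pos = 1000L * seq_len(k), major = "B", minor = "b",
                       stringsAsFactors = FALSE)
    genotype_dataset(g, ph, snps = snps)
  })
}

#' Epistatic relative-risk disease model
#'
#' Penetrance is `f0 * RR(g1, g2)` where `f0` is a baseline solved from
#' the population prevalence and `RR` is 1 unless both causal genotypes
#' carry at least one disease allele; then
#' `RR = rr_base * rr_increment^((g1 - 1) + (g2 - 1))`. With the defaults
#' (`rr_base = 2`, `rr_increment = sqrt(2)`) the genotype combinations
#' 1/1, 1/2, 2/1, 2/2 have relative risks 2, 2*sqrt(2), 2*sqrt(2), 4 —
#' each additional disease allele multiplies the risk by sqrt(2).
#'
#' @param prevalence population disease probability in (0, 1).
#' @param causal_pair length-2 integer: SNP columns of the interacting pair.
#' @param rr_base relative risk of the 1/1 combination (default 2).
#' @param rr_increment multiplier per additional disease allele
#'   (default `sqrt(2)`).
#' @return object of class `disease_model_spec`.
#' @export
disease_model_spec <- function(prevalence, causal_pair, rr_base = 2,
                               rr_increment = sqrt(2)) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  if (length(causal_pair) != 2) stop("causal_pair must name two SNP columns")
  if (rr_base <= 0 || rr_increment <= 0) stop("relative risks must be positive")
  structure(list(prevalence = prevalence, causal_pair = as.integer(causal_pair),
                 rr_base = rr_base, rr_increment = rr_increment),
            class = "disease_model_spec")
}

#' Relative risk of a causal genotype combination
#'
#' @param g1,g2 genotype codes in \{0, 1, 2\} at the two causal SNPs
#'   (vectorized).
#' @param model a [disease_model_spec()].
#' @return the relative risk: 1 when either code is 0, otherwise
#'   `rr_base * rr_increment^((g1 - 1) + (g2 - 1))`.
#' @examples
#' m <- disease_model_spec(0.1, c(1, 2))
#' genotype_relative_risk(1, 1, m) # 2
#' genotype_relative_risk(2, 2, m) # 4
#' @export
genotype_relative_risk <- function(g1, g2, model) {
  if (any(!(g1 %in% 0:2)) || any(!(g2 %in% 0:2))) {
    stop("genotype codes must be 0, 1, or 2")
  }
  ifelse(g1 == 0 | g2 == 0, 1,
         model$rr_base * model$rr_increment^((g1 - 1) + (g2 - 1)))
}

#' Baseline penetrance from prevalence
#'
#' Solves `prevalence = E[f0 * RR(g1, g2)]` for the baseline penetrance
#' `f0` by bisection on (0, 1/max(RR)], with the causal genotype
#' distribution estimated from a simulated pool. Errors when the
#' prevalence is unreachable with all penetrances at or below 1.
#'
#' @param spec a [haplotype_block_spec()].
#' @param model a [disease_model_spec()].
#' @param pool_size genotype pool used to estimate the causal genotype
#'   distribution.
#' @param seed RNG seed for the pool draw.
#' @return the baseline penetrance `f0`.
#' @export
solve_baseline <- function(spec, model, pool_size = 20000L, seed = 1L) {
  .with_seed(seed, function() {
    pool <- .draw_genotypes(spec, pool_size)
    .solve_baseline(model, pool[, model$causal_pair[1]],
                    pool[, model$causal_pair[2]])
  })
}

# Bisection core given the causal genotype pool columns.
.solve_baseline <- function(model, pool_g1, pool_g2, tol = 1e-12) {
  rr <- genotype_relative_risk(pool_g1, pool_g2, model)
  mean_rr <- mean(rr)
  max_rr <- max(rr)
  lo <- 0
  hi <- 1 / max_rr
  if (hi * mean_rr < model$prevalence) {
    stop("infeasible disease model: prevalence ", model$prevalence,
         " unreachable with max penetrance ", hi * max_rr)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mid * mean_rr < model$prevalence) lo <- mid else hi <- mid
  }
  f0 <- (lo + hi) / 2
  if (f0 * max_rr > 1) stop("infeasible disease model: penetrance above 1")
  f0
}

#' Simulate a case-control sample under the epistatic disease model
#'
#' Individuals are drawn from the haplotype-block genotype model; disease
#' status is Bernoulli with penetrance `f0 * RR(g1, g2)` at the causal
#' pair, where the baseline `f0` is solved from the prevalence by
#' bisection against the genotype distribution. Individuals are
#' rejection-sampled into the case and control pools until both quotas
#' are filled.
#'
#' @param spec a [haplotype_block_spec()] covering all simulated SNPs
#'   (causal SNPs included; withhold them from the analysis set afterwards
#'   to emulate untyped causal variants).
#' @param model a [disease_model_spec()]; `causal_pair` indexes columns of
#'   the simulated genotype matrix.
#' @param n_case,n_control group quotas.
#' @param seed RNG seed.
#' @param baseline optional pre-solved baseline penetrance `f0`; computed
#'   from a fresh 20000-genotype pool when `NULL`. Supply it when
#'   simulating many replicates under one model (see [solve_baseline()]).
#' @return a [genotype_dataset()] with `n_case + n_control` samples.
#' @export
simulate_case_control <- function(spec, model, n_case, n_control, seed = 1L,
                                  baseline = NULL) {
  .with_seed(seed, function() {
    f0 <- if (is.null(baseline)) {
      pool <- .draw_genotypes(spec, 20000L)
      .solve_baseline(model, pool[, model$causal_pair[1]],
                      pool[, model$causal_pair[2]])
    } else baseline
    cases <- NULL; controls <- NULL
    need_case <- n_case; need_ctrl <- n_control
    while (need_case > 0 || need_ctrl > 0) {
      # expected case rate is roughly the prevalence; size batches so the
      # case quota usually fills in one or two passes
      batch <- max(1000L, need_ctrl + need_case,
                   as.integer(ceiling(1.2 * need_case / model$prevalence)))
      g <- .draw_genotypes(spec, batch)
      pen <- f0 * genotype_relative_risk(g[, model$causal_pair[1]],
                                         g[, model$causal_pair[2]], model)
      dis <- stats::rbinom(batch, 1L, pen) == 1L
      if (need_case > 0) {
        take <- which(dis)[seq_len(min(need_case, sum(dis)))]
        cases <- rbind(cases, g[take, , drop = FALSE])
        need_case <- n_case - nrow(cases)
      }
      if (need_ctrl > 0) {
        take <- which(!dis)[seq_len(min(need_ctrl, sum(!dis)))]
        controls <- rbind(controls, g[take, , drop = FALSE])
        need_ctrl <- n_control - nrow(controls)
      }
    }
    g <- rbind(cases, controls)
    ph <- c(rep(1L, n_case), rep(0L, n_control))
    k <- ncol(g)
    snps <- data.frame(id = sprintf("snp%d", seq_len(k)), chrom = "1",
                       pos = 1000L * seq_len(k), major = "B", minor = "b",
                       stringsAsFactors = FALSE)
    genotype_dataset(g, ph, snps = snps, orient = FALSE)
  })
}

#' Type-I-error experiment: null phenotypes on fixed genotypes
#'
#' Holds the genotypes fixed (preserving their LD) and, for each
#' replicate, redraws the phenotype as Bernoulli(0.5), runs the
#' region-region test, and tallies rejections at each significance level.
#'
#' @param dataset a [genotype_dataset()] (its phenotype is ignored).
#' @param region1_snps,region2_snps SNP column indices of the two regions.
#' @param n_reps number of null replicates (>= 100).
#' @param alphas significance levels to tally.
#' @param seed RNG seed (replicate b uses seed + b for the integrator).
#' @param abseps,maxpts integrator controls per replicate; the defaults
#'   trade integration precision (~1e-3) for speed, ample for rejection
#'   decisions at the usual levels (adaptive tightening is off here).
#' @return object of class `type1_experiment`: data frame `rates` with
#'   columns `alpha`, `rate`, `se`, `lower`, `upper` (rate +/- 3 binomial
#'   SE), plus `p_values`, `n_reps`, `seed`.
#' @export
run_type1_experiment <- function(dataset, region1_snps, region2_snps,
                                 n_reps = 1000L, alphas = c(0.05, 0.01),
                                 seed = 1L, abseps = 1e-3, maxpts = 25000L) {
  if (n_reps < 100) stop("n_reps must be at least 100")
  n <- nrow(dataset$genotypes)
  pvals <- numeric(n_reps)
  d <- dataset
  for (b in seq_len(n_reps)) {
    ph <- .with_seed(seed + b, function() {
      ph <- stats::rbinom(n, 1L, 0.5)
      while (sum(ph) < 2 || sum(1 - ph) < 2) ph <- stats::rbinom(n, 1L, 0.5)
      ph
    })
    d$phenotype <- ph
    d$n_case <- sum(ph); d$n_control <- n - sum(ph)
    res <- test_region_pair(d, region1_snps, region2_snps, seed = seed + b,
                            abseps = abseps, maxpts = maxpts, adapt = FALSE)
    pvals[b] <- res$p_region
  }
  rates <- do.call(rbind, lapply(alphas, function(a) {
    r <- mean(pvals < a)
    se <- sqrt(a * (1 - a) / n_reps)
    data.frame(alpha = a, rate = r, se = se,
               lower = r - 3 * se, upper = r + 3 * se)
  }))
  structure(list(rates = rates, p_values = pvals, n_reps = n_reps, seed = seed),
            class = "type1_experiment")
}

#' @export
print.type1_experiment <- function(x, ...) {
  cat("Type-I-error experiment:", x$n_reps, "null replicates\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Power experiment under the epistatic relative-risk model
#'
#' For each sample size and replicate, simulates a balanced case-control
#' dataset under `model`, then scores three methods on the analysis SNPs:
#' \describe{
#'   \item{region}{the region-region test p-value,}
#'   \item{pairwise_bonf}{the best cross-region pair p-value Bonferroni
#'     corrected for the k1*k2 pairs tested (the SNP-level LD-contrast
#'     baseline),}
#'   \item{single_pair}{the uncorrected p-value of one pre-chosen pair
#'     (default: the analysis pair closest in column index to the causal
#'     pair).}
#' }
#' Power is the fraction of replicates with p below `alpha`.
#'
#' @param spec a [haplotype_block_spec()] for all simulated SNPs.
#' @param model a [disease_model_spec()].
#' @param region1_snps,region2_snps analysis SNP columns per region
#'   (exclude the causal SNPs to emulate untyped causal variants).
#' @param sample_sizes total sample sizes (split evenly case/control).
#' @param n_reps replicates per sample size.
#' @param alpha rejection threshold applied to every method's p-value
#'   (already corrected for the number of region pairs if relevant).
#' @param single_pair optional length-2 vector of analysis SNP columns for
#'   the single-pair baseline.
#' @param seed RNG seed.
#' @param abseps,maxpts integrator controls (see [run_type1_experiment()]).
#' @return object of class `power_experiment`: data frame `power` with
#'   columns `n`, `method`, `power`, `se`, and the settings.
#' @export
run_power_experiment <- function(spec, model, region1_snps, region2_snps,
                                 sample_sizes = c(1000L, 2000L, 3000L),
                                 n_reps = 200L, alpha = 0.05,
                                 single_pair = NULL, seed = 1L,
                                 abseps = 1e-3, maxpts = 25000L) {
  if (is.null(single_pair)) {
    single_pair <- c(region1_snps[which.min(abs(region1_snps - model$causal_pair[1]))],
                     region2_snps[which.min(abs(region2_snps - model$causal_pair[2]))])
  }
  f0 <- solve_baseline(spec, model, seed = seed)
  rows <- list()
  for (n_tot in sample_sizes) {
    hit <- c(region = 0L, pairwise_bonf = 0L, single_pair = 0L)
    for (b in seq_len(n_reps)) {
      rep_seed <- seed + 10000L * match(n_tot, sample_sizes) + b
      d <- simulate_case_control(spec, model, n_tot %/% 2L,
                                 n_tot - n_tot %/% 2L, seed = rep_seed,
                                 baseline = f0)
      res <- test_region_pair(d, region1_snps, region2_snps, seed = rep_seed,
                              abseps = abseps, maxpts = maxpts, adapt = FALSE)
      if (res$p_region < alpha) hit["region"] <- hit["region"] + 1L
      bonf <- min(1, res$min_pair_p * res$n_pairs)
      if (bonf < alpha) hit["pairwise_bonf"] <- hit["pairwise_bonf"] + 1L
      ps <- res$pair_stats
      sp <- ps[ps$snp_x == single_pair[1] & ps$snp_y == single_pair[2], ]
      if (nrow(sp) == 1 && sp$p < alpha) {
        hit["single_pair"] <- hit["single_pair"] + 1L
      }
    }
    pw <- hit / n_reps
    rows[[length(rows) + 1L]] <- data.frame(
      n = n_tot, method = names(pw), power = as.numeric(pw),
      se = sqrt(pw * (1 - pw) / n_reps), row.names = NULL)
  }
  structure(list(power = do.call(rbind, rows), alpha = alpha,
                 n_reps = n_reps, seed = seed, single_pair = single_pair),
            class = "power_experiment")
}

#' @export
print.power_experiment <- function(x, ...) {
  cat("Power experiment:", x$n_reps, "replicates per sample size, alpha =",
      x$alpha, "\n")
  print(x$power, row.names = FALSE)
  invisible(x)
}
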