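#' Threshold statistic from the minimum pair p-value
#'
#' Maps the smallest pair-level p-value to the absolute-value scale of a
#' standard normal statistic: `T = |qnorm(min(p) / 2)|`. Since pair
#' p-values are two-sided, `T` is the magnitude of the most extreme
#' standardized pair statistic implied by the p-values (a round trip when
#' p = 2 * pnorm(-|t|)). Ties are broken by the lowest index. p-values at
#' or below zero (numerical underflow) are clamped to the smallest positive
#' double with a message.
#'
#' @param pair_pvalues numeric vector of p-values in (0, 1].
#' @return list with `t` (threshold, >= 0) and `argmin` (index of the
#'   minimum).
#' @examples
#' min_p_threshold(c(0.5, 0.05, 1))$t # 1.959964
#' @export
min_p_threshold <- function(pair_pvalues) {
  if (length(pair_pvalues) == 0) stop("empty p-value list")
  if (any(pair_pvalues > 1)) stop("p-values must lie in (0, 1]")
  if (any(pair_pvalues <= 0)) {
    message("p-value underflow clamped at ", .Machine$double.xmin)
    pair_pvalues <- pmax(pair_pvalues, .Machine$double.xmin)
  }
  argmin <- which.min(pair_pvalues)
  list(t = abs(stats::qnorm(pair_pvalues[argmin] / 2)), argmin = argmin)
}

# Evaluate f() with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so region tests do not perturb surrounding simulations.
.with_seed <- function(seed, f) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}

#' Exceedance probability of the maximum |z| under MVN(0, Sigma)
#'
#' Computes `1 - Pr(|z_i| < T for all i)` for `z ~ MVN(0, Sigma)` — the
#' probability that the most extreme of m correlated standard normal
#' statistics exceeds the observed threshold. The rectangle probability is
#' evaluated with the Genz-Bretz randomized quasi-Monte-Carlo integrator
#' (package \pkg{mvtnorm}) under a fixed seed, so identical inputs give
#' bit-identical results. The dimension-1 case uses the closed form
#' `2 * pnorm(-T)`. When the first pass returns p below `1e-3` with an
#' error estimate above 10% of p, the tolerance is tightened adaptively
#' and the integration repeated.
#'
#' @param t_threshold threshold T >= 0.
#' @param sigma a [build_sigma()] result or a plain correlation matrix.
#' @param seed integer seed for the randomized integrator.
#' @param abseps target absolute error of the rectangle probability.
#' @param maxpts maximum integrand evaluations per pass.
#' @param adapt tighten the tolerance adaptively when p < 1e-3 (aiming at
#'   ~10% relative error for small p). Disable for screening runs where
#'   only the comparison against a moderate significance level matters.
#' @return list with `p` and `mc_error` (the integrator's error estimate).
#' @examples
#' mvn_max_prob(1.959964, diag(1))$p # 0.05
#' @export
mvn_max_prob <- function(t_threshold, sigma, seed = 1L,
                         abseps = 1e-4, maxpts = 250000L, adapt = TRUE) {
  if (inherits(sigma, "pair_covariance")) sigma <- sigma$sigma
  sigma <- as.matrix(sigma)
  if (t_threshold < 0) stop("threshold must be non-negative")
  m <- nrow(sigma)
  if (m == 1) {
    return(list(p = 2 * stats::pnorm(-t_threshold), mc_error = 0))
  }
  run <- function(eps, pts) {
    .with_seed(seed, function() {
      mvtnorm::pmvnorm(lower = rep(-t_threshold, m),
                       upper = rep(t_threshold, m),
                       sigma = sigma,
                       algorithm = mvtnorm::GenzBretz(abseps = eps,
                                                      maxpts = pts))
    })
  }
  rect <- run(abseps, maxpts)
  p <- max(0, min(1, 1 - rect[1]))
  err <- attr(rect, "error")
  if (adapt && p < 1e-3 && p > 0 && err > 0.1 * p) {
    rect <- run(max(p / 20, 1e-10), max(maxpts, 2000000L))
    p <- max(0, min(1, 1 - rect[1]))
    err <- attr(rect, "error")
  }
  list(p = p, mc_error = err)
}

#' Bonferroni-corrected family-wise error rates
#'
#' `min(1, p * n_tests)` per p-value. Use [format_cfwer()] when rendering:
#' values whose uncorrected product exceeds 1 are conventionally printed
#' as `">1"`.
#'
#' @param p_values numeric vector of p-values.
#' @param n_tests number of tests in the family (>= length of the list).
#' @return numeric vector of corrected values, capped at 1.
#' @export
bonferroni_cfwer <- function(p_values, n_tests) {
  if (n_tests <= 0) stop("n_tests must be positive")
  if (n_tests < length(p_values)) stop("n_tests smaller than the number of p-values")
  pmin(1, p_values * n_tests)
}

#' Render corrected FWERs, capping at ">1"
#' @param p_values uncorrected p-values.
#' @param n_tests family size.
#' @return character vector; products above 1 become `">1"`.
#' @export
format_cfwer <- function(p_values, n_tests) {
  prod <- p_values * n_tests
  ifelse(prod > 1, ">1", format(pmin(1, prod), digits = 4, trim = TRUE))
}

#' Region-region interaction test
#'
#' Tests whether any cross-region SNP pair shows a case-control difference
#' in composite LD, accounting for the correlation among the pair
#' statistics. All k1*k2 pair statistics are computed, their correlation
#' matrix Sigma is built analytically ([build_sigma()]), the minimum pair
#' p-value is mapped to the threshold T ([min_p_threshold()]), and the
#' region-level p-value is the probability that the maximum of
#' MVN(0, Sigma) magnitudes exceeds T ([mvn_max_prob()]).
#'
#' @param dataset an imputed [genotype_dataset()].
#' @param region1_snps,region2_snps SNP column indices of the two regions.
#' @param seed integer seed for the quasi-Monte-Carlo integrator.
#' @param bias_correct_delta4 see [moment_set()].
#' @param abseps,maxpts,adapt integrator controls, see [mvn_max_prob()].
#' @param n_tests family size for the Bonferroni-corrected FWER (defaults
#'   to 1, i.e. a single region pair; the caller testing many region pairs
#'   sets this explicitly).
#' @param region1,region2 optional [region()] descriptors carried through
#'   to the result for reporting.
#' @return object of class `region_pair_test` with elements `k1`, `k2`,
#'   `n_pairs`, `pair_stats` (data frame of per-pair results), `lead_pair`,
#'   `min_pair_p`, `t_threshold`, `p_region`, `p_region_mc_error`, `cfwer`,
#'   `sigma` (the [build_sigma()] object), `seed`, `n_tests`.
#' @export
test_region_pair <- function(dataset, region1_snps, region2_snps, seed = 1L,
                             bias_correct_delta4 = FALSE,
                             abseps = 1e-4, maxpts = 250000L, adapt = TRUE,
                             n_tests = 1L,
                             region1 = NULL, region2 = NULL) {
  sig <- build_sigma(dataset, region1_snps, region2_snps,
                     bias_correct_delta4 = bias_correct_delta4)
  core <- .region_core(dataset, sig$region1_snps, sig$region2_snps,
                       bias_correct_delta4)
  thr <- min_p_threshold(core$p)
  mv <- mvn_max_prob(thr$t, sig, seed = seed, abseps = abseps,
                     maxpts = maxpts, adapt = adapt)
  lead <- core$pairs[thr$argmin, ]
  pair_stats <- cbind(core$pairs,
                      snp_x_id = dataset$snps$id[core$pairs$snp_x],
                      snp_y_id = dataset$snps$id[core$pairs$snp_y],
                      delta_ld = core$delta, t = core$t,
                      chi2 = core$chi2, p = core$p)
  structure(list(
    region1 = region1, region2 = region2,
    k1 = length(sig$region1_snps), k2 = length(sig$region2_snps),
    n_pairs = nrow(core$pairs),
    pair_stats = pair_stats,
    lead_pair = c(snp_x = lead$snp_x, snp_y = lead$snp_y),
    min_pair_p = core$p[thr$argmin],
    t_threshold = thr$t,
    p_region = mv$p, p_region_mc_error = mv$mc_error,
    cfwer = bonferroni_cfwer(mv$p, n_tests),
    sigma = sig, seed = seed, n_tests = n_tests),
    class = "region_pair_test")
}

#' @export
print.region_pair_test <- function(x, ...) {
  cat("Region-region interaction test (", x$k1, " x ", x$k2, " SNPs, ",
      x$n_pairs, " pairs)\n", sep = "")
  lead <- x$pair_stats[x$pair_stats$snp_x == x$lead_pair["snp_x"] &
                         x$pair_stats$snp_y == x$lead_pair["snp_y"], ][1, ]
  cat("  lead pair:", lead$snp_x_id, "x", lead$snp_y_id,
      sprintf("(p = %.4g)\n", x$min_pair_p))
  cat(sprintf("  T = %.4f   p_region = %.4g (QMC error %.2g)\n",
              x$t_threshold, x$p_region, x$p_region_mc_error))
  cat("  cFWER (n_tests =", x$n_tests, "):",
      format_cfwer(x$p_region, x$n_tests), "\n")
  invisible(x)
}

#' Permutation oracle for the region-region p-value
#'
#' Independent check of the analytic region p-value: permutes the
#' case/control labels `n_perm` times, recomputes the maximum |t| over all
#' cross-region pairs for each permutation, and returns
#' `(1 + #(perm max >= observed max)) / (n_perm + 1)`. Pairs whose SNPs
#' become monomorphic within a permuted group contribute |t| = 0 for that
#' permutation.
#'
#' @param dataset an imputed [genotype_dataset()].
#' @param region1_snps,region2_snps SNP column indices.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return the permutation p-value.
#' @export
permutation_region_p <- function(dataset, region1_snps, region2_snps,
                                 n_perm = 1000L, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  r1 <- .polymorphic_in_groups(dataset, region1_snps)
  r2 <- .polymorphic_in_groups(dataset, region2_snps)
  obs <- max(abs(.region_core(dataset, r1, r2)$t))
  max_t <- function(d) {
    p1 <- .polymorphic_in_groups(d, r1)
    p2 <- .polymorphic_in_groups(d, r2)
    if (length(p1) == 0 || length(p2) == 0) return(0)
    max(abs(.region_core(d, p1, p2)$t))
  }
  .with_seed(seed, function() {
    hits <- 0L
    d <- dataset
    for (b in seq_len(n_perm)) {
      d$phenotype <- sample(dataset$phenotype)
      if (max_t(d) >= obs) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  })
}
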