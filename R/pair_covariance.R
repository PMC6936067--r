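#' Plug-in central fourth product moment
#'
#' The sample mean of the product of the four mean-centered columns,
#' `mean((x - mean(x)) * (y - mean(y)) * (u - mean(u)) * (v - mean(v)))`.
#' This is the asymptotically unbiased plug-in estimator of
#' \eqn{\delta_4 = E[(X-EX)(Y-EY)(U-EU)(V-EV)]}; no finite-sample bias
#' correction is applied here (see [moment_set()] for the optional
#' inversion of the finite-sample expectation).
#'
#' @param x,y,u,v numeric vectors of equal length.
#' @return the plug-in moment estimate.
#' @export
central_product_moment <- function(x, y, u, v) {
  n <- length(x)
  if (length(y) != n || length(u) != n || length(v) != n) {
    stop("all four columns must have equal length")
  }
  if (n < 2) stop("need at least 2 samples")
  mean((x - mean(x)) * (y - mean(y)) * (u - mean(u)) * (v - mean(v)))
}

#' Moment products entering the covariance of two sample covariances
#'
#' For the quadruple (X, Y, U, V) within one phenotype group, estimates the
#' four moment products that determine `cov[cov^(X,Y), cov^(U,V)]`:
#' \deqn{\delta_4 = E[(X-EX)(Y-EY)(U-EU)(V-EV)], \quad
#'       \delta_2 = cov(X,Y)\,cov(U,V),}
#' \deqn{\sigma_2 = cov(X,U)\,cov(Y,V), \quad
#'       \tau_2 = cov(X,V)\,cov(Y,U).}
#' Pairwise covariances use the unbiased (n-1) estimator; \eqn{\delta_4}
#' uses the plug-in sample mean with sample-mean centering. With
#' `bias_correct_delta4 = TRUE` the finite-sample expectation
#' \eqn{E[\hat\delta_4] = a_n\delta_4 + b_n(\delta_2+\sigma_2+\tau_2)}
#' (with \eqn{a_n = 1 - 4/n + 6/n^2 - 3/n^3},
#' \eqn{b_n = 2(n-1)/n^2 - 3(n-1)/n^3}) is inverted, treating the
#' second-order products as known.
#'
#' @param x,y,u,v numeric vectors of equal length (one group's columns).
#' @param bias_correct_delta4 invert the finite-sample expectation of the
#'   plug-in fourth moment (default `FALSE`).
#' @return object of class `moment_set`: list with `delta4`, `delta2`,
#'   `sigma2`, `tau2`, `n`.
#' @export
moment_set <- function(x, y, u, v, bias_correct_delta4 = FALSE) {
  n <- length(x)
  d4 <- central_product_moment(x, y, u, v)
  d2 <- stats::cov(x, y) * stats::cov(u, v)
  s2 <- stats::cov(x, u) * stats::cov(y, v)
  t2 <- stats::cov(x, v) * stats::cov(y, u)
  if (bias_correct_delta4) {
    a <- 1 - 4 / n + 6 / n^2 - 3 / n^3
    b <- 2 * (n - 1) / n^2 - 3 * (n - 1) / n^3
    d4 <- (d4 - b * (d2 + s2 + t2)) / a
  }
  structure(list(delta4 = d4, delta2 = d2, sigma2 = s2, tau2 = t2, n = n),
            class = "moment_set")
}

#' Covariance of two sample covariances
#'
#' For independent samples of size n from (X, Y, U, V),
#' \deqn{cov[\widehat{cov}(X,Y), \widehat{cov}(U,V)]
#'   = \frac{1}{n}\left(\delta_4 - \delta_2
#'     + \frac{\sigma_2 + \tau_2}{n - 1}\right).}
#' With (U, V) = (X, Y) this is the variance of a sample covariance; for a
#' bivariate normal it reduces to
#' \eqn{(\sigma_x^2\sigma_y^2 + \sigma_{xy}^2)/(n-1)}.
#'
#' @param moments a [moment_set()] (or any list with fields `delta4`,
#'   `delta2`, `sigma2`, `tau2`, `n`).
#' @return the covariance.
#' @export
cov_sample_cov <- function(moments) {
  n <- moments$n
  if (is.null(n) || n < 2) stop("moment set needs group size n >= 2")
  (moments$delta4 - moments$delta2 + (moments$sigma2 + moments$tau2) / (n - 1)) / n
}

#' Covariance of two LD-contrast differences
#'
#' The covariance between \eqn{\Delta LD} of SNP pair `pair1` = (x, y) and
#' \eqn{\Delta LD} of `pair2` = (u, v) decomposes, by independence of
#' individuals, into the case-group plus the control-group covariance of
#' the corresponding sample covariances, each evaluated by
#' [cov_sample_cov()] with that group's own size and group-centered
#' moments.
#'
#' @param dataset an imputed [genotype_dataset()].
#' @param pair1,pair2 length-2 integer vectors of SNP column indices.
#' @param bias_correct_delta4 see [moment_set()].
#' @return the covariance; with `pair2 = pair1` this is exactly the
#'   variance used in the denominator of [ld_contrast_test()].
#' @export
delta_ld_cov <- function(dataset, pair1, pair2, bias_correct_delta4 = FALSE) {
  g <- dataset$genotypes
  case <- dataset$phenotype == 1L
  total <- 0
  for (grp in list(case, !case)) {
    m <- moment_set(g[grp, pair1[1]], g[grp, pair1[2]],
                    g[grp, pair2[1]], g[grp, pair2[2]],
                    bias_correct_delta4 = bias_correct_delta4)
    total <- total + cov_sample_cov(m)
  }
  total
}

#' Correlation between two pair-level LD-contrast statistics
#'
#' Because each standardized pair statistic has unit variance by
#' construction, the covariance of two statistics equals their correlation:
#' `delta_ld_cov(p1, p2) / sqrt(delta_ld_cov(p1, p1) * delta_ld_cov(p2, p2))`,
#' clipped to \[-1, 1\].
#'
#' @inheritParams delta_ld_cov
#' @return correlation in \[-1, 1\].
#' @export
pair_corr <- function(dataset, pair1, pair2, bias_correct_delta4 = FALSE) {
  v1 <- delta_ld_cov(dataset, pair1, pair1, bias_correct_delta4 = bias_correct_delta4)
  v2 <- delta_ld_cov(dataset, pair2, pair2, bias_correct_delta4 = bias_correct_delta4)
  if (v1 <= 0 || v2 <= 0) stop("zero variance for a pair statistic")
  cv <- delta_ld_cov(dataset, pair1, pair2, bias_correct_delta4 = bias_correct_delta4)
  max(-1, min(1, cv / sqrt(v1 * v2)))
}

# ---------------------------------------------------------------------------
# Vectorized core. For one phenotype group with centered genotype matrices
# Z1 (n x k1, region 1) and Z2 (n x k2, region 2) and the row-major pair
# ordering (x outer, y inner; pair (x, y) has index (x-1)*k2 + y):
#   delta4 matrix : crossprod(P)/n with P[, i] = Z1[, x_i] * Z2[, y_i]
#   delta2        : s %o% s with s = vec of pairwise cross-covariances
#   sigma2        : kronecker(C1, C2)  (C1, C2 = within-region covariances)
#   tau2          : A * t(A) with A[i, j] = B[x_i, y_j], B = cross-covariance
# giving the group's contribution (delta4 - delta2 + (sigma2+tau2)/(n-1))/n
# to the m x m covariance of the Delta-LD vector (m = k1*k2).
.group_pair_cov <- function(G1, G2, bias_correct_delta4 = FALSE) {
  n <- nrow(G1)
  k1 <- ncol(G1); k2 <- ncol(G2)
  Z1 <- scale(G1, center = TRUE, scale = FALSE)
  Z2 <- scale(G2, center = TRUE, scale = FALSE)
  xi <- rep(seq_len(k1), each = k2)
  yi <- rep(seq_len(k2), times = k1)
  P <- Z1[, xi, drop = FALSE] * Z2[, yi, drop = FALSE]
  d4 <- crossprod(P) / n
  C1 <- crossprod(Z1) / (n - 1)
  C2 <- crossprod(Z2) / (n - 1)
  B <- crossprod(Z1, Z2) / (n - 1)
  s <- as.vector(t(B))
  d2 <- tcrossprod(s)
  s2 <- kronecker(C1, C2)
  A <- B[xi, yi, drop = FALSE]
  t2 <- A * t(A)
  if (bias_correct_delta4) {
    a <- 1 - 4 / n + 6 / n^2 - 3 / n^3
    b <- 2 * (n - 1) / n^2 - 3 * (n - 1) / n^3
    d4 <- (d4 - b * (d2 + s2 + t2)) / a
  }
  list(cov = (d4 - d2 + (s2 + t2) / (n - 1)) / n, s = s)
}

# Shared computation for one region pair: per-pair Delta-LD statistics and
# the m x m covariance of the Delta-LD vector (cases + controls).
.region_core <- function(dataset, region1_snps, region2_snps,
                         bias_correct_delta4 = FALSE) {
  g <- dataset$genotypes
  case <- dataset$phenotype == 1L
  gc1 <- g[case, region1_snps, drop = FALSE]
  gc2 <- g[case, region2_snps, drop = FALSE]
  gt1 <- g[!case, region1_snps, drop = FALSE]
  gt2 <- g[!case, region2_snps, drop = FALSE]
  pc <- .group_pair_cov(gc1, gc2, bias_correct_delta4)
  pt <- .group_pair_cov(gt1, gt2, bias_correct_delta4)
  cov_dl <- unname(pc$cov + pt$cov)
  delta <- unname(pc$s - pt$s)
  var_delta <- diag(cov_dl)
  t_stat <- delta / sqrt(var_delta)
  chi2 <- t_stat^2
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  k1 <- length(region1_snps); k2 <- length(region2_snps)
  pairs <- data.frame(snp_x = rep(region1_snps, each = k2),
                      snp_y = rep(region2_snps, times = k1))
  list(cov_dl = cov_dl, delta = delta, var_delta = var_delta,
       t = t_stat, chi2 = chi2, p = p, pairs = pairs)
}

# Indices of SNPs that are polymorphic within both phenotype groups.
.polymorphic_in_groups <- function(dataset, snp_idx) {
  g <- dataset$genotypes
  case <- dataset$phenotype == 1L
  ok <- vapply(snp_idx, function(j) {
    stats::var(g[case, j]) > 0 && stats::var(g[!case, j]) > 0
  }, logical(1))
  snp_idx[ok]
}

#' Correlation matrix of all cross-region pair statistics
#'
#' For regions with k1 and k2 usable SNPs, builds the m x m (m = k1*k2)
#' correlation matrix of the standardized LD-contrast statistics of all
#' cross-region SNP pairs, in row-major pair order (region-1 SNP outer,
#' region-2 SNP inner). Entries are the analytic pair correlations of
#' [pair_corr()], computed in one vectorized pass. The matrix is
#' symmetrized, its diagonal set to exactly 1, and repaired to positive
#' semidefiniteness by clipping negative eigenvalues at zero followed by
#' re-normalization to unit diagonal; the smallest pre-repair eigenvalue
#' and a repair flag are recorded.
#'
#' SNPs that are monomorphic within either phenotype group are excluded
#' with a message (their pair statistics are undefined); an empty region
#' after exclusion is an error.
#'
#' @param dataset an imputed [genotype_dataset()].
#' @param region1_snps,region2_snps integer vectors of SNP column indices.
#' @param bias_correct_delta4 see [moment_set()].
#' @param max_pairs guard on m = k1*k2 (default 961 = 31^2).
#' @return object of class `pair_covariance`: list with `sigma`,
#'   `pair_index` (data frame `snp_x`, `snp_y`), `psd_repaired`,
#'   `min_eig_before`, `excluded_snps`, `region1_snps`, `region2_snps`.
#' @export
build_sigma <- function(dataset, region1_snps, region2_snps,
                        bias_correct_delta4 = FALSE, max_pairs = 961L) {
  r1 <- .polymorphic_in_groups(dataset, region1_snps)
  r2 <- .polymorphic_in_groups(dataset, region2_snps)
  excluded <- setdiff(c(region1_snps, region2_snps), c(r1, r2))
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " SNP(s) monomorphic within a phenotype group: ",
            paste(dataset$snps$id[excluded], collapse = ", "))
  }
  if (length(r1) == 0 || length(r2) == 0) {
    stop("region degenerate: no polymorphic SNPs left in region ",
         if (length(r1) == 0) "1" else "2")
  }
  m <- length(r1) * length(r2)
  if (m > max_pairs) stop("k1*k2 = ", m, " exceeds the pair cap (", max_pairs, ")")
  core <- .region_core(dataset, r1, r2, bias_correct_delta4)
  d <- sqrt(core$var_delta)
  sigma <- core$cov_dl / tcrossprod(d)
  sigma <- (sigma + t(sigma)) / 2
  sigma[sigma > 1] <- 1
  sigma[sigma < -1] <- -1
  diag(sigma) <- 1
  eig <- eigen(sigma, symmetric = TRUE)
  min_eig <- min(eig$values)
  repaired <- min_eig < -1e-8
  if (repaired) {
    vals <- pmax(eig$values, 0)
    sigma <- eig$vectors %*% (vals * t(eig$vectors))
    dd <- sqrt(diag(sigma))
    dd[dd == 0] <- 1
    sigma <- sigma / tcrossprod(dd)
    sigma <- (sigma + t(sigma)) / 2
    diag(sigma) <- 1
  }
  structure(list(sigma = sigma, pair_index = core$pairs,
                 psd_repaired = repaired, min_eig_before = min_eig,
                 excluded_snps = excluded,
                 region1_snps = r1, region2_snps = r2),
            class = "pair_covariance")
}

#' @export
print.pair_covariance <- function(x, ...) {
  m <- nrow(x$sigma)
  cat("pair_covariance: ", m, " x ", m, " correlation matrix (",
      length(x$region1_snps), " x ", length(x$region2_snps), " SNPs)\n", sep = "")
  cat("  min eigenvalue before repair:", format(x$min_eig_before, digits = 4),
      if (x$psd_repaired) "(clipped to PSD)" else "", "\n")
  if (length(x$excluded_snps)) cat("  excluded SNPs:", length(x$excluded_snps), "\n")
  invisible(x)
}
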