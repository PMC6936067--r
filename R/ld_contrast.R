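#' Composite linkage disequilibrium of two genotype columns
#'
#' Composite LD is the phase-free surrogate for gametic LD computable from
#' unphased genotypes. Operationally it is the unbiased sample covariance of
#' the additive 0/1/2 codes: the LD-contrast statistic is invariant to any
#' constant rescaling of the measure, so the covariance itself (rather than
#' half of it) is used throughout.
#'
#' @param x,y numeric genotype columns of equal length (no missing values;
#'   impute first).
#' @return the sample covariance `sum((x - mean(x)) * (y - mean(y))) / (n - 1)`.
#' @examples
#' composite_ld(c(0, 1, 2, 1), c(0, 1, 2, 1)) # 2/3, the sample variance
#' @export
composite_ld <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 samples")
  if (anyNA(x) || anyNA(y)) stop("missing values: impute before computing LD")
  stats::cov(x, y)
}

#' Genotype correlation coefficient
#'
#' Pearson correlation of the 0/1/2 codes; equals
#' `composite_ld(x, y) / sqrt(var(x) * var(y))`. Under the additive coding
#' this is the standardized composite-LD measure.
#'
#' @param x,y numeric genotype columns, both non-constant.
#' @return correlation in \[-1, 1\].
#' @export
genotype_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance column")
  stats::cor(x, y)
}

# Condition class for monomorphic-within-group SNPs.
degenerate_snp_error <- function(msg) {
  structure(class = c("degenerate_snp_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' LD contrast test for one SNP pair
#'
#' Tests whether the composite LD between two SNPs differs between cases
#' and controls. The statistic is
#' \deqn{T = \frac{\Delta LD}{\sqrt{\widehat{Var}(\Delta LD)}}, \qquad
#'       \chi^2 = T^2,}
#' where \eqn{\Delta LD} is the case-group minus control-group sample
#' covariance of the two genotype columns and the variance is the sum of
#' the per-group variances of a sample covariance, each evaluated
#' analytically from plug-in fourth- and second-order moments of that group
#' (see [cov_sample_cov()]). Under the null of equal LD, \eqn{\chi^2}
#' follows a 1-df chi-squared distribution; the reported p-value is its
#' upper tail, equivalent to the two-sided normal p-value of `T`.
#'
#' @param dataset an imputed [genotype_dataset()].
#' @param snp_x,snp_y column indices of the two SNPs.
#' @param bias_correct_delta4 invert the finite-sample expectation of the
#'   plug-in fourth-moment estimator (sensitivity option; default off).
#' @return object of class `snp_pair_test`: list with `snp_x`, `snp_y`,
#'   `delta_ld`, `var_delta`, `t`, `chi2`, `p`.
#' @export
ld_contrast_test <- function(dataset, snp_x, snp_y, bias_correct_delta4 = FALSE) {
  g <- dataset$genotypes
  if (anyNA(g[, c(snp_x, snp_y)])) stop("missing genotypes: run impute_missing() first")
  case <- dataset$phenotype == 1L
  for (j in c(snp_x, snp_y)) {
    if (stats::var(g[case, j]) == 0 || stats::var(g[!case, j]) == 0) {
      stop(degenerate_snp_error(paste0(
        "SNP ", dataset$snps$id[j], " is monomorphic within a phenotype group")))
    }
  }
  x <- g[, snp_x]; y <- g[, snp_y]
  delta <- composite_ld(x[case], y[case]) - composite_ld(x[!case], y[!case])
  vd <- delta_ld_cov(dataset, c(snp_x, snp_y), c(snp_x, snp_y),
                     bias_correct_delta4 = bias_correct_delta4)
  t_stat <- delta / sqrt(vd)
  chi2 <- t_stat^2
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(snp_x = snp_x, snp_y = snp_y,
                 snp_x_id = dataset$snps$id[snp_x], snp_y_id = dataset$snps$id[snp_y],
                 delta_ld = delta, var_delta = vd,
                 t = t_stat, chi2 = chi2, p = p),
            class = "snp_pair_test")
}

#' @export
print.snp_pair_test <- function(x, ...) {
  cat("LD contrast test:", x$snp_x_id, "x", x$snp_y_id, "\n")
  cat(sprintf("  delta LD = %.6g  (var %.6g)\n", x$delta_ld, x$var_delta))
  cat(sprintf("  T = %.4f   chi-squared(1) = %.4f   p = %.4g\n", x$t, x$chi2, x$p))
  invisible(x)
}
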