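#' Genotype/phenotype container
#'
#' Bundles an `n_samples x n_snps` matrix of additive genotype codes
#' (0/1/2 = minor-allele dose, `NA` = missing) with per-SNP metadata and a
#' binary case/control phenotype. All downstream statistics assume this
#' additive coding; after loading, every SNP is oriented so that its minor
#' allele frequency is at most 0.5 (code 2 always means two minor alleles).
#'
#' @param genotypes numeric matrix, samples in rows, SNPs in columns; values
#'   in \{0, 1, 2\} or `NA`. Imputed datasets may hold non-integer values.
#' @param phenotype vector of 0 (control) / 1 (case), one per sample.
#' @param snps optional data frame with columns `id`, `chrom`, `pos`,
#'   `major`, `minor` (one row per SNP). Defaults are synthesized when
#'   absent; positional operations (region clumping) need real coordinates.
#' @param orient if `TRUE` (default), re-code SNPs with allele frequency of
#'   the counted allele above 0.5 as `2 - code`, swapping the allele labels,
#'   so that `maf <= 0.5` holds for every SNP.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `snps`, `phenotype`, `n_case`, `n_control`.
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 0, 0, 1, 2), nrow = 4)
#' d <- genotype_dataset(g, phenotype = c(1, 1, 0, 0))
#' d$n_case
#' @export
genotype_dataset <- function(genotypes, phenotype, snps = NULL, orient = TRUE) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (length(phenotype) != n) {
    stop("phenotype length (", length(phenotype), ") != number of samples (", n, ")")
  }
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% c(0L, 1L))) {
    stop("phenotype must be coded 0 (control) / 1 (case)")
  }
  bad <- !is.na(genotypes) & !(genotypes >= 0 & genotypes <= 2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("genotype value outside [0, 2] at sample ", idx[1], ", SNP ", idx[2])
  }
  if (is.null(snps)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- sprintf("snp%d", seq_len(m))
    snps <- data.frame(id = ids, chrom = "1", pos = seq_len(m),
                       major = "B", minor = "b", stringsAsFactors = FALSE)
  } else {
    snps <- as.data.frame(snps)
    if (nrow(snps) != m) stop("snps table has ", nrow(snps), " rows for ", m, " SNPs")
    if (anyDuplicated(snps$id)) stop("duplicate SNP ids: ",
                                     paste(unique(snps$id[duplicated(snps$id)]), collapse = ", "))
    if (any(snps$pos <= 0)) stop("SNP positions must be positive (1-based)")
  }
  colnames(genotypes) <- snps$id
  x <- structure(
    list(genotypes = genotypes, snps = snps, phenotype = phenotype,
         n_case = sum(phenotype == 1L), n_control = sum(phenotype == 0L)),
    class = "genotype_dataset")
  if (x$n_case < 2L || x$n_control < 2L) {
    stop("need at least 2 cases and 2 controls (have ", x$n_case, "/", x$n_control, ")")
  }
  if (orient) x <- orient_minor(x)
  x
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "samples x", ncol(x$genotypes), "SNPs\n")
  cat("  cases:", x$n_case, " controls:", x$n_control, "\n")
  nmiss <- sum(is.na(x$genotypes))
  if (nmiss > 0) cat("  missing genotype calls:", nmiss, "\n")
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  s <- do.call(rbind, lapply(seq_len(ncol(object$genotypes)), function(j) {
    ss <- snp_summary(object, j)
    data.frame(id = object$snps$id[j], maf = ss$maf, hwd = ss$hwd, var = ss$var)
  }))
  s
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

# Orient every SNP to count the minor allele: frequency of the counted
# allele > 0.5 flips the coding (g -> 2 - g) and swaps the allele labels.
orient_minor <- function(dataset) {
  g <- dataset$genotypes
  for (j in seq_len(ncol(g))) {
    col <- g[, j]
    ok <- !is.na(col)
    if (!any(ok)) next
    f <- sum(col[ok]) / (2 * sum(ok))
    if (f > 0.5) {
      g[ok, j] <- 2 - col[ok]
      tmp <- dataset$snps$major[j]
      dataset$snps$major[j] <- dataset$snps$minor[j]
      dataset$snps$minor[j] <- tmp
    }
  }
  dataset$genotypes <- g
  dataset
}

#' Per-SNP summary: minor-allele frequency, HWD, variance
#'
#' Computes from the non-missing calls of one genotype column: the minor
#' allele frequency `maf = (allele count)/(2 n)`, the Hardy-Weinberg
#' disequilibrium `hwd = freq(code 2) - maf^2` (deviation of the
#' minor-homozygote frequency from its Hardy-Weinberg expectation), and the
#' unbiased sample variance of the codes. `hwd` enters the relation between
#' composite LD and the genotype correlation coefficient; under
#' Hardy-Weinberg equilibrium it is near zero.
#'
#' @param dataset a [genotype_dataset()].
#' @param snp_index column index of the SNP.
#' @return list with elements `maf`, `hwd`, `var`, `n_called`,
#'   `monomorphic`.
#' @examples
#' d <- genotype_dataset(cbind(c(0, 0, 1, 1)), phenotype = c(1, 1, 0, 0))
#' snp_summary(d, 1) # maf 0.25, hwd -0.0625
#' @export
snp_summary <- function(dataset, snp_index) {
  col <- dataset$genotypes[, snp_index]
  ok <- !is.na(col)
  if (!any(ok)) stop("SNP ", snp_index, " has no non-missing calls")
  col <- col[ok]
  n <- length(col)
  maf <- sum(col) / (2 * n)
  hwd <- mean(col == 2) - maf^2
  v <- if (n >= 2) stats::var(col) else 0
  list(maf = maf, hwd = hwd, var = v, n_called = n, monomorphic = v == 0)
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing call with the SNP's mean genotype over all
#' non-missing samples, cases and controls pooled. Pooled imputation keeps
#' the per-group sample size identical across all SNP pairs of a region
#' pair, which the analytic covariance of pair statistics requires (every
#' entry of the matrix must be computed on the same n per group).
#' Imputed values are generally non-integer; all moment formulas accept
#' real-valued codes.
#'
#' @param dataset a [genotype_dataset()].
#' @return The dataset with no missing calls. Returned unchanged when there
#'   is nothing to impute.
#' @export
impute_missing <- function(dataset) {
  g <- dataset$genotypes
  if (!anyNA(g)) return(dataset)
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (!any(miss)) next
    if (all(miss)) stop("SNP ", dataset$snps$id[j], " is all-missing; drop it at load time")
    g[miss, j] <- mean(g[!miss, j])
  }
  dataset$genotypes <- g
  dataset
}

# Map a raw phenotype column to 0/1, accepting both the PLINK 1/2 dialect
# (1 = control, 2 = case; 0 or -9 = missing) and plain 0/1 (with -9
# missing). Returns list(code = 0/1/NA vector, dialect).
.map_phenotype <- function(ph) {
  ph <- suppressWarnings(as.numeric(ph))
  if (any(ph == 2, na.rm = TRUE)) {
    code <- ifelse(ph == 2, 1L, ifelse(ph == 1, 0L, NA_integer_))
    dialect <- "plink12"
  } else {
    code <- ifelse(ph == 1, 1L, ifelse(ph == 0, 0L, NA_integer_))
    code[!is.na(ph) & ph == -9] <- NA_integer_
    dialect <- "01"
  }
  code[is.na(ph)] <- NA_integer_
  list(code = code, dialect = dialect)
}

#' Read genotypes from a plain-text TSV
#'
#' Expects a header line `sample  phenotype  <snp ids...>` followed by one
#' row per sample with genotype codes in \{0, 1, 2, NA\}. The phenotype
#' accepts both the PLINK 1/2 and the 0/1 case-control dialects; samples
#' with missing phenotype (0/-9 under the 1/2 dialect, -9 under 0/1) are
#' dropped with a message. SNPs are oriented to minor-allele dose on load.
#'
#' Text input carries no genomic coordinates: SNPs are assigned
#' chromosome "1" and consecutive positions. Supply PLINK input or an
#' explicit `snps` table to [genotype_dataset()] when positions matter.
#'
#' @param path TSV file as above.
#' @return a [genotype_dataset()].
#' @seealso [write_text_genotypes()] for the inverse.
#' @export
read_text_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 3) stop("expected columns: sample, phenotype, then one per SNP")
  ids <- colnames(tab)[-(1:2)]
  if (anyDuplicated(ids)) stop("duplicate SNP ids in header: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  g <- as.matrix(tab[, -(1:2), drop = FALSE])
  gm <- suppressWarnings(matrix(as.numeric(g), nrow = nrow(g)))
  gm[g %in% c("NA", "")] <- NA
  bad <- which(!is.na(g) & !(g %in% c("NA", "")) &
                 (is.na(gm) | !(gm %in% c(0, 1, 2))), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(gm))
    stop("invalid genotype value '", g[bad[1]], "' at row ", rc[1],
         ", SNP column '", ids[rc[2]], "'")
  }
  ph <- .map_phenotype(tab[[2]])
  keep <- !is.na(ph$code)
  if (!all(keep)) {
    message(sum(!keep), " sample(s) dropped for missing phenotype")
  }
  gm <- gm[keep, , drop = FALSE]
  rownames(gm) <- tab[[1]][keep]
  colnames(gm) <- ids
  genotype_dataset(gm, ph$code[keep])
}

#' Write genotypes to a plain-text TSV
#'
#' Inverse of [read_text_genotypes()]: header `sample  phenotype  <ids>`,
#' phenotype written as 1 = case / 0 = control, missing calls as `NA`.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_text_genotypes <- function(dataset, path) {
  g <- dataset$genotypes
  samp <- rownames(g)
  if (is.null(samp)) samp <- sprintf("s%d", seq_len(nrow(g)))
  out <- data.frame(sample = samp, phenotype = dataset$phenotype,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(g, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- PLINK 1 binary (.bed/.bim/.fam) ---------------------------------------
# SNP-major .bed layout: 3 magic bytes 0x6c 0x1b 0x01, then ceiling(n/4)
# bytes per SNP, 2 bits per sample (LSB first within each byte):
#   00 = homozygous A1, 01 = missing, 10 = heterozygous, 11 = homozygous A2.
# .bim lists A1/A2 per SNP; we count A1 copies (00 -> 2, 10 -> 1, 11 -> 0)
# and then orient to minor-allele dose, so the A1/A2 convention of the
# producing tool does not matter.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> 4 decoded genotype codes (NA = missing).
.bed_lut <- local({
  two_bits <- function(b, i) bitwAnd(bitwShiftR(b, 2L * i), 3L)
  dec <- c(2, NA, 1, 0) # index by code + 1
  lut <- matrix(NA_real_, 256, 4)
  for (b in 0:255) for (i in 0:3) lut[b + 1, i + 1] <- dec[two_bits(b, i) + 1]
  lut
})

#' Read a PLINK .bed/.bim/.fam triplet
#'
#' Reads SNP-major PLINK 1 binary genotypes, orienting every SNP to
#' minor-allele dose (code 2 = two minor alleles) regardless of the A1/A2
#' convention of the producing tool. The phenotype is taken from column 6
#' of the .fam file unless `phenotype` supplies an explicit 0/1 vector;
#' .fam values 1/2 map to control/case and 0/-9 drop the sample with a
#' message. SNPs with no non-missing calls are dropped with a message.
#'
#' @param bed_prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @param phenotype optional numeric vector overriding the .fam phenotype
#'   (same length and order as the .fam file; PLINK 1/2 or 0/1 coding).
#' @return a [genotype_dataset()].
#' @export
read_plink_dataset <- function(bed_prefix, phenotype = NULL) {
  paths <- paste0(bed_prefix, c(".bed", ".bim", ".fam"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) stop("missing PLINK file(s): ",
                                  paste(missing_files, collapse = ", "))
  bim <- utils::read.table(paths[2], header = FALSE, colClasses = "character")
  if (ncol(bim) < 6) stop("malformed .bim: expected 6 columns")
  fam <- utils::read.table(paths[3], header = FALSE, colClasses = "character")
  if (ncol(fam) < 6) stop("malformed .fam: expected 6 columns")
  n <- nrow(fam)
  m <- nrow(bim)
  bpb <- ceiling(n / 4) # bytes per SNP block
  con <- file(paths[1], "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, .bed_magic)) {
    stop(".bed magic bytes wrong or file is individual-major; ",
         "only SNP-major PLINK 1 .bed is supported")
  }
  raw_all <- readBin(con, "raw", bpb * m)
  if (length(raw_all) < bpb * m) stop(".bed truncated: expected ", bpb * m,
                                      " data bytes, got ", length(raw_all))
  bytes <- as.integer(raw_all)
  # decode all SNPs at once: (bpb x m) bytes -> (4*bpb x m) codes
  codes <- matrix(t(.bed_lut[bytes + 1L, , drop = FALSE]), nrow = 4L * bpb)
  g <- codes[seq_len(n), , drop = FALSE]
  rownames(g) <- fam[[2]]

  ph_raw <- if (is.null(phenotype)) fam[[6]] else phenotype
  if (length(ph_raw) != n) stop("phenotype length != number of .fam samples")
  ph <- .map_phenotype(ph_raw)
  keep <- !is.na(ph$code)
  if (!all(keep)) message(sum(!keep), " sample(s) dropped for missing phenotype")
  g <- g[keep, , drop = FALSE]

  all_missing <- colSums(!is.na(g)) == 0
  if (any(all_missing)) {
    message("dropping ", sum(all_missing), " all-missing SNP(s): ",
            paste(bim[[2]][all_missing], collapse = ", "))
    g <- g[, !all_missing, drop = FALSE]
    bim <- bim[!all_missing, , drop = FALSE]
  }
  snps <- data.frame(id = bim[[2]], chrom = bim[[1]],
                     pos = as.integer(bim[[4]]),
                     major = bim[[6]], minor = bim[[5]],
                     stringsAsFactors = FALSE)
  genotype_dataset(g, ph$code[keep], snps = snps)
}

#' Write a PLINK .bed/.bim/.fam triplet
#'
#' Writes SNP-major PLINK 1 binary. Minor allele is written as A1, so a
#' code of 2 becomes homozygous A1. Missing calls are encoded as the
#' dedicated missing bit pattern; the phenotype is written in the 1/2
#' (control/case) dialect. Non-integer (imputed) codes cannot be
#' represented and raise an error.
#'
#' @param dataset a [genotype_dataset()].
#' @param bed_prefix output path prefix.
#' @return `bed_prefix`, invisibly.
#' @export
write_plink <- function(dataset, bed_prefix) {
  g <- dataset$genotypes
  if (any(!is.na(g) & g != round(g))) {
    stop("dataset holds non-integer (imputed) codes; PLINK .bed cannot represent them")
  }
  n <- nrow(g)
  m <- ncol(g)
  enc <- c(3L, 2L, 0L) # code 0/1/2 -> bit pair 11/10/00
  bpb <- ceiling(n / 4)
  con <- file(paste0(bed_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  for (j in seq_len(m)) {
    codes <- g[, j]
    bits <- ifelse(is.na(codes), 1L, enc[codes + 1L])
    bits <- c(bits, rep(0L, bpb * 4 - n)) # pad tail with hom-A2 (11? pad 0 ok)
    byte <- bits[c(TRUE, FALSE, FALSE, FALSE)] +
      bitwShiftL(bits[c(FALSE, TRUE, FALSE, FALSE)], 2L) +
      bitwShiftL(bits[c(FALSE, FALSE, TRUE, FALSE)], 4L) +
      bitwShiftL(bits[c(FALSE, FALSE, FALSE, TRUE)], 6L)
    writeBin(as.raw(byte), con)
  }
  samp <- rownames(g)
  if (is.null(samp)) samp <- sprintf("s%d", seq_len(n))
  fam <- data.frame(fid = samp, iid = samp, pid = 0, mid = 0, sex = 0,
                    phen = ifelse(dataset$phenotype == 1L, 2L, 1L))
  utils::write.table(fam, paste0(bed_prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = dataset$snps$chrom, id = dataset$snps$id, cm = 0,
                    pos = dataset$snps$pos, a1 = dataset$snps$minor,
                    a2 = dataset$snps$major)
  utils::write.table(bim, paste0(bed_prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(bed_prefix)
}
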