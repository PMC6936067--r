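#' Genomic region descriptor
#'
#' A 1-based inclusive interval on one chromosome, with the dataset column
#' indices of its member SNPs.
#'
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds in bp (`start <= end`).
#' @param snp_indices integer vector of member SNP columns (may be empty).
#' @return object of class `region`.
#' @export
region <- function(chrom, start, end, snp_indices = integer()) {
  if (start > end) stop("region start > end")
  if (start <= 0) stop("region start must be positive (1-based)")
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end), snp_indices = as.integer(snp_indices)),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region %s:[%d, %d] (%d SNPs)\n", x$chrom, x$start, x$end,
              length(x$snp_indices)))
  invisible(x)
}

#' @export
format.region <- function(x, ...) sprintf("%s:%d-%d", x$chrom, x$start, x$end)

#' Read screened candidate SNP pairs
#'
#' Parses a tolerant TSV of candidate SNP pairs as emitted by exhaustive
#' pairwise screening tools (BOOST-family output reformatted): required
#' columns `snp_a, chrom_a, pos_a, snp_b, chrom_b, pos_b, p`, matched
#' case-insensitively and in any order. Malformed rows (non-numeric or
#' missing position, p outside (0, 1]) are rejected with their line
#' numbers.
#'
#' @param path TSV file with a header.
#' @return data frame with the seven columns above, p numeric.
#' @export
read_candidate_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#")
  wanted <- c("snp_a", "chrom_a", "pos_a", "snp_b", "chrom_b", "pos_b", "p")
  idx <- match(wanted, tolower(colnames(tab)))
  if (anyNA(idx)) stop("missing column(s): ",
                       paste(wanted[is.na(idx)], collapse = ", "))
  tab <- tab[, idx]
  colnames(tab) <- wanted
  pos_a <- suppressWarnings(as.numeric(tab$pos_a))
  pos_b <- suppressWarnings(as.numeric(tab$pos_b))
  p <- suppressWarnings(as.numeric(tab$p))
  ok <- !is.na(pos_a) & !is.na(pos_b) & pos_a > 0 & pos_b > 0 &
    !is.na(p) & p > 0 & p <= 1 & nzchar(tab$snp_a) & nzchar(tab$snp_b)
  if (any(!ok)) {
    message("rejecting ", sum(!ok), " malformed candidate-pair row(s): lines ",
            paste(which(!ok) + 1L, collapse = ", "))
  }
  if (!any(ok)) stop("no parseable candidate-pair rows in ", path)
  out <- tab[ok, , drop = FALSE]
  out$pos_a <- as.integer(pos_a[ok])
  out$pos_b <- as.integer(pos_b[ok])
  out$p <- p[ok]
  rownames(out) <- NULL
  out
}

#' Filter candidate pairs at a suggestive threshold
#'
#' Retains pairs with screening p-value strictly below the threshold. The
#' default 5e-10 is a suggestive genome-wide threshold for exhaustive
#' pairwise screens: loose enough to keep regions worth re-testing, far
#' above the Bonferroni level for all SNP pairs.
#'
#' @param pairs data frame from [read_candidate_pairs()].
#' @param threshold suggestive p-value threshold (default `5e-10`).
#' @return the surviving rows.
#' @export
filter_suggestive <- function(pairs, threshold = 5e-10) {
  out <- pairs[pairs$p < threshold, , drop = FALSE]
  if (nrow(out) == 0) warning("no candidate pairs survive the suggestive threshold")
  rownames(out) <- NULL
  out
}

# Merge 1-based inclusive intervals (start sorted); returns matrix cols start,end.
.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out <- rbind(out, c(ms, me))
      ms <- start[i]; me <- end[i]
    }
  }
  rbind(out, c(ms, me))
}

#' Clump surviving candidate pairs into region pairs
#'
#' Each anchor SNP of a surviving candidate pair seeds a window of
#' `window` bp (by default centered on the anchor: `[pos - window/2,
#' pos + window/2 - 1]`, exactly `window` bp). Overlapping windows on the
#' same chromosome are merged, so merged regions may exceed `window`. All
#' dataset SNPs inside each final region become its members; regions with
#' more than `max_snps` members are represented by a uniform random subset
#' of `max_snps` SNPs drawn under `seed` (the cap keeps k1*k2 per region
#' pair bounded). One region pair is emitted per surviving candidate pair,
#' deduplicated.
#'
#' @param pairs surviving rows from [filter_suggestive()].
#' @param dataset a [genotype_dataset()] with genuine chrom/pos metadata.
#' @param window region size in bp (default 200000, roughly a gene).
#' @param max_snps cap on SNPs per region (default 31, so k1*k2 < 1000).
#' @param seed RNG seed for the random subset draw.
#' @param anchor `"center"` (default) centers the window on the anchor
#'   SNP; `"start"` begins it there.
#' @return list of region pairs; each element is a list with `region1`,
#'   `region2` ([region()] objects) and `source_pairs` (row indices of
#'   `pairs` mapping to this region pair).
#' @export
clump_to_regions <- function(pairs, dataset, window = 200000L, max_snps = 31L,
                             seed = 1L, anchor = c("center", "start")) {
  anchor <- match.arg(anchor)
  if (nrow(pairs) == 0) {
    warning("no candidate pairs to clump")
    return(list())
  }
  snp_row <- function(id) match(id, dataset$snps$id)
  a_idx <- snp_row(pairs$snp_a)
  b_idx <- snp_row(pairs$snp_b)
  usable <- !is.na(a_idx) & !is.na(b_idx)
  if (any(!usable)) {
    message("skipping ", sum(!usable),
            " candidate pair(s) with anchor SNPs absent from the dataset")
  }
  pairs <- pairs[usable, , drop = FALSE]
  if (nrow(pairs) == 0) {
    warning("no candidate pairs with anchors present in the dataset")
    return(list())
  }
  anchors <- unique(data.frame(
    chrom = c(pairs$chrom_a, pairs$chrom_b),
    pos = c(pairs$pos_a, pairs$pos_b)))
  half <- as.integer(window %/% 2)
  if (anchor == "center") {
    ws <- pmax(1L, anchors$pos - half)
    we <- ws + as.integer(window) - 1L
  } else {
    ws <- anchors$pos
    we <- ws + as.integer(window) - 1L
  }
  # merge per chromosome, then build region objects with member SNPs
  regions <- list()
  for (ch in unique(anchors$chrom)) {
    sel <- anchors$chrom == ch
    merged <- .merge_intervals(ws[sel], we[sel])
    for (r in seq_len(nrow(merged))) {
      members <- which(dataset$snps$chrom == ch &
                         dataset$snps$pos >= merged[r, 1] &
                         dataset$snps$pos <= merged[r, 2])
      if (length(members) > max_snps) {
        # offset the seed per region so different capped regions draw
        # different (but still reproducible) subsets
        sub_seed <- seed + length(regions)
        members <- .with_seed(sub_seed, function() sort(sample(members, max_snps)))
      }
      regions[[length(regions) + 1L]] <-
        region(ch, merged[r, 1], merged[r, 2], members)
    }
  }
  locate <- function(chrom, pos) {
    for (i in seq_along(regions)) {
      r <- regions[[i]]
      if (r$chrom == chrom && pos >= r$start && pos <= r$end) return(i)
    }
    NA_integer_
  }
  ra <- mapply(locate, pairs$chrom_a, pairs$pos_a)
  rb <- mapply(locate, pairs$chrom_b, pairs$pos_b)
  key <- paste(pmin(ra, rb), pmax(ra, rb))
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    i <- ra[rows[1]]; j <- rb[rows[1]]
    out[[length(out) + 1L]] <- list(region1 = regions[[i]],
                                    region2 = regions[[j]],
                                    source_pairs = rows)
  }
  out
}

#' Read explicit regions from a BED file
#'
#' BED coordinates are 0-based half-open; they are converted to the
#' package's 1-based inclusive convention on read (`start + 1 .. end`).
#' Dataset SNPs falling inside each interval become region members. Use
#' this to test regions chosen from pathway or network knowledge instead
#' of screening-based clumping.
#'
#' @param path BED file (3+ columns, no header; `#`/`track` lines ignored).
#' @param dataset a [genotype_dataset()].
#' @return list of [region()] objects.
#' @export
read_regions_bed <- function(path, dataset) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no BED records in ", path)
  tab <- utils::read.table(text = lines, sep = "\t", colClasses = "character")
  if (ncol(tab) < 3) stop("BED needs at least 3 columns")
  lapply(seq_len(nrow(tab)), function(i) {
    ch <- tab[i, 1]
    s0 <- as.integer(tab[i, 2]); e0 <- as.integer(tab[i, 3])
    if (is.na(s0) || is.na(e0) || e0 <= s0) stop("malformed BED record at line ", i)
    members <- which(dataset$snps$chrom == ch &
                       dataset$snps$pos >= s0 + 1L & dataset$snps$pos <= e0)
    region(ch, s0 + 1L, e0, members)
  })
}
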