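write_pairs_file <- function(rows, path) {
  header <- "snp_a\tchrom_a\tpos_a\tsnp_b\tchrom_b\tpos_b\tp"
  writeLines(c(header, rows), path)
  path
}

test_that("candidate-pair TSV parses well-formed rows, rejects malformed ones", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_file(c("rs1\t1\t100\trs2\t2\t200\t0.5",
                     "rs3\t1\t300\trs4\t2\t400\t1e-12",
                     "rs5\t1\t500\trs6\t2\t\t1e-3"), path)
  expect_message(got <- read_candidate_pairs(path), "lines 4")
  expect_equal(nrow(got), 2)
  expect_equal(got$p[2], 1e-12)
  expect_type(got$pos_a, "integer")
  # a file with no usable rows is an error
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_file("rs1\t1\t\trs2\t2\t200\t0.5", path2)
  expect_error(suppressMessages(read_candidate_pairs(path2)), "no parseable")
})

test_that("suggestive filter keeps only pairs strictly below the threshold", {
  pairs <- data.frame(snp_a = c("a", "b"), chrom_a = "1", pos_a = 1:2,
                      snp_b = c("c", "d"), chrom_b = "2", pos_b = 3:4,
                      p = c(1e-11, 1e-9))
  kept <- filter_suggestive(pairs)
  expect_equal(kept$snp_a, "a")
  expect_warning(filter_suggestive(pairs, threshold = 1e-20), "no candidate")
})

# dataset whose SNPs span two well-separated loci on one chromosome
make_positioned_dataset <- function(extra_positions = integer()) {
  n_snps <- 8 + length(extra_positions)
  set.seed(5)
  g <- matrix(rbinom(40 * n_snps, 2, 0.3), 40, n_snps)
  ph <- rep(c(1, 0), 20)
  pos <- c(500000L + 100L * (1:4), 5000000L + 100L * (1:4), extra_positions)
  snps <- data.frame(id = sprintf("m%d", seq_len(n_snps)), chrom = "1",
                     pos = pos, major = "B", minor = "b")
  genotype_dataset(g, ph, snps = snps, orient = FALSE)
}

test_that("isolated anchors produce centered windows of exactly the set size", {
  d <- make_positioned_dataset()
  pairs <- data.frame(snp_a = "m1", chrom_a = "1", pos_a = d$snps$pos[1],
                      snp_b = "m5", chrom_b = "1", pos_b = d$snps$pos[5],
                      p = 1e-12)
  rps <- clump_to_regions(pairs, d)
  expect_length(rps, 1)
  r1 <- rps[[1]]$region1; r2 <- rps[[1]]$region2
  expect_equal(r1$end - r1$start + 1L, 200000L)
  expect_equal(r2$end - r2$start + 1L, 200000L)
  expect_equal((r1$start + r1$end) %/% 2, d$snps$pos[1], tolerance = 1)
  expect_setequal(r1$snp_indices, 1:4)
  expect_setequal(r2$snp_indices, 5:8)
})

test_that("anchors 150 kbp apart merge into one 350 kbp region", {
  d <- make_positioned_dataset(extra_positions = 650100L)
  pairs <- data.frame(snp_a = c("m1", "m9"), chrom_a = "1",
                      pos_a = c(500100L, 650100L),
                      snp_b = c("m5", "m5"), chrom_b = "1",
                      pos_b = c(5000100L, 5000100L), p = 1e-12)
  rps <- clump_to_regions(pairs, d)
  expect_length(rps, 1) # both candidate pairs map to the same region pair
  merged <- rps[[1]]$region1
  expect_equal(merged$end - merged$start + 1L, 350000L)
  # merging is idempotent
  iv <- regionepi:::.merge_intervals(c(merged$start), c(merged$end))
  expect_equal(as.vector(iv), c(merged$start, merged$end))
})

test_that("oversized regions are capped by a reproducible random subset", {
  extra <- 500000L + 150L * (1:40)
  d <- make_positioned_dataset(extra_positions = extra)
  pairs <- data.frame(snp_a = "m1", chrom_a = "1", pos_a = d$snps$pos[1],
                      snp_b = "m5", chrom_b = "1", pos_b = d$snps$pos[5],
                      p = 1e-12)
  r_a <- clump_to_regions(pairs, d, max_snps = 31, seed = 9)
  r_b <- clump_to_regions(pairs, d, max_snps = 31, seed = 9)
  expect_length(r_a[[1]]$region1$snp_indices, 31)
  expect_identical(r_a[[1]]$region1$snp_indices, r_b[[1]]$region1$snp_indices)
  r_c <- clump_to_regions(pairs, d, max_snps = 31, seed = 10)
  expect_false(identical(r_c[[1]]$region1$snp_indices,
                         r_a[[1]]$region1$snp_indices))
})

test_that("pairs with anchors absent from the dataset are skipped", {
  d <- make_positioned_dataset()
  pairs <- data.frame(snp_a = c("m1", "nope"), chrom_a = "1",
                      pos_a = c(d$snps$pos[1], 1L),
                      snp_b = c("m5", "m5"), chrom_b = "1",
                      pos_b = d$snps$pos[5], p = 1e-12)
  expect_message(rps <- clump_to_regions(pairs, d), "skipping 1")
  expect_length(rps, 1)
})

test_that("BED regions convert 0-based half-open to 1-based inclusive", {
  d <- make_positioned_dataset()
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# comment", "1\t500099\t500400", "1\t4999999\t5000500"), path)
  regs <- read_regions_bed(path, d)
  expect_length(regs, 2)
  expect_equal(regs[[1]]$start, 500100L)
  expect_equal(regs[[1]]$end, 500400L)
  expect_setequal(regs[[1]]$snp_indices, 1:4) # pos 500100..500400 inclusive
  expect_setequal(regs[[2]]$snp_indices, 5:8)
})
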