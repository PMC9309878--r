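sites_df <- function(n, chrom = "chr1") {
  data.frame(chrom = chrom, pos = seq_len(n) * 10L, ref = "A", alt = "T",
             stringsAsFactors = FALSE)
}

test_that("D' matches hand-computed two-locus tables", {
  # identical columns: perfect positive LD
  x <- c(0, 0, 2, 2, 0, 2)
  expect_equal(dprime(x, x), 1)
  # complementary columns: perfect negative association, |D'| = 1
  expect_equal(abs(dprime(x, 2 - x)), 1)
  # constructed counts: haplotypes AB=4 Ab=1 aB=1 ab=4, pA=pB=0.5
  # D = 0.4 - 0.25 = 0.15, Dmax = 0.25, D' = 0.6
  x2 <- c(rep(2, 5), rep(0, 5))
  y2 <- c(rep(2, 4), 0, 2, rep(0, 4))
  expect_equal(dprime(x2, y2), 0.15 / 0.25)
  # independence by construction: D = 0
  x3 <- c(2, 2, 0, 0)
  y3 <- c(2, 0, 2, 0)
  expect_equal(dprime(x3, y3), 0)
  # monomorphic column: no information
  expect_equal(dprime(rep(2, 6), x), 0)
})

test_that("QC filter applies the missing/het/MAF rules per site", {
  calls <- rbind(
    c(0L, 0L, 2L, 1L, NA),
    c(0L, 2L, 2L, 1L, NA),
    c(0L, 2L, 2L, 1L, NA),
    c(0L, 2L, 2L, 0L, 0L),
    c(0L, 2L, 2L, 0L, 0L),
    c(0L, 2L, 2L, 0L, 0L),
    c(0L, 2L, 2L, 0L, 0L),
    c(0L, 2L, 2L, 0L, 0L),
    c(0L, 2L, 2L, 0L, 0L),
    c(0L, 2L, NA, 0L, 0L))
  m <- snp_matrix(calls, sites_df(5))
  expect_warning(f0 <- qc_filter_snps(m, min_maf = 0.05), NA)
  # site 1 monomorphic -> dropped; site 2 fine; site 3 one missing of 10 ->
  # kept but monomorphic among non-missing -> dropped by MAF; site 4 has 30%
  # het -> dropped; site 5 30% missing -> dropped
  expect_equal(colnames(f0$calls), "chr1:20")
  # all-monomorphic matrix leaves nothing
  mono <- snp_matrix(matrix(2L, 4, 3), sites_df(3))
  expect_warning(fm <- qc_filter_snps(mono), "no SNP")
  expect_equal(ncol(fm$calls), 0L)
  # retained set equals brute-force per-site evaluation on random data
  set.seed(12)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 300, replace = TRUE,
                         prob = c(0.45, 0.05, 0.4, 0.1)), 15, 20)
  m <- snp_matrix(calls, sites_df(20))
  f <- suppressWarnings(qc_filter_snps(m, 0.2, 0.1, 0.05))
  manual <- vapply(seq_len(20), function(j) {
    col <- calls[, j]
    het <- mean(col == 1L, na.rm = TRUE)
    if (is.nan(het)) het <- 1
    col[col == 1L] <- NA
    miss <- mean(is.na(col))
    p <- mean(col, na.rm = TRUE) / 2
    if (is.nan(p)) p <- 0
    het <= 0.1 && miss <= 0.2 && min(p, 1 - p) >= 0.05
  }, logical(1))
  expect_equal(colnames(f$calls), colnames(m$calls)[manual])
})

test_that("perfectly linked sites form one block, independent sites split", {
  x <- c(0, 0, 2, 2, 0, 2, 0, 2)
  m <- snp_matrix(cbind(x, x), sites_df(2))
  h <- assemble_snpldb(m)
  expect_equal(ncol(h$geno), 1L)
  expect_equal(h$loci$n_haplotypes, 2L)
  expect_equal(h$loci$n_sites, 2L)

  x3 <- c(2, 2, 0, 0)
  y3 <- c(2, 0, 2, 0) # D' = 0 by construction
  m2 <- snp_matrix(cbind(x3, y3), sites_df(2))
  h2 <- assemble_snpldb(m2)
  expect_equal(ncol(h2$geno), 2L)
  expect_equal(h2$loci$n_sites, c(1L, 1L))
})

test_that("blocks tile the retained sites and haplotype frequencies sum to 1", {
  set.seed(5)
  cfg <- sim_config(founders_per_region = 5L, generations = 2L,
                    crosses_per_generation = 8L, n_chromosomes = 2L,
                    snps_per_chromosome = 40L, seed = 5L)
  prog <- simulate_program(cfg)
  qc <- suppressWarnings(qc_filter_snps(prog$snps))
  h <- assemble_snpldb(qc)
  # tiling: every site in exactly one block, blocks contiguous
  expect_equal(length(h$site_block), ncol(qc$calls))
  expect_equal(sort(unique(h$site_block)), seq_len(ncol(h$geno)))
  expect_equal(sum(h$loci$n_sites), ncol(qc$calls))
  expect_true(all(diff(h$site_block) %in% c(0L, 1L)))
  for (k in seq_len(ncol(h$geno))) {
    fr <- attr(h$catalog[[k]], "freq")
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_equal(h$loci$n_haplotypes[k], length(h$catalog[[k]]))
    expect_lte(max(h$geno[, k], na.rm = TRUE), length(h$catalog[[k]]))
  }
  # blocked pairs really exceed the threshold pairwise
  multi <- which(h$loci$n_sites > 1L)[1]
  if (!is.na(multi)) {
    sset <- which(h$site_block == multi)
    for (i in sset) for (j in sset) if (i < j) {
      expect_gt(abs(dprime(qc$calls[, i], qc$calls[, j])), 0.7)
    }
  }
})

test_that("rare haplotype classes merge into a single rare class", {
  x <- c(rep(0, 60), rep(2, 39), 2)
  y <- c(rep(0, 60), rep(2, 39), 0) # last sample: rare haplotype "10"
  m <- snp_matrix(cbind(x, y), sites_df(2))
  h <- assemble_snpldb(m, dprime_threshold = 0.7, rare_floor = 0.02)
  expect_equal(ncol(h$geno), 1L)
  expect_equal(h$catalog[[1]][length(h$catalog[[1]])], "rare")
  expect_equal(h$loci$n_haplotypes, 3L)
  expect_equal(sum(attr(h$catalog[[1]], "freq")), 1)
  # the rare sample is coded to the rare class
  expect_equal(unname(h$geno[100, 1]), 3L)
})

test_that("hap matrix and block map round-trip through TSV", {
  set.seed(9)
  g <- hm(matrix(sample(1:3, 30, replace = TRUE), 5, 6))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hap_matrix(g, f)
  g2 <- read_hap_matrix(f)
  expect_equal(g2$geno, g$geno, ignore_attr = TRUE)
  expect_equal(g2$samples, g$samples)
})
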