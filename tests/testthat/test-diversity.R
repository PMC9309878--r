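test_that("richness counts distinct haplotypes per locus", {
  g <- hm(cbind(c(1L, 1L, 1L), c(1L, 2L, 2L), c(1L, 2L, 3L)))
  r <- richness_summary(g)
  expect_equal(r$total_alleles, 1L + 2L + 3L)
  expect_equal(r$per_locus_mean, 2)
  expect_equal(r$per_locus_max, 3L)
  expect_equal(r$allele_load_per_cultivar, 2)
  # one sample: one allele per locus
  r1 <- richness_summary(g, "S1")
  expect_equal(r1$total_alleles, 3L)
  expect_equal(r1$per_locus_mean, 1)
  expect_error(richness_summary(g, character()), "empty")
  # random subset equals brute-force set-union count
  set.seed(2)
  gg <- hm(matrix(sample(c(1:4, NA), 200, replace = TRUE), 10, 20))
  sub <- sample(gg$samples, 6L)
  r2 <- richness_summary(gg, sub)
  manual <- sum(vapply(seq_len(20), function(k)
    length(unique(na.omit(gg$geno[sub, k]))), integer(1)))
  expect_equal(r2$total_alleles, manual)
})

test_that("richness summaries reproduce the published allele-load ratios", {
  # subpopulation totals: 74,386 distinct haplotypes over 28,066 loci in a
  # 279-cultivar panel -> allele load 266.62
  n_loci <- 28066L; n3 <- 74386L - 2L * n_loci
  alleles_per_locus <- rep(2L, n_loci)
  alleles_per_locus[seq_len(n3)] <- 3L
  geno <- matrix(1L, nrow = 279L, ncol = n_loci)
  geno[1, ] <- ifelse(alleles_per_locus >= 2L, 2L, 1L)
  geno[2, ] <- ifelse(alleles_per_locus >= 3L, 3L, 1L)
  r <- richness_summary(hm(geno))
  expect_equal(r$total_alleles, 74386L)
  expect_equal(round(r$allele_load_per_cultivar, 2), 266.62)
  # population level: 84,069 haplotypes over the same loci -> 3.00 per locus
  n3b <- 84069L - 2L * n_loci
  gb <- matrix(1L, nrow = 3L, ncol = n_loci)
  gb[2, ] <- 2L
  gb[3, seq_len(n3b)] <- 3L
  rb <- richness_summary(hm(gb))
  expect_equal(rb$total_alleles, 84069L)
  expect_equal(round(rb$per_locus_mean, 2), 3.00)
})

test_that("pi follows the n/(n-1) sum p(1-p) form", {
  # monomorphic locus
  expect_equal(pi_dispersion(hm(matrix(1L, 4, 1)))$mean, 0)
  # n = 2, two haplotypes at 0.5: 2/1 * (0.25 + 0.25) = 1
  expect_equal(pi_dispersion(hm(matrix(c(1L, 2L), 2, 1)))$mean, 1)
  expect_error(pi_dispersion(hm(matrix(1L, 1, 1))), "two samples")
  # random loci match brute-force recomputation
  set.seed(3)
  g <- hm(matrix(sample(c(1:3, NA), 120, replace = TRUE), 8, 15))
  got <- pi_dispersion(g)
  manual <- vapply(seq_len(15), function(k) {
    col <- na.omit(g$geno[, k]); n <- length(col)
    if (n < 2) return(NA_real_)
    p <- as.numeric(table(col)) / n
    n / (n - 1) * sum(p * (1 - p))
  }, numeric(1))
  expect_equal(got$per_locus, manual, ignore_attr = TRUE)
  expect_equal(got$mean, mean(manual, na.rm = TRUE))
  expect_true(all(got$per_locus >= 0 & got$per_locus <= 1, na.rm = TRUE))
})

test_that("SPA and SDA count population-specific alleles", {
  # identical populations: nothing specific
  geno <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 2L), c(2L, 1L))
  part <- setNames(c("X", "X", "Y", "Y"), paste0("S", 1:4))
  res <- spa_sda(hm(geno), part)
  expect_equal(res$spa, c(0L, 0L))
  expect_equal(res$sda, c(0L, 0L))
  expect_error(spa_sda(hm(geno), setNames(rep("X", 4), paste0("S", 1:4))),
               "two populations")
  # population A uniquely carries k haplotypes
  geno2 <- rbind(c(3L, 4L, 5L), # A: three private haplotypes
                 c(1L, 1L, 1L),
                 c(1L, 1L, 1L), # B
                 c(1L, 1L, 1L)) # C
  part2 <- setNames(c("A", "A", "B", "C"), paste0("S", 1:4))
  res2 <- spa_sda(hm(geno2), part2)
  expect_equal(res2$spa[res2$population == "A"], 3L)
  # B and C lack nothing that all others share exclusively
  expect_equal(res2$sda[res2$population == "A"], 0L)
  # random partitions match a brute-force presence-table scan
  set.seed(6)
  g <- hm(matrix(sample(c(1:4, NA), 300, replace = TRUE), 12, 25))
  part3 <- setNames(sample(c("P", "Q", "R"), 12, replace = TRUE),
                    g$samples)
  res3 <- spa_sda(g, part3)
  pops <- sort(unique(part3))
  for (pp in pops) {
    spa <- 0L; sda <- 0L
    for (k in 1:25) {
      pres <- lapply(pops, function(q)
        unique(na.omit(g$geno[names(part3)[part3 == q], k])))
      names(pres) <- pops
      all_h <- sort(unique(unlist(pres)))
      for (u in all_h) {
        inp <- u %in% pres[[pp]]
        others <- vapply(setdiff(pops, pp), function(q)
          u %in% pres[[q]], logical(1))
        if (inp && !any(others)) spa <- spa + 1L
        if (!inp && all(others)) sda <- sda + 1L
      }
    }
    expect_equal(res3$spa[res3$population == pp], spa)
    expect_equal(res3$sda[res3$population == pp], sda)
  }
  # an SPA allele belongs to at most one population
  expect_lte(sum(res3$spa), richness_summary(g)$total_alleles)
})

test_that("diversity_table combines richness, pi and specificity", {
  set.seed(11)
  g <- hm(matrix(sample(1:3, 80, replace = TRUE), 8, 10))
  part <- setNames(rep(c("X", "Y"), each = 4), g$samples)
  dt <- diversity_table(g, part)
  expect_equal(dt$population, c("X", "Y", "ALL"))
  expect_equal(dt$n, c(4L, 4L, 8L))
  expect_equal(dt$total_alleles[3],
               richness_summary(g)$total_alleles)
  expect_true(all(dt$pi_mean >= 0 & dt$pi_mean <= 1))
})
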