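small_cfg <- function(...) {
  args <- utils::modifyList(
    list(founders_per_region = 4L, generations = 2L,
         crosses_per_generation = 6L, n_chromosomes = 2L,
         snps_per_chromosome = 30L),
    list(...))
  do.call(sim_config, args)
}

test_that("zero generations leaves only founder records", {
  g <- simulate_breeding_program(small_cfg(generations = 0L, seed = 1L))
  expect_equal(nrow(g$records), 12L)
  expect_setequal(g$records$method, "terminal")
})

test_that("the simulator is deterministic given the seed", {
  a <- simulate_program(small_cfg(seed = 5L))
  b <- simulate_program(small_cfg(seed = 5L))
  expect_identical(a$graph$records, b$graph$records)
  expect_identical(a$snps$calls, b$snps$calls)
  c <- simulate_program(small_cfg(seed = 6L))
  expect_false(identical(a$graph$records, c$graph$records) &&
                 identical(a$snps$calls, c$snps$calls))
})

test_that("without migration every lineage stays inside its region", {
  g <- simulate_breeding_program(small_cfg(migration_rate = 0, seed = 11L))
  for (id in ped_ids(g)) {
    reg <- g$records[id, "ecoregion"]
    anc_regions <- g$records[terminal_ancestors(g, id), "ecoregion"]
    expect_true(all(anc_regions == reg), info = id)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(founders_per_region = 0L))
  expect_error(sim_config(divergence = 2))
  expect_error(sim_config(migration_rate = -0.1))
})

test_that("divergence creates region-private alleles, none without divergence", {
  cfg1 <- small_cfg(divergence = 1, generations = 0L,
                    founders_per_region = 6L, seed = 21L)
  g1 <- simulate_breeding_program(cfg1)
  fh1 <- simulate_founder_haplotypes(cfg1, g1)
  snps1 <- gene_drop(g1, fh1, recomb_per_block = 0, seed = 22L)
  h1 <- assemble_snpldb(suppressWarnings(
    qc_filter_snps(snps1, min_maf = 0.01)))
  part1 <- setNames(g1$records$ecoregion, g1$records$id)[h1$samples]
  res1 <- spa_sda(h1, part1)
  expect_true(all(res1$spa > 0))

  # with many founders per region and few prototype classes, every common
  # haplotype is sampled by every region and private alleles stay rare
  cfg0 <- small_cfg(divergence = 0, generations = 0L,
                    founders_per_region = 30L, n_prototypes = 2L,
                    seed = 23L)
  g0 <- simulate_breeding_program(cfg0)
  fh0 <- simulate_founder_haplotypes(cfg0, g0)
  # identical regional prototype frequencies: private alleles arise only
  # from sampling noise, so they stay far below the divergent case
  snps0 <- gene_drop(g0, fh0, recomb_per_block = 0, seed = 24L)
  h0 <- assemble_snpldb(suppressWarnings(qc_filter_snps(snps0)))
  part0 <- setNames(g0$records$ecoregion, g0$records$id)[h0$samples]
  res0 <- spa_sda(h0, part0)
  expect_lt(mean(res0$spa), mean(res1$spa))
})

test_that("selection children copy their source genotype exactly", {
  cfg <- small_cfg(selection_fraction = 0.6, seed = 31L)
  prog <- simulate_program(cfg)
  rec <- prog$graph$records
  sels <- rec$id[rec$method == "selection"]
  expect_gt(length(sels), 0L)
  for (id in sels) {
    src <- rec[id, "female_or_source"]
    expect_identical(prog$snps$calls[id, ], prog$snps$calls[src, ])
  }
})

test_that("cross children inherit whole parental blocks when recombination is off", {
  cfg <- small_cfg(seed = 41L, recomb_per_block = 0,
                   mutation_site_fraction = 0)
  g <- simulate_breeding_program(cfg)
  fh <- simulate_founder_haplotypes(cfg, g)
  snps <- gene_drop(g, fh, recomb_per_block = 0,
                    mutation_site_fraction = 0, seed = 42L)
  rec <- g$records
  crosses <- rec$id[rec$method == "cross"]
  for (id in crosses) {
    f <- rec[id, "female_or_source"]; m <- rec[id, "male"]
    for (k in seq_along(fh$block_sites)) {
      s <- fh$block_sites[[k]]
      child <- snps$calls[id, s]
      expect_true(identical(child, snps$calls[f, s]) ||
                    identical(child, snps$calls[m, s]),
                  info = paste(id, "block", k))
    }
  }
})

test_that("block transmission is a fair coin over many blocks", {
  # one cross of two founders fixed for different alleles, 1000 blocks
  cfg <- sim_config(n_regions = 1L, founders_per_region = 2L,
                    generations = 0L, crosses_per_generation = 1L,
                    n_chromosomes = 1L, snps_per_chromosome = 1000L,
                    block_length_mean = 1L, divergence = 0, seed = 51L)
  g <- ped_graph(data.frame(
    id = c("NNC_F01", "NNC_F02", "X"), name = "x",
    method = c("terminal", "terminal", "cross"),
    female_or_source = c(NA, NA, "NNC_F01"), male = c(NA, NA, "NNC_F02"),
    ecoregion = "NNC", period = "UNKNOWN"))
  fh <- simulate_founder_haplotypes(cfg, g)
  # overwrite founder haplotypes to be fully distinct
  for (k in seq_along(fh$block_sites)) {
    fh$prototypes[[k]] <- rbind(rep(0L, length(fh$block_sites[[k]])),
                                rep(1L, length(fh$block_sites[[k]])))
    fh$founder_blocks[, k] <- c(1L, 2L)
  }
  snps <- gene_drop(g, fh, recomb_per_block = 0, seed = 52L)
  female_frac <- mean(snps$calls["X", ] == snps$calls["NNC_F01", ])
  expect_gt(female_frac, 0.45)
  expect_lt(female_frac, 0.55)
})

test_that("gene-dropped CGS matches the COP-founder IBS mixture in expectation", {
  # cross-only pedigree; E[CGS_ij] = COP_ij + (1 - COP_ij) * sbar_founders
  cfg <- sim_config(n_regions = 1L, founders_per_region = 6L,
                    generations = 3L, crosses_per_generation = 8L,
                    selection_fraction = 0, migration_rate = 0,
                    n_chromosomes = 2L, snps_per_chromosome = 100L,
                    block_length_mean = 4L, divergence = 0,
                    recomb_per_block = 0, seed = 61L)
  g <- simulate_breeding_program(cfg)
  fh <- simulate_founder_haplotypes(cfg, g)
  founders <- terminal_ids(g)
  nonf <- setdiff(ped_ids(g), founders)
  pair <- nonf[1:2]
  reps <- 60L
  sims <- vapply(seq_len(reps), function(r) {
    snps <- gene_drop(g, fh, recomb_per_block = 0, seed = 1000L + r)
    # site-level identity-by-state between the two lines
    mean(snps$calls[pair[1], ] == snps$calls[pair[2], ])
  }, numeric(1))
  p_cop <- cop(g, pair[1], pair[2])
  # founder-level mean site identity
  fcalls <- gene_drop(g, fh, recomb_per_block = 0, seed = 999L)$calls
  sbar <- mean(vapply(seq_along(founders), function(i)
    vapply(seq_along(founders), function(j)
      if (i < j) mean(fcalls[founders[i], ] == fcalls[founders[j], ])
      else NA_real_, numeric(1)), numeric(length(founders))), na.rm = TRUE)
  expected <- p_cop + (1 - p_cop) * sbar
  se <- sd(sims) / sqrt(reps)
  expect_lt(abs(mean(sims) - expected), 4 * se + 0.02)
})
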