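#' Simulation configuration for a multi-ecoregion breeding program
#'
#' Defaults emulate a three-ecoregion inbred breeding program: regionally
#' diverged founder pools, generations of crossing with occasional
#' cross-region parents, a fraction of lines re-derived by pure-line
#' selection, and genotypes transmitted down the pedigree in linked blocks.
#'
#' @param n_regions number of ecoregions (default 3, labelled from the
#'   NNC/HHH/SC convention when <= 3).
#' @param founders_per_region founder landraces per region (default 10).
#' @param generations breeding generations after the founders (default 5).
#' @param crosses_per_generation new cross-bred cultivars per generation
#'   (default 20).
#' @param selection_fraction probability a new cultivar is re-released as a
#'   pure-line selection of an existing line instead of a cross (default
#'   0.1).
#' @param migration_rate probability that one parent of a cross comes from
#'   another region (default 0.05).
#' @param divergence founder allele-frequency divergence among regions in
#'   `[0, 1]` (default 0.6; 0 = identical founder pools, 1 = regions fixed
#'   for private block haplotypes).
#' @param n_chromosomes,snps_per_chromosome genome size (defaults 3 x 200).
#' @param block_length_mean mean SNPs per linked founder block (default 5).
#' @param n_prototypes ancestral haplotype prototypes per block (default 4).
#' @param recomb_per_block within-block recombination probability per
#'   transmission (default 0.01).
#' @param mutation_site_fraction fraction of sites flipped in a mutant
#'   (default 0.005).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 3L, founders_per_region = 10L,
                       generations = 5L, crosses_per_generation = 20L,
                       selection_fraction = 0.1, migration_rate = 0.05,
                       divergence = 0.6, n_chromosomes = 3L,
                       snps_per_chromosome = 200L, block_length_mean = 5L,
                       n_prototypes = 4L, recomb_per_block = 0.01,
                       mutation_site_fraction = 0.005, seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              founders_per_region = as.integer(founders_per_region),
              generations = as.integer(generations),
              crosses_per_generation = as.integer(crosses_per_generation),
              selection_fraction = selection_fraction,
              migration_rate = migration_rate, divergence = divergence,
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              block_length_mean = as.integer(block_length_mean),
              n_prototypes = as.integer(n_prototypes),
              recomb_per_block = recomb_per_block,
              mutation_site_fraction = mutation_site_fraction,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_regions >= 1L, founders_per_region >= 1L, generations >= 0L,
              crosses_per_generation >= 1L,
              selection_fraction >= 0, selection_fraction <= 1,
              migration_rate >= 0, migration_rate <= 1,
              divergence >= 0, divergence <= 1,
              n_chromosomes >= 1L, snps_per_chromosome >= 1L,
              block_length_mean >= 1L, n_prototypes >= 2L,
              recomb_per_block >= 0, recomb_per_block <= 1)
  })
  class(cfg) <- "sim_config"
  cfg
}

.sim_region_names <- function(k) {
  base <- c("NNC", "HHH", "SC")
  if (k <= 3L) base[seq_len(k)] else c(base, paste0("R", 4:k))[seq_len(k)]
}

#' Simulate a breeding-program pedigree
#'
#' Founders become terminal records, one per region pool. Each generation
#' draws parent pairs from the accumulated lines (the second parent from
#' another region with probability `migration_rate`) and emits cross
#' children; a `selection_fraction` share of the new lines are instead
#' pure-line selections of an existing line. Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @return a [ped_graph()] with `ecoregion` metadata; founder records are
#'   the terminal ancestors.
#' @export
simulate_breeding_program <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rng <- .local_rng(cfg$seed)
  regions <- .sim_region_names(cfg$n_regions)
  rec <- data.frame(id = character(), name = character(),
                    method = character(), female_or_source = character(),
                    male = character(), ecoregion = character(),
                    period = character(), stringsAsFactors = FALSE)
  for (r in seq_along(regions)) {
    ids <- sprintf("%s_F%02d", regions[r], seq_len(cfg$founders_per_region))
    rec <- rbind(rec, data.frame(
      id = ids, name = ids, method = "terminal",
      female_or_source = NA_character_, male = NA_character_,
      ecoregion = regions[r], period = "P1923_2005",
      stringsAsFactors = FALSE))
  }
  pool <- split(rec$id, rec$ecoregion)[regions]
  draw <- function(v) v[ceiling(rng$runif(1) * length(v))]
  for (gen in seq_len(cfg$generations)) {
    for (i in seq_len(cfg$crosses_per_generation)) {
      reg <- draw(seq_along(regions))
      id <- sprintf("%s_G%dC%02d", regions[reg], gen, i)
      if (rng$runif(1) < cfg$selection_fraction) {
        src <- draw(pool[[reg]])
        rec <- rbind(rec, data.frame(
          id = id, name = id, method = "selection",
          female_or_source = src, male = NA_character_,
          ecoregion = regions[reg], period = "P2006_2015",
          stringsAsFactors = FALSE))
      } else {
        fem <- draw(pool[[reg]])
        other <- if (cfg$n_regions > 1L && rng$runif(1) < cfg$migration_rate)
          draw(seq_along(regions)[-reg]) else reg
        mal <- draw(setdiff(pool[[other]], fem))
        if (length(mal) == 0L || is.na(mal)) next
        rec <- rbind(rec, data.frame(
          id = id, name = id, method = "cross",
          female_or_source = fem, male = mal,
          ecoregion = regions[reg], period = "P2006_2015",
          stringsAsFactors = FALSE))
      }
      pool[[reg]] <- c(pool[[reg]], id)
    }
  }
  ped_graph(rec)
}

#' Simulate founder block haplotypes with regional divergence
#'
#' The genome is partitioned into linked blocks (geometric length, mean
#' `block_length_mean` SNPs, clipped at chromosome ends). Each block carries
#' `n_prototypes` ancestral haplotype prototypes (random biallelic strings);
#' every region draws its own prototype frequencies from a Balding-Nichols
#' style Dirichlet centred on shared base weights with concentration
#' `(1 - divergence) / divergence`, so divergence 0 gives identical pools
#' and divergence 1 fixes each region on a single (often private)
#' prototype. Founders then draw one prototype per block.
#'
#' @param cfg a [sim_config()].
#' @return list with `sites` (chrom/pos/ref/alt data.frame), `block_of_site`
#'   (block index per site), `block_sites` (list of site indices),
#'   `prototypes` (per block: matrix prototypes x sites-in-block of 0/1),
#'   `founder_blocks` (founder x block matrix of prototype indices),
#'   `founder_ids`, `founder_region`.
#' @export
simulate_founder_haplotypes <- function(cfg, graph = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  rng <- .local_rng(cfg$seed + 1L)
  if (is.null(graph)) graph <- simulate_breeding_program(cfg)
  founders <- terminal_ids(graph)
  freg <- graph$records[founders, "ecoregion"]
  regions <- .sim_region_names(cfg$n_regions)
  nsite_total <- cfg$n_chromosomes * cfg$snps_per_chromosome
  sites <- data.frame(
    chrom = rep(sprintf("chr%02d", seq_len(cfg$n_chromosomes)),
                each = cfg$snps_per_chromosome),
    pos = rep(seq_len(cfg$snps_per_chromosome) * 100L, cfg$n_chromosomes),
    ref = "A", alt = "T", stringsAsFactors = FALSE)
  # geometric block lengths within chromosomes
  block_of_site <- integer(nsite_total)
  bid <- 0L
  for (ch in seq_len(cfg$n_chromosomes)) {
    offset <- (ch - 1L) * cfg$snps_per_chromosome
    pos <- 1L
    while (pos <= cfg$snps_per_chromosome) {
      len <- 1L + stats::qgeom(rng$runif(1),
                               prob = 1 / cfg$block_length_mean)
      len <- min(len, cfg$snps_per_chromosome - pos + 1L)
      bid <- bid + 1L
      block_of_site[offset + pos:(pos + len - 1L)] <- bid
      pos <- pos + len
    }
  }
  block_sites <- split(seq_len(nsite_total), block_of_site)
  nb <- length(block_sites)
  K <- cfg$n_prototypes
  prototypes <- vector("list", nb)
  founder_blocks <- matrix(NA_integer_, length(founders), nb,
                           dimnames = list(founders, NULL))
  dirichlet <- function(alpha) {
    x <- vapply(alpha, function(a)
      stats::qgamma(max(min(rng$runif(1), 1 - 1e-12), 1e-12), shape = a),
      numeric(1))
    if (sum(x) == 0) x <- rep(1, length(alpha))
    x / sum(x)
  }
  for (k in seq_len(nb)) {
    L <- length(block_sites[[k]])
    Kb <- min(K, 2^min(L, 20L)) # short blocks cannot carry K distinct strings
    proto <- matrix(as.integer(rng$runif(Kb * L) < 0.5), Kb, L)
    # ensure prototypes are distinct haplotype strings
    if (Kb > 1L) for (q in 2:Kb) {
      while (any(apply(proto[seq_len(q - 1L), , drop = FALSE], 1L,
                       identical, y = proto[q, ]))) {
        proto[q, ] <- as.integer(rng$runif(L) < 0.5)
      }
    }
    prototypes[[k]] <- proto
    base <- dirichlet(rep(1, Kb))
    for (r in seq_along(regions)) {
      w <- if (cfg$divergence == 0) {
        base
      } else if (cfg$divergence >= 1) {
        v <- numeric(K)
        v[which(rng$runif(1) <= cumsum(base))[1]] <- 1
        v
      } else {
        dirichlet(base * (1 - cfg$divergence) / cfg$divergence)
      }
      idx <- which(freg == regions[r])
      for (f in idx) {
        founder_blocks[f, k] <- which(rng$runif(1) <= cumsum(w))[1]
      }
    }
    unknown <- which(!freg %in% regions)
    for (f in unknown)
      founder_blocks[f, k] <- which(rng$runif(1) <= cumsum(base))[1]
  }
  list(sites = sites, block_of_site = block_of_site,
       block_sites = block_sites, prototypes = prototypes,
       founder_blocks = founder_blocks, founder_ids = founders,
       founder_region = stats::setNames(freg, founders))
}

#' Gene-drop genotypes down a pedigree
#'
#' Fully-inbred transmission: a cross child inherits, independently per
#' linked block, the block haplotype of its female or male parent with
#' probability 1/2 each (with probability `recomb_per_block` the block is
#' instead recombined: a switch point splits it between the two parental
#' haplotypes), and is instantly homozygous. Selection children copy their
#' source; mutation children copy the source and flip a small fraction of
#' sites. Deterministic given the seed.
#'
#' @param graph a [ped_graph()].
#' @param founder_haps output of [simulate_founder_haplotypes()].
#' @param recomb_per_block within-block recombination probability.
#' @param mutation_site_fraction fraction of sites flipped for mutation
#'   records.
#' @param seed integer seed.
#' @return a [snp_matrix()] of homozygous dosages (0/2) for every cultivar
#'   in the graph.
#' @export
gene_drop <- function(graph, founder_haps, recomb_per_block = 0.01,
                      mutation_site_fraction = 0.005, seed = 1L) {
  rng <- .local_rng(seed)
  fh <- founder_haps
  nsite <- nrow(fh$sites)
  ids <- ped_ids(graph)
  # topological order: parents before children
  depths <- .ped_depths(graph)
  ids <- ids[order(depths[ids])]
  hap <- matrix(NA_integer_, length(ids), nsite,
                dimnames = list(ids, NULL))
  founder_string <- function(f) {
    out <- integer(nsite)
    for (k in seq_along(fh$block_sites)) {
      out[fh$block_sites[[k]]] <-
        fh$prototypes[[k]][fh$founder_blocks[f, k], ]
    }
    out
  }
  for (id in ids) {
    ps <- ped_parents(graph, id)
    if (length(ps) == 0L) {
      if (!id %in% fh$founder_ids)
        stop("founder '", id, "' has no simulated haplotype")
      hap[id, ] <- founder_string(id)
    } else if (length(ps) == 1L) {
      h <- hap[ps, ]
      if (graph$records[id, "method"] == "mutation" &&
          mutation_site_fraction > 0) {
        flip <- rng$runif(nsite) < mutation_site_fraction
        h[flip] <- 1L - h[flip]
      }
      hap[id, ] <- h
    } else {
      hf <- hap[ps[[1]], ]; hm <- hap[ps[[2]], ]
      child <- integer(nsite)
      for (k in seq_along(fh$block_sites)) {
        s <- fh$block_sites[[k]]
        from_female <- rng$runif(1) < 0.5
        blk <- if (from_female) hf[s] else hm[s]
        if (length(s) > 1L && rng$runif(1) < recomb_per_block) {
          cut <- 1L + floor(rng$runif(1) * (length(s) - 1L))
          blk <- c(if (from_female) hf[s[seq_len(cut)]] else hm[s[seq_len(cut)]],
                   if (from_female) hm[s[-seq_len(cut)]] else hf[s[-seq_len(cut)]])
        }
        child[s] <- blk
      }
      hap[id, ] <- child
    }
  }
  snp_matrix(hap * 2L, fh$sites)
}

#' Simulate a complete breeding program with genotypes
#'
#' Convenience wrapper: pedigree, founder haplotypes, gene-dropped SNP
#' genotypes and the region label of every cultivar.
#'
#' @param cfg a [sim_config()].
#' @return list with `graph`, `founder_haps`, `snps` (a [snp_matrix()]),
#'   `regions` (named vector id -> region).
#' @export
simulate_program <- function(cfg) {
  graph <- simulate_breeding_program(cfg)
  fh <- simulate_founder_haplotypes(cfg, graph)
  snps <- gene_drop(graph, fh, recomb_per_block = cfg$recomb_per_block,
                    mutation_site_fraction = cfg$mutation_site_fraction,
                    seed = cfg$seed + 2L)
  regions <- stats::setNames(graph$records$ecoregion, graph$records$id)
  list(graph = graph, founder_haps = fh, snps = snps, regions = regions)
}
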