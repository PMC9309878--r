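# Shared fixtures and independent oracles. Oracles deliberately take a
# different computational route from the package implementation they check.

nannong_graph <- function() {
  read_pedigree(system.file("extdata", "nannong32_pedigree_synthetic.tsv",
                            package = "germtrace"))
}

# random valid pedigree built directly from record rows (independent of the
# package's breeding-program simulator)
random_pedigree <- function(seed, n_founders = 5L, n_events = 12L,
                            p_selection = 0.25) {
  set.seed(seed)
  ids <- paste0("F", seq_len(n_founders))
  rec <- data.frame(id = ids, name = ids, method = "terminal",
                    female_or_source = NA_character_, male = NA_character_,
                    ecoregion = sample(c("NNC", "HHH", "SC"), n_founders,
                                       replace = TRUE),
                    period = "UNKNOWN", stringsAsFactors = FALSE)
  pool <- ids
  for (i in seq_len(n_events)) {
    id <- paste0("D", i)
    if (stats::runif(1) < p_selection || length(pool) < 2L) {
      src <- sample(pool, 1L)
      rec <- rbind(rec, data.frame(id = id, name = id, method = "selection",
                                   female_or_source = src,
                                   male = NA_character_,
                                   ecoregion = "UNKNOWN", period = "UNKNOWN",
                                   stringsAsFactors = FALSE))
    } else {
      ps <- sample(pool, 2L)
      rec <- rbind(rec, data.frame(id = id, name = id, method = "cross",
                                   female_or_source = ps[1], male = ps[2],
                                   ecoregion = "UNKNOWN", period = "UNKNOWN",
                                   stringsAsFactors = FALSE))
    }
    pool <- c(pool, id)
  }
  ped_graph(rec)
}

# explicit enumeration of every parental path: founder weights as
# sum over paths of (1/2)^(#cross steps), founders reached, max cross count
path_enumeration <- function(graph, cultivar) {
  rec <- graph$records
  paths <- list()
  walk <- function(id, w, ncross) {
    ps <- germtrace:::ped_parents(graph, id)
    if (length(ps) == 0L) {
      paths[[length(paths) + 1L]] <<- list(anc = id, w = w, ncross = ncross)
      return(invisible())
    }
    if (rec[id, "method"] == "cross") {
      walk(ps[[1]], w / 2, ncross + 1L)
      walk(ps[[2]], w / 2, ncross + 1L)
    } else {
      walk(ps[[1]], w, ncross)
    }
  }
  walk(cultivar, 1, 0L)
  anc <- vapply(paths, `[[`, character(1), "anc")
  w <- vapply(paths, `[[`, numeric(1), "w")
  nc <- vapply(paths, `[[`, integer(1), "ncross")
  list(contrib = tapply(w, anc, sum),
       ancestors = sort(unique(anc)),
       max_cross = tapply(nc, anc, max))
}

# plain unmemoized COP recursion driven by ancestor-set checks instead of
# the implementation's depth bookkeeping
cop_oracle <- function(graph, a, b) {
  rec <- graph$records
  expand <- function(x, y) {
    ps <- germtrace:::ped_parents(graph, x)
    if (length(ps) == 0L) return(0)
    if (length(ps) == 1L) {
      if (ps == y) 0.75 else 0.75 * cop_oracle(graph, ps, y)
    } else {
      0.5 * (cop_oracle(graph, ps[[1]], y) + cop_oracle(graph, ps[[2]], y))
    }
  }
  if (a == b) return(1)
  if (b %in% all_ancestors(graph, a)) return(expand(a, b))
  if (a %in% all_ancestors(graph, b)) return(expand(b, a))
  if (rec[a, "method"] != "terminal") return(expand(a, b))
  expand(b, a)
}

# single-locus gene dropping with unique founder alleles, vectorized over
# replicates; returns reps x cultivars matrix of founder labels
ibd_drop <- function(graph, reps, seed) {
  set.seed(seed)
  depths <- germtrace:::.ped_depths(graph)
  ids <- ped_ids(graph)[order(depths[ped_ids(graph)])]
  out <- matrix(NA_integer_, reps, length(ids),
                dimnames = list(NULL, ids))
  for (id in ids) {
    ps <- germtrace:::ped_parents(graph, id)
    out[, id] <- if (length(ps) == 0L) {
      rep(match(id, ids), reps)
    } else if (length(ps) == 1L) {
      out[, ps]
    } else {
      ifelse(stats::runif(reps) < 0.5, out[, ps[[1]]], out[, ps[[2]]])
    }
  }
  out
}

# Weir-Cockerham components via the three-level (population / individual /
# gamete) ANOVA mean squares, per allele, summed over loci
fst_anova_oracle <- function(g, popA, popB) {
  geno <- g$geno
  sum_a <- 0; sum_abc <- 0
  for (k in seq_len(ncol(geno))) {
    xa <- geno[popA, k]; xa <- xa[!is.na(xa)]
    xb <- geno[popB, k]; xb <- xb[!is.na(xb)]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 1L || n2 < 1L) next
    alleles <- sort(unique(c(xa, xb)))
    if (length(alleles) < 2L) next
    N <- n1 + n2
    nc <- (N - (n1^2 + n2^2) / N) / 1
    for (u in alleles) {
      ya <- as.numeric(xa == u); yb <- as.numeric(xb == u)
      m1 <- mean(ya); m2 <- mean(yb)
      mall <- (n1 * m1 + n2 * m2) / N
      msg <- 0 # homozygous: both gametes identical within an individual
      ssi <- 2 * (sum((ya - m1)^2) + sum((yb - m2)^2))
      msi <- ssi / (N - 2)
      ssp <- 2 * (n1 * (m1 - mall)^2 + n2 * (m2 - mall)^2)
      msp <- ssp / 1
      a <- (msp - msi) / (2 * nc)
      b <- (msi - msg) / 2
      cc <- msg
      sum_a <- sum_a + a
      sum_abc <- sum_abc + a + b + cc
    }
  }
  sum_a / sum_abc
}

# tiny hap_matrix straight from an integer matrix
hm <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  hap_matrix(m)
}

# random additive tree metric: random topology + exponential branch lengths
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::rexp(k, rate = 5) + 0.05)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
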