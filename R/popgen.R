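.hap_subset <- function(g, subset) {
  if (is.null(subset)) return(g$geno)
  miss <- setdiff(subset, g$samples)
  if (length(miss)) stop("unknown sample id: ", paste(miss, collapse = ", "))
  g$geno[subset, , drop = FALSE]
}

#' Genetic richness summary of a (sub)population
#'
#' Counts the distinct haplotypes (alleles) observed in the subset at every
#' SNPLDB locus. The total over loci is the genetic richness; the allele
#' load per cultivar is `total / n`, smaller in populations whose members
#' share more of the catalogue.
#'
#' @param g a [hap_matrix()].
#' @param subset sample ids (default: all samples).
#' @return list with `n_samples`, `n_loci`, `total_alleles`,
#'   `per_locus_mean`, `per_locus_max`, `allele_load_per_cultivar`.
#' @export
richness_summary <- function(g, subset = NULL) {
  geno <- .hap_subset(g, subset)
  if (nrow(geno) == 0L) stop("empty subset")
  per_locus <- apply(geno, 2L, function(col) length(unique(col[!is.na(col)])))
  total <- sum(per_locus)
  list(n_samples = nrow(geno), n_loci = ncol(geno), total_alleles = total,
       per_locus_mean = total / ncol(geno), per_locus_max = max(per_locus),
       allele_load_per_cultivar = total / nrow(geno))
}

#' Allele-frequency dispersion (pi) per locus and averaged
#'
#' `pi = n/(n-1) * sum_i p_i (1 - p_i)` over a locus's haplotype frequencies
#' among the subset's non-missing members, `n` being the number of members
#' scored at the locus. The population value is the unweighted mean over
#' loci. Monomorphic loci have `pi = 0`.
#'
#' @param g a [hap_matrix()].
#' @param subset sample ids (default: all).
#' @return list with `per_locus` (numeric vector), `mean`, `max`.
#' @export
pi_dispersion <- function(g, subset = NULL) {
  geno <- .hap_subset(g, subset)
  if (nrow(geno) < 2L) stop("pi needs at least two samples")
  per_locus <- apply(geno, 2L, function(col) {
    col <- col[!is.na(col)]
    n <- length(col)
    if (n < 2L) return(NA_real_)
    p <- as.numeric(table(col)) / n
    n / (n - 1) * sum(p * (1 - p))
  })
  list(per_locus = per_locus,
       mean = mean(per_locus, na.rm = TRUE),
       max  = max(per_locus, na.rm = TRUE))
}

.presence_tables <- function(g, partition) {
  pops <- sort(unique(unname(partition)))
  lapply(stats::setNames(pops, pops), function(pp) {
    ids <- names(partition)[partition == pp]
    geno <- g$geno[ids, , drop = FALSE]
    lapply(seq_len(ncol(geno)), function(k)
      sort(unique(geno[, k][!is.na(geno[, k])])))
  })
}

#' Specific present and specific deficient alleles per subpopulation
#'
#' SPA of a population: (locus, haplotype) pairs present in it and absent
#' from every other population. SDA: pairs absent from it but present in all
#' other populations.
#'
#' @param g a [hap_matrix()].
#' @param partition named character vector: sample id -> population label
#'   (at least two labels).
#' @return data.frame with columns `population`, `spa`, `sda`.
#' @export
spa_sda <- function(g, partition) {
  pops <- sort(unique(unname(partition)))
  if (length(pops) < 2L) stop("need at least two populations")
  pres <- .presence_tables(g, partition)
  out <- lapply(pops, function(pp) {
    others <- setdiff(pops, pp)
    spa <- 0L; sda <- 0L
    for (k in seq_len(ncol(g$geno))) {
      own <- pres[[pp]][[k]]
      oth <- lapply(others, function(o) pres[[o]][[k]])
      oth_union <- sort(unique(unlist(oth)))
      oth_inter <- Reduce(intersect, oth)
      spa <- spa + length(setdiff(own, oth_union))
      sda <- sda + length(setdiff(oth_inter, own))
    }
    data.frame(population = pp, spa = spa, sda = sda,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Coefficient of genetic similarity (CGS) matrix
#'
#' Identity-by-state similarity over SNPLDB loci:
#' `s_ij = sum_k C_ijk / (2 m)`, where for homozygous lines `C_ijk` is 2 when
#' the two cultivars carry the same haplotype at locus `k` and 0 otherwise,
#' and `m` is the number of loci where both are scored (pairwise-complete).
#' The genetic distance is `d_ij = 1 - s_ij`.
#'
#' @param g a [hap_matrix()].
#' @param subset sample ids (default: all).
#' @return symmetric matrix with unit diagonal; a pair with no overlapping
#'   scored locus is `NA`.
#' @export
cgs_matrix <- function(g, subset = NULL) {
  geno <- .hap_subset(g, subset)
  if (nrow(geno) == 0L) stop("empty subset")
  n <- nrow(geno)
  s <- diag(1, n)
  dimnames(s) <- list(rownames(geno), rownames(geno))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      gi <- geno[i, ]
      for (j in (i + 1L):n) {
        gj <- geno[j, ]
        ok <- !is.na(gi) & !is.na(gj)
        m <- sum(ok)
        v <- if (m == 0L) NA_real_ else sum(gi[ok] == gj[ok]) / m
        s[i, j] <- v; s[j, i] <- v
      }
    }
  }
  s
}

#' Mean CGS within and between labelled subsets
#'
#' @param s CGS matrix.
#' @param partition named vector sample -> label (names must cover
#'   rownames of `s`).
#' @return matrix of mean off-diagonal CGS per (label, label) cell.
#' @export
cgs_group_means <- function(s, partition) {
  labs <- sort(unique(unname(partition)))
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (a in labs) for (b in labs) {
    ia <- rownames(s)[partition[rownames(s)] == a]
    ib <- rownames(s)[partition[rownames(s)] == b]
    block <- s[ia, ib, drop = FALSE]
    if (a == b) diag(block) <- NA
    out[a, b] <- mean(block, na.rm = TRUE)
  }
  out
}

#' Weir-Cockerham F_ST between two subpopulations
#'
#' Multi-allelic ratio-of-sums estimator: for every haplotype `u` at every
#' locus the among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) variance components are accumulated and
#' `F_ST = sum(a) / sum(a + b + c)`. Homozygous lines carry observed
#' heterozygosity 0, so `c` vanishes for inbred panels; negative per-locus
#' components are retained in the sums.
#'
#' @param g a [hap_matrix()].
#' @param popA,popB sample-id vectors (each of size >= 2).
#' @return list with `fst` (raw estimate; `NA` if every locus is
#'   monomorphic), `fst_clamped` (negative estimates reported as 0),
#'   `sum_a`, `sum_abc`.
#' @export
fst_weir_cockerham <- function(g, popA, popB) {
  if (length(popA) < 2L || length(popB) < 2L)
    stop("each population needs at least two samples")
  ga <- .hap_subset(g, popA)
  gb <- .hap_subset(g, popB)
  sum_a <- 0; sum_abc <- 0
  r <- 2
  for (k in seq_len(ncol(ga))) {
    xa <- ga[, k][!is.na(ga[, k])]
    xb <- gb[, k][!is.na(gb[, k])]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 1L || n2 < 1L) next
    alleles <- sort(unique(c(xa, xb)))
    if (length(alleles) < 2L) next
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (u in alleles) {
      p1 <- mean(xa == u); p2 <- mean(xb == u)
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- 0 # fully homozygous lines: no observed heterozygotes
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) *
           (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      sum_a <- sum_a + a
      sum_abc <- sum_abc + a + b + cc
    }
  }
  if (sum_abc == 0) {
    warning("F_ST undefined: no polymorphic locus")
    return(list(fst = NA_real_, fst_clamped = NA_real_,
                sum_a = sum_a, sum_abc = sum_abc))
  }
  fst <- sum_a / sum_abc
  list(fst = fst, fst_clamped = max(fst, 0), sum_a = sum_a,
       sum_abc = sum_abc)
}

#' Mantel test between two relationship/distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a
#' permutation p-value: rows and columns of `m2` are permuted jointly
#' `n_perm` times and `p = (count(|r_perm| >= |r|) + 1) / (n_perm + 1)`
#' (two-sided by default).
#'
#' @param m1,m2 symmetric matrices with identical dimensions and id order.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed (local RNG; global state untouched).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999L, seed = 1L,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!all(dim(m1) == dim(m2))) stop("matrix dimensions differ")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- stats::cor(v1, m2[ut])
  n <- nrow(m1)
  rng <- .local_rng(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- rng$sample_int(n)
    rp <- stats::cor(v1, m2[perm, perm][ut])
    hit <- if (alternative == "two.sided") abs(rp) >= abs(r_obs)
           else rp >= r_obs
    if (isTRUE(hit)) count <- count + 1L
  }
  list(r = r_obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm)
}

# seeded RNG stream that does not disturb the global .Random.seed
.local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample_int = function(n) with_state(function() sample.int(n)),
    runif = function(n) with_state(function() stats::runif(n)),
    state = function() env$state
  )
}

#' Principal-component coordinates of a haplotype genotype matrix
#'
#' One-hot encodes the haplotype calls (one indicator column per observed
#' (locus, haplotype) pair; missing calls contribute the locus mean),
#' column-centers, and eigendecomposes the sample covariance. Component
#' signs are fixed so the largest-magnitude loading of each component is
#' positive.
#'
#' @param g a [hap_matrix()].
#' @param n_components number of leading components (truncated to the rank
#'   with a warning if too large).
#' @return list with `scores` (samples x components), `sdev`,
#'   `prop_variance`.
#' @export
pca_coordinates <- function(g, n_components = 3L) {
  geno <- g$geno
  if (nrow(geno) < 2L) stop("PCA needs at least two samples")
  enc <- list()
  for (k in seq_len(ncol(geno))) {
    col <- geno[, k]
    alleles <- sort(unique(col[!is.na(col)]))
    for (u in alleles) {
      v <- as.numeric(col == u)
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      enc[[length(enc) + 1L]] <- v
    }
  }
  x <- do.call(cbind, enc)
  x <- scale(x, center = TRUE, scale = FALSE)
  p <- stats::prcomp(x, center = FALSE)
  rank <- sum(p$sdev > max(p$sdev) * 1e-10)
  if (n_components > rank) {
    warning("n_components exceeds rank (", rank, "); truncated")
    n_components <- rank
  }
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  rot <- p$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      scores[, j] <- -scores[, j]
      rot[, j] <- -rot[, j]
    }
  }
  rownames(scores) <- rownames(geno)
  list(scores = scores, sdev = p$sdev[seq_len(n_components)],
       prop_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)])
}

#' Diversity summary table for several subpopulations
#'
#' Convenience wrapper combining [richness_summary()], [pi_dispersion()] and
#' [spa_sda()] into one table, one row per population plus a pooled row.
#'
#' @param g a [hap_matrix()].
#' @param partition named vector sample -> population label.
#' @return data.frame.
#' @export
diversity_table <- function(g, partition) {
  pops <- sort(unique(unname(partition)))
  ss <- if (length(pops) >= 2L) spa_sda(g, partition) else NULL
  rows <- lapply(c(pops, "ALL"), function(pp) {
    ids <- if (pp == "ALL") g$samples else names(partition)[partition == pp]
    r <- richness_summary(g, ids)
    p <- pi_dispersion(g, ids)
    data.frame(population = pp, n = r$n_samples,
               total_alleles = r$total_alleles,
               per_locus_mean = r$per_locus_mean,
               per_locus_max = r$per_locus_max,
               allele_load = r$allele_load_per_cultivar,
               pi_mean = p$mean, pi_max = p$max,
               spa = if (!is.null(ss) && pp %in% ss$population)
                 ss$spa[ss$population == pp] else NA_integer_,
               sda = if (!is.null(ss) && pp %in% ss$population)
                 ss$sda[ss$population == pp] else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
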