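#' Two-locus normalized linkage disequilibrium D'
#'
#' Computed directly from haplotype counts of two biallelic sites on inbred
#' (homozygous) lines: dosage 0 and 2 are read as the two haplotypes,
#' heterozygous or missing calls are excluded pairwise. Returns 0 when either
#' site is monomorphic among the pairwise-complete samples (no LD
#' information).
#'
#' @param x,y integer dosage vectors (0/2, with 1 treated as missing).
#' @return signed D' in `[-1, 1]`.
#' @export
dprime <- function(x, y) {
  ok <- !is.na(x) & !is.na(y) & x != 1L & y != 1L
  a <- x[ok] / 2L
  b <- y[ok] / 2L
  n <- length(a)
  if (n == 0L) return(0)
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(0)
  pab <- mean(a == 1 & b == 1)
  d <- pab - pa * pb
  if (d == 0) return(0)
  dmax <- if (d > 0) min(pa * (1 - pb), (1 - pa) * pb)
          else       min(pa * pb, (1 - pa) * (1 - pb))
  d / dmax
}

#' Assemble SNP linkage-disequilibrium blocks (SNPLDBs)
#'
#' Greedy left-to-right blocking within each chromosome: the current block is
#' extended by the next site while the absolute D' between the candidate and
#' every site already in the block exceeds `dprime_threshold`; otherwise a
#' new block starts. Single-SNP blocks are allowed. Each block becomes one
#' multi-allelic locus whose alleles are the observed sample haplotypes;
#' haplotype classes rarer than `rare_floor` are merged into one rare class.
#'
#' Lines are treated as phased haplotypes (fully homozygous panel);
#' heterozygous calls are set to missing during recoding, with a warning if
#' any are present.
#'
#' @param m a [snp_matrix()] (after QC).
#' @param dprime_threshold block-extension threshold on |D'|, in (0, 1]
#'   (default 0.7).
#' @param rare_floor haplotype classes with frequency below this are merged
#'   (default 0.01).
#' @return a `hap_matrix` object: list with `samples`, `loci` (data.frame
#'   `chrom`, `start_pos`, `end_pos`, `n_sites`, `n_haplotypes`), `catalog`
#'   (per locus: character haplotype strings, `"rare"` last when merged,
#'   with attribute `freq`), `geno` (samples x loci haplotype indices,
#'   `NA` = missing), and `site_block` (block index of every input site).
#' @export
assemble_snpldb <- function(m, dprime_threshold = 0.7, rare_floor = 0.01) {
  if (dprime_threshold <= 0 || dprime_threshold > 1)
    stop("dprime_threshold must be in (0, 1]")
  if (nrow(m$sites) == 0L) stop("empty SNP matrix")
  calls <- m$calls
  if (any(calls == 1L, na.rm = TRUE)) {
    warning("heterozygous calls set to missing for haplotype recoding")
    calls[calls == 1L] <- NA_integer_
  }
  nsite <- ncol(calls)
  block_id <- integer(nsite)
  nb <- 0L
  for (ch in unique(m$sites$chrom)) {
    idx <- which(m$sites$chrom == ch)
    cur <- integer()
    for (j in idx) {
      fits <- length(cur) > 0L &&
        all(vapply(cur, function(i)
          abs(dprime(calls[, i], calls[, j])) > dprime_threshold, logical(1)))
      if (!fits) {
        nb <- nb + 1L
        cur <- integer()
      }
      cur <- c(cur, j)
      block_id[j] <- nb
    }
  }
  blocks <- split(seq_len(nsite), block_id)
  geno <- matrix(NA_integer_, nrow = nrow(calls), ncol = length(blocks),
                 dimnames = list(rownames(calls), NULL))
  catalog <- vector("list", length(blocks))
  loci <- data.frame(chrom = character(length(blocks)),
                     start_pos = integer(length(blocks)),
                     end_pos = integer(length(blocks)),
                     n_sites = integer(length(blocks)),
                     n_haplotypes = integer(length(blocks)),
                     stringsAsFactors = FALSE)
  for (k in seq_along(blocks)) {
    sites <- blocks[[k]]
    sub <- calls[, sites, drop = FALSE] / 2L
    str <- apply(sub, 1L, function(r)
      if (anyNA(r)) NA_character_ else paste(r, collapse = ""))
    tab <- sort(table(str), decreasing = TRUE)
    freq <- as.numeric(tab) / sum(tab)
    haps <- names(tab)
    rare <- freq < rare_floor
    if (any(rare) && sum(!rare) > 0L) {
      haps <- c(haps[!rare], "rare")
      fr <- c(freq[!rare], sum(freq[rare]))
      code <- ifelse(str %in% names(tab)[!rare],
                     match(str, names(tab)[!rare]), length(haps))
    } else {
      fr <- freq
      code <- match(str, haps)
    }
    code[is.na(str)] <- NA_integer_
    geno[, k] <- code
    attr(haps, "freq") <- fr
    catalog[[k]] <- haps
    loci$chrom[k] <- m$sites$chrom[sites[1]]
    loci$start_pos[k] <- m$sites$pos[sites[1]]
    loci$end_pos[k] <- m$sites$pos[sites[length(sites)]]
    loci$n_sites[k] <- length(sites)
    loci$n_haplotypes[k] <- length(haps)
  }
  hap_matrix(geno, loci = loci, catalog = catalog, site_block = block_id)
}

#' Construct a multi-allelic haplotype-locus genotype matrix
#'
#' Container for cultivars x SNPLDB loci with haplotype-index calls
#' (homozygous lines carry one index per locus). Pre-assembled block
#' definitions can be loaded this way when blocking should not be
#' recomputed.
#'
#' @param geno integer matrix samples x loci of haplotype indices (`NA`
#'   missing).
#' @param loci optional data.frame describing the blocks.
#' @param catalog optional per-locus haplotype catalogs.
#' @param site_block optional site -> block index map.
#' @return object of class `hap_matrix`.
#' @export
hap_matrix <- function(geno, loci = NULL, catalog = NULL, site_block = NULL) {
  stopifnot(is.matrix(geno))
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("S", seq_len(nrow(geno)))
  if (any(geno < 1L, na.rm = TRUE)) stop("haplotype indices are 1-based")
  structure(list(samples = rownames(geno), geno = geno, loci = loci,
                 catalog = catalog, site_block = site_block),
            class = "hap_matrix")
}

#' @export
#' @method print hap_matrix
print.hap_matrix <- function(x, ...) {
  cat("hap_matrix:", nrow(x$geno), "samples x", ncol(x$geno),
      "SNPLDB loci\n")
  invisible(x)
}

#' Write an SNPLDB block map as BED-like TSV
#'
#' Columns: `chrom`, `start` (0-based), `end` (half-open), `n_sites`,
#' `n_haplotypes`.
#'
#' @param h a `hap_matrix` with block metadata.
#' @param path output path.
#' @export
write_snpldb_map <- function(h, path) {
  if (is.null(h$loci)) stop("hap_matrix carries no block metadata")
  out <- data.frame(chrom = h$loci$chrom, start = h$loci$start_pos - 1L,
                    end = h$loci$end_pos, n_sites = h$loci$n_sites,
                    n_haplotypes = h$loci$n_haplotypes)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a haplotype genotype matrix as TSV
#'
#' @param h a `hap_matrix`.
#' @param path file path.
#' @export
write_hap_matrix <- function(h, path) {
  out <- data.frame(sample = h$samples, h$geno, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hap_matrix
#' @export
read_hap_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  g <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- as.character(tab[[1]])
  hap_matrix(g)
}
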