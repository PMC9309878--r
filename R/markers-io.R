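#' Construct a SNP matrix
#'
#' @param calls integer matrix, samples x sites, alt-allele dosages coded
#'   0/1/2 with `NA` for missing.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`;
#'   positions must be strictly increasing within each chromosome.
#' @return object of class `snp_matrix` (list with `calls`, `sites`,
#'   `samples`).
#' @export
snp_matrix <- function(calls, sites) {
  stopifnot(is.matrix(calls), is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            ncol(calls) == nrow(sites))
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("SNP calls must be 0/1/2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  storage.mode(calls) <- "integer"
  if (ncol(calls) > 0L)
    colnames(calls) <- paste0(sites$chrom, ":", sites$pos)
  structure(list(calls = calls, sites = sites,
                 samples = rownames(calls)), class = "snp_matrix")
}

#' @export
#' @method print snp_matrix
print.snp_matrix <- function(x, ...) {
  cat("snp_matrix:", length(x$samples), "samples x", nrow(x$sites), "sites\n")
  invisible(x)
}

#' Read biallelic SNPs from a VCF file into a `snp_matrix`
#'
#' Uses `vcfR` for parsing; genotypes are converted to alt-allele dosages.
#' Multiallelic records are dropped with a warning.
#'
#' @param path VCF (v4.x) file path.
#' @return a [snp_matrix()].
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT)
  if (!all(keep)) {
    warning(sum(!keep), " multiallelic records dropped")
    v <- v[keep, ]
    fix <- fix[keep, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT") # sites x samples
  flat <- sub(":.*", "", as.character(gt))
  dose <- vapply(strsplit(flat, "[/|]"), function(x) {
    if (length(x) == 0L || any(is.na(x)) || any(x == ".")) NA_integer_
    else sum(as.integer(x))
  }, integer(1))
  calls <- t(matrix(dose, nrow = nrow(gt), ncol = ncol(gt))) # samples x sites
  rownames(calls) <- colnames(gt)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  snp_matrix(calls[, ord, drop = FALSE], sites[ord, , drop = FALSE])
}

#' Write a `snp_matrix` as a minimal VCF v4.2 file
#'
#' Dosage 0/1/2 is emitted as `0/0`, `0/1`, `1/1`; missing as `./.`.
#' An optional provenance line (e.g. the simulation seed) is written as a
#' `##` header comment.
#'
#' @param m a `snp_matrix`.
#' @param path output path.
#' @param provenance optional character scalar for a `##provenance=` line.
#' @export
write_snp_vcf <- function(m, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(provenance))
    writeLines(paste0("##provenance=", provenance), con)
  writeLines(paste0("##contig=<ID=", unique(m$sites$chrom), ">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", m$samples), collapse = "\t"), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(m$sites))) {
    g <- m$calls[, j]
    gt <- ifelse(is.na(g), "./.", code[g + 1L])
    writeLines(paste(c(m$sites$chrom[j], m$sites$pos[j], ".",
                       m$sites$ref[j], m$sites$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' SNP quality-control filter
#'
#' Removes sites with missing rate above `max_missing`, heterozygote rate
#' above `max_het`, or minor allele frequency below `min_maf`. With
#' `het_to_missing = TRUE` (default, matching inbred-line panels)
#' heterozygous calls are set to missing before the missing-rate and MAF
#' rules are evaluated.
#'
#' @param m a [snp_matrix()].
#' @param max_missing maximum per-site missing fraction (default 0.2).
#' @param max_het maximum per-site heterozygote fraction (default 0.1).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param het_to_missing convert heterozygous calls to missing first.
#' @return filtered `snp_matrix` (possibly with zero sites, with a warning).
#' @export
qc_filter_snps <- function(m, max_missing = 0.2, max_het = 0.1,
                           min_maf = 0.01, het_to_missing = TRUE) {
  stopifnot(max_missing >= 0, max_missing <= 1, max_het >= 0, max_het <= 1,
            min_maf >= 0, min_maf <= 1)
  calls <- m$calls
  n <- nrow(calls)
  het_rate <- colMeans(calls == 1L, na.rm = TRUE)
  het_rate[is.nan(het_rate)] <- 1 # all-missing site: fails anyway
  if (het_to_missing) calls[calls == 1L] <- NA_integer_
  miss_rate <- colMeans(is.na(calls))
  p_alt <- colMeans(calls, na.rm = TRUE) / 2
  p_alt[is.nan(p_alt)] <- 0
  maf <- pmin(p_alt, 1 - p_alt)
  keep <- het_rate <= max_het & miss_rate <= max_missing & maf >= min_maf
  if (!any(keep)) warning("no SNP passed quality control")
  snp_matrix(calls[, keep, drop = FALSE], m$sites[keep, , drop = FALSE])
}
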