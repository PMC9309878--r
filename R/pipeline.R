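#' Bin COP or CGS values into the standard frequency-distribution classes
#'
#' Values (on the 0-100 scale) are classed as exactly `0`, `(0,10]`,
#' `(10,20]`, ..., `(90,100]`; the zero class is kept separate from
#' `(0,10]`.
#'
#' @param x numeric vector on the 0-100 scale.
#' @return factor with levels `0`, `0-10`, ..., `90-100`.
#' @export
cop_bins <- function(x) {
  stopifnot(all(x >= -1e-9 & x <= 100 + 1e-9))
  lev <- c("0", paste(seq(0, 90, 10), seq(10, 100, 10), sep = "-"))
  out <- as.character(cut(x, breaks = seq(0, 100, 10),
                          labels = lev[-1], include.lowest = FALSE))
  out[x == 0] <- "0"
  factor(out, levels = lev)
}

#' Joint frequency table of COP by CGS classes
#'
#' Off-diagonal pairwise values of the two relationship matrices (scaled
#' x100) cross-tabulated in the standard class bins.
#'
#' @param cop_m,cgs_m symmetric matrices on the `[0, 1]` scale with the same
#'   id order.
#' @return contingency table (COP bins x CGS bins).
#' @export
cop_cgs_joint_table <- function(cop_m, cgs_m) {
  if (!all(dim(cop_m) == dim(cgs_m))) stop("matrix dimensions differ")
  ut <- upper.tri(cop_m)
  table(COP = cop_bins(100 * cop_m[ut]), CGS = cop_bins(100 * cgs_m[ut]))
}

.write_tsv_atomic <- function(df, path, comments = character()) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(format(df, trim = TRUE, digits = NULL,
                            nsmall = 0, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

.num <- function(x, digits = 6) {
  ifelse(is.na(x), NA, formatC(x, digits = digits, format = "f"))
}

#' Run one analysis report of the germplasm pipeline
#'
#' End-to-end orchestration over a configuration list. Subcommands:
#' \describe{
#'   \item{trace}{terminal ancestors and contribution profiles of every
#'     population member.}
#'   \item{cop}{population COP matrix.}
#'   \item{core}{candidate table and core-terminal-ancestor nominations.}
#'   \item{families}{ancestor-derived family table for given ancestors.}
#'   \item{diversity}{richness / pi / SPA / SDA table per region.}
#'   \item{cluster}{NJ tree (Newick), group assignments, group x region
#'     table.}
#'   \item{compare}{COP vs CGS: Mantel test and the joint class-frequency
#'     table (values x100).}
#'   \item{anova}{RCBD ANOVA + GCV per trait.}
#'   \item{simulate}{write a simulated program (pedigree TSV + VCF).}
#' }
#' Outputs are TSV (headers commented with `#`), Newick, and a JSON run
#' manifest with input checksums, parameters and the seed. Files are
#' written atomically (write-then-rename).
#'
#' @param cfg named list. Common fields: `out_dir`, `seed`. Inputs either as
#'   file paths (`pedigree`, `vcf`) or in-memory objects (`graph`, `hap`,
#'   `trial`, `population`, `regions`, `ancestors`, `k_groups`,
#'   `n_perm`, thresholds `max_missing`, `max_het`, `min_maf`,
#'   `dprime_threshold`, `rare_floor`, `min_cycles`, `sim` a
#'   [sim_config()]).
#' @param subcommand one of the names above.
#' @return (invisibly) named character vector of the files written.
#' @export
run_report <- function(cfg, subcommand = c("trace", "cop", "core",
                                           "families", "diversity",
                                           "cluster", "compare", "anova",
                                           "simulate")) {
  subcommand <- match.arg(subcommand)
  if (is.null(cfg$out_dir)) stop("cfg$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  out <- character()
  emit <- function(name, df, comments = character()) {
    p <- file.path(cfg$out_dir, name)
    .write_tsv_atomic(df, p, comments)
    out[[name]] <<- p
  }
  graph <- cfg$graph
  if (is.null(graph) && !is.null(cfg$pedigree))
    graph <- read_pedigree(cfg$pedigree)
  hap <- cfg$hap
  if (is.null(hap) && !is.null(cfg$vcf)) {
    snps <- read_snp_vcf(cfg$vcf)
    snps <- qc_filter_snps(snps,
                           max_missing = cfg$max_missing %||% 0.2,
                           max_het = cfg$max_het %||% 0.1,
                           min_maf = cfg$min_maf %||% 0.01)
    hap <- assemble_snpldb(snps,
                           dprime_threshold = cfg$dprime_threshold %||% 0.7,
                           rare_floor = cfg$rare_floor %||% 0.01)
  }
  population <- cfg$population
  if (is.null(population) && !is.null(graph)) population <- ped_ids(graph)

  need <- function(obj, what)
    if (is.null(obj)) stop("subcommand '", subcommand, "' needs ", what)

  if (subcommand == "trace") {
    need(graph, "a pedigree")
    rows <- do.call(rbind, lapply(population, function(c) {
      p <- contribution_profile(graph, c)
      data.frame(cultivar = c, ancestor = names(p$nuclear),
                 nuclear_contribution = .num(unname(p$nuclear)),
                 is_cytoplasmic = names(p$nuclear) == p$cytoplasmic_ancestor)
    }))
    emit("trace_contributions.tsv", rows)
  } else if (subcommand == "cop") {
    need(graph, "a pedigree")
    m <- cop_matrix(graph, population)
    p <- file.path(cfg$out_dir, "cop_matrix.tsv")
    df <- data.frame(id = rownames(m),
                     apply(m, 2, .num), check.names = FALSE)
    .write_tsv_atomic(df, p)
    out[["cop_matrix.tsv"]] <- p
  } else if (subcommand == "core") {
    need(graph, "a pedigree")
    tab <- candidate_ancestors(graph, population,
                               min_cycles = cfg$min_cycles %||% 3L)
    core <- nominate_core_ancestors(tab,
                                    mode = cfg$core_mode %||% "within_set")
    tab$is_core <- tab$ancestor %in% core
    tab$ngc_percent <- .num(tab$ngc_percent, 2)
    tab$cgc_percent <- .num(tab$cgc_percent, 2)
    emit("core_ancestors.tsv", tab)
  } else if (subcommand == "families") {
    need(graph, "a pedigree")
    need(cfg$ancestors, "cfg$ancestors")
    ft <- family_table(graph, cfg$ancestors, population)
    ft$ngc_percent <- .num(ft$ngc_percent, 2)
    ft$cgc_percent <- .num(ft$cgc_percent, 2)
    emit("families.tsv", ft,
         comments = c(paste0("member_times=", attr(ft, "member_times")),
                      paste0("distinct_members=",
                             attr(ft, "n_distinct_members"))))
  } else if (subcommand == "diversity") {
    need(hap, "genotypes")
    need(cfg$regions, "cfg$regions")
    dt <- diversity_table(hap, cfg$regions)
    dt$per_locus_mean <- .num(dt$per_locus_mean, 2)
    dt$allele_load <- .num(dt$allele_load, 2)
    dt$pi_mean <- .num(dt$pi_mean, 3)
    dt$pi_max <- .num(dt$pi_max, 3)
    emit("diversity.tsv", dt)
  } else if (subcommand == "cluster") {
    need(hap, "genotypes")
    s <- cgs_matrix(hap)
    d <- 1 - s
    tree <- nj_tree(d)
    pt <- file.path(cfg$out_dir, "nj_tree.nwk")
    tmp <- paste0(pt, ".tmp")
    write_tree_newick(tree, tmp)
    file.rename(tmp, pt)
    out[["nj_tree.nwk"]] <- pt
    grp <- assign_groups(tree, cfg$k_groups %||% 3L)
    emit("groups.tsv", data.frame(id = names(grp), group = unname(grp)))
    if (!is.null(cfg$regions)) {
      ct <- group_by_region_table(grp, cfg$regions[names(grp)])
      emit("group_by_region.tsv",
           data.frame(region = rownames(ct), ct, check.names = FALSE))
    }
  } else if (subcommand == "compare") {
    need(graph, "a pedigree")
    need(hap, "genotypes")
    ids <- intersect(population, hap$samples)
    cm <- cop_matrix(graph, ids)
    sm <- cgs_matrix(hap, ids)
    mt <- mantel_test(cm, sm, n_perm = cfg$n_perm %||% 999L, seed = seed)
    jt <- cop_cgs_joint_table(cm, sm)
    emit("compare_mantel.tsv",
         data.frame(statistic = c("mantel_r", "p_value", "n_perm", "n"),
                    value = c(.num(mt$r, 4), .num(mt$p, 4), mt$n_perm,
                              length(ids))))
    emit("compare_joint_bins.tsv",
         data.frame(cop_bin = rownames(jt), unclass(jt),
                    check.names = FALSE))
    emit("compare_means.tsv",
         data.frame(statistic = c("cop_mean_x100", "cgs_mean_x100"),
                    value = .num(c(100 * mean(cm[upper.tri(cm)]),
                                   100 * mean(sm[upper.tri(sm)])), 2)))
  } else if (subcommand == "anova") {
    need(cfg$trial, "cfg$trial")
    traits <- unique(cfg$trial$trait)
    rows <- do.call(rbind, lapply(traits, function(tr) {
      a <- rcbd_anova_gcv(cfg$trial, tr)
      data.frame(trait = tr, mu = .num(a$mu, 3),
                 s2_g = .num(a$varcomp[["s2_g"]], 4),
                 s2_ge = .num(a$varcomp[["s2_ge"]], 4),
                 s2_e = .num(a$varcomp[["s2_e"]], 4),
                 gcv_percent = .num(a$gcv_percent, 2),
                 negative_component = a$negative_component)
    }))
    emit("anova_gcv.tsv", rows)
  } else if (subcommand == "simulate") {
    sim <- cfg$sim %||% sim_config(seed = seed)
    prog <- simulate_program(sim)
    pped <- file.path(cfg$out_dir, "sim_pedigree.tsv")
    tmp <- paste0(pped, ".tmp")
    write_pedigree(prog$graph, tmp)
    file.rename(tmp, pped)
    out[["sim_pedigree.tsv"]] <- pped
    pvcf <- file.path(cfg$out_dir, "sim_genotypes.vcf")
    tmp <- paste0(pvcf, ".tmp")
    write_snp_vcf(prog$snps, tmp, provenance = paste0("seed=", sim$seed))
    file.rename(tmp, pvcf)
    out[["sim_genotypes.vcf"]] <- pvcf
    emit("sim_regions.tsv", data.frame(id = names(prog$regions),
                                       region = unname(prog$regions)))
  }

  manifest <- list(
    subcommand = subcommand, seed = seed,
    parameters = cfg[intersect(names(cfg),
                               c("max_missing", "max_het", "min_maf",
                                 "dprime_threshold", "rare_floor",
                                 "min_cycles", "core_mode", "k_groups",
                                 "n_perm"))],
    inputs = {
      paths <- unlist(cfg[intersect(names(cfg), c("pedigree", "vcf"))])
      if (length(paths))
        lapply(stats::setNames(as.list(paths), names(paths)), function(p)
          list(path = p, md5 = unname(tools::md5sum(p))))
      else list()
    },
    outputs = lapply(out, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    package_version = as.character(utils::packageVersion("germtrace")))
  mp <- file.path(cfg$out_dir, paste0("manifest_", subcommand, ".json"))
  tmp <- paste0(mp, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, mp)
  out[[basename(mp)]] <- mp
  invisible(out)
}
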