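#' Candidate terminal ancestors of a population
#'
#' Scores every terminal ancestor of any population member with the four
#' prominence indicators (nuclear contribution %, cytoplasmic contribution %,
#' number of derived cultivars, maximum breeding-cycle count) and keeps those
#' involved in at least `min_cycles` breeding cycles.
#'
#' @param graph a [ped_graph()].
#' @param population character vector of cultivar ids.
#' @param min_cycles candidacy threshold on the breeding-cycle indicator
#'   (default 3).
#' @param group_by_origin if `TRUE` (default) an `origin` column with the
#'   ancestor's ecoregion is attached so nomination can run within geographic
#'   sets.
#' @return data.frame with columns `ancestor`, `origin`, `ngc_percent`,
#'   `cgc_percent`, `n_derived`, `max_cycles`, one row per candidate.
#' @export
candidate_ancestors <- function(graph, population, min_cycles = 3L,
                                group_by_origin = TRUE) {
  if (length(population) == 0L) stop("empty population")
  ped_check_id(graph, population)
  anc <- sort(unique(unlist(lapply(population, function(c)
    terminal_ancestors(graph, c)))))
  rows <- lapply(anc, function(a) {
    pc <- population_contribution(graph, population, a)
    data.frame(ancestor = a,
               origin = graph$records[a, "ecoregion"],
               ngc_percent = pc$ngc_percent,
               cgc_percent = pc$cgc_percent,
               n_derived = pc$n_derived,
               max_cycles = pc$max_cycles,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$max_cycles >= min_cycles, , drop = FALSE]
  if (!group_by_origin) tab$origin <- NULL
  rownames(tab) <- NULL
  tab
}

.nominate_one_set <- function(tab, min_above = 2L) {
  if (nrow(tab) == 0L) return(character())
  ind <- c("ngc_percent", "cgc_percent", "n_derived", "max_cycles")
  means <- colMeans(tab[, ind, drop = FALSE])
  above <- rowSums(sweep(as.matrix(tab[, ind, drop = FALSE]), 2, means, ">"))
  sort(tab$ancestor[above >= min_above])
}

#' Nominate core-terminal ancestors from a candidate table
#'
#' A candidate becomes a core-terminal ancestor when at least `min_above` of
#' its four indicators are strictly greater than the candidate-set mean of
#' that indicator. Ties at the mean do not count. With `mode = "within_set"`
#' (default) the mean comparison runs separately inside each geographic
#' origin set (`origin` column required); with `mode = "pooled"` all
#' candidates are compared against the pooled means.
#'
#' @param table candidate table from [candidate_ancestors()].
#' @param min_above how many of the 4 indicators must exceed the mean
#'   (default 2).
#' @param mode `"within_set"` or `"pooled"`.
#' @return sorted character vector of nominated ancestor ids (possibly empty).
#' @export
nominate_core_ancestors <- function(table, min_above = 2L,
                                    mode = c("within_set", "pooled")) {
  mode <- match.arg(mode)
  if (is.null(table) || nrow(table) == 0L) return(character())
  if (mode == "pooled" || is.null(table$origin))
    return(.nominate_one_set(table, min_above))
  sort(unlist(lapply(split(table, table$origin),
                     .nominate_one_set, min_above = min_above),
              use.names = FALSE))
}

#' Core-terminal-ancestor-derived family of an ancestor
#'
#' A core-terminal ancestor together with all its derived cultivars in the
#' population forms an ancestor-derived family. Reports membership, the
#' ecoregion distribution of the members, and the ancestor's nuclear and
#' cytoplasmic contribution percentages over the full population denominator.
#'
#' @param graph a `ped_graph`.
#' @param ancestor terminal ancestor id.
#' @param population character vector of cultivar ids.
#' @return list with `ancestor`, `members`, `n_members`, `ngc_percent`,
#'   `cgc_percent`, `ecoregion_counts` (named integer vector).
#' @export
ancestor_family <- function(graph, ancestor, population) {
  ped_check_id(graph, c(ancestor, population))
  if (graph$records[ancestor, "method"] != "terminal")
    stop("'", ancestor, "' is not a terminal ancestor")
  members <- derived_cultivars(graph, ancestor, population)
  pc <- population_contribution(graph, population, ancestor)
  eco <- table(factor(graph$records[members, "ecoregion"],
                      levels = ECOREGIONS))
  list(ancestor = ancestor, members = members, n_members = length(members),
       ngc_percent = pc$ngc_percent, cgc_percent = pc$cgc_percent,
       ecoregion_counts = stats::setNames(as.integer(eco), names(eco)))
}

#' Family table across several core ancestors
#'
#' One row per ancestor-derived family plus a `Total` row. `member_times`
#' counts (cultivar, family) incidences, so a cultivar derived from several of
#' the ancestors is counted once per family; `n_distinct_members` of the
#' total row counts each cultivar once.
#'
#' @param graph a `ped_graph`.
#' @param ancestors terminal ancestor ids.
#' @param population character vector of cultivar ids.
#' @return data.frame.
#' @export
family_table <- function(graph, ancestors, population) {
  fams <- lapply(ancestors, ancestor_family, graph = graph,
                 population = population)
  rows <- do.call(rbind, lapply(fams, function(f) {
    data.frame(ancestor = f$ancestor, n_members = f$n_members,
               ngc_percent = f$ngc_percent, cgc_percent = f$cgc_percent,
               t(f$ecoregion_counts), stringsAsFactors = FALSE)
  }))
  all_members <- unique(unlist(lapply(fams, `[[`, "members")))
  attr(rows, "member_times") <- sum(rows$n_members)
  attr(rows, "n_distinct_members") <- length(all_members)
  rows
}

#' Exclusive sharing partition of region item sets (Venn cells)
#'
#' Partitions the union of the per-region id sets into exclusive cells
#' (only-A, A-and-B-only, ..., all-regions). Every id lands in exactly one
#' cell and the cell counts sum to the union size.
#'
#' @param item_sets named list: region -> character vector of ids.
#' @return list with `cells` (named list of id vectors, names like
#'   `"A"`, `"A&B"`) and `counts` (named integer vector).
#' @export
sharing_partition <- function(item_sets) {
  if (length(item_sets) < 2L) stop("need at least two regions")
  regions <- names(item_sets)
  if (is.null(regions) || any(!nzchar(regions)))
    stop("item_sets must be a named list")
  universe <- sort(unique(unlist(item_sets)))
  member <- vapply(item_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, regions))
  key <- apply(member, 1L, function(row)
    paste(regions[row], collapse = "&"))
  cells <- split(universe, key)
  # present every possible cell, empty ones included, in subset order
  all_keys <- unlist(lapply(seq_along(regions), function(k)
    utils::combn(regions, k, paste, collapse = "&", simplify = FALSE)))
  out <- stats::setNames(lapply(all_keys, function(k)
    if (!is.null(cells[[k]])) cells[[k]] else character()), all_keys)
  list(cells = out,
       counts = vapply(out, length, integer(1)))
}

#' Percentage of core ancestors among all terminal ancestors
#'
#' Report arithmetic for ancestor summaries: `100 * length(core) /
#' length(all_terminal)`.
#'
#' @param core_ids core-terminal ancestor ids.
#' @param all_terminal_ids all terminal ancestor ids.
#' @return percentage, rounded to 2 decimals.
#' @export
core_ancestor_share <- function(core_ids, all_terminal_ids) {
  if (length(all_terminal_ids) == 0L) stop("no terminal ancestors")
  round(100 * length(unique(core_ids)) / length(unique(all_terminal_ids)), 2)
}

#' Population share of a summed nuclear (or counted cytoplasmic) contribution
#'
#' Report arithmetic: `100 * total / n`, where `total` is either a summed
#' nuclear contribution over a population (in cultivar-equivalents) or a
#' count of cultivars with a given cytoplasmic ancestor, and `n` the
#' population size.
#'
#' @param total summed contribution or count.
#' @param n population size.
#' @return percentage, rounded to 2 decimals.
#' @export
contribution_share <- function(total, n) {
  if (n <= 0) stop("population size must be positive")
  round(100 * total / n, 2)
}
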