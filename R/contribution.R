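#' Nuclear genetic contribution of terminal ancestors to a cultivar
#'
#' Propagates germplasm shares down the parental pedigree: a hybridization
#' (cross) passes 1/2 of the incoming share to each parent's lineage, while a
#' pure-line selection or mutation passes the full share to its single source.
#' Shares accumulate additively on terminal ancestors, so the returned values
#' always sum to 1.
#'
#' @param graph a [ped_graph()].
#' @param cultivar cultivar id.
#' @return named numeric vector: terminal-ancestor id -> contribution in
#'   `[0, 1]`, summing to 1.
#' @export
nuclear_contribution <- function(graph, cultivar) {
  ped_check_id(graph, cultivar)
  memo <- new.env(parent = emptyenv())
  profile <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- ped_parents(graph, id)
    val <- if (length(ps) == 0L) {
      stats::setNames(1, id)
    } else if (length(ps) == 1L) {
      profile(ps)
    } else {
      a <- profile(ps[[1]]); b <- profile(ps[[2]])
      keys <- union(names(a), names(b))
      stats::setNames(0.5 * (ifelse(keys %in% names(a), a[keys], 0) +
                             ifelse(keys %in% names(b), b[keys], 0)), keys)
    }
    memo[[id]] <- val
    val
  }
  out <- profile(cultivar)
  out[order(names(out))]
}

#' Cytoplasmic terminal ancestor of a cultivar
#'
#' Follows the maternal line upward: the female parent of each cross and the
#' single source of each selection/mutation (a selected line physically
#' inherits its source's cytoplasm), until a terminal record is reached. That
#' terminal female ancestor contributes the whole cytoplasm (value 1); all
#' other ancestors contribute 0.
#'
#' @inheritParams nuclear_contribution
#' @return the id of the single cytoplasmic terminal ancestor.
#' @export
cytoplasmic_ancestor <- function(graph, cultivar) {
  ped_check_id(graph, cultivar)
  id <- cultivar
  repeat {
    fem <- graph$records[id, "female_or_source"]
    if (is.na(fem)) return(id)
    id <- fem
  }
}

#' Full contribution profile of a cultivar
#'
#' @inheritParams nuclear_contribution
#' @return list with `cultivar`, `nuclear` (named vector as
#'   [nuclear_contribution()]) and `cytoplasmic_ancestor`.
#' @export
contribution_profile <- function(graph, cultivar) {
  list(cultivar = cultivar,
       nuclear = nuclear_contribution(graph, cultivar),
       cytoplasmic_ancestor = cytoplasmic_ancestor(graph, cultivar))
}

#' Write contribution profiles as long-format TSV
#'
#' Columns: `cultivar`, `ancestor`, `nuclear_contribution`, `is_cytoplasmic`.
#'
#' @param graph a `ped_graph`.
#' @param cultivars ids to profile.
#' @param path output path.
#' @export
write_contributions <- function(graph, cultivars, path) {
  rows <- do.call(rbind, lapply(cultivars, function(c) {
    p <- contribution_profile(graph, c)
    data.frame(cultivar = c, ancestor = names(p$nuclear),
               nuclear_contribution = unname(p$nuclear),
               is_cytoplasmic = names(p$nuclear) == p$cytoplasmic_ancestor,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# longest-path depth from the founders; descendants are strictly deeper
.ped_depths <- function(graph) {
  rec <- graph$records
  memo <- stats::setNames(rep(NA_integer_, nrow(rec)), rec$id)
  depth <- function(id) {
    if (!is.na(memo[[id]])) return(memo[[id]])
    ps <- ped_parents(graph, id)
    val <- if (length(ps) == 0L) 0L else
      max(vapply(ps, depth, integer(1))) + 1L
    memo[[id]] <<- val
    val
  }
  for (id in rec$id) depth(id)
  memo
}

#' Coefficient of parentage between two cultivars
#'
#' Recursive identity-by-descent evaluation under the breeding rules used for
#' pedigrees of homozygous, homogeneous lines:
#' \itemize{
#'   \item `cop(x, x) = 1`;
#'   \item the COP between two distinct terminal ancestors is 0 (unknown
#'     relatedness among founders is fixed at 0, i.e. unrelated);
#'   \item a cross child `c` of `f` and `m`: `cop(c, x) = (cop(f, x) +
#'     cop(m, x)) / 2` for any `x` not descended from `c`, which realises
#'     `COP = sum (1/2)^n` over paths through common parents;
#'   \item a selected line or mutant `s` with source `p`: `cop(s, p) = 0.75`,
#'     and `cop(s, x) = 0.75 * cop(p, x)` for other `x`.
#' }
#' The recursion always expands the deeper (more derived) member of the pair,
#' so the "not descended from" side condition holds by construction. Values
#' are memoized and symmetric.
#'
#' @param graph a `ped_graph`.
#' @param a,b cultivar ids.
#' @return COP value in `[0, 1]`.
#' @export
cop <- function(graph, a, b) {
  ped_check_id(graph, c(a, b))
  depths <- .ped_depths(graph)
  .cop_engine(graph, depths, new.env(parent = emptyenv()))(a, b)
}

.cop_engine <- function(graph, depths, memo) {
  rec <- graph$records
  f <- function(a, b) {
    if (a == b) return(1)
    key <- if (a < b) paste0(a, "\r", b) else paste0(b, "\r", a)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    # expand the deeper node; a descendant is strictly deeper than its ancestor
    if (depths[[b]] > depths[[a]] ||
        (depths[[b]] == depths[[a]] && rec[a, "method"] == "terminal")) {
      tmp <- a; a <- b; b <- tmp
    }
    ps <- ped_parents(graph, a)
    val <- if (length(ps) == 0L) {
      0 # two distinct terminal ancestors
    } else if (length(ps) == 1L) {
      if (ps == b) 0.75 else 0.75 * f(ps, b)
    } else {
      0.5 * (f(ps[[1]], b) + f(ps[[2]], b))
    }
    memo[[key]] <- val
    val
  }
  f
}

#' COP matrix over a set of cultivars
#'
#' @param graph a `ped_graph`.
#' @param ids ordered cultivar ids.
#' @return symmetric matrix with unit diagonal, dimnames `ids`.
#' @export
cop_matrix <- function(graph, ids) {
  ped_check_id(graph, ids)
  depths <- .ped_depths(graph)
  f <- .cop_engine(graph, depths, new.env(parent = emptyenv()))
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- f(ids[[i]], ids[[j]])
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m
}

#' Population-level contribution indicators of a terminal ancestor
#'
#' Aggregates per-cultivar contribution profiles over a population:
#' the nuclear genetic contribution percentage
#' `NGC = 100 * sum(nuclear contribution) / n`, the cytoplasmic percentage
#' `CGC = 100 * (number of members whose maternal line traces to the
#' ancestor) / n`, the number of derived cultivars, and the maximum breeding
#' cycle count over derived members.
#'
#' @param graph a `ped_graph`.
#' @param population character vector of cultivar ids (nonempty).
#' @param ancestor terminal ancestor id.
#' @return list with `ancestor`, `ngc_percent`, `cgc_percent`, `n_derived`,
#'   `max_cycles`.
#' @export
population_contribution <- function(graph, population, ancestor) {
  if (length(population) == 0L) stop("empty population")
  ped_check_id(graph, c(population, ancestor))
  n <- length(population)
  contrib <- vapply(population, function(c) {
    p <- nuclear_contribution(graph, c)
    if (ancestor %in% names(p)) p[[ancestor]] else 0
  }, numeric(1))
  cyto <- vapply(population, function(c)
    cytoplasmic_ancestor(graph, c) == ancestor, logical(1))
  derived <- derived_cultivars(graph, ancestor, population)
  maxcyc <- if (length(derived) == 0L) 0L else
    max(vapply(derived, function(c)
      breeding_cycles(graph, ancestor, c), integer(1)))
  list(ancestor = ancestor,
       ngc_percent = 100 * sum(contrib) / n,
       cgc_percent = 100 * sum(cyto) / n,
       n_derived = length(derived),
       max_cycles = maxcyc)
}

#' Write a square relationship matrix (COP or CGS) as TSV
#'
#' @param m symmetric matrix with dimnames.
#' @param path output path.
#' @export
write_square_matrix <- function(m, path) {
  out <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square relationship matrix written by [write_square_matrix()]
#' @param path file path.
#' @return matrix with dimnames.
#' @export
read_square_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
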