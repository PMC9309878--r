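#' Neighbor-joining tree from a genetic-distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimising the
#' Q-criterion `Q(i,j) = (n-2) d(i,j) - R_i - R_j` is joined, with the
#' standard branch-length formulas. Ties on Q are broken deterministically by
#' the lowest index pair (row-major over the current matrix order). Negative
#' branch lengths are clamped to 0 with the deficit transferred to the
#' sibling edge, so total path lengths through the new node are preserved.
#'
#' @param d symmetric distance matrix (zero diagonal, nonnegative) with
#'   dimnames, n >= 2.
#' @return an unrooted `ape::phylo` tree whose tips are the row names of
#'   `d`.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2L) stop("neighbor joining needs at least two taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix not symmetric")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = rep(d[1, 2] / 2, 2L),
               tip.label = labels, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  if (n == 3L) {
    tr <- list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), 3L, 2L, byrow = TRUE),
               edge.length = .three_point(d[1, 2], d[1, 3], d[2, 3]),
               tip.label = labels, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  # node bookkeeping: tips 1..n, unrooted tree with internal nodes
  # n+1 .. 2n-2; the final trifurcation gets id n+1 (ape's root), earlier
  # joins take ids downward from 2n-2.
  active_node <- seq_len(n)          # phylo node id of each active cluster
  dd <- d
  edges <- matrix(integer(), 0L, 2L)
  elen <- numeric()
  next_internal <- 2L * n - 2L
  m <- n
  while (m > 3L) {
    R <- rowSums(dd)
    q_best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * dd[i, j] - R[i] - R[j]
        if (q < q_best - 1e-12) {
          q_best <- q; bi <- i; bj <- j
        }
      }
    }
    li <- 0.5 * dd[bi, bj] + (R[bi] - R[bj]) / (2 * (m - 2))
    lj <- dd[bi, bj] - li
    # clamp negatives, moving the deficit to the sibling edge
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_id <- next_internal
    next_internal <- next_internal - 1L
    edges <- rbind(edges, c(new_id, active_node[bi]),
                   c(new_id, active_node[bj]))
    elen <- c(elen, li, lj)
    dnew <- vapply(seq_len(m), function(k) {
      if (k == bi || k == bj) return(NA_real_)
      0.5 * (dd[bi, k] + dd[bj, k] - dd[bi, bj])
    }, numeric(1))
    keep <- setdiff(seq_len(m), c(bi, bj))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    active_node <- c(active_node[keep], new_id)
    m <- m - 1L
  }
  # final trifurcation of the three remaining clusters at the root n+1
  root <- n + 1L
  stopifnot(next_internal == root)
  lens <- .three_point(dd[1, 2], dd[1, 3], dd[2, 3])
  edges <- rbind(edges, c(root, active_node[1]), c(root, active_node[2]),
                 c(root, active_node[3]))
  elen <- c(elen, lens)
  tr <- list(edge = edges, edge.length = elen, tip.label = labels,
             Nnode = n - 2L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

# three-point branch lengths around a trifurcation, negatives clamped with
# the deficit shared by the sibling edges
.three_point <- function(dab, dac, dbc) {
  l <- c((dab + dac - dbc) / 2, (dab + dbc - dac) / 2,
         (dac + dbc - dab) / 2)
  for (i in 1:3) {
    if (l[i] < 0) {
      l[-i] <- l[-i] + l[i] / 2
      l[i] <- 0
    }
  }
  pmax(l, 0)
}

#' Cut a tree into k groups at its longest internal edges
#'
#' The tree is midpoint-rooted and the `k - 1` longest internal edges are
#' removed; the tips of each resulting connected component form one group.
#' Groups are labelled `A`, `B`, ... ordered by decreasing size, ties broken
#' by the lexicographically smallest member.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param k number of groups, `1 <= k <=` number of tips.
#' @return named character vector: tip label -> group label.
#' @export
assign_groups <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k < 1L || k > n) stop("k must be between 1 and the number of tips")
  tr <- phangorn::midpoint(tree)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  internal <- tr$edge[, 2] > n
  # cut priority: internal edges by decreasing length, then pendant edges by
  # decreasing length (pendant cuts are needed only when k approaches n);
  # ties broken by edge index for determinism
  cand <- which(internal)
  tipe <- which(!internal)
  priority <- c(cand[order(-tr$edge.length[cand], cand)],
                tipe[order(-tr$edge.length[tipe], tipe)])
  leaf_groups <- function(cut_edges) {
    keep <- setdiff(seq_len(nrow(tr$edge)), cut_edges)
    parent <- seq_len(n + tr$Nnode)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (e in keep) {
      a <- find(tr$edge[e, 1]); b <- find(tr$edge[e, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n), find, integer(1))
  }
  # cutting an edge does not always split the leaf set (an internal-only
  # fragment may result), so cut in priority order until k leaf groups exist
  ncut <- k - 1L
  comp <- leaf_groups(utils::head(priority, ncut))
  while (length(unique(comp)) < k && ncut < length(priority)) {
    ncut <- ncut + 1L
    comp <- leaf_groups(utils::head(priority, ncut))
  }
  groups <- split(tr$tip.label, comp)
  leader <- vapply(groups, function(g) sort(g)[1], character(1))
  ord <- order(-vapply(groups, length, integer(1)), leader)
  groups <- groups[ord]
  lab <- stats::setNames(rep(LETTERS[seq_along(groups)],
                             vapply(groups, length, integer(1))),
                         unlist(groups))
  lab[tree$tip.label]
}

#' Cross-tabulate genetic groups against ecoregions
#'
#' @param groups named vector id -> group label.
#' @param regions named vector id -> region label (same id set).
#' @return contingency table (regions x groups) with margins, as a matrix
#'   whose last row/column are totals.
#' @export
group_by_region_table <- function(groups, regions) {
  if (!setequal(names(groups), names(regions)))
    stop("group and region id sets differ")
  ids <- names(groups)
  tab <- table(region = regions[ids], group = groups[ids])
  m <- as.matrix(unclass(tab))
  m <- rbind(m, Total = colSums(m))
  cbind(m, Total = rowSums(m))
}

#' Root distance of every tip (midpoint rooting)
#'
#' @param tree an `ape::phylo`.
#' @return named numeric vector tip -> distance to the midpoint root.
#' @export
root_distances <- function(tree) {
  tr <- phangorn::midpoint(tree)
  n <- length(tr$tip.label)
  nd <- ape::node.depth.edgelength(tr)
  stats::setNames(nd[seq_len(n)], tr$tip.label)
}

#' Write a tree in Newick format (6 significant digits)
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
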