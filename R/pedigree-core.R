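#' @keywords internal
"_PACKAGE"

PED_METHODS  <- c("cross", "selection", "mutation", "terminal")
ECOREGIONS   <- c("NNC", "HHH", "SC", "FOREIGN", "UNKNOWN")
PERIODS      <- c("P1923_2005", "P2006_2015", "UNKNOWN")

#' Construct a pedigree graph
#'
#' A pedigree graph is a directed acyclic graph of cultivars with one typed
#' breeding event (cross, selection, mutation) per non-terminal record.
#' Terminal ancestors -- landraces or lines whose parentage cannot be traced
#' further -- are exactly the parentless records.
#'
#' @param records data.frame with columns `id`, `name`, `method`
#'   (`cross`/`selection`/`mutation`/`terminal`), `female_or_source`, `male`
#'   (use `NA` for an absent parent), `ecoregion`, `period`. Parents that are
#'   referenced but not declared as rows are auto-created as terminal records
#'   with UNKNOWN metadata.
#' @return An object of class `ped_graph`.
#' @export
ped_graph <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("id", "name", "method", "female_or_source", "male",
            "ecoregion", "period")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("pedigree records lack columns: ", paste(miss, collapse = ", "))
  rec <- records[, need]
  for (col in need) rec[[col]] <- as.character(rec[[col]])
  rec$female_or_source[rec$female_or_source %in% c(".", "")] <- NA
  rec$male[rec$male %in% c(".", "")] <- NA
  rec$method <- tolower(rec$method)
  # "introduction" carries full contribution like a selection; kept in metadata
  rec$introduced <- rec$method == "introduction"
  rec$method[rec$introduced] <- "selection"

  if (anyNA(rec$id) || any(!nzchar(rec$id)))
    stop("empty cultivar id")
  dup <- rec$id[duplicated(rec$id)]
  if (length(dup))
    stop("duplicate child id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(rec$method, PED_METHODS)
  if (length(bad))
    stop("unknown breeding method: ", paste(bad, collapse = ", "))

  # auto-create referenced-but-undeclared parents as terminal ancestors
  refs <- setdiff(stats::na.omit(c(rec$female_or_source, rec$male)), rec$id)
  if (length(refs)) {
    rec <- rbind(rec, data.frame(
      id = refs, name = refs, method = "terminal",
      female_or_source = NA_character_, male = NA_character_,
      ecoregion = "UNKNOWN", period = "UNKNOWN", introduced = FALSE,
      stringsAsFactors = FALSE))
  }
  rec$ecoregion[is.na(rec$ecoregion) | !rec$ecoregion %in% ECOREGIONS] <- "UNKNOWN"
  rec$period[is.na(rec$period) | !rec$period %in% PERIODS] <- "UNKNOWN"

  n_par <- (!is.na(rec$female_or_source)) + (!is.na(rec$male))
  for (i in seq_len(nrow(rec))) {
    m <- rec$method[i]
    if (m == "cross") {
      if (n_par[i] != 2L)
        stop("cross record '", rec$id[i], "' needs two parents")
      if (rec$female_or_source[i] == rec$male[i])
        stop("cross record '", rec$id[i], "' lists the same line twice; ",
             "selfing of a single line is not a breeding event")
    } else if (m %in% c("selection", "mutation")) {
      if (is.na(rec$female_or_source[i]) || !is.na(rec$male[i]))
        stop(m, " record '", rec$id[i], "' needs exactly one source parent")
    } else { # terminal
      if (n_par[i] != 0L)
        stop("terminal record '", rec$id[i], "' must have no parents")
    }
  }
  rownames(rec) <- rec$id
  g <- structure(list(records = rec), class = "ped_graph")
  cyc <- .ped_find_cycle(g)
  if (!is.null(cyc))
    stop("pedigree contains a cycle: ", paste(cyc, collapse = " -> "))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print ped_graph
print.ped_graph <- function(x, ...) {
  r <- x$records
  cat("ped_graph:", nrow(r), "cultivars (",
      sum(r$method == "terminal"), "terminal ancestors )\n")
  invisible(x)
}

#' @export
#' @method format ped_graph
format.ped_graph <- function(x, ...) {
  paste0("ped_graph<", nrow(x$records), ">")
}

#' Cultivar ids of a pedigree graph
#' @param graph a `ped_graph`.
#' @return character vector of all record ids.
#' @export
ped_ids <- function(graph) graph$records$id

ped_parents <- function(graph, id) {
  r <- graph$records[id, ]
  stats::na.omit(c(r$female_or_source, r$male))
}

ped_check_id <- function(graph, id) {
  ok <- id %in% graph$records$id
  if (!all(ok))
    stop("unknown cultivar id: ", paste(id[!ok], collapse = ", "))
  invisible(TRUE)
}

# depth-first cycle search on the child -> parent relation
.ped_find_cycle <- function(graph) {
  rec <- graph$records
  state <- stats::setNames(integer(nrow(rec)), rec$id) # 0 new 1 open 2 done
  parent_of <- function(id) {
    r <- rec[id, ]
    stats::na.omit(c(r$female_or_source, r$male))
  }
  for (start in rec$id) {
    if (state[start] != 0L) next
    stack <- list(list(id = start, ps = parent_of(start), i = 0L))
    state[start] <- 1L
    path <- start
    while (length(stack)) {
      top <- stack[[length(stack)]]
      if (top$i < length(top$ps)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- top$ps[[top$i + 1L]]
        if (state[nxt] == 1L) {
          k <- match(nxt, path)
          return(c(path[k:length(path)], nxt))
        }
        if (state[nxt] == 0L) {
          state[nxt] <- 1L
          path <- c(path, nxt)
          stack[[length(stack) + 1L]] <- list(id = nxt, ps = parent_of(nxt),
                                              i = 0L)
        }
      } else {
        state[top$id] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

#' Read a pedigree from a tab-delimited file
#'
#' Expected columns (in order): `id`, `name`, `method`
#' (`cross|selection|mutation|terminal`), `female_or_source`, `male`,
#' `ecoregion` (`NNC|HHH|SC|FOREIGN|UNKNOWN`), `period`. A `.` denotes an
#' absent parent. UTF-8, header row required.
#'
#' @param path file path.
#' @return a validated [ped_graph()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#",
                           na.strings = c(".", "NA", ""), encoding = "UTF-8")
  if (nrow(tab) == 0L) {
    tab <- data.frame(id = character(), name = character(),
                      method = character(), female_or_source = character(),
                      male = character(), ecoregion = character(),
                      period = character(), stringsAsFactors = FALSE)
  }
  names(tab) <- c("id", "name", "method", "female_or_source", "male",
                  "ecoregion", "period")[seq_len(ncol(tab))]
  ped_graph(tab)
}

#' Write a pedigree graph in the tab-delimited dialect read by [read_pedigree()]
#'
#' @param graph a `ped_graph`.
#' @param path output file path.
#' @export
write_pedigree <- function(graph, path) {
  rec <- graph$records
  out <- rec[, c("id", "name", "method", "female_or_source", "male",
                 "ecoregion", "period")]
  out$female_or_source[is.na(out$female_or_source)] <- "."
  out$male[is.na(out$male)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a pedigree as an edge list for visualization
#'
#' One row per (parent, child) edge with the event type and the parental role.
#'
#' @param graph a `ped_graph`.
#' @return data.frame with columns `parent`, `child`, `method`, `role`.
#' @export
pedigree_edges <- function(graph) {
  rec <- graph$records
  nt <- rec[rec$method != "terminal", ]
  fe <- data.frame(parent = nt$female_or_source, child = nt$id,
                   method = nt$method,
                   role = ifelse(nt$method == "cross", "female", "source"),
                   stringsAsFactors = FALSE)
  ma <- nt[!is.na(nt$male), ]
  me <- data.frame(parent = ma$male, child = ma$id, method = ma$method,
                   role = "male", stringsAsFactors = FALSE)
  out <- rbind(fe, me)
  out[order(out$child, out$role), , drop = FALSE]
}

#' Terminal ancestors of a pedigree graph
#'
#' @param graph a `ped_graph`.
#' @return character vector of ids of all parentless (terminal) records.
#' @export
terminal_ids <- function(graph) {
  rec <- graph$records
  rec$id[rec$method == "terminal"]
}

#' Terminal ancestors of a cultivar
#'
#' Traverses the parental pedigree upward and returns the set of parentless
#' records reachable from `cultivar`. A terminal record's set is itself.
#'
#' @param graph a `ped_graph`.
#' @param cultivar cultivar id.
#' @return character vector of terminal-ancestor ids (sorted).
#' @export
terminal_ancestors <- function(graph, cultivar) {
  ped_check_id(graph, cultivar)
  rec <- graph$records
  seen <- character()
  term <- character()
  stack <- cultivar
  while (length(stack)) {
    id <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (id %in% seen) next
    seen <- c(seen, id)
    ps <- ped_parents(graph, id)
    if (length(ps) == 0L) term <- c(term, id) else stack <- c(stack, ps)
  }
  sort(unique(term))
}

#' All ancestors (terminal or not) of a cultivar, excluding itself
#' @inheritParams terminal_ancestors
#' @return character vector of ancestor ids.
#' @export
all_ancestors <- function(graph, cultivar) {
  ped_check_id(graph, cultivar)
  seen <- character()
  stack <- ped_parents(graph, cultivar)
  while (length(stack)) {
    id <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (id %in% seen) next
    seen <- c(seen, id)
    stack <- c(stack, ped_parents(graph, id))
  }
  sort(seen)
}

#' Cultivars of a universe derived from an ancestor
#'
#' The progeny-pedigree view: every member of `universe` whose
#' terminal-ancestor set contains `ancestor`.
#'
#' @param graph a `ped_graph`.
#' @param ancestor ancestor id.
#' @param universe character vector of cultivar ids to scan.
#' @return character vector (sorted) of derived cultivar ids.
#' @export
derived_cultivars <- function(graph, ancestor, universe) {
  ped_check_id(graph, ancestor)
  ped_check_id(graph, universe)
  hit <- vapply(universe, function(c)
    ancestor %in% terminal_ancestors(graph, c), logical(1))
  sort(unique(universe[hit]))
}

#' Breeding cycles between an ancestor and a derived cultivar
#'
#' The number of hybridization (cross) events on the deepest directed path
#' from `ancestor` down to `cultivar`; selection and mutation steps are
#' traversed but not counted, since they add no recombination cycle.
#'
#' @param graph a `ped_graph`.
#' @param ancestor terminal (or internal) ancestor id.
#' @param cultivar derived cultivar id.
#' @return nonnegative integer.
#' @export
breeding_cycles <- function(graph, ancestor, cultivar) {
  ped_check_id(graph, c(ancestor, cultivar))
  memo <- new.env(parent = emptyenv())
  # ids from which `ancestor` is reachable
  reach <- function(id) {
    if (!is.null(memo[[paste0("r.", id)]])) return(memo[[paste0("r.", id)]])
    val <- if (id == ancestor) TRUE else {
      ps <- ped_parents(graph, id)
      length(ps) > 0L && any(vapply(ps, reach, logical(1)))
    }
    memo[[paste0("r.", id)]] <- val
    val
  }
  if (!reach(cultivar))
    stop("'", ancestor, "' is not an ancestor of '", cultivar, "'")
  deep <- function(id) {
    if (!is.null(memo[[paste0("d.", id)]])) return(memo[[paste0("d.", id)]])
    val <- if (id == ancestor) 0L else {
      ps <- Filter(reach, ped_parents(graph, id))
      step <- if (graph$records[id, "method"] == "cross") 1L else 0L
      max(vapply(ps, deep, integer(1))) + step
    }
    memo[[paste0("d.", id)]] <- val
    val
  }
  deep(cultivar)
}
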