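ladder_graph <- function(k = 4L) {
  rec <- data.frame(id = c("B0", paste0("T", 1:k)), name = "x",
                    method = "terminal", female_or_source = NA_character_,
                    male = NA_character_, ecoregion = "NNC",
                    period = "UNKNOWN", stringsAsFactors = FALSE)
  prev <- "B0"
  for (i in seq_len(k)) {
    rec <- rbind(rec, data.frame(id = paste0("L", i), name = "x",
                                 method = "cross", female_or_source = prev,
                                 male = paste0("T", i), ecoregion = "NNC",
                                 period = "UNKNOWN"))
    prev <- paste0("L", i)
  }
  ped_graph(rec)
}

test_that("populations of direct selections yield no candidate ancestors", {
  rec <- data.frame(id = c("A", "B", "S1", "S2"), name = "x",
                    method = c("terminal", "terminal", "selection",
                               "selection"),
                    female_or_source = c(NA, NA, "A", "B"), male = NA,
                    ecoregion = "NNC", period = "UNKNOWN")
  g <- ped_graph(rec)
  tab <- candidate_ancestors(g, c("S1", "S2"))
  expect_equal(nrow(tab), 0L)
})

test_that("ladder pedigrees expose deep founders as candidates", {
  g <- ladder_graph(4L)
  tab <- candidate_ancestors(g, "L4")
  expect_true("B0" %in% tab$ancestor)
  expect_equal(tab$max_cycles[tab$ancestor == "B0"], 4L)
  # shallow founders (fewer than 3 cycles) are excluded
  expect_false("T4" %in% tab$ancestor) # only 1 cycle
  expect_true("T1" %in% tab$ancestor)  # rides the full ladder: 4 cycles
})

test_that("candidate indicators match per-ancestor recomputation", {
  g <- random_pedigree(31, n_founders = 4L, n_events = 20L)
  pop <- setdiff(ped_ids(g), terminal_ids(g))
  tab <- candidate_ancestors(g, pop, min_cycles = 1L)
  expect_gt(nrow(tab), 0L)
  for (r in seq_len(nrow(tab))) {
    pc <- population_contribution(g, pop, tab$ancestor[r])
    expect_equal(tab$ngc_percent[r], pc$ngc_percent)
    expect_equal(tab$cgc_percent[r], pc$cgc_percent)
    expect_equal(tab$n_derived[r], pc$n_derived)
    expect_equal(tab$max_cycles[r], pc$max_cycles)
  }
})

test_that("core nomination uses strict mean comparisons, 2 of 4", {
  # single candidate: nothing strictly exceeds its own mean
  one <- data.frame(ancestor = "A", ngc_percent = 5, cgc_percent = 2,
                    n_derived = 10, max_cycles = 4)
  expect_equal(nominate_core_ancestors(one), character())
  # a dominator over all four indicators is the unique nominee
  two <- data.frame(ancestor = c("A", "B"),
                    ngc_percent = c(9, 1), cgc_percent = c(8, 0),
                    n_derived = c(20, 2), max_cycles = c(6, 3))
  expect_equal(nominate_core_ancestors(two), "A")
  # ties at the mean do not count
  tied <- data.frame(ancestor = c("A", "B"),
                     ngc_percent = c(5, 5), cgc_percent = c(5, 5),
                     n_derived = c(10, 10), max_cycles = c(4, 4))
  expect_equal(nominate_core_ancestors(tied), character())
  expect_equal(nominate_core_ancestors(tied[0, ]), character())
})

test_that("pooled nomination equals brute-force mean comparison and is order-invariant", {
  set.seed(8)
  tab <- data.frame(ancestor = paste0("A", 1:50),
                    ngc_percent = runif(50, 0, 10),
                    cgc_percent = runif(50, 0, 10),
                    n_derived = rpois(50, 20),
                    max_cycles = 3L + rpois(50, 2))
  got <- nominate_core_ancestors(tab, mode = "pooled")
  ind <- c("ngc_percent", "cgc_percent", "n_derived", "max_cycles")
  manual <- tab$ancestor[vapply(seq_len(50), function(i)
    sum(vapply(ind, function(cn) tab[[cn]][i] > mean(tab[[cn]]),
               logical(1))) >= 2L, logical(1))]
  expect_setequal(got, manual)
  perm <- tab[sample.int(50), ]
  expect_setequal(nominate_core_ancestors(perm, mode = "pooled"), got)
  expect_true(all(got %in% tab$ancestor))
})

test_that("within-set nomination compares against set-level means", {
  tab <- data.frame(ancestor = c("N1", "N2", "S1", "S2"),
                    origin = c("NNC", "NNC", "SC", "SC"),
                    ngc_percent = c(9, 1, 0.9, 0.1),
                    cgc_percent = c(8, 0, 0.8, 0),
                    n_derived = c(20, 2, 4, 1),
                    max_cycles = c(6, 3, 5, 3))
  # S1 dominates within SC though it would lose against pooled means
  expect_setequal(nominate_core_ancestors(tab, mode = "within_set"),
                  c("N1", "S1"))
  expect_equal(nominate_core_ancestors(tab, mode = "pooled"), "N1")
})

test_that("ancestor families report membership, shares, and ecoregions", {
  g <- nannong_graph()
  fam <- ancestor_family(g, "51-83", "Nannong 32")
  expect_equal(fam$members, "Nannong 32")
  expect_equal(fam$ngc_percent, 12.5)
  expect_equal(unname(fam$ecoregion_counts["SC"]), 1L)
  expect_error(ancestor_family(g, "Chuxiu", "Nannong 32"), "terminal")
  # an unrelated ancestor has an empty family
  g2 <- ped_graph(rbind(g$records[, 1:7], data.frame(
    id = "LONER", name = "LONER", method = "terminal",
    female_or_source = NA, male = NA, ecoregion = "NNC",
    period = "UNKNOWN")))
  fam2 <- ancestor_family(g2, "LONER", "Nannong 32")
  expect_equal(fam2$n_members, 0L)
})

test_that("family member-times sum matches per-cultivar membership counts", {
  g <- random_pedigree(23, n_founders = 5L, n_events = 18L, p_selection = 0.1)
  pop <- setdiff(ped_ids(g), terminal_ids(g))
  ancs <- terminal_ids(g)
  ft <- family_table(g, ancs, pop)
  per_cultivar <- vapply(pop, function(c)
    length(intersect(terminal_ancestors(g, c), ancs)), integer(1))
  expect_equal(attr(ft, "member_times"), sum(per_cultivar))
  expect_lte(attr(ft, "n_distinct_members"), length(pop))
})

test_that("sharing partition forms exclusive Venn cells covering the union", {
  disj <- sharing_partition(list(A = c("x", "y"), B = c("z"), C = c("w")))
  expect_equal(sum(disj$counts), 4L)
  expect_equal(unname(disj$counts[c("A&B", "A&B&C")]), c(0L, 0L))
  ident <- sharing_partition(list(A = c("x", "y"), B = c("x", "y"),
                                  C = c("x", "y")))
  expect_equal(unname(ident$counts["A&B&C"]), 2L)
  expect_equal(sum(ident$counts), 2L)

  set.seed(4)
  sets <- lapply(1:3, function(i) sample(letters, 12L))
  names(sets) <- c("NNC", "HHH", "SC")
  part <- sharing_partition(sets)
  uni <- unique(unlist(sets))
  expect_equal(sum(part$counts), length(uni))
  # each id in exactly one cell, and in the right one
  all_ids <- unlist(part$cells)
  expect_equal(sort(unname(all_ids)), sort(uni))
  for (cell in names(part$cells)) {
    inside <- strsplit(cell, "&")[[1]]
    for (id in part$cells[[cell]]) {
      expect_equal(names(sets)[vapply(sets, function(s) id %in% s,
                                      logical(1))], inside)
    }
  }
})

test_that("report arithmetic reproduces published summary ratios", {
  expect_equal(core_ancestor_share(paste0("CA", 1:41), paste0("T", 1:604)),
               6.79)
  expect_equal(contribution_share(100.65, 560), 17.97)
  expect_equal(contribution_share(177, 560), 31.61)
})
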