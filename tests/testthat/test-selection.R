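# toy tree (O,(D,(C,(A,B)))) with outgroup O; node ids: O=1 D=2 C=3 A=4 B=5,
# root=6, (D..)=7, (C,(A,B))=8, (A,B)=9
toy_candidate <- function(node, site, to, from = "Q", n_missing = 0L) {
  tibble::tibble(site = site, gene = NA_character_, parent_node = NA_integer_,
                 child_node = node, clade_label = paste0("node_", node),
                 from_state = from, to_state = to, ci = 1, ambiguous = FALSE,
                 n_clade_taxa = 2L, n_carriers = 2L,
                 n_missing_leaves = n_missing)
}

test_that("sister overlap vetoes a candidate, missing sisters do not", {
  tr <- toy_tree()
  m1 <- toy_matrix(list(c("Q", "Q", "Q", "R", "R")))
  expect_false(sister_overlap(toy_candidate(9L, 1L, "R"), tr, m1))
  m2 <- toy_matrix(list(c("Q", "Q", "R", "R", "R")))
  expect_true(sister_overlap(toy_candidate(9L, 1L, "R"), tr, m2))
  m3 <- toy_matrix(list(c("Q", "Q", "X", "R", "R")))
  expect_false(sister_overlap(toy_candidate(9L, 1L, "R"), tr, m3))
  expect_error(sister_overlap(toy_candidate(6L, 1L, "R"), tr, m1), "root")
})

test_that("missing-data screen rejects unknowable comparisons and gappy clades", {
  tr <- toy_tree()
  # sister (C) entirely missing at the site
  mC <- toy_matrix(list(c("Q", "Q", "X", "R", "R")))
  expect_identical(missing_check(toy_candidate(9L, 1L, "R"), tr, mC),
                   "sister_or_basal_missing")
  # earliest-branching child of the clade entirely missing: clade 8 = (C,(A,B))
  mB <- toy_matrix(list(c("Q", "Q", "?", "R", "R")))
  expect_identical(missing_check(toy_candidate(8L, 1L, "R"), tr, mB),
                   "sister_or_basal_missing")
  # clade missing fraction above the default 0.5: 2 of 3 leaves of clade 8
  mX <- toy_matrix(list(c("Q", "Q", "R", "X", "X")))
  expect_identical(missing_check(toy_candidate(8L, 1L, "R"), tr, mX),
                   "clade_missing_excess")
  # a minority of missing clade leaves is tolerated (1 of 3 in clade 8,
  # with its earliest-branching child C present)
  m1of3 <- toy_matrix(list(c("Q", "Q", "R", "X", "R")))
  expect_identical(missing_check(toy_candidate(8L, 1L, "R"), tr, m1of3), "ok")
})

test_that("uniqueness classes follow the autapomorphy/trend hierarchy", {
  tr <- toy_tree()
  # derived R nowhere outside the clade
  u <- uniqueness_class(toy_candidate(9L, 1L, "R"), tr,
                        toy_matrix(list(c("Q", "Q", "Q", "R", "R"))))
  expect_identical(u$class, "unique")
  # R reappears in D (outside, non-sister): clade-unique
  cu <- uniqueness_class(toy_candidate(9L, 1L, "R"), tr,
                         toy_matrix(list(c("Q", "R", "Q", "R", "R"))))
  expect_identical(cu$class, "clade_unique")
  # clade 8 = (C,(A,B)): C all T, (A,B) all V, outside A: binary trend
  tv <- uniqueness_class(toy_candidate(8L, 1L, "T", from = "A"), tr,
                         toy_matrix(list(c("A", "A", "T", "V", "V"))))
  expect_identical(tv$class, "multistate_trend")
  expect_identical(tv$states, c("T", "V"))
  # mixed T/V scattered across a child subclade: inconsistent
  bad <- uniqueness_class(toy_candidate(8L, 1L, "T", from = "A"), tr,
                          toy_matrix(list(c("A", "A", "V", "T", "V"))))
  expect_identical(bad$class, "inconsistent_multistate")
})

test_that("ranking prefers uniqueness, coverage and broad genes, then is lexicographic", {
  tr <- toy_tree()
  m <- toy_matrix(list(c("Q", "Q", "Q", "R", "R"),
                       c("Q", "R", "Q", "R", "R"),
                       c("Q", "Q", "Q", "K", "K"),
                       c("X", "X", "X", "K", "K")))
  part <- gene_partition(c("g1", "g2"), c(1, 3), c(2, 4))
  cand <- dplyr::bind_rows(
    toy_candidate(9L, 2L, "R"),   # clade_unique, g1
    toy_candidate(9L, 1L, "R"),   # unique, g1
    toy_candidate(9L, 3L, "K"),   # unique, g2 (narrow gene: 2 taxa with data)
    toy_candidate(9L, 4L, "K"))   # unique, g2 but site mostly missing outside
  cand$gene <- c("g1", "g1", "g2", "g2")
  scr <- screen_candidates(cand, tr, m)
  acc <- dplyr::filter(scr, verdict == "accepted")
  ranked <- rank_candidates(acc, m, part)
  # unique beats clade_unique; g1 breadth (5) beats g2 (2)
  expect_identical(ranked$site[1], 1L)
  expect_identical(ranked$priority_class[1], "unique")
  # determinism: identical call, identical order
  expect_identical(ranked, rank_candidates(acc, m, part))
})

test_that("selection skips singleton clades and honours codes_per_clade", {
  sim <- simulate_apomorphy_data(n_taxa = 16, tree_shape = "balanced",
                                 n_genes = 4, sites_per_gene = 30,
                                 apomorphies_per_clade = 3, seed = 21)
  apo <- mine_apomorphies(sim$tree, sim$matrix, sim$partition)
  cand <- filter_candidates(apo, sim$tree, sim$matrix, 1.0)
  sel1 <- suppressMessages(
    select_codes(sim$tree, cand, sim$matrix, sim$partition))
  expect_true(all(table(sel1$selection$child_node) == 1L))
  sel2 <- suppressMessages(
    select_codes(sim$tree, cand, sim$matrix, sim$partition,
                 screening_config(codes_per_clade = 2)))
  expect_true(all(table(sel2$selection$child_node) == 2L))
  # every chosen code passes the sister-overlap criterion post hoc
  idx <- apoclass:::tree_index(sim$tree)
  for (i in seq_len(nrow(sel1$selection))) {
    expect_false(sister_overlap(sel1$selection[i, ], idx, sim$matrix))
  }
  # singleton clades (leaves) are never coded
  expect_true(all(sel1$selection$child_node > length(sim$tree$tip.label)))
})

test_that("clean simulations select exactly the planted truth", {
  sim <- simulate_apomorphy_data(n_taxa = 16, tree_shape = "balanced",
                                 n_genes = 4, sites_per_gene = 30, seed = 8)
  apo <- mine_apomorphies(sim$tree, sim$matrix, sim$partition)
  cand <- filter_candidates(apo, sim$tree, sim$matrix, 1.0)
  sel <- suppressMessages(
    select_codes(sim$tree, cand, sim$matrix, sim$partition))
  expect_setequal(paste(sel$selection$child_node, sel$selection$site),
                  paste(sim$truth$node, sim$truth$site))
  # byte-for-byte determinism
  sel_b <- suppressMessages(
    select_codes(sim$tree, cand, sim$matrix, sim$partition))
  expect_identical(sel, sel_b)
})
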