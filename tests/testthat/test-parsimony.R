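quartet <- function() ape::read.tree(text = "((A,B),(C,D));")

rec_for <- function(phy, states, outgroup = character(0)) {
  idx <- apoclass:::tree_index(phy, outgroup = outgroup)
  apoclass:::reconstruct_states(idx, states[phy$tip.label], site = 1L)
}

test_that("quartet site lengths match enumeration-derived values", {
  phy <- quartet()
  expect_equal(rec_for(phy, c(A = "I", B = "I", C = "V", D = "V"))$length, 1L)
  expect_equal(rec_for(phy, c(A = "I", B = "I", C = "I", D = "I"))$length, 0L)
  # missing leaf is non-constraining
  expect_equal(rec_for(phy, c(A = "I", B = "X", C = "V", D = "V"))$length, 1L)
})

test_that("MPR sets are exact: forced states are singletons", {
  phy <- ape::read.tree(text = "(((A,B),C),D);")
  rec <- rec_for(phy, c(A = "G", B = "A", C = "A", D = "A"))
  expect_equal(rec$length, 1L)
  idx <- apoclass:::tree_index(phy)
  nAB <- which(vapply(seq_len(idx$N), function(v)
    setequal(apoclass:::clade_leaf_labels(idx, v), c("A", "B")), logical(1)))
  expect_identical(rec$mpr[[nAB]], "A")
  # invariant site: every set is the observed singleton
  rec0 <- rec_for(phy, c(A = "K", B = "K", C = "K", D = "K"))
  expect_true(all(vapply(rec0$mpr, identical, logical(1), "K")))
})

test_that("DELTRAN delays changes toward the tips", {
  phy <- ape::read.tree(text = "(((A,B),C),Out);")
  rec <- rec_for(phy, c(A = "G", B = "A", C = "A", Out = "A"),
                 outgroup = "Out")
  n <- length(phy$tip.label)
  expect_true(all(rec$final[(n + 1):(n + phy$Nnode)] == "A"))
  ch <- site_changes(phy, rec)
  expect_equal(nrow(ch), 1L)
  expect_identical(ch$clade_label, "A")  # the G arises on A's terminal edge

  # ACCTRAN/DELTRAN divergence: derived R on two non-sister leaves with an
  # alternative stem-change reconstruction of equal length
  rec2 <- rec_for(phy, c(A = "R", B = "Q", C = "R", Out = "Q"),
                  outgroup = "Out")
  expect_equal(rec2$length, 2L)
  idx <- apoclass:::tree_index(phy, outgroup = "Out")
  expect_true(all(rec2$final[(n + 1):(n + phy$Nnode)] == "Q"))
  ch2 <- site_changes(idx, rec2)
  expect_setequal(ch2$clade_label, c("A", "C"))  # terminal edges, not the stem
  expect_true(all(ch2$ambiguous))  # both endpoints have non-singleton MPRs
})

test_that("convergent derived states yield one change per carrier leaf", {
  phy <- ape::read.tree(text = "((A,B),(C,D));")
  rec <- rec_for(phy, c(A = "R", B = "Q", C = "R", D = "Q"))
  ch <- site_changes(phy, rec)
  expect_equal(nrow(ch), 2L)
  expect_setequal(ch$clade_label, c("A", "C"))
  expect_true(all(ch$to_state == "R"))
})

test_that("consistency index follows the Kluge-Farris form", {
  m <- toy_matrix(list(s1 = c("Q", "Q", "Q", "R", "R"),
                       s2 = c("Q", "R", "Q", "R", "Q"),
                       s3 = c("A", "A", "C", "D", "D")))
  expect_equal(consistency_index(m, 1, 1L), 1.0)   # k=2, one change
  expect_equal(consistency_index(m, 2, 2L), 0.5)   # R arose twice
  expect_equal(consistency_index(m, 3, 2L), 1.0)   # k=3, two changes
  expect_true(is.na(consistency_index(m, 1, 0L)))  # invariant: undefined
})

test_that("engine matches the exhaustive enumeration oracle", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    phy <- random_small_tree(n)
    if (rep %% 3 == 0) {  # include polytomies
      phy <- ape::rtree(n)
      phy$edge.length[sample(length(phy$edge.length), 1)] <- 0
      phy <- ape::di2multi(phy)
      phy$edge.length <- NULL
      phy$tip.label <- paste0("t", seq_len(n))
    }
    og <- "t1"
    states <- random_site(phy$tip.label, n_states = sample(2:3, 1))
    o <- oracle_site(phy, states, outgroup = og)
    idx <- apoclass:::tree_index(phy, outgroup = og)
    rec <- apoclass:::reconstruct_states(idx, states[phy$tip.label], 1L)
    expect_equal(rec$length, o$length)
    if (o$length == 0) next
    for (v in (n + 1):idx$N) {
      expect_setequal(rec$mpr[[v]], o$mpr[[v]])
      expect_false(o$extra %in% rec$mpr[[v]])  # unobserved states never optimal
    }
    expect_identical(unname(rec$final[(n + 1):idx$N]),
                     unname(o$deltran[(n + 1):idx$N]))
  }
})

test_that("site lengths agree with an independent Fitch implementation", {
  skip_if_not_installed("phangorn")
  set.seed(77)
  phy <- ape::rtree(10, br = NULL)
  phy$tip.label <- paste0("t", 1:10)
  mat <- matrix(sample(c("A", "R", "N", "D"), 10 * 40, replace = TRUE),
                nrow = 10, dimnames = list(phy$tip.label, NULL))
  mat <- as_aa_matrix(mat)
  idx <- apoclass:::tree_index(phy)
  mine <- vapply(seq_len(40), function(s)
    apoclass:::reconstruct_states(idx, mat[phy$tip.label, s], s)$length,
    integer(1))
  pd <- phangorn::phyDat(mat, type = "AA")
  theirs <- phangorn::fitch(phy, pd, site = "site")
  expect_equal(mine, as.integer(theirs)[attr(pd, "index")][seq_len(40)])
})

test_that("change count equals reported length and missing data is monotone", {
  set.seed(55)
  for (rep in 1:25) {
    phy <- random_small_tree(sample(5:8, 1))
    states <- random_site(phy$tip.label, n_states = 3, p_missing = 0.1)
    idx <- apoclass:::tree_index(phy, outgroup = "t1")
    rec <- apoclass:::reconstruct_states(idx, states[phy$tip.label], 1L)
    if (rec$length > 0) {
      # conservation over ALL edges (ingroup and outgroup)
      diffs <- sum(rec$final[idx$phy$edge[, 1]] != rec$final[idx$phy$edge[, 2]])
      expect_equal(diffs, rec$length)
    }
    # masking any leaf never increases the length
    for (tip in sample(seq_along(phy$tip.label), 2)) {
      masked <- states
      masked[phy$tip.label[tip]] <- "X"
      rec2 <- apoclass:::reconstruct_states(idx, masked[phy$tip.label], 1L)
      expect_lte(rec2$length, rec$length)
    }
  }
})

test_that("apolist is deterministic, gene-annotated and oracle-complete", {
  sim <- simulate_apomorphy_data(n_taxa = 8, tree_shape = "random",
                                 n_genes = 3, sites_per_gene = 20,
                                 homoplasy_rate = 0.5, seed = 31)
  apo1 <- mine_apomorphies(sim$tree, sim$matrix, sim$partition)
  apo2 <- mine_apomorphies(sim$tree, sim$matrix, sim$partition)
  expect_identical(apo1, apo2)
  expect_true(all(apo1$gene %in% sim$partition$gene))
  expect_true(all(apo1$from_state != apo1$to_state))
  # every entry reproducible from its own site reconstruction
  for (s in unique(apo1$site)) {
    rec <- site_reconstruction(sim$tree, sim$matrix, s)
    ch <- site_changes(sim$tree, rec)
    expect_equal(sum(apo1$site == s), nrow(ch))
  }
  # a matrix of invariant sites yields an empty apolist
  m0 <- as_aa_matrix(matrix("A", nrow = length(sim$tree$tip.label), ncol = 5,
                            dimnames = list(sim$tree$tip.label, NULL)))
  expect_equal(nrow(mine_apomorphies(sim$tree, m0)), 0L)
})
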