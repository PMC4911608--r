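# Exhaustive-enumeration parsimony oracle for small trees.
#
# Enumerates every assignment of states (observed states plus one extra,
# never seen at a leaf) to internal nodes and missing-data leaves, scores
# each by the number of parent/child state differences, and reports:
#   length    minimal score
#   mpr       per-node set of states over all minimal assignments
#   deltran   the minimal assignment maximizing the summed depth of change
#             edges, ties broken like the package: root prefers a state
#             seen in the outgroup then alphabetical, other nodes prefer
#             the parent's state then alphabetical, in pre-order
#   changes   edges (parent, child) differing under the deltran assignment
oracle_site <- function(phy, states, outgroup = character(0)) {
  idx <- apoclass:::tree_index(phy, outgroup = outgroup)
  obs <- states[phy$tip.label]
  miss <- obs %in% c("X", "-", "?")
  U <- sort(unique(obs[!miss]))
  if (length(U) <= 1) {
    return(list(length = 0L, mpr = NULL, deltran = NULL, U = U))
  }
  extra <- setdiff(LETTERS, U)[1]
  Uext <- c(U, extra)
  free <- c(idx$preorder[idx$preorder > idx$n_tip], which(miss))
  fixed <- stats::setNames(rep(NA_character_, idx$N), NULL)
  fixed[which(!miss)] <- obs[!miss]
  grid <- as.matrix(expand.grid(rep(list(Uext), length(free)),
                                stringsAsFactors = FALSE))
  edges <- idx$phy$edge
  score <- numeric(nrow(grid))
  dsum <- numeric(nrow(grid))
  assign_full <- matrix(rep(fixed, each = nrow(grid)), nrow = nrow(grid))
  assign_full[, free] <- grid
  for (e in seq_len(nrow(edges))) {
    diffE <- assign_full[, edges[e, 1]] != assign_full[, edges[e, 2]]
    score <- score + diffE
    dsum <- dsum + diffE * idx$depth[edges[e, 2]]
  }
  L <- min(score)
  opt <- assign_full[score == L, , drop = FALSE]
  mpr <- lapply(seq_len(idx$N), function(v) sort(unique(opt[, v])))
  # DELTRAN: max dsum, then greedy pre-order tie-break
  dopt <- opt[dsum[score == L] == max(dsum[score == L]), , drop = FALSE]
  out_states <- unique(obs[idx$outgroup_tips][!miss[idx$outgroup_tips]])
  for (v in idx$preorder) {
    vals <- sort(unique(dopt[, v]))
    if (length(vals) == 1) next
    pick <- if (v == idx$root) {
      hit <- vals[vals %in% out_states]
      if (length(hit) > 0) hit[1] else vals[1]
    } else {
      pv <- dopt[1, idx$parent[v]]  # parent already resolved (pre-order)
      if (pv %in% vals) pv else vals[1]
    }
    dopt <- dopt[dopt[, v] == pick, , drop = FALSE]
  }
  deltran <- dopt[1, ]
  ch <- idx$phy$edge[deltran[idx$phy$edge[, 1]] != deltran[idx$phy$edge[, 2]], ,
                     drop = FALSE]
  list(length = as.integer(L), mpr = mpr, deltran = deltran,
       changes = ch, max_dsum = max(dsum[score == L]), U = U, extra = extra)
}

# random site states over a small alphabet, with optional missing symbols
random_site <- function(tips, n_states = 3, p_missing = 0.15) {
  alpha <- c("A", "R", "N", "D")[seq_len(n_states)]
  s <- sample(alpha, length(tips), replace = TRUE)
  m <- runif(length(tips)) < p_missing
  s[m] <- sample(c("X", "-", "?"), sum(m), replace = TRUE)
  stats::setNames(s, tips)
}

random_small_tree <- function(n_tips) {
  phy <- ape::rtree(n_tips, br = NULL)
  phy$tip.label <- paste0("t", seq_len(n_tips))
  phy
}

# small worked alignment used across selection/coding tests:
# caterpillar ingroup (((A,B),C),D) plus outgroup O
toy_tree <- function() {
  phy <- ape::read.tree(text = "(O,(D,(C,(A,B))));")
  apoclass::prepare_tree(phy, outgroup = "O")
}

toy_matrix <- function(cols) {
  m <- do.call(cbind, cols)
  rownames(m) <- c("O", "D", "C", "A", "B")
  apoclass::as_aa_matrix(m)
}

# deepest coded trie terminal containing a leaf: the leaf's true terminal
# category in a simulated database
truth_terminal_of <- function(db, tree, taxon) {
  idx <- apoclass:::tree_index(tree)
  tip <- match(taxon, tree$tip.label)
  anc <- which(vapply(seq_len(idx$N), function(v)
    tip %in% idx$leaves_under[[v]], logical(1)))
  id <- intersect(db$terminals$id, db$codes$id[db$codes$node %in% anc])
  db$terminals$name[match(id, db$terminals$id)]
}

# run one taxon's own rows through the matcher
self_assign <- function(db, sim, taxon) {
  obs <- apoclass::extract_states(
    db, apoclass::query_from_row(sim$matrix, sim$partition, taxon),
    sim$partition)
  apoclass::assign_query(db, obs)
}
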