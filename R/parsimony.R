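#' Parsimony reconstruction of one alignment column
#'
#' Unit-cost (Fitch-style) parsimony on the fixed rooted topology, exact on
#' polytomies. Three passes:
#'
#' 1. a post-order pass computes, for every node and state, the minimum
#'    number of changes in the node's subtree (and, lexicographically second,
#'    the maximum total depth of change edges — the delayed-transformation
#'    objective);
#' 2. an "outside" pass turns the subtree costs into full MPR sets — the
#'    exact set of states each node takes in at least one most-parsimonious
#'    reconstruction;
#' 3. a pre-order backtrack assigns DELTRAN final states: among
#'    reconstructions of minimal length, total change-edge depth is
#'    maximized (changes pushed toward the tips); remaining ties prefer the
#'    parent's state, then a state seen in the outgroup (at the root), then
#'    the alphabetically smallest state.
#'
#' Missing symbols (`X`, `-`, `?`) are non-constraining: such leaves accept
#' any state at zero cost and never contribute to the length.
#'
#' @param tree `ape::phylo` (rooted; polytomies allowed) or a prebuilt index.
#' @param matrix an [as_aa_matrix()] whose taxa cover the tree leaves.
#' @param site 1-based column index.
#' @param outgroup outgroup leaf labels (defaults to `attr(tree, "outgroup")`).
#' @return a list with elements `site`, `length` (parsimony length in
#'   changes), `states` (the site's observed state universe), `prelim`,
#'   `mpr` (lists of state vectors per node id), `final` (character vector of
#'   final states per node id) and `ambiguous` (per node, MPR set size > 1).
#' @export
site_reconstruction <- function(tree, matrix, site, outgroup = NULL) {
  idx <- if (is.list(tree) && !inherits(tree, "phylo")) tree else
    tree_index(tree, outgroup = outgroup %||% attr(tree, "outgroup"))
  if (site < 1 || site > ncol(matrix)) {
    stop("site out of range [1, ", ncol(matrix), "]", call. = FALSE)
  }
  obs <- matrix[idx$phy$tip.label, site]
  reconstruct_states(idx, obs, site)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# obs: character vector of symbols in tip-id order
reconstruct_states <- function(idx, obs, site = NA_integer_) {
  N <- idx$N; n_tip <- idx$n_tip
  miss <- is_missing_symbol(obs)
  U <- sort(unique(obs[!miss]))
  S <- length(U)
  if (S <= 1L) {
    st <- if (S == 1L) U else NA_character_
    one <- if (S == 1L) list(U) else list(character(0))
    return(list(site = site, length = 0L, states = U,
                prelim = rep(one, N), mpr = rep(one, N),
                final = rep(st, N), ambiguous = rep(FALSE, N)))
  }
  depth <- idx$depth
  C <- matrix(Inf, N, S)   # min changes in subtree given node state
  D <- matrix(0, N, S)     # max change-edge depth sum given that cost
  CONTRIB <- vector("list", N)  # per-child cost contribution by parent state
  for (v in idx$postorder) {
    if (v <= n_tip) {
      if (miss[v]) C[v, ] <- 0 else C[v, match(obs[v], U)] <- 0
      next
    }
    cC <- rep(0, S); cD <- rep(0, S)
    for (ch in idx$children[[v]]) {
      minc <- min(C[ch, ])
      sel <- C[ch, ] == minc
      dminmax <- max(D[ch, sel])
      contrib <- pmin(C[ch, ], minc + 1)
      eq <- C[ch, ] == minc + 1
      lt <- C[ch, ] < minc + 1
      dc <- rep(dminmax + depth[ch], S)
      dc[lt] <- D[ch, lt]
      dc[eq] <- pmax(D[ch, eq], dminmax + depth[ch])
      CONTRIB[[ch]] <- contrib
      cC <- cC + contrib
      cD <- cD + dc
    }
    C[v, ] <- cC
    D[v, ] <- cD
  }
  root <- idx$root
  L <- min(C[root, ])

  # outside pass: min changes in the rest of the tree given node state
  OUT <- matrix(0, N, S)
  sumC <- rep(0, S)
  for (v in idx$preorder) {
    kids <- idx$children[[v]]
    if (length(kids) == 0) next
    tot <- OUT[v, ]
    for (ch in kids) tot <- tot + CONTRIB[[ch]]
    for (ch in kids) {
      B <- tot - CONTRIB[[ch]]
      OUT[ch, ] <- pmin(B, min(B) + 1)
    }
  }
  mpr <- lapply(seq_len(N), function(v) U[C[v, ] + OUT[v, ] == L])
  prelim <- lapply(seq_len(N), function(v) U[C[v, ] == min(C[v, ])])

  # DELTRAN backtrack
  final <- character(N)
  out_states <- unique(obs[idx$outgroup_tips][!miss[idx$outgroup_tips]])
  rsel <- C[root, ] == L
  rsel <- rsel & (D[root, ] == max(D[root, rsel]))
  cand <- U[rsel]
  final[root] <- if (any(cand %in% out_states)) cand[cand %in% out_states][1] else cand[1]
  for (v in idx$preorder) {
    if (v == root) next
    t <- final[idx$parent[v]]
    cost_u <- C[v, ] + (U != t)
    d_u <- D[v, ] + (U != t) * depth[v]
    sel <- cost_u == min(cost_u)
    sel <- sel & (d_u == max(d_u[sel]))
    cand <- U[sel]
    final[v] <- if (t %in% cand) t else {
      pre_hit <- intersect(cand, prelim[[v]])
      if (length(pre_hit) > 0) pre_hit[1] else cand[1]
    }
  }
  list(site = site, length = as.integer(L), states = U, prelim = prelim,
       mpr = mpr, final = final, ambiguous = lengths(mpr) > 1L)
}

#' Per-site state changes under the DELTRAN reconstruction
#'
#' One row per edge whose endpoints carry different final states. Changes on
#' edges leading into the outgroup (or into any node whose leaves are not all
#' ingroup) are excluded: only ingroup clades are apomorphy candidates. A
#' change is flagged `ambiguous` when either endpoint's MPR set is
#' non-singleton.
#'
#' @param tree `ape::phylo` or tree index.
#' @param reconstruction result of [site_reconstruction()].
#' @return tibble: `site`, `parent_node`, `child_node`, `clade_label`,
#'   `from_state`, `to_state`, `ambiguous`.
#' @export
site_changes <- function(tree, reconstruction) {
  idx <- if (is.list(tree) && !inherits(tree, "phylo")) tree else
    tree_index(tree)
  rec <- reconstruction
  rows <- list()
  if (rec$length > 0L) {
    for (v in idx$preorder) {
      p <- idx$parent[v]
      if (p == 0L) next
      if (is.na(rec$final[p]) || rec$final[p] == rec$final[v]) next
      if (!idx$is_ingroup[v]) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site = rec$site,
        parent_node = p, child_node = v,
        clade_label = idx$labels[v],
        from_state = rec$final[p], to_state = rec$final[v],
        ambiguous = rec$ambiguous[p] || rec$ambiguous[v]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(site = integer(0), parent_node = integer(0),
                          child_node = integer(0), clade_label = character(0),
                          from_state = character(0), to_state = character(0),
                          ambiguous = logical(0)))
  }
  dplyr::bind_rows(rows)
}

#' Consistency index of a variable site
#'
#' `CI = (k - 1) / length`, where `k` is the number of distinct non-missing
#' states at the site (the Kluge-Farris minimum conceivable change count for
#' an unordered character) and `length` the observed parsimony length.
#' Invariant sites (`length = 0`) carry no apomorphies; their CI is `NA`.
#'
#' @param matrix an [as_aa_matrix()].
#' @param site column index.
#' @param length parsimony length of the site.
#' @return CI in `(0, 1]`, or `NA_real_` for `length = 0`.
#' @export
consistency_index <- function(matrix, site, length) {
  if (length == 0L) return(NA_real_)
  states <- matrix[, site]
  k <- length(unique(states[!is_missing_symbol(states)]))
  (k - 1) / length
}

#' Mine the complete apomorphy list
#'
#' Runs the DELTRAN reconstruction over every variable column and
#' concatenates the per-site change lists, each annotated with its gene (via
#' the partition) and its site's consistency index. Order is deterministic:
#' by site, then pre-order edge position.
#'
#' @param tree rooted `ape::phylo` with an `outgroup` attribute (see
#'   [read_reference_tree()]), or pass `outgroup` explicitly.
#' @param matrix an [as_aa_matrix()]; taxa must cover the tree leaves.
#' @param partition optional [gene_partition()].
#' @param outgroup outgroup leaf labels.
#' @return the apolist tibble: `site`, `gene`, `parent_node`, `child_node`,
#'   `clade_label`, `from_state`, `to_state`, `ci`, `ambiguous`.
#' @export
mine_apomorphies <- function(tree, matrix, partition = NULL, outgroup = NULL) {
  outgroup <- outgroup %||% attr(tree, "outgroup") %||% character(0)
  missing_tips <- setdiff(tree$tip.label, rownames(matrix))
  if (length(missing_tips) > 0) {
    stop("tree leaves absent from the matrix: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  idx <- tree_index(tree, outgroup = outgroup)
  mat <- matrix[idx$phy$tip.label, , drop = FALSE]
  out <- vector("list", ncol(mat))
  for (s in seq_len(ncol(mat))) {
    col <- mat[, s]
    if (length(unique(col[!is_missing_symbol(col)])) <= 1L) next
    rec <- reconstruct_states(idx, col, site = s)
    if (rec$length == 0L) next
    ch <- site_changes(idx, rec)
    if (nrow(ch) == 0) next
    ch$ci <- consistency_index(matrix, s, rec$length)
    out[[s]] <- ch
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(site = integer(0), parent_node = integer(0),
                          child_node = integer(0), clade_label = character(0),
                          from_state = character(0), to_state = character(0),
                          ambiguous = logical(0), ci = double(0))
  }
  res$gene <- if (is.null(partition)) NA_character_ else gene_of(partition, res$site)
  dplyr::select(res, "site", "gene", "parent_node", "child_node",
                "clade_label", "from_state", "to_state", "ci", "ambiguous")
}
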