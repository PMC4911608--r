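#' Read the fixed reference topology
#'
#' Reads a Newick tree, optionally roots it on the configured outgroup, and
#' reconciles its leaf set with the alignment taxa. Polytomies are retained
#' (the reference topology is an input, not something this tool resolves).
#'
#' @param path Newick file path.
#' @param outgroup character vector of outgroup leaf labels (may be empty;
#'   then the tree must already be rooted and all leaves are ingroup).
#' @param taxa optional character vector of matrix taxon labels to reconcile
#'   against.
#' @param on_extra what to do with tree leaves absent from `taxa`:
#'   `"prune"` (default) or `"error"`.
#' @return an `ape::phylo` with attributes `outgroup` (labels) set.
#' @export
read_reference_tree <- function(path, outgroup = character(0), taxa = NULL,
                                on_extra = c("prune", "error")) {
  on_extra <- match.arg(on_extra)
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path, call. = FALSE)
  prepare_tree(phy, outgroup = outgroup, taxa = taxa, on_extra = on_extra)
}

#' @rdname read_reference_tree
#' @param phy an `ape::phylo` already in memory.
#' @export
prepare_tree <- function(phy, outgroup = character(0), taxa = NULL,
                         on_extra = c("prune", "error")) {
  on_extra <- match.arg(on_extra)
  if (!is.null(taxa)) {
    extra <- setdiff(phy$tip.label, taxa)
    if (length(extra) > 0) {
      if (on_extra == "error") {
        stop("tree leaves absent from the matrix: ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
      phy <- ape::drop.tip(phy, extra)
    }
    missing_tips <- setdiff(taxa, phy$tip.label)
    if (length(missing_tips) > 0) {
      stop("matrix taxa absent from the tree: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
    }
  }
  if (length(outgroup) > 0) {
    absent <- setdiff(outgroup, phy$tip.label)
    if (length(absent) > 0) {
      stop("outgroup leaves not in tree: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    # acceptable as-is when the ingroup is monophyletic with no outgroup
    # leaf inside it (covers a binary root and a basal root polytomy, which
    # keeps the ingroup-stem state polarized by two or more outgroup edges)
    ingroup <- setdiff(phy$tip.label, outgroup)
    mrca <- if (length(ingroup) > 1) ape::getMRCA(phy, ingroup) else NULL
    ok <- !is.null(mrca) && mrca != ape::Ntip(phy) + 1L &&
      !any(outgroup %in% ape::extract.clade(phy, mrca)$tip.label)
    if (!ok) phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(phy)) {
    stop("tree is unrooted and no outgroup was given", call. = FALSE)
  }
  attr(phy, "outgroup") <- outgroup
  phy
}

# ---- internal indexed view of a rooted tree -------------------------------
# Node ids follow ape convention: tips 1..n, internals n+1..n+m.
tree_index <- function(phy, outgroup = attr(phy, "outgroup")) {
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  N <- n_tip + n_node
  parent <- integer(N)
  children <- vector("list", N)
  for (i in seq_len(N)) children[[i]] <- integer(0)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)  # edge order = input child order
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  parent[root] <- 0L
  # iterative preorder
  pre <- integer(N); depth <- integer(N)
  stack <- root; k <- 0L
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; pre[k] <- v
    depth[v] <- if (v == root) 0L else depth[parent[v]] + 1L
    kids <- children[[v]]
    if (length(kids) > 0) stack <- c(stack, rev(kids))
  }
  post <- rev(pre)
  # leaves under every node
  leaves_under <- vector("list", N)
  for (v in post) {
    leaves_under[[v]] <- if (v <= n_tip) v else
      unlist(lapply(children[[v]], function(c) leaves_under[[c]]))
  }
  outgroup <- if (is.null(outgroup)) character(0) else outgroup
  out_tips <- match(outgroup, phy$tip.label)
  ingroup_tips <- setdiff(seq_len(n_tip), out_tips)
  # a node is an ingroup node iff all its leaves are ingroup
  is_ingroup <- vapply(seq_len(N), function(v)
    all(leaves_under[[v]] %in% ingroup_tips), logical(1))
  labels <- c(phy$tip.label,
              if (!is.null(phy$node.label) && length(phy$node.label) == n_node)
                phy$node.label else paste0("node_", (n_tip + 1):N))
  blank <- !nzchar(labels)
  labels[blank] <- paste0("node_", which(blank))
  list(phy = phy, n_tip = n_tip, N = N, root = root, parent = parent,
       children = children, preorder = pre, postorder = post, depth = depth,
       leaves_under = leaves_under, labels = labels,
       outgroup_tips = out_tips, ingroup_tips = ingroup_tips,
       is_ingroup = is_ingroup)
}

# leaf labels under a node
clade_leaf_labels <- function(idx, node) {
  idx$phy$tip.label[idx$leaves_under[[node]]]
}

# sister group leaves: union of the other children of node's parent
sister_leaf_labels <- function(idx, node) {
  p <- idx$parent[node]
  if (p == 0L) stop("root has no sister group", call. = FALSE)
  sibs <- setdiff(idx$children[[p]], node)
  idx$phy$tip.label[unlist(lapply(sibs, function(s) idx$leaves_under[[s]]))]
}
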