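#' Simulate an alignment with planted apomorphies
#'
#' Generates a rooted tree (ingroup of the requested shape plus two
#' outgroup leaves in a basal trichotomy), a gene-partitioned amino-acid
#' alignment whose background columns are fully conserved (so every planted
#' column's consistency index is analytically known), and a truth table of
#' planted apomorphies: for each selected ingroup clade, columns where all
#' clade leaves carry the derived state and everyone else the ancestral
#' state. With probability `homoplasy_rate` a planted column additionally
#' gives the derived state to one ingroup leaf outside the clade, chosen so
#' that the derived leaves do not form a clade — driving that column's CI
#' to 0.5. An optional low-rate noisy background is available for stress
#' tests.
#'
#' @param n_taxa ingroup leaf count (a power of 2 for `"balanced"`).
#' @param tree_shape `"balanced"`, `"caterpillar"` or `"random"`.
#' @param n_genes,sites_per_gene partition geometry.
#' @param apomorphies_per_clade planted columns per codable clade.
#' @param homoplasy_rate per-planted-column probability of one convergent
#'   outside leaf.
#' @param gene_missing_p,site_missing_p forwarded to [inject_missing()]
#'   (applied to ingroup rows) when positive.
#' @param background_noise_p per-background-cell probability of a random
#'   substitution (default 0: fully conserved background).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list: `tree` (with `outgroup` attribute), `matrix`, `partition`,
#'   `truth` (tibble: clade_label, node, gene, site, from_state, to_state,
#'   homoplasy_leaf), `mask` (from [inject_missing()], or `NULL`), `params`.
#' @export
simulate_apomorphy_data <- function(n_taxa = 32, tree_shape = c("balanced",
                                    "caterpillar", "random"),
                                    n_genes = 10, sites_per_gene = 60,
                                    apomorphies_per_clade = 1,
                                    homoplasy_rate = 0,
                                    gene_missing_p = 0, site_missing_p = 0,
                                    background_noise_p = 0, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_taxa >= 4, n_genes >= 1, sites_per_gene >= 1,
            apomorphies_per_clade >= 1,
            homoplasy_rate >= 0, homoplasy_rate <= 1)
  set.seed(seed)
  ing <- switch(tree_shape,
    balanced = {
      if (log2(n_taxa) %% 1 != 0) stop("balanced shape needs a power-of-2 n_taxa",
                                       call. = FALSE)
      ape::stree(n_taxa, type = "balanced")
    },
    caterpillar = ape::stree(n_taxa, type = "left"),
    random = ape::rtree(n_taxa, br = NULL))
  ing$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  nwk <- ape::write.tree(ing)
  # two outgroup leaves in a basal trichotomy: the root state of a planted
  # column is then unambiguous (one change beats two), so clean planted
  # apomorphies are recoverable even for the ingroup-root clade
  phy <- ape::read.tree(text = paste0("(OUT1,OUT2,", sub(";$", "", nwk), ");"))
  phy <- prepare_tree(phy, outgroup = c("OUT1", "OUT2"))
  idx <- tree_index(phy)
  internal <- idx$preorder[idx$preorder > idx$n_tip]
  # proper ingroup clades only: the ingroup root is excluded because its
  # convergent (homoplasious) variant cannot be represented — every leaf
  # outside it is an outgroup leaf adjacent to the root, which collapses
  # the second change
  n_ingroup <- length(idx$ingroup_tips)
  clades <- internal[vapply(internal, function(v)
    idx$is_ingroup[v] && length(idx$leaves_under[[v]]) >= 2 &&
      length(idx$leaves_under[[v]]) < n_ingroup, logical(1))]
  n_cols <- n_genes * sites_per_gene
  n_planted <- length(clades) * apomorphies_per_clade
  if (n_planted > n_cols) {
    stop("more planted columns (", n_planted, ") than available sites (",
         n_cols, ")", call. = FALSE)
  }
  partition <- gene_partition(sprintf("g%02d", seq_len(n_genes)),
                              start = (seq_len(n_genes) - 1L) * sites_per_gene + 1L,
                              end = seq_len(n_genes) * sites_per_gene)
  taxa <- phy$tip.label
  mat <- matrix(sample(AA_STATES, n_cols, replace = TRUE),
                nrow = length(taxa), ncol = n_cols, byrow = TRUE)
  rownames(mat) <- taxa
  if (background_noise_p > 0) {
    flip <- which(matrix(stats::runif(length(mat)) < background_noise_p,
                         nrow(mat)))
    mat[flip] <- sample(AA_STATES, length(flip), replace = TRUE)
  }
  planted_sites <- sort(sample(n_cols, n_planted))
  truth <- vector("list", n_planted)
  k <- 0L
  for (v in clades) {
    clade_tips <- clade_leaf_labels(idx, v)
    for (a in seq_len(apomorphies_per_clade)) {
      k <- k + 1L
      s <- planted_sites[k]
      sts <- sample(AA_STATES, 2)
      from <- sts[1]; to <- sts[2]
      mat[, s] <- from
      mat[clade_tips, s] <- to
      hleaf <- NA_character_
      if (stats::runif(1) < homoplasy_rate) {
        outside <- setdiff(idx$phy$tip.label[idx$ingroup_tips], clade_tips)
        ok <- vapply(outside, function(l) {
          grp <- c(clade_tips, l)
          !any(vapply(internal, function(w)
            setequal(clade_leaf_labels(idx, w), grp), logical(1)))
        }, logical(1))
        pool <- outside[ok]
        if (length(pool) == 0) stop("no non-clade-forming convergence leaf available",
                                    call. = FALSE)
        hleaf <- sample(pool, 1)
        mat[hleaf, s] <- to
      }
      truth[[k]] <- tibble::tibble(clade_label = idx$labels[v], node = v,
                                   gene = gene_of(partition, s), site = s,
                                   from_state = from, to_state = to,
                                   homoplasy_leaf = hleaf)
    }
  }
  mat <- as_aa_matrix(mat)
  mask <- NULL
  if (gene_missing_p > 0 || site_missing_p > 0) {
    inj <- inject_missing(mat, partition, gene_missing_p, site_missing_p,
                          seed = seed + 1L,
                          taxa = idx$phy$tip.label[idx$ingroup_tips])
    mat <- inj$matrix
    mask <- inj$mask
  }
  list(tree = phy, matrix = mat, partition = partition,
       truth = dplyr::bind_rows(truth), mask = mask,
       params = list(n_taxa = n_taxa, tree_shape = tree_shape,
                     n_genes = n_genes, sites_per_gene = sites_per_gene,
                     apomorphies_per_clade = apomorphies_per_clade,
                     homoplasy_rate = homoplasy_rate,
                     gene_missing_p = gene_missing_p,
                     site_missing_p = site_missing_p,
                     background_noise_p = background_noise_p, seed = seed))
}

#' Inject the two missing-data processes
#'
#' Emulates transcriptome incompleteness: per (taxon, gene), with
#' probability `gene_missing_p` the whole gene segment becomes `?` (gene
#' absent); independently, each surviving cell becomes `X` with probability
#' `site_missing_p` (missing residue).
#'
#' @param matrix an [as_aa_matrix()].
#' @param partition a [gene_partition()] covering the columns.
#' @param gene_missing_p,site_missing_p probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @param taxa rows to degrade (default: all).
#' @return list: `matrix` (degraded) and `mask` (tibble: `taxon`, `type`
#'   (`gene`/`site`), `gene`, `site`).
#' @export
inject_missing <- function(matrix, partition, gene_missing_p = 0,
                           site_missing_p = 0, seed = 1L,
                           taxa = rownames(matrix)) {
  stopifnot(gene_missing_p >= 0, gene_missing_p <= 1,
            site_missing_p >= 0, site_missing_p <= 1)
  set.seed(seed)
  mask <- list()
  for (tx in taxa) {
    for (g in seq_len(nrow(partition))) {
      if (stats::runif(1) < gene_missing_p) {
        cols <- partition$start[g]:partition$end[g]
        matrix[tx, cols] <- "?"
        mask[[length(mask) + 1L]] <- tibble::tibble(
          taxon = tx, type = "gene", gene = partition$gene[g], site = NA_integer_)
      }
    }
    alive <- which(matrix[tx, ] != "?")
    hit <- alive[stats::runif(length(alive)) < site_missing_p]
    if (length(hit) > 0) {
      matrix[tx, hit] <- "X"
      mask[[length(mask) + 1L]] <- tibble::tibble(
        taxon = tx, type = "site", gene = gene_of(partition, hit), site = hit)
    }
  }
  mask <- if (length(mask) > 0) dplyr::bind_rows(mask) else
    tibble::tibble(taxon = character(0), type = character(0),
                   gene = character(0), site = integer(0))
  list(matrix = as_aa_matrix(unclass(matrix)), mask = mask)
}

#' Split one taxon's alignment row into per-gene query sequences
#'
#' Convenience for querying a database with a taxon's own data (or a
#' degraded copy): genes whose whole segment is `?` are declared absent.
#'
#' @param matrix an [as_aa_matrix()].
#' @param partition a [gene_partition()].
#' @param taxon row name.
#' @return named list gene -> character vector, omitting absent genes.
#' @export
query_from_row <- function(matrix, partition, taxon) {
  out <- list()
  for (g in seq_len(nrow(partition))) {
    seg <- matrix[taxon, partition$start[g]:partition$end[g]]
    if (all(seg == "?")) next
    out[[partition$gene[g]]] <- seg
  }
  out
}
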