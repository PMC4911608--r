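#' Filter the apolist into candidate apomorphies
#'
#' Drops ambiguous changes, keeps entries with `ci >= ci_threshold`, and
#' annotates each survivor with its clade size, carrier count and
#' missing-leaf count at the site. Lowering the threshold never removes a
#' candidate (the candidate sets are nested across thresholds).
#'
#' @param apolist tibble from [mine_apomorphies()].
#' @param tree the tree the apolist was mined on.
#' @param matrix the alignment the apolist was mined on.
#' @param ci_threshold consistency-index threshold in `(0, 1]`; the study
#'   design uses 1.0, 0.9 and 0.8.
#' @return candidates tibble: apolist columns plus `n_clade_taxa`,
#'   `n_carriers`, `n_missing_leaves`.
#' @export
filter_candidates <- function(apolist, tree, matrix, ci_threshold = 1.0) {
  if (!is.numeric(ci_threshold) || ci_threshold <= 0 || ci_threshold > 1) {
    stop("ci_threshold must be in (0, 1]", call. = FALSE)
  }
  idx <- tree_index(tree)
  kept <- dplyr::filter(apolist, !.data$ambiguous, .data$ci >= ci_threshold)
  if (nrow(kept) == 0) {
    return(dplyr::mutate(kept, n_clade_taxa = integer(0),
                         n_carriers = integer(0), n_missing_leaves = integer(0)))
  }
  ann <- purrr::pmap(list(kept$child_node, kept$site, kept$to_state),
    function(node, site, to_state) {
      taxa <- clade_leaf_labels(idx, node)
      states <- matrix[taxa, site]
      miss <- is_missing_symbol(states)
      c(n_clade_taxa = length(taxa),
        n_carriers = sum(states == to_state & !miss),
        n_missing_leaves = sum(miss))
    })
  ann <- do.call(rbind, ann)
  dplyr::bind_cols(kept, tibble::as_tibble(ann))
}

#' Assemble a filtered-site sub-dataset
#'
#' Restricts the alignment to the sorted union of candidate sites. A site
#' appears once even if it hosts several candidates, so the candidate count
#' (comparable counts of "apomorphies identified") and the column count are
#' reported separately as attributes.
#'
#' @param matrix an [as_aa_matrix()].
#' @param candidates tibble from [filter_candidates()].
#' @return an [as_aa_matrix()] with attributes `n_candidates` and `sites`
#'   (original column indices).
#' @export
build_subdataset <- function(matrix, candidates) {
  if (nrow(candidates) == 0) stop("no candidates to assemble", call. = FALSE)
  sites <- sort(unique(candidates$site))
  sub <- matrix[, sites, drop = FALSE]
  sub <- as_aa_matrix(sub)
  attr(sub, "n_candidates") <- nrow(candidates)
  attr(sub, "sites") <- sites
  sub
}
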