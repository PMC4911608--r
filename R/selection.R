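#' Screening configuration
#'
#' Knobs for the per-clade apomorphy screen. The source study states that
#' missing taxa "should be limited" and that clades with "extremely low
#' coverage" are skipped without quantifying either; both are explicit,
#' logged knobs here.
#'
#' @param max_missing_fraction reject a candidate when the fraction of its
#'   clade's leaves missing at the site exceeds this (default 0.5).
#' @param min_clade_taxa clades with fewer sampled leaves are never coded
#'   (default 2 — the singleton rule; raise it to drop low-coverage clades).
#' @param allow_multistate admit binary per-subclade-uniform trends as codes.
#' @param codes_per_clade how many codes to retain per clade (redundant
#'   multi-code databases; default 1).
#' @return a list of class `screening_config`.
#' @export
screening_config <- function(max_missing_fraction = 0.5, min_clade_taxa = 2L,
                             allow_multistate = TRUE, codes_per_clade = 1L) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_clade_taxa >= 2L, codes_per_clade >= 1L,
            is.logical(allow_multistate))
  structure(list(max_missing_fraction = max_missing_fraction,
                 min_clade_taxa = as.integer(min_clade_taxa),
                 allow_multistate = isTRUE(allow_multistate),
                 codes_per_clade = as.integer(codes_per_clade)),
            class = "screening_config")
}

#' Does a candidate's derived state leak into the sister group?
#'
#' The first selection criterion: an apomorphic state also found in the
#' clade's sister group cannot be used (it may be a plesiomorphy). At
#' polytomies the sister group is the union of the other children. Missing
#' symbols in the sister group do not count as overlap (they are handled by
#' [missing_check()]).
#'
#' @param candidate one candidate row (list or one-row tibble).
#' @param tree,matrix the mining inputs.
#' @return `TRUE` if the derived state occurs in any non-missing sister leaf.
#' @export
sister_overlap <- function(candidate, tree, matrix) {
  idx <- if (is.list(tree) && !inherits(tree, "phylo")) tree else tree_index(tree)
  node <- candidate$child_node
  if (idx$parent[node] == 0L) stop("the root is never coded", call. = FALSE)
  sis <- sister_leaf_labels(idx, node)
  states <- matrix[sis, candidate$site]
  any(states == candidate$to_state & !is_missing_symbol(states))
}

#' Missing-data screen for one candidate
#'
#' Rejects with `sister_or_basal_missing` when the whole sister group, or
#' the whole earliest-branching child lineage of the clade, is missing at
#' the site (the state of the comparison group is then unknowable), and with
#' `clade_missing_excess` when the fraction of clade leaves missing at the
#' site exceeds `config$max_missing_fraction`.
#'
#' @inheritParams sister_overlap
#' @param config a [screening_config()].
#' @return `"ok"`, `"sister_or_basal_missing"` or `"clade_missing_excess"`.
#' @export
missing_check <- function(candidate, tree, matrix, config = screening_config()) {
  idx <- if (is.list(tree) && !inherits(tree, "phylo")) tree else tree_index(tree)
  node <- candidate$child_node
  site <- candidate$site
  all_missing <- function(taxa) {
    length(taxa) > 0 && all(is_missing_symbol(matrix[taxa, site]))
  }
  if (all_missing(sister_leaf_labels(idx, node))) return("sister_or_basal_missing")
  kids <- idx$children[[node]]
  if (length(kids) > 0) {
    basal <- clade_leaf_labels(idx, kids[1])  # earliest-branching child lineage
    if (all_missing(basal)) return("sister_or_basal_missing")
  }
  clade <- clade_leaf_labels(idx, node)
  frac <- mean(is_missing_symbol(matrix[clade, site]))
  if (frac > config$max_missing_fraction) return("clade_missing_excess")
  "ok"
}

#' Priority class of a surviving candidate
#'
#' `"unique"` when the derived state occurs nowhere outside the clade in the
#' whole matrix (autapomorphic for the clade — highest priority);
#' `"clade_unique"` when it occurs elsewhere (but, by the overlap screen,
#' not in the sister group) and the clade's non-missing leaves are uniform;
#' `"multistate_trend"` when the clade shows exactly two states, each
#' uniform within one child subclade (the binary `|T/V|` pattern); anything
#' else is `"inconsistent_multistate"` and is rejected.
#'
#' @inheritParams sister_overlap
#' @return list with `class` and `states` (the 1- or 2-state set).
#' @export
uniqueness_class <- function(candidate, tree, matrix) {
  idx <- if (is.list(tree) && !inherits(tree, "phylo")) tree else tree_index(tree)
  node <- candidate$child_node
  site <- candidate$site
  clade <- clade_leaf_labels(idx, node)
  col <- matrix[, site]
  inside <- col[clade]
  inside <- inside[!is_missing_symbol(inside)]
  outside <- col[setdiff(rownames(matrix), clade)]
  outside <- outside[!is_missing_symbol(outside)]
  in_states <- sort(unique(inside))
  if (length(in_states) == 1L) {
    cls <- if (!(candidate$to_state %in% outside)) "unique" else "clade_unique"
    return(list(class = cls, states = in_states))
  }
  if (length(in_states) == 2L) {
    uniform_per_child <- all(vapply(idx$children[[node]], function(k) {
      s <- matrix[clade_leaf_labels(idx, k), site]
      s <- s[!is_missing_symbol(s)]
      length(unique(s)) <= 1L
    }, logical(1)))
    sis <- matrix[sister_leaf_labels(idx, node), site]
    sis <- sis[!is_missing_symbol(sis)]
    if (uniform_per_child && !any(in_states %in% sis)) {
      return(list(class = "multistate_trend", states = in_states))
    }
  }
  list(class = "inconsistent_multistate", states = in_states)
}

#' Screen every candidate and report verdicts
#'
#' Applies, in order: the clade-size rule, the sister-overlap criterion, the
#' missing-data criteria, and the uniqueness classification. Every candidate
#' receives exactly one verdict.
#'
#' @param candidates tibble from [filter_candidates()].
#' @param tree,matrix the mining inputs.
#' @param config a [screening_config()].
#' @return the candidates tibble plus `verdict` (`accepted`/`rejected`),
#'   `reason` (`NA` when accepted), `priority_class` and `states` (a
#'   `"T"`/`"T/V"` string).
#' @export
screen_candidates <- function(candidates, tree, matrix,
                              config = screening_config()) {
  idx <- tree_index(tree)
  n <- nrow(candidates)
  verdict <- character(n); reason <- rep(NA_character_, n)
  p_class <- rep(NA_character_, n); states <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    n_leaves <- length(clade_leaf_labels(idx, cand$child_node))
    if (n_leaves < config$min_clade_taxa) {
      verdict[i] <- "rejected"
      reason[i] <- if (n_leaves == 1L) "singleton_clade" else "low_coverage"
      next
    }
    if (sister_overlap(cand, idx, matrix)) {
      verdict[i] <- "rejected"; reason[i] <- "sister_overlap"; next
    }
    mc <- missing_check(cand, idx, matrix, config)
    if (mc != "ok") { verdict[i] <- "rejected"; reason[i] <- mc; next }
    uc <- uniqueness_class(cand, idx, matrix)
    if (uc$class == "inconsistent_multistate" ||
        (uc$class == "multistate_trend" && !config$allow_multistate)) {
      verdict[i] <- "rejected"; reason[i] <- "inconsistent_multistate"; next
    }
    verdict[i] <- "accepted"
    p_class[i] <- uc$class
    states[i] <- paste(uc$states, collapse = "/")
  }
  dplyr::bind_cols(candidates,
                   tibble::tibble(verdict = verdict, reason = reason,
                                  priority_class = p_class, states = states))
}

#' Rank accepted candidates within each clade
#'
#' Order: priority class (`unique` > `clade_unique` > `multistate_trend`),
#' then fewer missing leaves, then broader gene (taxa with data in the gene,
#' descending), then `(gene, site)` lexicographically for determinism.
#'
#' @param accepted accepted rows from [screen_candidates()].
#' @param matrix the alignment (for gene breadth).
#' @param partition a [gene_partition()]; without one, breadth is constant.
#' @return the tibble ordered within clades, with `class_rank` and
#'   `gene_breadth` columns added.
#' @export
rank_candidates <- function(accepted, matrix, partition = NULL) {
  class_rank <- c(unique = 1L, clade_unique = 2L, multistate_trend = 3L)
  out <- dplyr::mutate(accepted,
                       class_rank = class_rank[.data$priority_class])
  if (!is.null(partition)) {
    gb <- gene_breadth(matrix, partition)
    out <- dplyr::left_join(out, gb, by = "gene")
    out$breadth <- dplyr::coalesce(out$breadth, 0L)
  } else {
    out$breadth <- 0L
  }
  dplyr::arrange(out, .data$child_node, .data$class_rank,
                 .data$n_missing_leaves, dplyr::desc(.data$breadth),
                 .data$gene, .data$site) |>
    dplyr::rename(gene_breadth = "breadth")
}

#' Select the codes for every qualifying clade
#'
#' Clades with fewer than `min_clade_taxa` sampled leaves are skipped. Each
#' remaining clade receives its top `codes_per_clade` ranked candidates; on
#' exact rank ties (same class, missing count and gene breadth) a greedy
#' pass prefers genes already chosen for other clades, so that fewer gene
#' markers end up in the database (gene economy as a tie-break, not a hard
#' constraint). Clades with no accepted candidate are left uncoded and
#' reported.
#'
#' @param tree,matrix,partition the mining inputs.
#' @param candidates tibble from [filter_candidates()].
#' @param config a [screening_config()].
#' @return list with `selection` (tibble: one row per chosen code, in tree
#'   pre-order), `report` (the full screening report) and `uncoded`
#'   (clade labels with zero accepted candidates).
#' @export
select_codes <- function(tree, candidates, matrix, partition = NULL,
                         config = screening_config()) {
  idx <- tree_index(tree)
  report <- screen_candidates(candidates, tree, matrix, config)
  acc <- dplyr::filter(report, .data$verdict == "accepted")
  ranked <- rank_candidates(acc, matrix, partition)
  pre_nodes <- idx$preorder[idx$preorder > idx$n_tip]
  chosen_genes <- character(0)
  picks <- list()
  for (node in pre_nodes) {
    rows <- ranked[ranked$child_node == node, , drop = FALSE]
    if (nrow(rows) == 0) next
    take <- min(config$codes_per_clade, nrow(rows))
    sel_i <- integer(0)
    remaining <- rows
    for (k in seq_len(take)) {
      key <- paste(remaining$class_rank, remaining$n_missing_leaves,
                   remaining$gene_breadth)
      top <- which(key == key[1])
      prefer <- top[remaining$gene[top] %in% chosen_genes]
      pick <- if (length(prefer) > 0) prefer[1] else top[1]
      chosen_genes <- union(chosen_genes, remaining$gene[pick])
      picks[[length(picks) + 1L]] <- remaining[pick, ]
      remaining <- remaining[-pick, , drop = FALSE]
      if (nrow(remaining) == 0) break
    }
  }
  selection <- dplyr::bind_rows(picks)
  coded_nodes <- unique(selection$child_node)
  codable <- pre_nodes[vapply(pre_nodes, function(v)
    length(idx$leaves_under[[v]]) >= config$min_clade_taxa &&
      idx$is_ingroup[v], logical(1))]
  uncoded <- idx$labels[setdiff(codable, coded_nodes)]
  if (length(uncoded) > 0) {
    message(length(uncoded), " codable clade(s) left uncoded: ",
            paste(utils::head(uncoded, 10), collapse = ", "),
            if (length(uncoded) > 10) ", ..." else "")
  }
  list(selection = selection, report = report, uncoded = uncoded)
}
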