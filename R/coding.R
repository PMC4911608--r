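#' Sequential base-36 code IDs
#'
#' Coded nodes are numbered in pre-order with consecutive two-character
#' base-36 tokens (`00`, `01`, ..., `0Z`, `10`, ...), optionally carrying a
#' one-letter dataset prefix (`S00`, `S01`, ... for a secondary database).
#' Dense IDs are emitted; sparse IDs (gaps left by unused codes) are
#' accepted on input.
#'
#' @param tree rooted `ape::phylo`.
#' @param coded_nodes integer node ids to code (any order).
#' @param prefix optional one-letter database prefix.
#' @return tibble `node`, `id` in pre-order.
#' @export
assign_ids <- function(tree, coded_nodes, prefix = "") {
  idx <- if (is.list(tree) && !inherits(tree, "phylo")) tree else tree_index(tree)
  ordered <- idx$preorder[idx$preorder %in% coded_nodes]
  tibble::tibble(node = ordered,
                 id = paste0(prefix, base36_id(seq_along(ordered) - 1L)))
}

base36_id <- function(i) {
  digits <- c(0:9, LETTERS)
  if (any(i < 0 | i >= 36L * 36L)) stop("id index out of base-36 range", call. = FALSE)
  paste0(digits[i %/% 36L + 1L], digits[i %% 36L + 1L])
}

#' Build the code database from a selection
#'
#' Assigns IDs, links every coded node to its nearest coded ancestor (the
#' lineage trie), and materializes the designed barcode of every terminal
#' category (coded node with no coded descendant). For a binary
#' (`multistate_trend`) code, the designed state written into a terminal's
#' barcode is the state carried by that terminal's side of the clade, read
#' from the alignment.
#'
#' @param selection selection tibble from [select_codes()].
#' @param tree the coded tree.
#' @param matrix the alignment (needed to resolve binary designed states;
#'   optional when every code is single-state).
#' @param prefix optional ID prefix letter.
#' @return a `code_db` object.
#' @export
build_code_database <- function(selection, tree, matrix = NULL, prefix = "") {
  if (nrow(selection) == 0) stop("empty selection: nothing to encode", call. = FALSE)
  idx <- tree_index(tree)
  ids <- assign_ids(idx, unique(selection$child_node), prefix = prefix)
  id_of <- stats::setNames(ids$id, ids$node)
  # nearest coded ancestor
  parent_id <- vapply(ids$node, function(v) {
    p <- idx$parent[v]
    while (p != 0L && !(p %in% ids$node)) p <- idx$parent[p]
    if (p == 0L) NA_character_ else unname(id_of[as.character(p)])
  }, character(1))
  parent_of <- stats::setNames(parent_id, ids$id)
  sel <- dplyr::mutate(selection, id = unname(id_of[as.character(.data$child_node)]))
  codes <- tibble::tibble(
    id = sel$id,
    node = sel$child_node,
    clade_label = sel$clade_label,
    parent_id = unname(parent_of[sel$id]),
    site = sel$site,
    gene = sel$gene,
    states = sel$states,
    plesiomorphic = sel$from_state
  )
  codes <- dplyr::arrange(codes, match(.data$id, ids$id))
  if (anyDuplicated(paste(codes$id, codes$site))) {
    stop("duplicate (id, site) code entries", call. = FALSE)
  }
  # terminals: coded nodes with no coded descendant
  has_coded_desc <- vapply(ids$node, function(v) {
    any(vapply(setdiff(ids$node, v), function(w) {
      p <- idx$parent[w]
      while (p != 0L) { if (p == v) return(TRUE); p <- idx$parent[p] }
      FALSE
    }, logical(1)))
  }, logical(1))
  terminals <- tibble::tibble(name = idx$labels[ids$node[!has_coded_desc]],
                              id = ids$id[!has_coded_desc])
  designed <- lapply(seq_len(nrow(terminals)), function(i) {
    path <- id_path(parent_of, terminals$id[i])
    st <- vapply(path, function(cid) {
      row <- codes[codes$id == cid, ][1, ]
      members <- strsplit(row$states, "/")[[1]]
      if (length(members) == 1L) return(members)
      if (is.null(matrix)) stop("matrix needed to resolve binary designed states",
                                call. = FALSE)
      term_node <- terminals_node(codes, terminals$id[i])
      leaf_states <- matrix[clade_leaf_labels(idx, term_node), row$site]
      leaf_states <- leaf_states[!is_missing_symbol(leaf_states)]
      hit <- members[members %in% leaf_states]
      if (length(hit) > 0) hit[1] else members[1]
    }, character(1))
    new_barcode(st, path)
  })
  names(designed) <- terminals$name
  labels <- stats::setNames(codes$clade_label[!duplicated(codes$id)],
                            codes$id[!duplicated(codes$id)])
  new_code_db(codes, ids$id, terminals, designed, labels)
}

terminals_node <- function(codes, id) codes$node[codes$id == id][1]

id_path <- function(parent_of, id) {
  path <- id
  p <- parent_of[[id]]
  while (!is.na(p)) { path <- c(p, path); p <- parent_of[[p]] }
  path
}

new_code_db <- function(codes, id_order, terminals, designed, labels) {
  structure(list(codes = codes, id_order = id_order, terminals = terminals,
                 designed = designed, labels = labels),
            class = "code_db")
}

#' @export
print.code_db <- function(x, ...) {
  cat("<code_db> ", length(x$id_order), " coded clades, ",
      nrow(x$terminals), " terminal categories\n", sep = "")
  invisible(x)
}

#' Build a code database from designed barcode strings
#'
#' Reconstructs the lineage trie from the designed barcodes of terminal
#' categories (e.g. the columns of a published query-test table): each
#' barcode is a root-to-terminal code path, consecutive pairs define
#' parent/child ID links, and the state at each ID must be consistent
#' across barcodes.
#'
#' @param barcodes character vector of designed barcode serializations.
#' @param terminal_names names of the terminal categories, same length.
#' @param clade_labels optional named character vector labelling internal
#'   IDs (e.g. `c("08" = "Pterygota")`).
#' @return a `code_db` object (no sites/genes; barcode-only database).
#' @export
db_from_barcodes <- function(barcodes, terminal_names, clade_labels = NULL) {
  stopifnot(length(barcodes) == length(terminal_names))
  parsed <- lapply(barcodes, parse_barcode)
  state_of <- character(0); parent_of <- character(0)
  for (bc in parsed) {
    prev <- NA_character_
    for (j in seq_len(nrow(bc))) {
      id <- bc$id[j]; st <- bc$state[j]
      if (!is.na(state_of[id] %||% NA_character_) && state_of[[id]] != st) {
        stop("conflicting designed states for id ", id, call. = FALSE)
      }
      state_of[id] <- st
      if (id %in% names(parent_of)) {
        if (!identical(parent_of[[id]], prev)) {
          stop("conflicting parents for id ", id, call. = FALSE)
        }
      } else {
        parent_of[id] <- prev
      }
      prev <- id
    }
  }
  ids <- sort(names(state_of))  # base-36 ascending = assignment pre-order
  dedup <- !duplicated(terminal_names)
  terminals <- tibble::tibble(name = terminal_names[dedup],
                              id = vapply(parsed[dedup], function(b)
                                b$id[nrow(b)], character(1)))
  labels <- stats::setNames(paste0("clade_", ids), ids)
  labels[terminals$id] <- terminals$name
  if (!is.null(clade_labels)) labels[names(clade_labels)] <- clade_labels
  codes <- tibble::tibble(
    id = ids, node = NA_integer_, clade_label = unname(labels[ids]),
    parent_id = unname(parent_of[ids]), site = NA_integer_,
    gene = NA_character_, states = unname(state_of[ids]),
    plesiomorphic = NA_character_
  )
  designed <- lapply(parsed[dedup], identity)
  names(designed) <- terminals$name
  new_code_db(codes, ids, terminals, designed, labels)
}

# ---- barcodes -------------------------------------------------------------

new_barcode <- function(state, id) {
  b <- tibble::tibble(state = as.character(state), id = as.character(id))
  class(b) <- c("apo_barcode", class(b))
  b
}

#' Designed barcode and lineage prefix of a clade
#'
#' `barcode_of()` returns the full root-to-clade code sequence (prefix plus
#' the clade's own diagnostic code); `lineage_prefix()` omits the clade's
#' own code. A first-level clade has an empty prefix.
#'
#' @param db a `code_db`.
#' @param clade a terminal category name, a clade label, or a code ID.
#' @return an `apo_barcode` tibble with columns `state`, `id`.
#' @export
barcode_of <- function(db, clade) {
  id <- resolve_clade_id(db, clade)
  if (!is.na(match(id, db$terminals$id))) {
    nm <- db$terminals$name[match(id, db$terminals$id)]
    return(db$designed[[nm]])
  }
  parent_of <- stats::setNames(db$codes$parent_id, db$codes$id)
  path <- id_path(parent_of, id)
  state_of <- stats::setNames(db$codes$states, db$codes$id)
  new_barcode(unname(state_of[path]), path)
}

#' @rdname barcode_of
#' @export
lineage_prefix <- function(db, clade) {
  bc <- barcode_of(db, clade)
  bc[-nrow(bc), , drop = FALSE]
}

resolve_clade_id <- function(db, clade) {
  if (clade %in% db$codes$id) return(clade)
  hit <- match(clade, db$terminals$name)
  if (!is.na(hit)) return(db$terminals$id[hit])
  hit <- match(clade, db$labels)
  if (!is.na(hit)) return(names(db$labels)[hit])
  stop("unknown clade: ", clade, call. = FALSE)
}

#' Serialize and parse barcodes
#'
#' The serialization is `<state>_<id>_` repeated, e.g.
#' `T_00_I_02_G_03_`. Binary designed states render as the compact display
#' form `|T/V|`. `parse_barcode()` is the exact inverse on well-formed
#' strings; it also normalizes the known typographical variant of a
#' single-character ID missing its leading `1` (e.g. `X_A_` is read as
#' `(X, 1A)`) with a message.
#'
#' @param barcode an `apo_barcode` tibble.
#' @return `format_barcode()`: the serialized string.
#' @export
format_barcode <- function(barcode) {
  st <- ifelse(grepl("/", barcode$state, fixed = TRUE),
               paste0("|", barcode$state, "|"), barcode$state)
  paste0(paste0(st, "_", barcode$id, "_"), collapse = "")
}

#' @rdname format_barcode
#' @param string a serialized barcode.
#' @export
parse_barcode <- function(string) {
  toks <- strsplit(string, "_", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) %% 2L != 0L) {
    stop("malformed barcode (odd token count) at token ", length(toks),
         ": ", string, call. = FALSE)
  }
  state <- toks[seq(1, length(toks), by = 2)]
  id <- toks[seq(2, length(toks), by = 2)]
  state <- gsub("^\\||\\|$", "", state)
  ok_state <- state %in% c(AA_STATES, "X", "?") | grepl("/", state)
  if (any(!ok_state)) {
    stop("malformed state token at pair ", which(!ok_state)[1], ": ",
         state[which(!ok_state)[1]], call. = FALSE)
  }
  short <- nchar(id) == 1L
  if (any(short)) {
    message("normalizing ", sum(short), " single-character id token(s): ",
            paste(id[short], collapse = ", "), " -> ",
            paste(paste0("1", id[short]), collapse = ", "))
    id[short] <- paste0("1", id[short])
  }
  bad_id <- !grepl("^[A-Za-z]?[0-9A-Z]{2}$", id)
  if (any(bad_id)) {
    stop("malformed id token at pair ", which(bad_id)[1], ": ",
         id[which(bad_id)[1]], call. = FALSE)
  }
  new_barcode(state, id)
}

#' Compact state string of a barcode
#'
#' Concatenation of the state tokens (binary states wrapped as `|T/V|`),
#' e.g. `TIGERSINNNAY` for a single-state lineage.
#'
#' @param barcode an `apo_barcode`.
#' @return a single string.
#' @export
compact_states <- function(barcode) {
  st <- ifelse(grepl("/", barcode$state, fixed = TRUE),
               paste0("|", barcode$state, "|"), barcode$state)
  paste0(st, collapse = "")
}

#' Two-dimensional sequential code table
#'
#' Rows are terminal categories, columns are IDs in database order; a cell
#' holds the designed state when the ID lies on the row's lineage, else it
#' is blank.
#'
#' @param db a `code_db`.
#' @return a tibble with a `terminal` column plus one column per ID.
#' @export
export_code_table <- function(db) {
  cells <- matrix("", nrow = nrow(db$terminals), ncol = length(db$id_order),
                  dimnames = list(NULL, db$id_order))
  for (i in seq_len(nrow(db$terminals))) {
    bc <- db$designed[[db$terminals$name[i]]]
    cells[i, bc$id] <- bc$state
  }
  dplyr::bind_cols(tibble::tibble(terminal = db$terminals$name),
                   tibble::as_tibble(cells))
}

children_ids <- function(db, parent_id) {
  sel <- if (is.na(parent_id)) is.na(db$codes$parent_id) else
    !is.na(db$codes$parent_id) & db$codes$parent_id == parent_id
  ids <- unique(db$codes$id[sel])
  ids[order(match(ids, db$id_order))]
}
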