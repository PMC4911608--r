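#' Observation of a query against a code database
#'
#' An observation holds, for every code in the database that could be read,
#' one token: an amino acid, `X` (site missing within a present gene) or `?`
#' (gene absent). Codes with no token at all (e.g. off-lineage codes of a
#' published generated barcode) are treated as unknown — they can never
#' positively confirm a branch.
#'
#' `extract_states()` reads the tokens from per-gene query sequences
#' pre-aligned to the database alignment's column space.
#'
#' @param db a `code_db` whose codes carry `site` and `gene`.
#' @param gene_seqs named list, gene name -> aligned query sequence (a
#'   string or character vector spanning exactly that gene's columns).
#'   Genes absent from the list are declared absent (`?`).
#' @param partition the [gene_partition()] of the database alignment.
#' @return observation tibble: `id`, `site`, `token`.
#' @export
extract_states <- function(db, gene_seqs, partition) {
  codes <- db$codes
  if (any(is.na(codes$site))) {
    stop("database carries no site/gene coordinates (barcode-only db)",
         call. = FALSE)
  }
  gene_seqs <- lapply(gene_seqs, function(s)
    if (length(s) == 1L && is.character(s)) strsplit(toupper(s), "")[[1]] else toupper(s))
  tok <- character(nrow(codes))
  for (i in seq_len(nrow(codes))) {
    g <- codes$gene[i]
    row <- match(g, partition$gene)
    if (is.na(row)) stop("code gene not in partition: ", g, call. = FALSE)
    width <- partition$end[row] - partition$start[row] + 1L
    if (!g %in% names(gene_seqs)) { tok[i] <- "?"; next }
    s <- gene_seqs[[g]]
    if (length(s) != width) {
      stop("query length mismatch for gene ", g, ": got ", length(s),
           ", expected ", width, call. = FALSE)
    }
    ch <- s[codes$site[i] - partition$start[row] + 1L]
    tok[i] <- if (ch == "?") "?" else if (ch %in% AA_STATES) ch else "X"
  }
  tibble::tibble(id = codes$id, site = codes$site, token = tok)
}

#' @rdname extract_states
#' @param barcode an `apo_barcode` (e.g. a parsed generated barcode); only
#'   the codes present in the barcode receive tokens.
#' @export
observation_from_barcode <- function(db, barcode) {
  tibble::tibble(id = barcode$id, site = NA_integer_, token = barcode$state)
}

# ---- per-id judgment ------------------------------------------------------
# Aggregates the code rows of each id: "match" when at least ceil(k/2) of
# the k non-missing codes match the designed state set, "missing" when all
# codes are missing/unknown, "mismatch" otherwise.
judge_ids <- function(db, observation) {
  tok_of <- stats::setNames(observation$token,
                            paste(observation$id, observation$site))
  res <- character(length(db$id_order))
  names(res) <- db$id_order
  for (id in db$id_order) {
    rows <- db$codes[db$codes$id == id, , drop = FALSE]
    verdicts <- vapply(seq_len(nrow(rows)), function(j) {
      key1 <- paste(id, rows$site[j]); key2 <- paste(id, NA)
      tok <- unname(tok_of[key1])
      if (is.na(tok)) tok <- unname(tok_of[key2])
      if (is.na(tok) || tok %in% c("X", "?", "-")) return("missing")
      members <- strsplit(rows$states[j], "/")[[1]]
      if (tok %in% members) "match" else "mismatch"
    }, character(1))
    nm <- sum(verdicts != "missing")
    res[id] <- if (nm == 0L) "missing" else
      if (sum(verdicts == "match") >= ceiling(nm / 2)) "match" else "mismatch"
  }
  res
}

#' Assign a query by root-to-leaf barcode matching
#'
#' Walks the lineage trie from the root. At each step a child is judged
#' `match` (observed amino acid in its designed state set), `mismatch`
#' (observed amino acid outside the set — that branch is excluded) or
#' `missing` (`X`, `?`, or unobserved). On a missing judgment the walk may
#' descend past the code and use deeper codes: a child is *confirmable*
#' while some downstream code matches with no non-missing mismatch on the
#' way. The walk descends while exactly one child is confirmable (or
#' exactly one matches directly); it stops when none is (all children
#' mismatched: `exhausted_mismatch`; otherwise `unresolved_missing`) or a
#' terminal is reached. The assigned clade is the deepest node whose own
#' code matched non-missing.
#'
#' @param db a `code_db`.
#' @param observation tibble from [extract_states()] /
#'   [observation_from_barcode()], or a named token vector keyed by ID.
#' @return list: `assigned_id`, `assigned_label`, `stop_reason`
#'   (`terminal`, `exhausted_mismatch`, `unresolved_missing`), `path`
#'   (IDs walked), `judgments` (named vector over all IDs),
#'   `complete_match`, `n_X`, `n_question`.
#' @export
assign_query <- function(db, observation) {
  if (!is.data.frame(observation)) {
    observation <- tibble::tibble(id = names(observation), site = NA_integer_,
                                  token = unname(observation))
  }
  J <- judge_ids(db, observation)
  kids_of <- function(pid) children_ids(db, pid)
  confirm_env <- new.env(parent = emptyenv())
  confirmable <- function(id) {
    key <- id
    if (!is.null(confirm_env[[key]])) return(confirm_env[[key]])
    v <- switch(J[[id]],
                mismatch = FALSE,
                match = TRUE,
                missing = {
                  kk <- kids_of(id)
                  length(kk) > 0 && any(vapply(kk, confirmable, logical(1)))
                })
    confirm_env[[key]] <- v
    v
  }
  pid <- NA_character_
  path <- character(0)
  assigned <- NA_character_
  reason <- NA_character_
  repeat {
    kids <- kids_of(pid)
    if (length(kids) == 0L) { reason <- "terminal"; break }
    conf <- kids[vapply(kids, confirmable, logical(1))]
    direct <- kids[J[kids] == "match"]
    step <- if (length(conf) == 1L) conf else
      if (length(direct) == 1L) direct else NA_character_
    if (is.na(step)) {
      reason <- if (all(J[kids] == "mismatch")) "exhausted_mismatch" else
        "unresolved_missing"
      break
    }
    path <- c(path, step)
    if (J[[step]] == "match") assigned <- step
    pid <- step
  }
  is_terminal <- !is.na(assigned) && assigned %in% db$terminals$id
  complete <- is_terminal && length(path) > 0 &&
    assigned == path[length(path)] && all(J[path] == "match")
  toks <- observation$token
  list(assigned_id = assigned,
       assigned_label = if (is.na(assigned)) NA_character_ else
         unname(db$labels[assigned]),
       stop_reason = reason, path = path, judgments = J,
       complete_match = complete,
       n_X = sum(toks %in% c("X", "-")), n_question = sum(toks == "?"))
}

#' Categorize an assignment against the known truth
#'
#' `positive`: assigned to the right terminal category; `false_positive`:
#' assigned to a wrong terminal; `negative`: the truth lineage is
#' contradicted by a non-missing mismatch; `false_negative`: the walk
#' stopped above the terminal because of missing states on the remaining
#' path.
#'
#' @param db a `code_db`.
#' @param assignment result of [assign_query()].
#' @param truth_terminal the true terminal category name.
#' @return one of `"positive"`, `"false_positive"`, `"negative"`,
#'   `"false_negative"`.
#' @export
categorize <- function(db, assignment, truth_terminal) {
  truth_id <- db$terminals$id[match(truth_terminal, db$terminals$name)]
  if (is.na(truth_id)) stop("unknown truth terminal: ", truth_terminal,
                            call. = FALSE)
  a <- assignment$assigned_id
  if (!is.na(a) && a == truth_id) return("positive")
  if (!is.na(a) && a %in% db$terminals$id) return("false_positive")
  truth_path <- barcode_of(db, truth_terminal)$id
  if (any(assignment$judgments[truth_path] == "mismatch")) return("negative")
  "false_negative"
}

#' Evaluate a set of queries with known truth
#'
#' Runs [assign_query()] and [categorize()] per query and aggregates the
#' four category counts and the complete-match count.
#'
#' @param db a `code_db`.
#' @param queries tibble with columns `species`, `generated` (serialized
#'   generated barcode) and `truth` (terminal category name).
#' @return an `apo_query_eval` object; `tidy()` gives per-query rows,
#'   `glance()` the aggregate counts.
#' @export
evaluate_queries <- function(db, queries) {
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    bc <- suppressMessages(parse_barcode(queries$generated[i]))
    a <- assign_query(db, observation_from_barcode(db, bc))
    tibble::tibble(
      species = queries$species[i],
      generated_barcode = queries$generated[i],
      assigned = a$assigned_label,
      category = categorize(db, a, queries$truth[i]),
      truth = queries$truth[i],
      complete_match = a$complete_match,
      stop_reason = a$stop_reason,
      n_X = a$n_X, n_question = a$n_question
    )
  })
  structure(list(results = dplyr::bind_rows(rows), db = db),
            class = "apo_query_eval")
}

#' @export
print.apo_query_eval <- function(x, ...) {
  counts <- table(factor(x$results$category,
                         levels = c("positive", "false_negative",
                                    "false_positive", "negative")))
  cat("<apo_query_eval> ", nrow(x$results), " queries: ",
      paste(names(counts), counts, sep = "=", collapse = ", "),
      "; complete matches=", sum(x$results$complete_match), "\n", sep = "")
  invisible(x)
}

#' Missing-token provenance report
#'
#' Among all missing tokens over a set of observations, the fraction
#' attributable to missing residues (`X`) versus missing genes (`?`), with
#' per-query counts. With no missing tokens the fractions are `NA` and the
#' counts zero.
#'
#' @param observations a list of observation tibbles, or an
#'   `apo_query_eval` (whose per-query `n_X`/`n_question` counts are used).
#' @return list with `per_query` tibble and overall `n_X`, `n_question`,
#'   `x_fraction`, `gene_fraction`.
#' @export
missingness_report <- function(observations) {
  per <- if (inherits(observations, "apo_query_eval")) {
    dplyr::select(observations$results, "species", "n_X", "n_question")
  } else {
    dplyr::bind_rows(lapply(seq_along(observations), function(i) {
      toks <- observations[[i]]$token
      tibble::tibble(species = as.character(i),
                     n_X = sum(toks %in% c("X", "-")),
                     n_question = sum(toks == "?"))
    }))
  }
  nX <- sum(per$n_X); nQ <- sum(per$n_question)
  tot <- nX + nQ
  list(per_query = per, n_X = nX, n_question = nQ,
       x_fraction = if (tot > 0) nX / tot else NA_real_,
       gene_fraction = if (tot > 0) nQ / tot else NA_real_)
}
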