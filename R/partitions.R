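#' Gene partition of a concatenated alignment
#'
#' A gene partition is a tibble with columns `gene`, `start`, `end`
#' (1-based, closed intervals), sorted and non-overlapping.
#'
#' @param gene character vector of gene names.
#' @param start,end integer column bounds, closed on both ends.
#' @param n_columns optional total column count to validate against.
#' @return a tibble of class `gene_partition`.
#' @export
gene_partition <- function(gene, start, end, n_columns = NULL) {
  p <- tibble::tibble(gene = as.character(gene),
                      start = as.integer(start), end = as.integer(end))
  p <- dplyr::arrange(p, .data$start)
  if (nrow(p) > 0) {
    if (any(p$start > p$end)) stop("interval with start > end", call. = FALSE)
    if (any(p$start < 1L)) stop("interval outside [1, columns]", call. = FALSE)
    if (!is.null(n_columns) && any(p$end > n_columns)) {
      stop("interval outside [1, ", n_columns, "]", call. = FALSE)
    }
    if (anyDuplicated(p$gene)) stop("duplicate gene names", call. = FALSE)
    if (nrow(p) > 1) {
      olap <- which(p$start[-1] <= p$end[-nrow(p)])
      if (length(olap) > 0) {
        stop("overlapping intervals: ", p$gene[olap[1]], " and ",
             p$gene[olap[1] + 1], call. = FALSE)
      }
    }
  }
  class(p) <- c("gene_partition", class(p))
  p
}

#' Read a gene partition from a tabular file
#'
#' One interval per line: `gene start end`, whitespace- or tab-separated.
#' An empty file yields an empty partition (every column "unassigned").
#'
#' @param path file path.
#' @param n_columns optional alignment width for bounds validation.
#' @return a [gene_partition()] tibble.
#' @export
read_gene_partition <- function(path, n_columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) > 0 && grepl("^gene\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]  # header row
  }
  if (length(lines) == 0L) {
    return(gene_partition(character(0), integer(0), integer(0)))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed partition line: ", lines[which(bad)[1]], call. = FALSE)
  gene_partition(
    gene = vapply(parts, `[[`, character(1), 1),
    start = as.integer(vapply(parts, `[[`, character(1), 2)),
    end = as.integer(vapply(parts, `[[`, character(1), 3)),
    n_columns = n_columns
  )
}

#' Map alignment columns to genes
#'
#' @param partition a [gene_partition()].
#' @param columns integer vector of 1-based column indices.
#' @return character vector; `"unassigned"` for columns outside every interval.
#' @export
gene_of <- function(partition, columns) {
  out <- rep("unassigned", length(columns))
  for (i in seq_len(nrow(partition))) {
    hit <- columns >= partition$start[i] & columns <= partition$end[i]
    out[hit] <- partition$gene[i]
  }
  out
}

#' Per-gene taxon breadth
#'
#' Number of taxa with at least one non-missing symbol within each gene's
#' columns; used by the gene-breadth tie-break when ranking candidates.
#'
#' @param matrix an [as_aa_matrix()].
#' @param partition a [gene_partition()].
#' @return tibble with `gene` and `breadth`.
#' @export
gene_breadth <- function(matrix, partition) {
  tibble::tibble(
    gene = partition$gene,
    breadth = vapply(seq_len(nrow(partition)), function(i) {
      block <- matrix[, partition$start[i]:partition$end[i], drop = FALSE]
      sum(apply(block, 1, function(r) any(!is_missing_symbol(r))))
    }, integer(1))
  )
}
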