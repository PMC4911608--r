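#' Amino-acid alignment matrix
#'
#' An `aa_matrix` is a plain character matrix (taxa in rows, aligned columns)
#' restricted to the 20 standard amino-acid one-letter codes plus three
#' distinct missing/gap symbols: `X` (missing residue within a sequenced
#' gene), `-` (alignment gap) and `?` (whole gene segment absent). The three
#' are stored separately because the identification stage reports their
#' provenance, but the parsimony engine treats all of them as
#' non-constraining.
#'
#' @param x character matrix with unique row names (taxon labels).
#' @return `x` validated, upper-cased, with class `aa_matrix` prepended.
#' @export
as_aa_matrix <- function(x) {
  if (!is.matrix(x) || !is.character(x)) {
    stop("`x` must be a character matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("taxon labels (row names) must be present and unique", call. = FALSE)
  }
  x[] <- toupper(x)
  bad <- !(x %in% aa_alphabet())
  if (any(bad)) {
    warning(sum(bad), " symbol(s) outside the amino-acid alphabet mapped to X",
            call. = FALSE)
    x[bad] <- "X"
  }
  class(x) <- c("aa_matrix", class(unclass(x)))
  x
}

#' @export
print.aa_matrix <- function(x, ...) {
  cat("<aa_matrix> ", nrow(x), " taxa x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

# full stored alphabet: 20 amino acids + missing symbols
aa_alphabet <- function() c(AA_STATES, "X", "-", "?")

#' @rdname as_aa_matrix
#' @format `AA_STATES`: the 20 standard amino-acid one-letter codes.
#' @export
AA_STATES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

is_missing_symbol <- function(x) x %in% c("X", "-", "?")

#' Read an aligned amino-acid matrix
#'
#' Reads FASTA or relaxed (sequential) PHYLIP. Symbols are upper-cased;
#' letters outside the alphabet are mapped to `X` with a warning; ragged rows
#' are an error naming the offending taxon.
#'
#' @param path file path.
#' @param format `"auto"` (sniff first non-blank character), `"fasta"` or
#'   `"phylip"`.
#' @return an [as_aa_matrix()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  seqs <- if (format == "fasta") read_fasta_seqs(path) else read_phylip_seqs(path)
  if (length(seqs) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  lens <- vapply(seqs, nchar, integer(1))
  if (length(unique(lens)) > 1L) {
    mode_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    off <- names(seqs)[lens != mode_len][1]
    stop("alignment rows have unequal length; offending taxon: ", off,
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(seqs)
  as_aa_matrix(m)
}

read_fasta_seqs <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE, set.attributes = FALSE)
  vapply(seqs, function(s) toupper(as.character(s)), character(1))
}

# relaxed sequential PHYLIP: header "ntax nchar"; then name + sequence,
# the sequence possibly split over whitespace and wrapped lines
read_phylip_seqs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty or truncated PHYLIP file", call. = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) < 2L || anyNA(hdr)) stop("malformed PHYLIP header", call. = FALSE)
  ntax <- hdr[1]; nchar_al <- hdr[2]
  toks <- unlist(strsplit(trimws(lines[-1]), "\\s+"))
  seqs <- character(0)
  i <- 1L
  for (k in seq_len(ntax)) {
    if (i > length(toks)) stop("PHYLIP file truncated at taxon ", k, call. = FALSE)
    nm <- toks[i]; i <- i + 1L
    s <- ""
    while (nchar(s) < nchar_al) {
      if (i > length(toks)) break
      s <- paste0(s, toks[i]); i <- i + 1L
    }
    seqs[nm] <- s
  }
  seqs
}

#' Write an alignment (or a site-restricted sub-dataset) as FASTA
#'
#' `write_subdataset()` restricts the matrix to `sites` (original column
#' order preserved), writes FASTA, and writes a sidecar TSV mapping each new
#' column to its original column and, when a partition is supplied, its gene.
#'
#' @param matrix an [as_aa_matrix()] object.
#' @param sites integer vector of original column indices (1-based).
#' @param path output FASTA path; the sidecar is written to
#'   `paste0(path, ".sites.tsv")`.
#' @param partition optional [read_gene_partition()] tibble for the gene
#'   column of the sidecar.
#' @return invisibly, the sidecar tibble (new_column, original_column, gene).
#' @export
write_subdataset <- function(matrix, sites, path, partition = NULL) {
  sites <- as.integer(sites)
  if (length(sites) == 0L) stop("empty site list", call. = FALSE)
  if (any(sites < 1L | sites > ncol(matrix))) {
    stop("site out of range [1, ", ncol(matrix), "]", call. = FALSE)
  }
  sites <- sort(unique(sites))
  sub <- matrix[, sites, drop = FALSE]
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(sub)), function(i) sub[i, ]),
    names = rownames(sub), file.out = path, nbchar = 10000
  )
  sidecar <- tibble::tibble(
    new_column = seq_along(sites),
    original_column = sites,
    gene = if (is.null(partition)) NA_character_ else gene_of(partition, sites)
  )
  utils::write.table(sidecar, paste0(path, ".sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sidecar)
}

#' @rdname write_subdataset
#' @export
write_alignment <- function(matrix, path) {
  write_subdataset(matrix, seq_len(ncol(matrix)), path)
  invisible(path)
}
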