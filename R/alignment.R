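#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a named
#' character vector. Headers are truncated at the first whitespace. Reading
#' as BStringSet (not AAStringSet) lets aligned files using '.' for gaps or
#' nonstandard letters through to the package's own validation, which
#' normalises them.
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("no records in FASTA: %s", path))
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or a `concat_set` data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "concat_set")) {
    x <- seqs$sequence
    names(x) <- seqs$species_id
    seqs <- x
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Construct an alignment matrix
#'
#' Represents an aligned set of sequences over the 21-state alphabet
#' (20 amino acids + gap) as an M x L character matrix with a designated
#' reference row (used to define insert columns and residue numbering).
#'
#' @param seqs named character vector of aligned sequences (equal length),
#'   or a character matrix of single residues with rownames
#' @param reference identifier (or row index) of the reference sequence;
#'   defaults to the first row
#' @return object of class `alignment_matrix`: list with `seqs` (character
#'   matrix), `row_ids`, `reference_row`
#' @export
alignment_matrix <- function(seqs, reference = 1L) {
  if (is.matrix(seqs)) {
    mat <- seqs
    ids <- rownames(mat)
    if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  } else {
    L <- unique(nchar(seqs))
    if (length(L) != 1L)
      stop("aligned sequences must all have equal length")
    mat <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  }
  mat[mat == "."] <- GAP_CHAR
  rownames(mat) <- ids
  ref <- if (is.character(reference)) match(reference, ids) else as.integer(reference)
  if (is.na(ref) || ref < 1L || ref > nrow(mat))
    stop("reference sequence not found in alignment")
  structure(list(seqs = mat, row_ids = ids, reference_row = ref),
            class = "alignment_matrix")
}

#' Read an aligned FASTA into an alignment matrix
#'
#' @param path aligned FASTA ('.' and '-' gap glyphs both accepted)
#' @param reference reference sequence id or row index
#' @return an `alignment_matrix`
#' @export
read_alignment_fasta <- function(path, reference = 1L) {
  alignment_matrix(read_fasta(path), reference = reference)
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d columns (reference: %s)\n",
              nrow(x$seqs), ncol(x$seqs), x$row_ids[x$reference_row]))
  invisible(x)
}

#' @export
dim.alignment_matrix <- function(x) dim(x$seqs)

#' Remove insert columns from an alignment
#'
#' An insert column is a column where the designated reference sequence
#' carries a gap. Removing them leaves exactly the ungapped positions of
#' the reference, so the cleaned alignment length equals the reference
#' sequence length and columns map 1:1 onto reference residue numbers.
#' Idempotent.
#'
#' @param aln an `alignment_matrix`
#' @return the cleaned `alignment_matrix`; attribute `kept_columns` records
#'   the original indices of the retained columns
#' @export
remove_insert_columns <- function(aln) {
  stopifnot(inherits(aln, "alignment_matrix"))
  ref <- aln$seqs[aln$reference_row, ]
  keep <- ref != GAP_CHAR
  if (!any(keep)) stop("reference row is entirely gaps")
  out <- aln
  out$seqs <- aln$seqs[, keep, drop = FALSE]
  attr(out, "kept_columns") <- which(keep)
  out
}

#' Map alignment columns to per-protein residue numbers
#'
#' For a cleaned (insert-free) alignment of a spacer-concatenated pair,
#' tags each column as belonging to protein A, the spacer, or protein B,
#' and assigns the 1-based residue number within that segment of the
#' reference sequence. This is what lets a column pair be reported as,
#' say, "A:147 / B:148" with each protein numbered independently.
#'
#' @param aln cleaned `alignment_matrix` (or its column count)
#' @param len_a ungapped reference length of protein A
#' @param spacer_len spacer length used at concatenation
#' @return data frame of class `position_map` with columns `column`,
#'   `segment` ("A", "SPACER", "B"), `residue`
#' @export
build_position_map <- function(aln, len_a, spacer_len) {
  L <- if (inherits(aln, "alignment_matrix")) ncol(aln$seqs) else as.integer(aln)
  len_a <- as.integer(len_a); spacer_len <- as.integer(spacer_len)
  if (len_a < 1L || spacer_len < 0L) stop("len_a must be >= 1 and spacer_len >= 0")
  if (L < len_a + spacer_len)
    stop(sprintf("alignment has %d columns; need at least len_a + spacer_len = %d",
                 L, len_a + spacer_len))
  len_b <- L - len_a - spacer_len
  map <- data.frame(
    column = seq_len(L),
    segment = c(rep("A", len_a), rep("SPACER", spacer_len), rep("B", len_b)),
    residue = c(seq_len(len_a), rep(NA_integer_, spacer_len),
                if (len_b > 0L) seq_len(len_b) else integer(0)),
    stringsAsFactors = FALSE)
  attr(map, "len_a") <- len_a
  attr(map, "spacer_len") <- spacer_len
  attr(map, "len_b") <- len_b
  class(map) <- c("position_map", class(map))
  map
}
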