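#' Read per-species paired protein sequences from two FASTA files
#'
#' Records are matched across the two files by identical FASTA identifier
#' (the first whitespace-delimited token of the header). One paired record
#' is returned for every identifier present in both files, in the order of
#' `path_a`. Identifiers present in only one file are dropped with a
#' message; duplicated identifiers within a file are an error.
#'
#' @param path_a FASTA file of protein A (e.g. PhoU orthologs)
#' @param path_b FASTA file of protein B (e.g. PhoR orthologs)
#' @return a data frame of class `paired_records` with columns
#'   `species_id`, `seq_a`, `seq_b`
#' @export
#' @examples
#' a <- tempfile(fileext = ".faa"); b <- tempfile(fileext = ".faa")
#' writeLines(c(">sp1", "MKV", ">sp2", "MAH"), a)
#' writeLines(c(">sp2", "WHD", ">sp3", "MMM"), b)
#' read_paired_fasta(a, b)
read_paired_fasta <- function(path_a, path_b) {
  sa <- read_fasta(path_a)
  sb <- read_fasta(path_b)
  if (anyDuplicated(names(sa)))
    stop(sprintf("duplicate identifier(s) in %s: %s", path_a,
                 paste(unique(names(sa)[duplicated(names(sa))]), collapse = ", ")))
  if (anyDuplicated(names(sb)))
    stop(sprintf("duplicate identifier(s) in %s: %s", path_b,
                 paste(unique(names(sb)[duplicated(names(sb))]), collapse = ", ")))
  shared <- names(sa)[names(sa) %in% names(sb)]
  if (length(shared) == 0L)
    stop("no shared identifiers between the two FASTA files")
  only_a <- setdiff(names(sa), shared)
  only_b <- setdiff(names(sb), shared)
  if (length(only_a) || length(only_b))
    message(sprintf("dropped %d unpaired record(s) from A, %d from B",
                    length(only_a), length(only_b)))
  seq_a <- vapply(unname(sa[shared]), validate_sequence, character(1))
  seq_b <- vapply(unname(sb[shared]), validate_sequence, character(1))
  out <- data.frame(species_id = shared, seq_a = seq_a, seq_b = seq_b,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("paired_records", class(out))
  out
}

#' Concatenate paired sequences with an artificial spacer
#'
#' Joins each species' protein-A sequence to its protein-B sequence as
#' `seq_a + spacer + seq_b`, A first. The spacer (twenty alanines by
#' default) marks the boundary between the two proteins so they can be
#' told apart after alignment.
#'
#' @param records a `paired_records` data frame
#' @param spacer_len number of spacer residues (>= 0)
#' @param spacer_char single amino-acid letter used for the spacer
#' @return a data frame of class `concat_set` with columns `species_id`,
#'   `sequence`, `len_a`, `len_b`; attributes `spacer_len`, `spacer_char`
#' @export
concatenate_with_spacer <- function(records, spacer_len = 20L, spacer_char = "A") {
  if (NROW(records) == 0L) stop("empty record list")
  stopifnot(is.numeric(spacer_len), length(spacer_len) == 1L)
  if (spacer_len < 0) stop("spacer_len must be >= 0")
  if (!is.character(spacer_char) || nchar(spacer_char) != 1L ||
      !(toupper(spacer_char) %in% AA_LETTERS))
    stop("spacer_char must be a single amino-acid letter")
  spacer <- strrep(toupper(spacer_char), spacer_len)
  out <- data.frame(
    species_id = records$species_id,
    sequence = paste0(records$seq_a, spacer, records$seq_b),
    len_a = nchar(records$seq_a),
    len_b = nchar(records$seq_b),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "spacer_len") <- as.integer(spacer_len)
  attr(out, "spacer_char") <- toupper(spacer_char)
  class(out) <- c("concat_set", class(out))
  out
}

#' Split a concatenated sequence back into its two proteins
#'
#' Inverse of [concatenate_with_spacer()] for a single record: drops the
#' spacer and returns the two flanking segments.
#'
#' @param sequence concatenated sequence string
#' @param len_a length of the protein-A segment
#' @param spacer_len spacer length used at concatenation
#' @return list with elements `seq_a`, `seq_b`
#' @export
split_concatenated <- function(sequence, len_a, spacer_len) {
  n <- nchar(sequence)
  if (n < len_a + spacer_len) stop("sequence shorter than len_a + spacer_len")
  list(seq_a = substr(sequence, 1L, len_a),
       seq_b = substr(sequence, len_a + spacer_len + 1L, n))
}
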