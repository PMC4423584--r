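#' @useDynLib pairdca, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 21-state alphabet: 20 amino acids (states 1..20) plus the gap as a full
# 21st state. The gap doubles as the reference state dropped in the
# mean-field inversion.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHAR <- "-"
AA_STATES <- c(AA_LETTERS, GAP_CHAR)
N_STATES <- 21L
GAP_STATE <- 21L

# letters outside the 20-AA alphabet that we fold into the gap state
NONSTANDARD_AA <- c("X", "B", "Z", "U", "O", "J")

#' Encode an alignment character matrix as integer states
#'
#' Maps the 20 amino-acid letters to states 1..20 and the gap to state 21.
#' Lower-case letters are accepted and upper-cased; the '.' gap glyph is
#' normalised to '-'. Nonstandard residue letters (X, B, Z, U, O, J) are
#' mapped to the gap state with a warning, which keeps the 21-state model
#' closed. Any other symbol is an error.
#'
#' @param chars character matrix of single residues
#' @return integer matrix of the same dimension with values in 1..21
#' @keywords internal
encode_states <- function(chars) {
  x <- toupper(chars)
  x[x == "."] <- GAP_CHAR
  ns <- x %in% NONSTANDARD_AA
  if (any(ns)) {
    warning(sprintf("%d nonstandard residue(s) (%s) mapped to the gap state",
                    sum(ns), paste(sort(unique(x[ns])), collapse = ",")))
    x[ns] <- GAP_CHAR
  }
  enc <- match(x, AA_STATES)
  if (anyNA(enc)) {
    bad <- sort(unique(x[is.na(enc)]))
    stop(sprintf("invalid residue symbol(s): %s", paste(bad, collapse = ", ")))
  }
  out <- matrix(as.integer(enc), nrow = NROW(chars), ncol = NCOL(chars))
  dimnames(out) <- dimnames(chars)
  out
}

#' Validate a protein sequence string
#'
#' @param seq single string
#' @param allow_gap permit '-' (aligned sequence)
#' @return the sequence, upper-cased, nonstandard letters folded to gap
#' @keywords internal
validate_sequence <- function(seq, allow_gap = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence must be a non-empty string")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ch[ch == "."] <- GAP_CHAR
  ns <- ch %in% NONSTANDARD_AA
  if (any(ns)) {
    warning(sprintf("%d nonstandard residue(s) mapped to the gap state", sum(ns)))
    ch[ns] <- GAP_CHAR
  }
  ok <- ch %in% AA_LETTERS | (allow_gap & ch == GAP_CHAR)
  if (!all(ok))
    stop(sprintf("invalid residue symbol(s): %s",
                 paste(sort(unique(ch[!ok])), collapse = ", ")))
  paste(ch, collapse = "")
}
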