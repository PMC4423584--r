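#' Similarity-based sequence reweighting
#'
#' Each sequence receives weight 1/n, where n is the number of sequences
#' (itself included) whose fraction of identical positions with it is at
#' least `1 - theta`. The sum of weights is the effective sequence number
#' M_eff. This down-weights clusters of near-identical sequences so that
#' phylogenetic redundancy does not masquerade as covariation.
#'
#' Identity is computed over all columns with the gap counted as an
#' ordinary 21st state. Implemented as a sparse one-hot cross-product, so
#' the pairwise match counts are exact integers.
#'
#' @param aln an `alignment_matrix` (or integer state matrix)
#' @param theta identity threshold fraction in `[0, 1)`; sequences closer
#'   than `1 - theta` identity are clustered. `theta = 0` clusters only
#'   exact duplicates.
#' @return object of class `seq_weights`: list with `w` (per-sequence
#'   weights), `M_eff`, `theta`
#' @export
compute_sequence_weights <- function(aln, theta = 0.2) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 1)
    stop("theta must be a fraction in [0, 1)")
  states <- as_state_matrix(aln)
  M <- nrow(states); L <- ncol(states)
  if (M < 1L || L < 1L) stop("alignment must have at least one row and column")
  X <- state_indicator(states)
  # matches[m, m'] = number of identical positions between rows m and m'
  matches <- as.matrix(Matrix::tcrossprod(X))
  n_similar <- rowSums(matches / L >= 1 - theta)
  w <- 1 / n_similar
  structure(list(w = w, M_eff = sum(w), theta = theta), class = "seq_weights")
}

#' @export
print.seq_weights <- function(x, ...) {
  cat(sprintf("sequence weights: M = %d, M_eff = %.2f (theta = %g)\n",
              length(x$w), x$M_eff, x$theta))
  invisible(x)
}

# coerce alignment-like input to an M x L integer state matrix (1..21)
as_state_matrix <- function(aln) {
  if (inherits(aln, "alignment_matrix")) return(encode_states(aln$seqs))
  if (is.matrix(aln) && is.numeric(aln)) return(aln)
  if (is.matrix(aln) && is.character(aln)) return(encode_states(aln))
  stop("expected an alignment_matrix or state matrix")
}

# sparse M x (L*q) one-hot indicator of the state matrix
state_indicator <- function(states) {
  M <- nrow(states); L <- ncol(states)
  cols <- (rep(seq_len(L), each = M) - 1L) * N_STATES + as.integer(states)
  Matrix::sparseMatrix(i = rep(seq_len(M), times = L), j = cols, x = 1,
                       dims = c(M, L * N_STATES))
}
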