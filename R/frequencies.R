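#' Reweighted, pseudocounted frequency estimates
#'
#' Computes single-column and pair-column frequencies over the 21-state
#' alphabet from a (reweighted) alignment:
#' \deqn{f_i(a) = \frac{\lambda/q + \sum_m w_m [A_{mi} = a]}{\lambda + M_{eff}}}
#' \deqn{f_{ij}(a,b) = \frac{\lambda/q^2 + \sum_m w_m [A_{mi}=a][A_{mj}=b]}{\lambda + M_{eff}}}
#' The same-site table is diagonal: `f_ii(a,b) = f_i(a)` for `a = b` and 0
#' otherwise (apart from its pseudocount term). The pseudocount `lambda`
#' regularises the correlation matrix so the mean-field inversion is
#' well-posed; `lambda = M_eff` (a 50/50 data/pseudocount mix) is the
#' conventional choice.
#'
#' @param aln an `alignment_matrix` or integer state matrix
#' @param w a `seq_weights` object (or numeric weight vector)
#' @param lambda pseudocount mass (>= 0)
#' @param columns columns to analyse (default all)
#' @return object of class `freq_model`: list with `q`, `lambda`, `M_eff`,
#'   `fi` (q x N single-site frequencies), `fij` ((N q) x (N q) matrix of
#'   q x q pair blocks), `columns` (original column indices), `N`
#' @export
estimate_frequencies <- function(aln, w, lambda, columns = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("lambda must be a single number >= 0")
  states <- as_state_matrix(aln)
  if (inherits(w, "seq_weights")) w <- w$w
  stopifnot(length(w) == nrow(states))
  if (!is.null(columns)) states <- states[, columns, drop = FALSE]
  else columns <- seq_len(ncol(states))
  N <- ncol(states)
  M_eff <- sum(w)
  q <- N_STATES
  denom <- lambda + M_eff

  X <- state_indicator(states)                       # M x (N q)
  counts1 <- as.numeric(Matrix::crossprod(X, w))     # weighted single counts
  fi <- matrix((lambda / q + counts1) / denom, nrow = q, ncol = N)

  counts2 <- as.matrix(Matrix::crossprod(X, X * w))  # (N q) x (N q)
  fij <- (lambda / q^2 + counts2) / denom
  # same-site blocks: diagonal f_i(a), zero off-diagonal
  for (i in seq_len(N)) {
    idx <- (i - 1L) * q + seq_len(q)
    blk <- matrix(0, q, q)
    diag(blk) <- fi[, i]
    fij[idx, idx] <- blk
  }
  structure(list(q = q, lambda = lambda, M_eff = M_eff, fi = fi, fij = fij,
                 columns = as.integer(columns), N = N),
            class = "freq_model")
}

#' @export
print.freq_model <- function(x, ...) {
  cat(sprintf("frequency model: %d columns, q = %d, lambda = %.3f, M_eff = %.2f\n",
              x$N, x$q, x$lambda, x$M_eff))
  invisible(x)
}

# extract the q x q pair block for local column indices (i, j)
pair_block <- function(fij, i, j, q = N_STATES) {
  fij[(i - 1L) * q + seq_len(q), (j - 1L) * q + seq_len(q)]
}

#' Mutual information for all column pairs
#'
#' \deqn{MI_{ij} = \sum_{a,b} f_{ij}(a,b) \ln \frac{f_{ij}(a,b)}{f_i(a) f_j(b)}}
#' in nats; terms with `f_ij = 0` contribute zero. MI captures both direct
#' and indirect (transitive) covariation between two columns.
#'
#' @param freqs a `freq_model`
#' @return data frame with columns `i`, `j` (local column indices, i < j)
#'   and `mi` (nats), all N(N-1)/2 pairs
#' @export
mutual_information <- function(freqs) {
  stopifnot(inherits(freqs, "freq_model"))
  N <- freqs$N; q <- freqs$q
  if (N < 2L) return(data.frame(i = integer(0), j = integer(0), mi = numeric(0)))
  pr <- pair_indices(N)
  mi <- numeric(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    pij <- pair_block(freqs$fij, i, j, q)
    indep <- tcrossprod(freqs$fi[, i], freqs$fi[, j])
    pos <- pij > 0
    mi[k] <- sum(pij[pos] * log(pij[pos] / indep[pos]))
  }
  cbind(pr, mi = mi)
}

# all pairs i < j in (i, j) ascending order
pair_indices <- function(N) {
  i <- rep.int(seq_len(N - 1L), times = (N - 1L):1L)
  j <- unlist(lapply(seq_len(N - 1L), function(k) (k + 1L):N), use.names = FALSE)
  data.frame(i = i, j = j)
}
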