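#' Mean-field inference of pairwise couplings
#'
#' Builds the connected-correlation matrix
#' `C_ij(a,b) = f_ij(a,b) - f_i(a) f_j(b)` over the reduced alphabet
#' (states 1..q-1, with the gap as the reference state) and takes the
#' couplings as the negative inverse: `e_ij(a,b) = -(C^-1)` at block
#' `(i,a),(j,b)`. This is the small-coupling (mean-field) solution of the
#' inverse Potts problem; the pseudocount in the frequency model is what
#' keeps C invertible.
#'
#' @param freqs a `freq_model` (pseudocounted; `lambda` of order `M_eff`
#'   recommended)
#' @return object of class `coupling_model`: list with `invC` (the
#'   negative-coupling matrix, `(q-1) N` square), `N`, `q`, `columns`
#' @export
infer_mean_field_couplings <- function(freqs) {
  stopifnot(inherits(freqs, "freq_model"))
  N <- freqs$N; q <- freqs$q; r <- q - 1L
  keep <- as.vector(outer(seq_len(r), (seq_len(N) - 1L) * q, `+`))
  C <- freqs$fij[keep, keep] - tcrossprod(as.vector(freqs$fi[seq_len(r), ]))
  invC <- tryCatch(solve(C), error = function(e)
    stop("connected-correlation matrix is numerically singular; ",
         "increase the pseudocount (lambda)"))
  structure(list(invC = invC, N = N, q = q, columns = freqs$columns),
            class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf("mean-field coupling model: %d columns, q = %d\n", x$N, x$q))
  invisible(x)
}

#' Extract the coupling matrix for one column pair
#'
#' Returns the q x q coupling block `e_ij(a,b)` in the gauge where the gap
#' (reference) state carries zero coupling, so the last row and column are
#' zero. Satisfies `e_ij(a,b) = e_ji(b,a)`.
#'
#' @param couplings a `coupling_model`
#' @param i,j local column indices (i != j)
#' @return q x q numeric matrix
#' @export
get_couplings <- function(couplings, i, j) {
  stopifnot(inherits(couplings, "coupling_model"))
  q <- couplings$q; r <- q - 1L
  if (i == j) stop("couplings are defined for i != j")
  e <- matrix(0, q, q)
  e[seq_len(r), seq_len(r)] <-
    -couplings$invC[(i - 1L) * r + seq_len(r), (j - 1L) * r + seq_len(r)]
  e
}

#' Direct information for all column pairs
#'
#' For each pair, fits the two-site "direct" distribution
#' `P_ij(a,b) proportional to exp(e_ij(a,b)) h_i(a) h_j(b)` whose
#' marginals are constrained to the single-site frequencies `f_i`, `f_j`;
#' the auxiliary fields are found by a damped fixed-point iteration. DI is
#' the mutual information of that distribution:
#' \deqn{DI_{ij} = \sum_{a,b} P_{ij}(a,b) \ln \frac{P_{ij}(a,b)}{f_i(a) f_j(b)}}
#' DI retains only the coupling carried directly by the pair, discarding
#' the transitive correlation that inflates MI.
#'
#' @param couplings a `coupling_model`
#' @param freqs the `freq_model` the couplings were inferred from
#' @param tol convergence tolerance on the marginal mismatch
#' @param max_iter maximum fixed-point iterations per pair
#' @param damp damping factor in `[0, 1)` (0 = plain substitution)
#' @return data frame with columns `i`, `j` (local indices, i < j), `di`
#'   (nats)
#' @export
direct_information <- function(couplings, freqs, tol = 1e-4, max_iter = 500L,
                               damp = 0.1) {
  stopifnot(inherits(couplings, "coupling_model"), inherits(freqs, "freq_model"))
  if (!identical(couplings$columns, freqs$columns))
    stop("couplings and frequencies come from different column sets")
  N <- freqs$N
  if (N < 2L) return(data.frame(i = integer(0), j = integer(0), di = numeric(0)))
  pr <- pair_indices(N)
  res <- di_pairs_cpp(couplings$invC, freqs$fi, pr$i, pr$j, freqs$q,
                      tol, as.integer(max_iter), damp)
  bad <- which(!res$converged)
  if (length(bad)) {
    # strongly coupled pairs can oscillate: retry with heavier damping
    retry <- di_pairs_cpp(couplings$invC, freqs$fi, pr$i[bad], pr$j[bad],
                          freqs$q, tol, 10L * as.integer(max_iter), 0.8)
    res$di[bad] <- retry$di
    res$converged[bad] <- retry$converged
    bad <- which(!res$converged)
  }
  if (length(bad))
    stop(sprintf("direct-information field iteration failed to converge for pair(s): %s",
                 paste(sprintf("(%d,%d)", pr$i[bad], pr$j[bad]), collapse = " ")))
  cbind(pr, di = res$di)
}
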