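#' Fit a mean-field direct coupling analysis model
#'
#' The central fitting function. Given a cleaned (insert-free) alignment
#' of a spacer-concatenated protein pair, it (1) reweights sequences at
#' identity threshold `1 - theta`, (2) estimates pseudocounted single- and
#' pair-column frequencies, (3) computes mutual information for every
#' column pair, (4) inverts the connected-correlation matrix to obtain
#' mean-field couplings, and (5) evaluates direct information for every
#' pair through the marginal-matched two-site model. The result carries
#' the full N(N-1)/2-row pair score table.
#'
#' When a `position_map` is supplied, spacer columns are dropped before
#' analysis (they are artificial, zero-variance columns), and the `i`, `j`
#' indices reported in the pair table remain concatenated-alignment column
#' numbers, so the map translates them directly to per-protein residues.
#'
#' @param aln an `alignment_matrix`, already insert-column-removed
#' @param position_map optional `position_map`; its SPACER columns are
#'   excluded from the analysis
#' @param theta reweighting identity threshold (fraction in `[0,1)`)
#' @param pseudocount pseudocount mass as a multiple of M_eff
#'   (`lambda = pseudocount * M_eff`); 1 is the conventional default
#' @param di_tol,di_max_iter,di_damp direct-information fixed-point
#'   controls (see [direct_information()])
#' @param keep_couplings retain the coupling matrix in the fit (needed by
#'   [coef.dca()]; can be large for long alignments)
#' @return object of class `dca` with components `pairs` (data frame
#'   `i`, `j`, `mi`, `di` over analysed columns, concatenated-coordinate
#'   indices), `weights`, `fi`, `couplings` (optional), `columns`,
#'   `theta`, `lambda`, `M`, `L`, `N`, `call`
#' @export
#' @examples
#' aln <- alignment_matrix(c(ref = "MKVH", s2 = "MKVH", s3 = "AKVH"))
#' fit <- dca(aln, pseudocount = 1)
#' fit$pairs
dca <- function(aln, position_map = NULL, theta = 0.2, pseudocount = 1,
                di_tol = 1e-4, di_max_iter = 500L, di_damp = 0.1,
                keep_couplings = TRUE) {
  stopifnot(inherits(aln, "alignment_matrix"))
  states <- as_state_matrix(aln)
  M <- nrow(states); L <- ncol(states)
  columns <- seq_len(L)
  if (!is.null(position_map)) {
    stopifnot(inherits(position_map, "position_map"))
    if (nrow(position_map) != L)
      stop("position map does not match the alignment width")
    columns <- position_map$column[position_map$segment != "SPACER"]
  }
  w <- compute_sequence_weights(states, theta = theta)
  lambda <- pseudocount * w$M_eff
  # MI from the reweighted empirical frequencies (no pseudocount: a heavy
  # pseudocount shrinks MI toward zero); couplings and DI from the
  # pseudocounted model, which the mean-field inversion requires.
  freqs0 <- estimate_frequencies(states, w, lambda = 0, columns = columns)
  mi <- mutual_information(freqs0)
  freqs <- estimate_frequencies(states, w, lambda = lambda, columns = columns)
  cpl <- infer_mean_field_couplings(freqs)
  di <- direct_information(cpl, freqs, tol = di_tol, max_iter = di_max_iter,
                           damp = di_damp)
  pairs <- data.frame(i = columns[mi$i], j = columns[mi$j],
                      mi = mi$mi, di = di$di)
  class(pairs) <- c("pair_table", class(pairs))
  structure(list(pairs = pairs, weights = w, fi = freqs$fi,
                 couplings = if (keep_couplings) cpl else NULL,
                 columns = as.integer(columns), theta = theta,
                 lambda = lambda, M = M, L = L, N = length(columns),
                 call = match.call()),
            class = "dca")
}

#' Run the DCA stage and return the pair score table
#'
#' Convenience wrapper around [dca()] returning only the four-column
#' (i, j, MI, DI) table with all N(N-1)/2 analysed-column pairs.
#'
#' @inheritParams dca
#' @return data frame of class `pair_table` with columns `i`, `j`, `mi`,
#'   `di`
#' @export
run_dca <- function(aln, position_map = NULL, theta = 0.2, pseudocount = 1, ...) {
  dca(aln, position_map = position_map, theta = theta,
      pseudocount = pseudocount, keep_couplings = FALSE, ...)$pairs
}

#' @export
print.dca <- function(x, ...) {
  cat("Mean-field direct coupling analysis\n")
  cat(sprintf("  alignment: %d sequences x %d columns (%d analysed)\n",
              x$M, x$L, x$N))
  cat(sprintf("  M_eff = %.2f (theta = %g), lambda = %.2f\n",
              x$weights$M_eff, x$theta, x$lambda))
  cat(sprintf("  pair table: %d rows\n", nrow(x$pairs)))
  invisible(x)
}

#' Summarise a DCA fit
#'
#' @param object a `dca` fit
#' @param top number of top pairs to tabulate
#' @param ... unused
#' @return object of class `summary.dca` listing the top pairs by MI and
#'   by DI
#' @export
summary.dca <- function(object, top = 10L, ...) {
  p <- object$pairs
  by_mi <- p[order(-p$mi, p$i, p$j), , drop = FALSE][seq_len(min(top, nrow(p))), ]
  by_di <- p[order(-p$di, p$i, p$j), , drop = FALSE][seq_len(min(top, nrow(p))), ]
  structure(list(fit = object, top_mi = by_mi, top_di = by_di),
            class = "summary.dca")
}

#' @export
print.summary.dca <- function(x, ...) {
  print(x$fit)
  cat("\nTop pairs by mutual information:\n")
  print(format(x$top_mi, digits = 4), row.names = FALSE)
  cat("\nTop pairs by direct information:\n")
  print(format(x$top_di, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Extract mean-field couplings from a DCA fit
#'
#' @param object a `dca` fit created with `keep_couplings = TRUE`
#' @param i,j concatenated-coordinate column indices of one analysed pair;
#'   if omitted, the full `coupling_model` is returned
#' @param ... unused
#' @return q x q coupling matrix `e_ij(a,b)` (rows/columns ordered as the
#'   20 amino acids then the gap), or the `coupling_model`
#' @export
coef.dca <- function(object, i = NULL, j = NULL, ...) {
  if (is.null(object$couplings))
    stop("fit was created with keep_couplings = FALSE")
  if (is.null(i) && is.null(j)) return(object$couplings)
  li <- match(i, object$columns); lj <- match(j, object$columns)
  if (is.na(li) || is.na(lj))
    stop("column not among the analysed columns")
  e <- get_couplings(object$couplings, li, lj)
  dimnames(e) <- list(AA_STATES, AA_STATES)
  e
}

#' Plot MI against DI for all pairs of a DCA fit
#'
#' A diagnostic scatter: indirect (transitive) correlation inflates MI but
#' not DI, so directly coupled pairs stand out on the DI axis.
#'
#' @param x a `dca` fit
#' @param highlight optional two-column matrix/data frame of (i, j) pairs
#'   to mark (e.g. planted or structurally validated pairs)
#' @param ... passed to [graphics::plot()]
#' @export
plot.dca <- function(x, highlight = NULL, ...) {
  p <- x$pairs
  graphics::plot(p$mi, p$di, xlab = "mutual information (nats)",
                 ylab = "direct information (nats)",
                 pch = 16, cex = 0.5, col = "grey40", ...)
  if (!is.null(highlight)) {
    hl <- paste(highlight[[1]], highlight[[2]])
    sel <- paste(p$i, p$j) %in% hl | paste(p$j, p$i) %in% hl
    graphics::points(p$mi[sel], p$di[sel], pch = 1, cex = 1.2, col = "red")
  }
  invisible(x)
}

#' Write a pair score table as whitespace-separated text
#'
#' Four columns — residue i, residue j, MI(i,j), DI(i,j) — one row per
#' pair, optionally preceded by a header line.
#'
#' @param pairs a `pair_table` data frame
#' @param path output file
#' @param header write a commented header line
#' @param digits significant digits (NULL = full precision)
#' @return `path`, invisibly
#' @export
write_pair_table <- function(pairs, path, header = FALSE, digits = NULL) {
  x <- pairs[, c("i", "j", "mi", "di")]
  if (!is.null(digits)) {
    x$mi <- signif(x$mi, digits); x$di <- signif(x$di, digits)
  }
  con <- file(path, "w"); on.exit(close(con))
  if (header) writeLines("# i j MI DI", con)
  utils::write.table(x, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = " ")
  invisible(path)
}

#' Read a pair score table written by [write_pair_table()]
#'
#' @param path whitespace-separated 4-column file; lines starting with '#'
#'   are skipped
#' @return data frame of class `pair_table`
#' @export
read_pair_table <- function(path) {
  x <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("i", "j", "mi", "di"))
  class(x) <- c("pair_table", class(x))
  x
}
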