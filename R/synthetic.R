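#' Construct a joint distribution for a planted coupled column pair
#'
#' A mixture of a permutation table over `n_states` amino acids (perfect
#' one-to-one covariation) and an independent uniform background over all
#' 20 amino acids:
#' `p = purity * permutation / n_states + (1 - purity) / 400`.
#' Tuning `n_states` and `purity` sets the pair's true mutual information,
#' which [true_pair_statistics()] computes exactly.
#'
#' @param n_states number of amino-acid states carrying the permutation
#' @param purity mixture weight of the permutation component in `[0, 1]`
#' @param states optional character vector of `n_states` amino-acid
#'   letters (drawn at random from the current RNG if omitted)
#' @return 20 x 20 joint probability matrix with amino-acid dimnames
#' @export
coupled_joint <- function(n_states = 6L, purity = 0.85, states = NULL) {
  if (purity < 0 || purity > 1) stop("purity must be in [0, 1]")
  if (is.null(states)) states <- sample(AA_LETTERS, n_states)
  stopifnot(length(states) == n_states, all(states %in% AA_LETTERS))
  partner <- sample(AA_LETTERS, n_states)
  joint <- matrix((1 - purity) / 400, 20, 20,
                  dimnames = list(AA_LETTERS, AA_LETTERS))
  for (k in seq_len(n_states))
    joint[states[k], partner[k]] <- joint[states[k], partner[k]] + purity / n_states
  joint
}

#' Specify a synthetic paired alignment with planted couplings
#'
#' Describes a paired MSA of `M` species over two concatenated proteins:
#' a small number of strongly co-varying inter-protein column pairs
#' (each drawn iid per sequence from a known joint table), independent
#' background columns (per-column categorical profiles drawn once from a
#' symmetric Dirichlet), iid gaps, and optional phylogeny-like redundancy
#' (mutated clones). Planted pairs form a matching — no column is reused —
#' so sequences factorise over pairs, sampling is exact, and each pair's
#' true MI (= true DI, the pair being the only coupling involving its
#' columns) has a closed form. All random structure is drawn at
#' construction time from `seed` and stored, so sampling is reproducible.
#'
#' The defaults are the validation conditions used throughout the
#' package's tests: a 30 + 40 residue protein pair, 5 planted pairs with
#' true MI around 1.6 nats, 2000 sequences, 5% gaps.
#'
#' @param len_a,len_b segment lengths of proteins A and B
#' @param M number of sequences to sample
#' @param n_planted number of planted inter-protein coupled pairs
#' @param joint_states,joint_purity parameters of each planted joint (see
#'   [coupled_joint()])
#' @param gap_rate iid per-cell gap probability in `[0, 1)`
#' @param n_clones,mutation_rate redundancy defaults used by
#'   [inject_redundancy()]
#' @param gap_free_reference keep the first (reference) sequence ungapped
#'   so insert-column removal is the identity on generated data
#' @param seed RNG seed for the spec's random structure and the default
#'   sampling seed
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(len_a = 30L, len_b = 40L, M = 2000L,
                           n_planted = 5L, joint_states = 6L,
                           joint_purity = 0.85, gap_rate = 0.05,
                           n_clones = 0L, mutation_rate = 0.02,
                           gap_free_reference = TRUE, seed = 1L) {
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")
  if (n_planted > min(len_a, len_b))
    stop("more planted pairs than available columns")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cols_a <- sort(sample.int(len_a, n_planted))
  cols_b <- sort(sample.int(len_b, n_planted))
  planted <- lapply(seq_len(n_planted), function(k)
    list(col_a = cols_a[k], col_b = cols_b[k],
         joint = coupled_joint(joint_states, joint_purity)))
  # per-column background profiles over the 20 amino acids, Dirichlet(1)
  g <- matrix(stats::rgamma(20L * (len_a + len_b), shape = 1), nrow = 20L)
  background <- sweep(g, 2L, colSums(g), "/")
  rownames(background) <- AA_LETTERS
  structure(list(len_a = as.integer(len_a), len_b = as.integer(len_b),
                 M = as.integer(M), planted = planted,
                 background = background, gap_rate = gap_rate,
                 n_clones = as.integer(n_clones),
                 mutation_rate = mutation_rate,
                 gap_free_reference = gap_free_reference,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic paired MSA spec: %d + %d residues, M = %d, %d planted pair(s), gap rate %g, seed %d\n",
    x$len_a, x$len_b, x$M, length(x$planted), x$gap_rate, x$seed))
  invisible(x)
}

#' Sample a paired MSA from a synthetic specification
#'
#' Planted column pairs are drawn iid per sequence from their joint
#' tables; background columns iid from their profiles; gaps then
#' overwrite cells independently at `gap_rate` (sparing the reference row
#' when `gap_free_reference`). Fully reproducible from the seed.
#'
#' @param spec a `synthetic_spec`
#' @param seed sampling seed (defaults to the spec's)
#' @return a `paired_records` data frame (species `sp0001`, `sp0002`, ...)
#' @export
sample_paired_msa <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (p in spec$planted)
    if (abs(sum(p$joint) - 1) > 1e-9) stop("planted joint table not normalised")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  M <- spec$M; L <- spec$len_a + spec$len_b
  mat <- matrix("", M, L)
  planted_cols <- integer(0)
  for (p in spec$planted) {
    cell <- sample.int(400L, M, replace = TRUE, prob = as.vector(p$joint))
    a <- (cell - 1L) %% 20L + 1L          # row index of the joint
    b <- (cell - 1L) %/% 20L + 1L
    ca <- p$col_a; cb <- spec$len_a + p$col_b
    mat[, ca] <- AA_LETTERS[a]
    mat[, cb] <- AA_LETTERS[b]
    planted_cols <- c(planted_cols, ca, cb)
  }
  for (col in setdiff(seq_len(L), planted_cols))
    mat[, col] <- sample(AA_LETTERS, M, replace = TRUE,
                         prob = spec$background[, col])
  if (spec$gap_rate > 0) {
    gaps <- matrix(stats::runif(M * L) < spec$gap_rate, M, L)
    if (spec$gap_free_reference) gaps[1L, ] <- FALSE
    mat[gaps] <- GAP_CHAR
  }
  seq_a <- apply(mat[, seq_len(spec$len_a), drop = FALSE], 1L, paste, collapse = "")
  seq_b <- apply(mat[, spec$len_a + seq_len(spec$len_b), drop = FALSE], 1L,
                 paste, collapse = "")
  out <- data.frame(species_id = sprintf("sp%04d", seq_len(M)),
                    seq_a = seq_a, seq_b = seq_b,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("paired_records", class(out))
  out
}

#' Add phylogeny-like redundancy by cloning and mutating records
#'
#' Each record spawns `n_clones` copies in which every amino-acid position
#' is substituted, independently with probability `mutation_rate`, by a
#' different amino acid drawn uniformly (gaps are left untouched). The
#' expected clone-parent identity over amino-acid sites is therefore
#' `1 - mutation_rate`. Emulates clusters of closely related species,
#' which sequence reweighting is designed to absorb.
#'
#' @param records a `paired_records` data frame
#' @param n_clones clones per record (>= 0)
#' @param mutation_rate per-site substitution probability in `[0, 1]`
#' @param seed RNG seed
#' @return a `paired_records` data frame of `nrow(records) * (1 + n_clones)`
#'   rows (originals first)
#' @export
inject_redundancy <- function(records, n_clones, mutation_rate, seed = 1L) {
  if (n_clones < 0) stop("n_clones must be >= 0")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  if (n_clones == 0L) return(records)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mutate <- function(seq) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    aa <- ch != GAP_CHAR
    hit <- aa & stats::runif(length(ch)) < mutation_rate
    if (any(hit)) {
      cur <- match(ch[hit], AA_LETTERS)
      # uniform over the 19 other letters
      repl <- (cur - 1L + sample.int(19L, sum(hit), replace = TRUE)) %% 20L + 1L
      ch[hit] <- AA_LETTERS[repl]
    }
    paste(ch, collapse = "")
  }
  clones <- lapply(seq_len(n_clones), function(k) {
    data.frame(species_id = paste0(records$species_id, "_c", k),
               seq_a = vapply(records$seq_a, mutate, character(1), USE.NAMES = FALSE),
               seq_b = vapply(records$seq_b, mutate, character(1), USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- rbind(as.data.frame(records), do.call(rbind, clones))
  rownames(out) <- NULL
  class(out) <- c("paired_records", class(out))
  out
}

#' Exact statistics of the planted pairs
#'
#' Computes each planted pair's true mutual information by direct
#' summation over its joint table. Because planted pairs form a matching,
#' each pair is the only coupling involving its two columns, so the
#' generator's two-site direct model is the joint itself and the true
#' direct information equals the true MI.
#'
#' @param spec a `synthetic_spec`
#' @return data frame of class `oracle_report`: one row per planted pair
#'   with `col_a`, `col_b` (per-protein residue numbers) and `true_mi`
#'   (nats; also the true DI)
#' @export
true_pair_statistics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- lapply(spec$planted, function(p) {
    pa <- rowSums(p$joint); pb <- colSums(p$joint)
    indep <- outer(pa, pb)
    pos <- p$joint > 0
    data.frame(col_a = p$col_a, col_b = p$col_b,
               true_mi = sum(p$joint[pos] * log(p$joint[pos] / indep[pos])))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("oracle_report", class(out))
  out
}

#' Precision and recall of planted-pair recovery
#'
#' Scores an inter-protein ranking against the planted pairs: the top-k
#' rows (by the chosen score) are compared with the planted (A, B)
#' residue pairs.
#'
#' @param pairs an `annotated_pairs` data frame (inter-protein)
#' @param spec the generating `synthetic_spec`
#' @param k ranking depth (> 0)
#' @param by score to rank by: "di" or "mi"
#' @return list with `precision`, `recall`, `k`, `hits` (logical vector
#'   over the top-k rows)
#' @export
evaluate_recovery <- function(pairs, spec, k = 5L, by = c("di", "mi")) {
  by <- match.arg(by)
  if (k <= 0) stop("k must be positive")
  stopifnot(inherits(spec, "synthetic_spec"))
  # orient every row as (A residue, B residue)
  res_a <- ifelse(pairs$protein_i == "A", pairs$res_i, pairs$res_j)
  res_b <- ifelse(pairs$protein_i == "B", pairs$res_i, pairs$res_j)
  ord <- order(-pairs[[by]], res_a, res_b)
  top <- utils::head(ord, k)
  truth <- vapply(spec$planted, function(p) paste(p$col_a, p$col_b), character(1))
  hits <- paste(res_a[top], res_b[top]) %in% truth
  list(precision = sum(hits) / k,
       recall = sum(hits) / length(spec$planted),
       k = as.integer(k), hits = hits)
}
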