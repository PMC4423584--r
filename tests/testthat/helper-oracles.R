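# Independent brute-force oracles and programmatic fixtures. These stay
# deliberately naive (O(M^2 L) loops, explicit double sums) so they check
# the vectorised implementation from a different route.

ALPHA21 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

# random aligned character matrix over the 21-state alphabet
random_alignment <- function(M, L, gap_rate = 0.1, n_letters = 21, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- c(rep((1 - gap_rate) / 20, 20), gap_rate)[seq_len(n_letters)]
  matrix(sample(ALPHA21[seq_len(n_letters)], M * L, replace = TRUE,
                prob = probs / sum(probs)),
         nrow = M, ncol = L, dimnames = list(paste0("s", seq_len(M)), NULL))
}

# O(M^2 L) definition of the reweighting
brute_force_weights <- function(chars, theta) {
  M <- nrow(chars); L <- ncol(chars)
  w <- numeric(M)
  for (m in seq_len(M)) {
    n_sim <- 0L
    for (m2 in seq_len(M)) {
      frac <- sum(chars[m, ] == chars[m2, ]) / L
      if (frac >= 1 - theta) n_sim <- n_sim + 1L
    }
    w[m] <- 1 / n_sim
  }
  w
}

# weighted empirical 21x21 joint table of two columns (no pseudocount)
brute_force_joint <- function(chars, i, j, w = rep(1, nrow(chars))) {
  tab <- matrix(0, 21, 21, dimnames = list(ALPHA21, ALPHA21))
  for (m in seq_len(nrow(chars)))
    tab[chars[m, i], chars[m, j]] <- tab[chars[m, i], chars[m, j]] + w[m]
  tab / sum(w)
}

# explicit double sum over the 21x21 joint
brute_force_mi <- function(chars, i, j, w = rep(1, nrow(chars))) {
  tab <- brute_force_joint(chars, i, j, w)
  pa <- rowSums(tab); pb <- colSums(tab)
  s <- 0
  for (a in 1:21) for (b in 1:21)
    if (tab[a, b] > 0) s <- s + tab[a, b] * log(tab[a, b] / (pa[a] * pb[b]))
  unname(s)
}

# exact MI of a joint probability table, by direct summation
joint_mi <- function(joint) {
  pa <- rowSums(joint); pb <- colSums(joint)
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / outer(pa, pb)[pos]))
}

# concatenate sampled records, clean, and map: the standard path from a
# synthetic spec to dca() inputs
synthetic_alignment <- function(spec, seed = spec$seed, spacer_len = 20) {
  rec <- pairdca::sample_paired_msa(spec, seed = seed)
  cc <- pairdca::concatenate_with_spacer(rec, spacer_len = spacer_len)
  seqs <- cc$sequence
  names(seqs) <- cc$species_id
  aln <- pairdca::remove_insert_columns(pairdca::alignment_matrix(seqs))
  map <- pairdca::build_position_map(aln, len_a = spec$len_a,
                                     spacer_len = spacer_len)
  list(aln = aln, map = map)
}

# planted (A, B) residue pairs of a spec as "a b" strings
planted_keys <- function(spec) {
  vapply(spec$planted, function(p) paste(p$col_a, p$col_b), character(1))
}

# write a minimal PDB file from an atom table (chain, resno, resname,
# atom, element, x, y, z)
write_pdb_fixture <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(k) {
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            k, atoms$atom[k], atoms$resname[k], atoms$chain[k],
            atoms$resno[k], atoms$x[k], atoms$y[k], atoms$z[k],
            atoms$element[k])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# a small two-chain structure with hand-placed coordinates
demo_structure_atoms <- function() {
  data.frame(
    chain   = c("E", "E", "E", "C", "C", "D"),
    resno   = c(1L, 1L, 2L, 1L, 1L, 1L),
    resname = c("ALA", "ALA", "GLY", "SER", "SER", "SER"),
    atom    = c("CA", "CB", "CA", "CA", "OG", "CA"),
    element = c("C", "C", "C", "C", "O", "C"),
    x = c(0, 1, 3, 10, 9, 0),
    y = c(0, 0, 4, 0, 0.5, 3),
    z = c(0, 0, 0, 0, 0, 4),
    stringsAsFactors = FALSE)
}
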