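#' Read a complex structure from a PDB file
#'
#' Parses ATOM records (via bio3d) into a flat atom table; hydrogens and,
#' by default, HETATM records are discarded. The structure is typically a
#' docking model of the two-protein complex whose co-varying residue pairs
#' are to be distance-validated.
#'
#' @param path PDB file
#' @param keep_hetatm retain HETATM records
#' @return object of class `structure_model`: list with `atoms` (data
#'   frame: `chain`, `resno`, `resname`, `atom`, `element`, `x`, `y`,
#'   `z`), `chains`
#' @export
read_structure <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop(sprintf("malformed PDB '%s': %s",
                                                   path, conditionMessage(e))))
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("no ATOM records in %s", path))
  # element symbol: PDB column when present, else first letter of atom name
  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  elem[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1, 1)
  elem <- toupper(trimws(elem))
  at <- at[elem != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("no heavy atoms in %s", path))
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad))
    stop(sprintf("non-numeric coordinates for atom %s %s%d (%s)",
                 at$elety[which(bad)[1]], at$chain[which(bad)[1]],
                 at$resno[which(bad)[1]], path))
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resname = at$resid, atom = at$elety,
                      element = toupper(elem[elem != "H"]),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, chains = sort(unique(atoms$chain))),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure: %d heavy atoms, %d residues, chains %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(x$chains, collapse = ",")))
  invisible(x)
}

residue_atoms <- function(s, chain, resno) {
  s$atoms[s$atoms$chain == chain & s$atoms$resno == resno, , drop = FALSE]
}

#' Minimum distance between two residues
#'
#' In `heavy_atom_min` mode, the minimum Euclidean distance over all
#' heavy-atom pairs of the two residues; in `calpha` mode, the distance
#' between their C-alpha atoms. Side-chain contacts (2-4 Angstrom) are
#' only visible in heavy-atom mode, which is therefore the default for
#' annotating predicted interaction pairs.
#'
#' @param s a `structure_model`
#' @param res1,res2 length-2 vectors `c(chain, residue_number)`
#' @param mode "heavy_atom_min" or "calpha"
#' @return distance in Angstrom
#' @export
residue_min_distance <- function(s, res1, res2,
                                 mode = c("heavy_atom_min", "calpha")) {
  mode <- match.arg(mode)
  a1 <- residue_atoms(s, as.character(res1[1]), as.integer(res1[2]))
  a2 <- residue_atoms(s, as.character(res2[1]), as.integer(res2[2]))
  if (nrow(a1) == 0L)
    stop(sprintf("residue %s:%s not found in structure", res1[1], res1[2]))
  if (nrow(a2) == 0L)
    stop(sprintf("residue %s:%s not found in structure", res2[1], res2[2]))
  if (mode == "calpha") {
    a1 <- a1[a1$atom == "CA", , drop = FALSE]
    a2 <- a2[a2$atom == "CA", , drop = FALSE]
    if (nrow(a1) == 0L || nrow(a2) == 0L)
      stop("calpha mode requires both residues to carry a CA atom")
  }
  x1 <- as.matrix(a1[, c("x", "y", "z")])
  x2 <- as.matrix(a2[, c("x", "y", "z")])
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), `+`) - 2 * tcrossprod(x1, x2)
  sqrt(max(min(d2), 0))
}

#' Annotate ranked pairs with structure distances
#'
#' Fills the `distance` column of an annotated pair table (or anchor
#' ranking) from a complex structure. The chain map assigns each protein
#' segment to one or more chains; when a segment maps to several chains
#' (e.g. the kinase is a homodimer), the minimum distance over all chain
#' combinations is reported — the convention when the contacting protomer
#' is unknown. Pairs whose residues are missing from the structure keep
#' `NA` distances rather than failing.
#'
#' @param pairs an `annotated_pairs` data frame (or `anchor_ranking`,
#'   whose query identifies the anchor)
#' @param s a `structure_model`
#' @param chain_map named list mapping segment tags to chain id vectors,
#'   e.g. `list(A = "E", B = c("C", "D"))`
#' @param mode distance definition (see [residue_min_distance()])
#' @return `pairs` with the `distance` column filled (Angstrom)
#' @export
annotate_pairs_with_distances <- function(pairs, s, chain_map,
                                          mode = c("heavy_atom_min", "calpha")) {
  mode <- match.arg(mode)
  if (length(chain_map) == 0L) stop("empty chain map")
  missing_chains <- setdiff(unlist(chain_map), s$chains)
  if (length(missing_chains))
    stop(sprintf("chain(s) not in structure: %s",
                 paste(missing_chains, collapse = ",")))
  if (inherits(pairs, "anchor_ranking")) {
    q <- attr(pairs, "query")
    seg_i <- rep(q$target_segment, nrow(pairs)); res_i <- pairs$partner_res
    seg_j <- rep(q$anchor_segment, nrow(pairs)); res_j <- pairs$anchor_res
  } else {
    seg_i <- pairs$protein_i; res_i <- pairs$res_i
    seg_j <- pairs$protein_j; res_j <- pairs$res_j
  }
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    ch_i <- chain_map[[seg_i[k]]]; ch_j <- chain_map[[seg_j[k]]]
    if (is.null(ch_i) || is.null(ch_j))
      stop(sprintf("segment without chain mapping in row %d", k))
    best <- Inf
    for (ci in ch_i) for (cj in ch_j) {
      dd <- tryCatch(residue_min_distance(s, c(ci, res_i[k]), c(cj, res_j[k]),
                                          mode = mode),
                     error = function(e) NA_real_)
      if (!is.na(dd) && dd < best) best <- dd
    }
    if (is.finite(best)) best else NA_real_
  }, numeric(1))
  pairs$distance <- d
  pairs
}
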