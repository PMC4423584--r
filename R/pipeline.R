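#' Run the full coevolution pipeline
#'
#' Orchestrates the stages: read paired FASTA (or take records directly)
#' -> concatenate with spacer -> (external alignment, or treat equal-length
#' concatenations as aligned) -> remove insert columns -> position map ->
#' DCA (MI + DI for all pairs) -> proximity filter -> inter-protein
#' restriction -> anchor rankings -> optional structure distances ->
#' reports. Writes all artifacts plus a JSON manifest of parameters into
#' `out_dir`. Sequence alignment itself is delegated: when the
#' concatenated sequences are not all the same length, the pipeline stops
#' after writing `concat.fasta` and asks for an externally aligned file
#' via `config$aligned`.
#'
#' @param config named list:
#'   \describe{
#'     \item{fasta_a, fasta_b}{paths to the two per-species FASTA files
#'       (alternative: `records`, a `paired_records` data frame)}
#'     \item{aligned}{path to an externally aligned concatenated FASTA
#'       (alternative to `fasta_a`/`fasta_b` + equal-length records)}
#'     \item{reference}{reference sequence id or row index (default 1)}
#'     \item{len_a}{ungapped reference length of protein A (required with
#'       `aligned`; derived from the records otherwise)}
#'     \item{spacer_len, spacer_char}{spacer parameters (default 20, "A")}
#'     \item{theta, pseudocount}{DCA parameters (default 0.2, 1)}
#'     \item{min_sep}{proximity filter threshold (default 5)}
#'     \item{anchors}{list of `anchor_query` objects (optional)}
#'     \item{structure, chain_map, distance_mode}{PDB path, segment-to-
#'       chain map and distance mode for annotation (optional)}
#'     \item{out_dir}{artifact directory (created)}
#'   }
#' @return invisibly, a list with the fit, the filtered inter-protein
#'   pairs, the rankings, and the manifest
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out_dir <- cfg$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spacer_len <- cfg$spacer_len %||% 20L
  spacer_char <- cfg$spacer_char %||% "A"
  reference <- cfg$reference %||% 1L
  # fail fast on a missing structure before any compute
  if (!is.null(cfg$structure) && !file.exists(cfg$structure))
    stop(sprintf("structure file not found: %s", cfg$structure))

  len_a <- cfg$len_a
  if (!is.null(cfg$aligned)) {
    aln <- stage("clean", read_alignment_fasta(cfg$aligned, reference = reference))
    if (is.null(len_a)) stop("config$len_a is required with a pre-aligned input")
  } else {
    records <- cfg$records
    if (is.null(records))
      records <- stage("read", read_paired_fasta(cfg$fasta_a, cfg$fasta_b))
    concat <- stage("concat", concatenate_with_spacer(records, spacer_len,
                                                      spacer_char))
    write_fasta(concat, file.path(out_dir, "concat.fasta"))
    if (length(unique(nchar(concat$sequence))) != 1L)
      stop("concatenated sequences differ in length; align concat.fasta ",
           "externally and rerun with config$aligned")
    seqs <- concat$sequence
    names(seqs) <- concat$species_id
    aln <- alignment_matrix(seqs, reference = reference)
    ref_idx <- aln$reference_row
    if (is.null(len_a)) len_a <- concat$len_a[ref_idx]
  }
  aln <- stage("clean", remove_insert_columns(aln))
  map <- stage("map", build_position_map(aln, len_a = len_a,
                                         spacer_len = spacer_len))
  fit <- stage("dca", dca(aln, position_map = map,
                          theta = cfg$theta %||% 0.2,
                          pseudocount = cfg$pseudocount %||% 1,
                          keep_couplings = FALSE))
  write_pair_table(fit$pairs, file.path(out_dir, "pairs.txt"))
  filt <- stage("filter", filter_proximal_pairs(fit$pairs,
                                                min_sep = cfg$min_sep %||% 5L))
  inter <- stage("restrict", restrict_inter_protein(filt, map))

  structure_model <- NULL
  if (!is.null(cfg$structure)) {
    structure_model <- stage("distances", read_structure(cfg$structure))
    inter <- stage("distances",
                   annotate_pairs_with_distances(inter, structure_model,
                                                 cfg$chain_map,
                                                 mode = cfg$distance_mode %||%
                                                   "heavy_atom_min"))
  }
  utils::write.csv(inter, file.path(out_dir, "inter_protein_pairs.csv"),
                   row.names = FALSE)

  rankings <- list()
  for (q in cfg$anchors %||% list()) {
    r <- stage("rank", rank_anchor_hits(inter, q))
    rankings[[sprintf("%s%d_by_%s", q$anchor_segment, q$anchor_residue,
                      q$sort_key)]] <- r
  }
  if (length(rankings))
    write_ranking_report(rankings, file.path(out_dir, "rankings.tsv"))

  manifest <- list(
    package = "pairdca",
    version = as.character(utils::packageVersion("pairdca")),
    parameters = list(spacer_len = spacer_len, spacer_char = spacer_char,
                      theta = cfg$theta %||% 0.2,
                      pseudocount = cfg$pseudocount %||% 1,
                      min_sep = cfg$min_sep %||% 5L,
                      reference = reference, len_a = len_a),
    alignment = list(M = fit$M, L = fit$L, N = fit$N,
                     M_eff = fit$weights$M_eff),
    n_pairs = nrow(fit$pairs), n_inter_protein = nrow(inter))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fit = fit, inter = inter, rankings = rankings,
                 manifest = manifest, position_map = map))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
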