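#' Remove sequence-proximal pairs from a pair table
#'
#' Drops every row whose two column indices are within `min_sep` of each
#' other (`|i - j| <= min_sep`), eliminating the trivially high scores of
#' near-neighbour residues. Applied in concatenated coordinates before
#' per-protein translation, so with a spacer at least `min_sep` long it
#' can only ever remove intra-protein neighbours.
#'
#' @param table a `pair_table` data frame (columns `i`, `j`, ...)
#' @param min_sep minimum separation; pairs with `|i - j| <= min_sep` are
#'   removed (>= 0)
#' @return the filtered table, row order preserved
#' @export
filter_proximal_pairs <- function(table, min_sep = 5L) {
  if (!is.numeric(min_sep) || length(min_sep) != 1L || min_sep < 0)
    stop("min_sep must be a single integer >= 0")
  keep <- abs(table$i - table$j) > min_sep
  table[keep, , drop = FALSE]
}

#' Restrict a pair table to inter-protein pairs
#'
#' Keeps only pairs whose two columns fall in different protein segments
#' (A vs B), translates column indices to per-protein residue numbers via
#' the position map, and drops pairs touching spacer columns.
#'
#' @param table a `pair_table` in concatenated coordinates
#' @param map the `position_map` built from the same cleaned alignment
#' @return data frame of class `annotated_pairs` with columns
#'   `protein_i`, `res_i`, `protein_j`, `res_j`, `mi`, `di`, `distance`
#'   (NA until annotated)
#' @export
restrict_inter_protein <- function(table, map) {
  stopifnot(inherits(map, "position_map"))
  if (any(!(table$i %in% map$column)) || any(!(table$j %in% map$column)))
    stop("pair table contains column indices absent from the position map")
  seg <- map$segment[match(table$i, map$column)]
  seg_j <- map$segment[match(table$j, map$column)]
  res <- map$residue[match(table$i, map$column)]
  res_j <- map$residue[match(table$j, map$column)]
  keep <- seg != "SPACER" & seg_j != "SPACER" & seg != seg_j
  out <- data.frame(protein_i = seg[keep], res_i = res[keep],
                    protein_j = seg_j[keep], res_j = res_j[keep],
                    mi = table$mi[keep], di = table$di[keep],
                    distance = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("annotated_pairs", class(out))
  out
}

#' Define an anchor-residue ranking query
#'
#' An anchor is a genetically implicated residue (such as PhoU A147)
#' against which all partner-domain residues are ranked by MI or DI.
#'
#' @param anchor length-2 vector `c(segment, residue)`, e.g. `c("A", 147)`
#' @param target_segment segment of the partner residues ("A" or "B")
#' @param target_range inclusive residue interval in the target segment,
#'   e.g. a PAS-domain span `c(96, 193)`
#' @param sort_key "mi" or "di"
#' @param top_n maximum number of hits to return
#' @return object of class `anchor_query`
#' @export
anchor_query <- function(anchor, target_segment, target_range,
                         sort_key = c("mi", "di"), top_n = 10L) {
  sort_key <- match.arg(sort_key)
  seg <- as.character(anchor[1]); res <- as.integer(anchor[2])
  target_segment <- as.character(target_segment)
  if (!seg %in% c("A", "B") || !target_segment %in% c("A", "B"))
    stop("segments must be 'A' or 'B'")
  if (seg == target_segment)
    stop("anchor and target segments must differ for inter-protein queries")
  target_range <- as.integer(target_range)
  if (length(target_range) != 2L || target_range[1] > target_range[2])
    stop("target_range must be a non-empty inclusive interval c(lo, hi)")
  if (top_n < 1L) stop("top_n must be positive")
  structure(list(anchor_segment = seg, anchor_residue = res,
                 target_segment = target_segment, target_range = target_range,
                 sort_key = sort_key, top_n = as.integer(top_n)),
            class = "anchor_query")
}

#' Rank partner residues against an anchor residue
#'
#' Selects the annotated pairs that join the anchor residue to a partner
#' inside the target segment and range, sorts them by the query's score
#' (descending), and returns at most `top_n` rows. Ties are broken by
#' ascending partner residue number for reproducibility.
#'
#' @param pairs an `annotated_pairs` data frame
#' @param query an `anchor_query`
#' @return the ranked subset with columns `partner_res`, `anchor_res`
#'   prepended (partner first, mirroring the field's reporting convention)
#' @export
rank_anchor_hits <- function(pairs, query) {
  stopifnot(inherits(query, "anchor_query"))
  a_is_i <- pairs$protein_i == query$anchor_segment &
    pairs$res_i == query$anchor_residue &
    pairs$protein_j == query$target_segment
  a_is_j <- pairs$protein_j == query$anchor_segment &
    pairs$res_j == query$anchor_residue &
    pairs$protein_i == query$target_segment
  partner <- ifelse(a_is_i, pairs$res_j, ifelse(a_is_j, pairs$res_i, NA))
  sel <- (a_is_i | a_is_j) & partner >= query$target_range[1] &
    partner <= query$target_range[2]
  if (!any(sel)) {
    warning(sprintf("anchor %s:%d has no pairs in %s:%d-%d",
                    query$anchor_segment, query$anchor_residue,
                    query$target_segment, query$target_range[1],
                    query$target_range[2]))
  }
  out <- data.frame(partner_res = partner[sel],
                    anchor_res = rep(query$anchor_residue, sum(sel)),
                    mi = pairs$mi[sel], di = pairs$di[sel],
                    distance = pairs$distance[sel])
  key <- out[[query$sort_key]]
  out <- out[order(-key, out$partner_res), , drop = FALSE]
  out <- out[seq_len(min(query$top_n, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "query") <- query
  class(out) <- c("anchor_ranking", class(out))
  out
}

#' Write an anchor ranking report
#'
#' Tab-separated table with columns partner residue, anchor residue, MI,
#' DI and distance (Angstrom; empty when not annotated), mirroring the
#' field's reporting convention for anchor-versus-domain rankings.
#'
#' @param ranking an `anchor_ranking` (or list of them; concatenated with
#'   a blank line between blocks)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ranking_report <- function(ranking, path) {
  if (inherits(ranking, "anchor_ranking")) ranking <- list(ranking)
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(ranking)) {
    r <- ranking[[k]]
    x <- data.frame(partner_res = r$partner_res, anchor_res = r$anchor_res,
                    mi = sprintf("%.15g", r$mi), di = sprintf("%.15g", r$di),
                    distance = ifelse(is.na(r$distance), "",
                                      sprintf("%.15g", r$distance)))
    utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = (k == 1L))
  }
  invisible(path)
}

#' Read an anchor ranking report written by [write_ranking_report()]
#'
#' @param path tab-separated report file
#' @return data frame with columns `partner_res`, `anchor_res`, `mi`,
#'   `di`, `distance`
#' @export
read_ranking_report <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("integer", "integer", "numeric",
                                        "numeric", "character"))
  x$distance <- suppressWarnings(as.numeric(x$distance))
  x
}
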