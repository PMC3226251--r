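#' Jaccard coefficient of two compound sets
#'
#' The fraction of active compounds shared by two assays among all distinct
#' active compounds of the two: `|a intersect b| / |a union b|`.
#'
#' @param a,b Character vectors of compound ids; at least one nonempty.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0)
    stop("jaccard undefined for two empty sets", call. = FALSE)
  length(intersect(a, b)) / length(union(a, b))
}

#' Project a bipartite screening network onto assays
#'
#' Builds the assay-assay similarity network: nodes are assays with at least
#' one active compound, and two assays are connected when the Jaccard
#' coefficient of their active-compound sets reaches `min_jaccard`
#' (boundary inclusive — "at least 10% shared" at the default 0.10).  Pairs
#' are enumerated through an inverted compound-to-assay index, so only
#' assays sharing at least one compound are ever compared; the result is
#' identical to the all-pairs computation.
#'
#' @param net Bipartite network from [build_bipartite()].
#' @param min_jaccard Edge threshold in (0, 1\]; default 0.10.
#' @param drop_isolates Drop assays left without any edge (default keeps
#'   them, so the node count reflects every active assay).
#' @return An [igraph::igraph] whose vertices carry `assay_type`,
#'   `target_symbol` and `n_active_compounds`, and whose edges carry the
#'   `jaccard` weight (also copied to `weight`).
#' @export
project <- function(net, min_jaccard = 0.10, drop_isolates = FALSE) {
  stopifnot(min_jaccard > 0, min_jaccard <= 1)
  is_assay <- !igraph::V(net)$type
  assays <- igraph::V(net)$name[is_assay]
  sets <- lapply(igraph::adjacent_vertices(net, assays),
                 function(v) v$name)
  names(sets) <- assays

  edges <- candidate_jaccard_edges(sets, min_jaccard)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = assays, stringsAsFactors = FALSE))
  idx <- match(assays, igraph::V(net)$name)
  igraph::V(g)$assay_type <- igraph::V(net)$assay_type[idx]
  igraph::V(g)$target_symbol <- igraph::V(net)$target_symbol[idx]
  igraph::V(g)$n_active_compounds <- lengths(sets)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- igraph::E(g)$jaccard
  if (drop_isolates)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g
}

# Enumerate assay pairs sharing >=1 compound via the inverted index and
# keep those at or above the threshold.
candidate_jaccard_edges <- function(sets, min_jaccard) {
  empty <- data.frame(from = character(), to = character(),
                      jaccard = numeric(), stringsAsFactors = FALSE)
  if (length(sets) < 2) return(empty)
  inv <- split(rep(names(sets), lengths(sets)), unlist(sets, use.names = FALSE))
  pair_keys <- unique(unlist(lapply(inv, function(as) {
    if (length(as) < 2) return(NULL)
    as <- sort(as)
    cmb <- utils::combn(as, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE))
  if (length(pair_keys) == 0) return(empty)
  parts <- strsplit(pair_keys, "\r", fixed = TRUE)
  u <- vapply(parts, `[`, "", 1)
  v <- vapply(parts, `[`, "", 2)
  j <- mapply(function(a, b) jaccard(sets[[a]], sets[[b]]), u, v)
  keep <- j >= min_jaccard
  data.frame(from = u[keep], to = v[keep], jaccard = j[keep],
             stringsAsFactors = FALSE)
}
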