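#' Screening activity table
#'
#' The basic input of the pipeline: active (assay, compound) pairs plus
#' per-assay metadata.  Assays are either target-based (screened against a
#' specific protein, recorded in `target_symbol`) or cell-based (phenotypic,
#' `target_symbol` absent).
#'
#' @param pairs data.frame with character columns `assay_id`, `compound_id`;
#'   one row per active pair, no duplicates.
#' @param assay_meta data.frame with columns `assay_id`,
#'   `assay_type` (`"target_based"` or `"cell_based"`) and `target_symbol`
#'   (`NA` allowed; required `NA` for cell-based assays).  Every assay in
#'   `pairs` must appear here.
#'
#' @return A list of class `"activity_table"` with elements `pairs` and
#'   `assay_meta`.
#' @export
activity_table <- function(pairs, assay_meta) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  assay_meta <- as.data.frame(assay_meta, stringsAsFactors = FALSE)
  stopifnot(all(c("assay_id", "compound_id") %in% names(pairs)),
            all(c("assay_id", "assay_type", "target_symbol") %in%
                  names(assay_meta)))
  key <- paste(pairs$assay_id, pairs$compound_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (assay, compound) pairs: ",
         paste(utils::head(key[duplicated(key)], 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(assay_meta$assay_id))
    stop("duplicate assay_id in metadata", call. = FALSE)
  missing_meta <- setdiff(pairs$assay_id, assay_meta$assay_id)
  if (length(missing_meta))
    stop("assays without metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "), call. = FALSE)
  bad_type <- setdiff(assay_meta$assay_type, c("target_based", "cell_based"))
  if (length(bad_type))
    stop("unknown assay_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  sym_no_target <- !is.na(assay_meta$target_symbol) &
    assay_meta$assay_type != "target_based"
  if (any(sym_no_target))
    stop("target_symbol set on non-target-based assay: ",
         paste(assay_meta$assay_id[sym_no_target], collapse = ", "),
         call. = FALSE)
  structure(list(pairs = pairs, assay_meta = assay_meta),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat("Activity table:", nrow(x$pairs), "active pairs,",
      length(unique(x$pairs$assay_id)), "assays with >=1 active compound,",
      length(unique(x$pairs$compound_id)), "active compounds\n")
  invisible(x)
}

#' Build the bioassay-compound bipartite network
#'
#' One node per distinct assay with at least one active compound, one node
#' per distinct active compound, one edge per active pair.  Assay metadata
#' (`assay_type`, `target_symbol`) is carried as vertex attributes; the
#' igraph bipartite `type` attribute is `FALSE` for assays and `TRUE` for
#' compounds, with a readable `kind` attribute alongside.
#'
#' @param table An [activity_table()].
#' @return A bipartite [igraph::igraph].
#' @export
build_bipartite <- function(table) {
  stopifnot(inherits(table, "activity_table"))
  pairs <- table$pairs
  assays <- sort(unique(pairs$assay_id))
  compounds <- sort(unique(pairs$compound_id))
  g <- igraph::graph_from_data_frame(
    pairs,
    directed = FALSE,
    vertices = data.frame(name = c(assays, compounds),
                          type = rep(c(FALSE, TRUE),
                                     c(length(assays), length(compounds))),
                          kind = rep(c("assay", "compound"),
                                     c(length(assays), length(compounds))),
                          stringsAsFactors = FALSE))
  igraph::V(g)$bipartite <- igraph::V(g)$kind
  meta <- table$assay_meta[match(assays, table$assay_meta$assay_id), ]
  igraph::V(g)$assay_type <- c(meta$assay_type,
                               rep(NA_character_, length(compounds)))
  igraph::V(g)$target_symbol <- c(meta$target_symbol,
                                  rep(NA_character_, length(compounds)))
  g
}

#' Summarize a bipartite screening network
#'
#' Reports the counts and the two mean-activity quotients:
#' compounds per active assay (`n_pairs / n_assays_active`) and assays per
#' active compound (`n_pairs / n_active_compounds`).  Quotients are kept at
#' full precision; round to one decimal for display.
#'
#' @param net A bipartite network from [build_bipartite()].
#' @return A list of class `"bipartite_summary"`.
#' @export
summarize_bipartite <- function(net) {
  if (igraph::vcount(net) == 0)
    stop("empty network: summary means are undefined", call. = FALSE)
  n_assays <- sum(!igraph::V(net)$type)
  n_compounds <- sum(igraph::V(net)$type)
  summary_from_counts(igraph::ecount(net), n_assays, n_compounds)
}

#' Summary quotients from bare counts
#'
#' The arithmetic core of [summarize_bipartite()], exposed so the summary
#' can also be computed from published campaign totals without materializing
#' the network.
#'
#' @param n_pairs Number of active (assay, compound) pairs.
#' @param n_assays_active Number of assays with >= 1 active compound.
#' @param n_active_compounds Number of compounds active in >= 1 assay.
#' @return A list of class `"bipartite_summary"` with the counts and the two
#'   means `mean_compounds_per_assay` and `mean_assays_per_compound`.
#' @export
summary_from_counts <- function(n_pairs, n_assays_active,
                                n_active_compounds) {
  if (n_assays_active < 1 || n_active_compounds < 1)
    stop("means undefined without active assays and compounds",
         call. = FALSE)
  structure(list(n_assays_active = n_assays_active,
                 n_active_compounds = n_active_compounds,
                 n_pairs = n_pairs,
                 mean_compounds_per_assay = n_pairs / n_assays_active,
                 mean_assays_per_compound = n_pairs / n_active_compounds),
            class = "bipartite_summary")
}

#' @export
print.bipartite_summary <- function(x, ...) {
  cat(sprintf(paste0("Bipartite summary: %d pairs | %d assays ",
                     "(%.1f compounds/assay) | %d compounds ",
                     "(%.1f assays/compound)\n"),
              x$n_pairs, x$n_assays_active, x$mean_compounds_per_assay,
              x$n_active_compounds, x$mean_assays_per_compound))
  invisible(x)
}

#' Extract a degree-window bipartite subnetwork
#'
#' Keeps assay nodes whose degree falls in `assay_deg` and compound nodes
#' whose degree falls in `compound_deg` (inclusive bounds), with degrees
#' measured in the input network (a single pass), then keeps edges with both
#' endpoints surviving and drops nodes left isolated.  With
#' `iterate = TRUE` the filter is instead applied repeatedly on the shrinking
#' network until a fixed point.
#'
#' @param net Bipartite network from [build_bipartite()].
#' @param assay_deg,compound_deg Length-2 inclusive degree windows
#'   `c(lo, hi)`.
#' @param iterate Recompute degrees and re-filter until stable.
#' @return A bipartite igraph, possibly empty.
#' @export
extract_subnetwork <- function(net, assay_deg, compound_deg,
                               iterate = FALSE) {
  stopifnot(length(assay_deg) == 2, length(compound_deg) == 2,
            assay_deg[1] <= assay_deg[2],
            compound_deg[1] <= compound_deg[2])
  one_pass <- function(g) {
    deg <- igraph::degree(g)
    is_compound <- igraph::V(g)$type
    lo <- ifelse(is_compound, compound_deg[1], assay_deg[1])
    hi <- ifelse(is_compound, compound_deg[2], assay_deg[2])
    sub <- igraph::induced_subgraph(g, which(deg >= lo & deg <= hi))
    igraph::delete_vertices(sub, which(igraph::degree(sub) == 0))
  }
  out <- one_pass(net)
  if (iterate) {
    repeat {
      nxt <- one_pass(out)
      if (igraph::vcount(nxt) == igraph::vcount(out)) break
      out <- nxt
    }
    out <- nxt
  }
  out
}

#' Decompose a bipartite network back into its active pairs
#'
#' Inverse of [build_bipartite()] (up to row order): returns the
#' (assay_id, compound_id) edge list.
#'
#' @param net Bipartite network.
#' @return data.frame with columns `assay_id`, `compound_id`.
#' @export
bipartite_pairs <- function(net) {
  if (igraph::ecount(net) == 0)
    return(data.frame(assay_id = character(), compound_id = character(),
                      stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(net)
  swap <- igraph::V(net)$type[match(el[, 1], igraph::V(net)$name)]
  pairs <- data.frame(assay_id = ifelse(swap, el[, 2], el[, 1]),
                      compound_id = ifelse(swap, el[, 1], el[, 2]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$assay_id, pairs$compound_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
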