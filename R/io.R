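#' Read an activity table from TSV files
#'
#' `activity_path` must have header columns `assay_id`, `compound_id` (one
#' active pair per row); `meta_path` must have `assay_id`, `assay_type`,
#' `target_symbol` (empty allowed).  Duplicate pairs, unknown assay types
#' and assays missing metadata are rejected with the offending line numbers
#' or ids.
#'
#' @param activity_path,meta_path Paths to the two TSV files.
#' @return An [activity_table()].
#' @export
read_activity <- function(activity_path, meta_path) {
  pairs <- read_tsv_checked(activity_path, c("assay_id", "compound_id"))
  meta <- read_tsv_checked(meta_path,
                           c("assay_id", "assay_type", "target_symbol"))
  key <- paste(pairs$assay_id, pairs$compound_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate pair(s) in %s at data line(s): %s",
                 activity_path, paste(dup, collapse = ", ")), call. = FALSE)
  meta$target_symbol[!nzchar(trimws(as.character(
    ifelse(is.na(meta$target_symbol), "", meta$target_symbol))))] <-
    NA_character_
  activity_table(pairs, meta)
}

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "#",
                          quote = "", blank.lines.skip = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Read an undirected PPI edge list from TSV
#'
#' Two whitespace-separated gene symbols per line; `#` comment lines
#' allowed.  Self-loops and duplicate edges (in either direction) are
#' dropped, with counts reported via `message()`.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::igraph].
#' @export
read_edges <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("no edges in ", path, call. = FALSE)
    return(igraph::make_empty_graph(directed = FALSE))
  }
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop(sprintf("%s: expected 2 fields on line(s) %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  el <- do.call(rbind, parts)
  self <- el[, 1] == el[, 2]
  if (any(self))
    message("dropped ", sum(self), " self-loop(s) from ", path)
  el <- el[!self, , drop = FALSE]
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message("dropped ", sum(dup), " duplicate edge(s) from ", path)
  el <- el[!dup, , drop = FALSE]
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Read / write a one-symbol-per-line marker file
#'
#' Blank and `#` comment lines are ignored on read.
#'
#' @param path File path.
#' @return `read_marker_set`: character vector of symbols.
#' @export
read_marker_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @param symbols Character vector to write.
#' @rdname read_marker_set
#' @export
write_marker_set <- function(symbols, path) {
  writeLines(symbols, path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Emits GraphML with all vertex/edge attributes typed, loadable in
#' Cytoscape; byte-stable for identical inputs.  `NA` character attributes
#' are written as empty strings (the GraphML writer cannot encode NA).
#'
#' @param graph igraph object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(graph, path) {
  for (at in igraph::vertex_attr_names(graph)) {
    v <- igraph::vertex_attr(graph, at)
    if (is.character(v) && anyNA(v))
      graph <- igraph::set_vertex_attr(graph, at,
                                       value = ifelse(is.na(v), "", v))
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network
#'
#' @param path GraphML file path.
#' @return An igraph object.
#' @export
read_graphml <- function(path) igraph::read_graph(path, format = "graphml")

#' Write a data frame as TSV
#'
#' Tab-separated, header, no quoting, no row names; byte-stable.
#'
#' @param rows data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write an activity table to the two TSV files the readers consume
#'
#' @param table An [activity_table()].
#' @param activity_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_activity <- function(table, activity_path, meta_path) {
  stopifnot(inherits(table, "activity_table"))
  write_table(table$pairs, activity_path)
  write_table(table$assay_meta, meta_path)
  invisible(c(activity_path, meta_path))
}

#' Write a PPI network as a two-column TSV edge list
#'
#' @param ppi igraph network with named vertices.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edges <- function(ppi, path) {
  el <- igraph::as_edgelist(ppi)
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  ord <- order(a, b)
  writeLines(c("# gene_a\tgene_b", paste(a[ord], b[ord], sep = "\t")), path)
  invisible(path)
}
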