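# Independent brute-force oracles used to validate the package's
# implementations on small randomized instances.  Deliberately written with
# different algorithms than the code under test.

# All-pairs shortest paths by Floyd-Warshall (matrix relaxation).
fw_distances <- function(graph) {
  n <- igraph::vcount(graph)
  D <- matrix(Inf, n, n,
              dimnames = list(igraph::V(graph)$name, igraph::V(graph)$name))
  diag(D) <- 0
  el <- igraph::as_edgelist(graph, names = FALSE)
  D[el] <- 1
  D[el[, 2:1, drop = FALSE]] <- 1
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# All-pairs Jaccard projection by direct double loop over assays.
brute_projection_edges <- function(sets, min_jaccard) {
  ids <- sort(names(sets))
  out <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    a <- sets[[ids[i]]]; b <- sets[[ids[j]]]
    jac <- length(intersect(a, b)) / length(union(a, b))
    if (jac >= min_jaccard)
      out[[length(out) + 1L]] <- data.frame(
        from = min(ids[i], ids[j]), to = max(ids[i], ids[j]), jaccard = jac,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(from = character(), to = character(),
                      jaccard = numeric()))
  df <- do.call(rbind, out)
  df[order(df$from, df$to), , drop = FALSE]
}

# Local clustering coefficients by explicit neighbor-pair enumeration on the
# adjacency matrix.
brute_clustering <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# Random connected-ish test graph with names.
random_test_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}

# Tiny deterministic activity table spanning the edge cases used in several
# files.
toy_activity <- function() {
  pairs <- data.frame(
    assay_id = c("A1", "A1", "A1", "A2", "A2", "A3"),
    compound_id = c("c1", "c2", "c3", "c2", "c3", "c9"),
    stringsAsFactors = FALSE)
  meta <- data.frame(
    assay_id = c("A1", "A2", "A3", "A4"),
    assay_type = c("target_based", "cell_based", "cell_based",
                   "target_based"),
    target_symbol = c("G000001", NA, NA, "G000002"),
    stringsAsFactors = FALSE)
  activity_table(pairs, meta)
}
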