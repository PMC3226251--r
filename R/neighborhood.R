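#' Map gene symbols onto a PPI network
#'
#' Case-sensitive exact matching against vertex names.  Unmapped symbols are
#' reported in input order rather than silently dropped.
#'
#' @param symbols Character vector of gene symbols.
#' @param ppi igraph PPI network with named vertices.
#' @return List with `mapped` (unique matched symbols) and `unmapped`
#'   (unmatched symbols, input order preserved).
#' @export
map_symbols <- function(symbols, ppi) {
  nodes <- igraph::V(ppi)$name
  hit <- symbols %in% nodes
  list(mapped = unique(symbols[hit]), unmapped = symbols[!hit])
}

#' Breadth-first shortest-path distances from one node
#'
#' Unweighted shortest-path distances from `source` to every reachable node
#' (including itself at distance 0); unreachable nodes are absent.
#'
#' @param ppi igraph network.
#' @param source A vertex name present in the network.
#' @return Named integer vector of distances.
#' @export
bfs_distances <- function(ppi, source) {
  if (!(source %in% igraph::V(ppi)$name))
    stop("unknown source node: ", source, call. = FALSE)
  d <- igraph::distances(ppi, v = source, weights = NA)[1, ]
  d <- d[is.finite(d)]
  storage.mode(d) <- "integer"
  d
}

#' Fraction of marker nodes at each distance from a seed
#'
#' For every distance d >= 1 with at least one node, the fraction of those
#' nodes that belong to `markers`.  The seed itself (distance 0) never
#' counts as its own neighbor.
#'
#' @param ppi igraph network.
#' @param seed Vertex name.
#' @param markers Character vector of marker node names.
#' @return Named numeric vector, names = distances, values in \[0, 1\].
#' @export
fraction_profile <- function(ppi, seed, markers) {
  d <- bfs_distances(ppi, seed)
  d <- d[d >= 1]
  if (length(d) == 0) return(stats::setNames(numeric(), character()))
  is_marker <- names(d) %in% markers
  tot <- tapply(rep(1L, length(d)), d, sum)
  hit <- tapply(as.integer(is_marker), d, sum)
  stats::setNames(as.numeric(hit / tot), names(tot))
}

# Per-source per-distance marker fractions from a distance matrix.
# Rows are sources; NA where a source has no node at that distance.
# The source itself sits at distance 0 and is therefore never counted.
fraction_matrix <- function(D, is_marker, d_max) {
  out <- matrix(NA_real_, nrow(D), d_max)
  for (d in seq_len(d_max)) {
    at_d <- D == d
    tot <- rowSums(at_d, na.rm = TRUE)
    hit <- as.numeric(at_d %*% is_marker)
    out[, d] <- ifelse(tot > 0, hit / tot, NA_real_)
  }
  out
}

#' Distance-profile enrichment of markers around seed nodes
#'
#' For each distance d, the mean over seeds of the fraction of markers among
#' nodes at distance d (seeds with no node at d are skipped at that d),
#' compared against `n_random` control trials that repeat the computation
#' from a uniformly drawn protein (with replacement across trials).  The
#' per-distance p-value is a two-sided Wilcoxon rank-sum test of the
#' per-seed fraction sample against the per-trial control sample.
#'
#' @param ppi igraph network.
#' @param seeds Nonempty character vector of seed vertex names (e.g.
#'   essential genes).
#' @param markers Nonempty character vector of marker vertex names (e.g.
#'   bioassay targets).
#' @param n_random Number of random control trials (default 10000).
#' @param rng_seed Optional integer seed for the control draws.
#' @param d_max Largest distance reported; defaults to the largest distance
#'   observed from any seed.
#' @return List of class `"enrichment_result"`: `distances`,
#'   `mean_fraction`, `random_mean_fraction`, `p_value` (all indexed by
#'   distance), `n_seeds`, `n_random`, plus the underlying per-seed and
#'   per-trial fraction matrices.
#' @export
enrichment <- function(ppi, seeds, markers, n_random = 10000,
                       rng_seed = NULL, d_max = NULL) {
  if (length(seeds) == 0) stop("seeds must be nonempty", call. = FALSE)
  if (length(markers) == 0) stop("markers must be nonempty", call. = FALSE)
  nodes <- igraph::V(ppi)$name
  stopifnot(all(seeds %in% nodes), all(markers %in% nodes))

  D_seed <- igraph::distances(ppi, v = seeds, weights = NA)
  D_seed[!is.finite(D_seed)] <- NA
  if (is.null(d_max)) d_max <- max(D_seed, na.rm = TRUE)
  d_max <- as.integer(d_max)
  is_marker <- as.numeric(nodes %in% markers)

  draw <- function() sample(nodes, n_random, replace = TRUE)
  trials <- if (is.null(rng_seed)) draw() else
    withr::with_seed(as.integer(rng_seed), draw())
  uniq <- unique(trials)
  D_rand <- igraph::distances(ppi, v = uniq, weights = NA)
  D_rand[!is.finite(D_rand)] <- NA
  D_rand <- D_rand[match(trials, uniq), , drop = FALSE]

  F_seed <- fraction_matrix(D_seed, is_marker, d_max)
  F_rand <- fraction_matrix(D_rand, is_marker, d_max)

  p <- vapply(seq_len(d_max), function(d) {
    x <- F_seed[, d]; y <- F_rand[, d]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) NA_real_ else ranksum(x, y)
  }, numeric(1))

  structure(list(distances = seq_len(d_max),
                 mean_fraction = colMeans(F_seed, na.rm = TRUE),
                 random_mean_fraction = colMeans(F_rand, na.rm = TRUE),
                 p_value = p,
                 n_seeds = length(seeds),
                 n_random = n_random,
                 seed_fractions = F_seed,
                 random_fractions = F_rand),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Marker enrichment around", x$n_seeds, "seeds vs", x$n_random,
      "random trials\n")
  df <- data.frame(distance = x$distances,
                   mean_fraction = round(x$mean_fraction, 4),
                   random = round(x$random_mean_fraction, 4),
                   p = signif(x$p_value, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Complementary cumulative degree curve of a node set
#'
#' At each degree k in 1..`k_max`, the percentage of set members with degree
#' >= k in the network; non-increasing in k, and 100 at k = 1 when no member
#' is isolated.
#'
#' @param ppi igraph network.
#' @param node_set Nonempty character vector of member vertex names.
#' @param k_max Largest degree evaluated (default 51).
#' @return Named numeric vector of percentages, names `1..k_max`.
#' @export
degree_cdf <- function(ppi, node_set, k_max = 51) {
  if (length(node_set) == 0) stop("empty node set", call. = FALSE)
  stopifnot(all(node_set %in% igraph::V(ppi)$name))
  deg <- igraph::degree(ppi, v = node_set)
  ks <- seq_len(k_max)
  stats::setNames(vapply(ks, function(k) 100 * mean(deg >= k), numeric(1)),
                  ks)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Tests whether two samples share a common location.  For combined sample
#' sizes up to 10 without ties the null distribution of the rank sum is
#' enumerated exactly; otherwise the normal approximation with tie
#' correction and continuity correction is used (the convention of the
#' classic numerical-computing `ranksum` routine).
#'
#' @param x,y Nonempty numeric samples.
#' @return Two-sided p-value in (0, 1\].
#' @export
ranksum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must be nonempty", call. = FALSE)
  m <- length(x); n <- length(y); N <- m + n
  v <- c(x, y)
  r <- rank(v)
  w <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  has_ties <- anyDuplicated(v) > 0
  if (N <= 10 && !has_ties) {
    ws <- colSums(utils::combn(N, m))  # ranks are a permutation of 1..N
    return(mean(abs(ws - mu) >= abs(w - mu) - 1e-12))
  }
  tt <- table(v)
  tie_term <- sum(tt^3 - tt) / (N * (N - 1))
  sig2 <- m * n / 12 * (N + 1 - tie_term)
  if (sig2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}
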