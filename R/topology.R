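#' Normalized degree distribution
#'
#' Counts nodes at each observed degree and normalizes to probabilities.
#' Isolated nodes contribute mass at k = 0; they are retained here but
#' excluded from log-log power-law fitting, which only uses k >= 1.
#'
#' @param graph An igraph object, nonempty.
#' @return data.frame of class `"degree_distribution"` with columns `k`
#'   (degrees with at least one node) and `pk` (probabilities summing to 1).
#' @export
degree_distribution <- function(graph) {
  if (igraph::vcount(graph) == 0)
    stop("degree distribution of an empty graph is undefined", call. = FALSE)
  tab <- table(igraph::degree(graph))
  out <- data.frame(k = as.integer(names(tab)),
                    pk = as.numeric(tab) / igraph::vcount(graph))
  class(out) <- c("degree_distribution", "data.frame")
  out
}

#' Fit a power law to a degree distribution by log-log regression
#'
#' Ordinary least squares of `log10 P(k)` on `log10 k` over support points
#' with k >= 1 — the fit behind the usual "scale-free" diagnostic, matching
#' how network-analysis GUIs report an exponent with a fitting correlation
#' and an R-squared.  If `outlier_sigma` is given, points whose standardized
#' residual exceeds it in absolute value are removed once and the line is
#' refit.  Maximum-likelihood (Clauset-style) fitting is deliberately not
#' offered here; this function reproduces the regression-based convention.
#'
#' @param dist A [degree_distribution()].
#' @param outlier_sigma Optional positive number; one round of residual
#'   trimming at this many standard deviations.
#' @return List of class `"power_law_fit"`: `exponent` (the slope),
#'   `intercept`, `pearson_r` of the fitted log-log points, `r_squared`,
#'   `n_points`.
#' @export
fit_power_law <- function(dist, outlier_sigma = NULL) {
  pts <- dist[dist$k >= 1, , drop = FALSE]
  if (nrow(pts) < 3)
    stop("need at least 3 support points with k >= 1", call. = FALSE)
  lk <- log10(pts$k); lp <- log10(pts$pk)
  fit <- stats::lm(lp ~ lk)
  if (!is.null(outlier_sigma)) {
    keep <- abs(stats::rstandard(fit)) <= outlier_sigma
    if (sum(keep) >= 3 && any(!keep)) {
      lk <- lk[keep]; lp <- lp[keep]
      fit <- stats::lm(lp ~ lk)
    }
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((lp - mean(lp))^2)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = stats::cor(lk, lp),
                 r_squared = 1 - ss_res / ss_tot,
                 n_points = length(lk)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: exponent %.4f, r = %.3f, R^2 = %.3f (%d points)\n",
              x$exponent, x$pearson_r, x$r_squared, x$n_points))
  invisible(x)
}

#' Clustering-coefficient profile of a network
#'
#' The local clustering coefficient C_i = 2 n_i / \[k_i (k_i - 1)\], where
#' k_i is the degree of node i and n_i the number of links among its
#' neighbors; C_i = 1 marks the center of a clique.  Nodes with degree <= 1
#' get C_i = 0 by convention and are excluded from the by-degree means
#' (which would otherwise be 0/0).  A degree-independent C(k) profile is the
#' signature of a non-hierarchical network; C(k) ~ 1/k of a hierarchical
#' one.
#'
#' @param graph An igraph object, nonempty.
#' @return List of class `"clustering_profile"`: `per_node` (named numeric),
#'   `by_degree` (data.frame `k`, `mean_c` over nodes of degree >= 2),
#'   `overall_mean`, `overall_sd` (over all nodes).
#' @export
clustering_profile <- function(graph) {
  if (igraph::vcount(graph) == 0)
    stop("clustering profile of an empty graph is undefined", call. = FALSE)
  ci <- igraph::transitivity(graph, type = "local", isolates = "zero")
  names(ci) <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  eligible <- deg >= 2
  by_degree <- if (any(eligible)) {
    agg <- tapply(ci[eligible], deg[eligible], mean)
    data.frame(k = as.integer(names(agg)), mean_c = as.numeric(agg))
  } else data.frame(k = integer(), mean_c = numeric())
  structure(list(per_node = ci,
                 by_degree = by_degree,
                 overall_mean = mean(ci),
                 overall_sd = stats::sd(ci)),
            class = "clustering_profile")
}

#' Network diameter
#'
#' Maximum shortest-path distance, computed on the largest connected
#' component when the graph is disconnected (so the value is always
#' finite).  Used as the upper summation limit of the characteristic
#' distance field.
#'
#' @param graph An igraph object, nonempty.
#' @return Integer diameter.
#' @export
net_diameter <- function(graph) {
  if (igraph::vcount(graph) == 0)
    stop("diameter of an empty graph is undefined", call. = FALSE)
  comp <- igraph::components(graph)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(graph, which(comp$membership == big))
  as.integer(igraph::diameter(sub, unconnected = FALSE, weights = NA))
}
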