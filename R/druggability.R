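#' Distance profile of a charged marker set around a target
#'
#' Treating each member of `charged` (e.g. every essential gene) as a unit
#' charge, records the fraction f(d) of the charged set at each shortest
#' distance d >= 1 from `target`.  The target itself, if charged, is
#' excluded from both numerator and denominator; unreachable members stay in
#' the denominator (they weaken the field) unless `reachable_only = TRUE`.
#'
#' @param ppi igraph network.
#' @param target Vertex name.
#' @param charged Nonempty character vector of charged vertex names.
#' @param reachable_only Normalize over reachable members only.
#' @return List of class `"distance_profile"`: `f` (named fractions by
#'   distance), `charged_set_size` (after self-exclusion),
#'   `reachable_fraction`.
#' @export
charge_profile <- function(ppi, target, charged, reachable_only = FALSE) {
  if (!(target %in% igraph::V(ppi)$name))
    stop("unknown target node: ", target, call. = FALSE)
  charged <- setdiff(unique(charged), target)
  if (length(charged) == 0)
    stop("charged set empty after excluding the target itself",
         call. = FALSE)
  stopifnot(all(charged %in% igraph::V(ppi)$name))
  d <- igraph::distances(ppi, v = target, to = charged, weights = NA)[1, ]
  reach <- is.finite(d)
  denom <- if (reachable_only) sum(reach) else length(charged)
  f <- if (any(reach)) {
    tab <- table(d[reach])
    stats::setNames(as.numeric(tab) / denom, names(tab))
  } else stats::setNames(numeric(), character())
  structure(list(f = f,
                 charged_set_size = length(charged),
                 reachable_fraction = mean(reach)),
            class = "distance_profile")
}

#' Characteristic distance from a distance profile
#'
#' Coulomb-law summary of proximity to a charged set: each charge at
#' distance d contributes field strength 1/d^2, the fractions accumulate
#' into E = sum_d f(d)/d^2, and the characteristic distance is
#' d-hat = E^(-1/2) — the distance at which a single unit charge would
#' produce the same field.  If the whole set sits at distance k, d-hat = k
#' exactly; d-hat < 1 requires strong concentration at distance 1.  An
#' empty profile (nothing reachable) gives +Inf.
#'
#' This closed form is a reconstruction: it realizes the stated unit-charge
#' inverse-square mechanism and its published boundary behavior, but the
#' original display equation is not preserved in the source text.
#'
#' @param profile A [charge_profile()] result, or a bare named numeric
#'   vector of fractions keyed by distance.
#' @return A single positive number (possibly `Inf`).
#' @export
characteristic_distance <- function(profile) {
  f <- if (inherits(profile, "distance_profile")) profile$f else profile
  if (length(f) == 0) return(Inf)
  d <- as.numeric(names(f))
  stopifnot(all(d >= 1), all(f >= 0))
  E <- sum(f / d^2)
  if (E == 0) Inf else E^(-1 / 2)
}

#' Characteristic distances of many targets to a charged set
#'
#' Vectorized convenience: one BFS sweep gives d-hat for every target.
#'
#' @param ppi igraph network.
#' @param targets Character vector of target vertex names.
#' @param charged Nonempty character vector of charged vertex names.
#' @param reachable_only Passed to the profile normalization.
#' @return Named numeric vector of d-hat values.
#' @export
characteristic_distances <- function(ppi, targets, charged,
                                     reachable_only = FALSE) {
  if (length(targets) == 0) return(stats::setNames(numeric(), character()))
  charged <- unique(charged)
  D <- igraph::distances(ppi, v = targets, to = charged, weights = NA)
  self <- outer(targets, charged, "==")
  vals <- vapply(seq_along(targets), function(i) {
    d <- D[i, !self[i, ]]
    reach <- is.finite(d) & d >= 1
    denom <- if (reachable_only) sum(reach) else length(d)
    if (denom == 0 || !any(reach)) return(Inf)
    E <- sum(1 / d[reach]^2) / denom
    if (E == 0) Inf else E^(-1 / 2)
  }, numeric(1))
  stats::setNames(vals, targets)
}

#' Bin-and-rank prioritization of bioassay targets
#'
#' The candidate drug-target ranking: (1) drop genes in `exclude`
#' (typically the approved drug targets themselves); (2) drop genes with
#' network degree below `min_degree`; (3) bin the characteristic distance
#' to essential genes into left-closed intervals of width `bin_width`
#' (`[1.0, 1.5)`, `[1.5, 2.0)`, ...), traversed in ascending order — closer
#' to the essential-gene field first; (4) within each bin rank by the
#' characteristic distance to drug targets, descending — farther from
#' already-drugged space first, i.e. more novel; ties broken by gene symbol.
#'
#' @param rows data.frame with columns `gene`, `d_essential`, `d_drug`,
#'   `degree`.
#' @param bin_width Width of the `d_essential` bins (default 0.5).
#' @param min_degree Minimum network degree retained (default 17, inclusive).
#' @param exclude Character vector of genes to remove before ranking.
#' @return data.frame with columns `gene`, `d_essential`, `d_drug`,
#'   `degree`, `bin_index`, `rank`, ordered by rank.
#' @export
prioritize <- function(rows, bin_width = 0.5, min_degree = 17,
                       exclude = character()) {
  stopifnot(bin_width > 0,
            all(c("gene", "d_essential", "d_drug", "degree") %in%
                  names(rows)))
  rows <- rows[!(rows$gene %in% exclude) & rows$degree >= min_degree, ,
               drop = FALSE]
  rows$bin_index <- floor(rows$d_essential / bin_width)
  ord <- order(rows$bin_index, -rows$d_drug, rows$gene)
  rows <- rows[ord, c("gene", "d_essential", "d_drug", "degree",
                      "bin_index")]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}
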