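#' Configuration for the synthetic screening-data generator
#'
#' Bundles and validates every knob of the synthetic-data generators:
#' a preferential-attachment protein-protein interaction (PPI) network,
#' marker sets with a planted proximity signal, and a clustered
#' bioassay-compound activity table.  The defaults are a desk-scale model of
#' a public screening snapshot: a 2,000-protein interactome whose marker-set
#' sizes keep the proportions of the curated sets typically mapped onto the
#' human interactome (roughly 12% essential genes, 6% approved drug targets,
#' 8% disease genes, 1% bioassay targets).
#'
#' @param n_proteins Number of proteins in the synthetic PPI network.
#' @param attach_m Edges added per new node during preferential attachment;
#'   controls density and the heaviness of the degree tail.
#' @param n_essential,n_drug_targets,n_disease,n_bioassay_targets Marker-set
#'   sizes (non-negative; essential + drug targets must fit in the network).
#'   When `NULL` (the default) they scale with `n_proteins` at the published
#'   proportions above, giving 244 / 127 / 169 / 22 at the default size.
#' @param proximity_rho Relative odds (>= 1) that a bioassay target is drawn
#'   from the distance-<=1 neighborhood of essential genes rather than
#'   uniformly; `1` is the uniform null, larger values plant the proximity
#'   enrichment the downstream tests look for.
#' @param n_assays,n_compounds,n_clusters Activity-table dimensions; assays
#'   and compounds are assigned round-robin to `n_clusters` screening
#'   clusters.
#' @param p_in,p_out Activity probability for a (assay, compound) pair in the
#'   same / a different cluster; `p_out < p_in <= 1`.
#' @param frac_target_based Fraction of assays annotated as target-based
#'   (the rest are cell-based).
#' @param rng_seed Integer seed; identical seeds give bitwise-identical
#'   output from every generator.
#'
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_proteins = 2000, attach_m = 3,
                             n_essential = NULL, n_drug_targets = NULL,
                             n_disease = NULL, n_bioassay_targets = NULL,
                             proximity_rho = 10,
                             n_assays = 50, n_compounds = 500, n_clusters = 5,
                             p_in = 0.3, p_out = 0.005,
                             frac_target_based = 0.5,
                             rng_seed = 1L) {
  # marker-set sizes default to the proportions of the curated human sets
  # (2,564 essential / 1,339 drug targets / 1,777 disease genes / 228
  # bioassay targets among 21,051 interactome proteins)
  n_proteins <- as.integer(n_proteins)
  if (is.null(n_essential)) n_essential <- round(n_proteins * 2564 / 21051)
  if (is.null(n_drug_targets))
    n_drug_targets <- round(n_proteins * 1339 / 21051)
  if (is.null(n_disease)) n_disease <- round(n_proteins * 1777 / 21051)
  if (is.null(n_bioassay_targets))
    n_bioassay_targets <- round(n_proteins * 228 / 21051)
  cfg <- list(n_proteins = as.integer(n_proteins),
              attach_m = as.integer(attach_m),
              n_essential = as.integer(n_essential),
              n_drug_targets = as.integer(n_drug_targets),
              n_disease = as.integer(n_disease),
              n_bioassay_targets = as.integer(n_bioassay_targets),
              proximity_rho = proximity_rho,
              n_assays = as.integer(n_assays),
              n_compounds = as.integer(n_compounds),
              n_clusters = as.integer(n_clusters),
              p_in = p_in, p_out = p_out,
              frac_target_based = frac_target_based,
              rng_seed = as.integer(rng_seed))
  if (cfg$n_proteins <= cfg$attach_m || cfg$attach_m < 1L)
    stop("need n_proteins > attach_m >= 1", call. = FALSE)
  if (min(cfg$n_assays, cfg$n_compounds, cfg$n_clusters) < 1L)
    stop("activity-table dimensions must be positive", call. = FALSE)
  if (min(cfg$n_essential, cfg$n_drug_targets, cfg$n_disease,
          cfg$n_bioassay_targets) < 0L)
    stop("marker-set sizes must be non-negative", call. = FALSE)
  if (cfg$n_essential + cfg$n_drug_targets > cfg$n_proteins)
    stop("n_essential + n_drug_targets exceeds n_proteins", call. = FALSE)
  if (cfg$proximity_rho < 1)
    stop("proximity_rho must be >= 1", call. = FALSE)
  if (!(cfg$p_out >= 0 && cfg$p_out < cfg$p_in && cfg$p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
  if (cfg$frac_target_based < 0 || cfg$frac_target_based > 1)
    stop("frac_target_based must be in [0, 1]", call. = FALSE)
  if (cfg$n_clusters > cfg$n_assays)
    stop("n_clusters must not exceed n_assays", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic protein-protein interaction network
#'
#' Grows an undirected, simple, connected graph by Barabasi-Albert
#' preferential attachment, the classic generator of heavy-tailed
#' (scale-free) degree sequences.  Nodes carry synthetic gene symbols
#' `"G000001"`, `"G000002"`, ... so that lexicographic tie-breaks downstream
#' are stable.
#'
#' @param n_proteins Number of nodes (> `attach_m`).
#' @param attach_m Edges attached by each incoming node (>= 1).
#' @param rng_seed Integer seed; the generator is a pure function of its
#'   arguments.
#'
#' @return An [igraph::igraph] object with `n_proteins` named vertices.
#' @export
gen_ppi <- function(n_proteins, attach_m, rng_seed = 1L) {
  if (attach_m < 1L || n_proteins <= attach_m)
    stop("need n_proteins > attach_m >= 1", call. = FALSE)
  g <- withr::with_seed(as.integer(rng_seed),
    igraph::sample_pa(n_proteins, power = 1, m = attach_m,
                      directed = FALSE))
  igraph::V(g)$name <- synthetic_symbols(n_proteins)
  g
}

synthetic_symbols <- function(n) sprintf("G%06d", seq_len(n))

#' Generate marker sets with a planted proximity signal
#'
#' Draws the four node subsets used throughout the analysis from a PPI
#' network.  Essential genes are sampled with degree-proportional bias
#' (mirroring the empirical association between hubs and knockout
#' lethality); drug targets and disease genes are uniform; bioassay targets
#' are sampled with odds multiplied by `proximity_rho` when they lie within
#' distance 1 of an essential gene, which plants the proximity enrichment
#' the [enrichment()] analysis is designed to detect.  By default bioassay
#' targets are disjoint from drug targets, because the prioritization ranks
#' bioassay targets that are not already drugged.
#'
#' @param ppi An igraph PPI network (named vertices).
#' @param cfg A [synthetic_config()].
#' @param allow_drug_overlap If `TRUE`, bioassay targets may also be drug
#'   targets.
#'
#' @return A list of class `"marker_sets"` with character vectors
#'   `essential`, `drug_targets`, `disease_genes`, `bioassay_targets`.
#' @export
gen_markers <- function(ppi, cfg, allow_drug_overlap = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nodes <- igraph::V(ppi)$name
  n <- length(nodes)
  if (cfg$n_essential > n || cfg$n_drug_targets > n || cfg$n_disease > n)
    stop("requested marker set larger than the network", call. = FALSE)
  withr::with_seed(cfg$rng_seed, {
    deg <- igraph::degree(ppi)
    essential <- if (cfg$n_essential > 0L)
      sample(nodes, cfg$n_essential, prob = deg) else character()
    drug_targets <- if (cfg$n_drug_targets > 0L)
      sample(nodes, cfg$n_drug_targets) else character()
    disease_genes <- if (cfg$n_disease > 0L)
      sample(nodes, cfg$n_disease) else character()

    pool <- if (allow_drug_overlap) nodes else setdiff(nodes, drug_targets)
    if (cfg$n_bioassay_targets > length(pool))
      stop("requested bioassay-target set larger than the eligible pool",
           call. = FALSE)
    bioassay_targets <- if (cfg$n_bioassay_targets > 0L) {
      near <- union(essential,
                    nodes[unique(unlist(igraph::adjacent_vertices(
                      ppi, essential)))])
      w <- ifelse(pool %in% near, cfg$proximity_rho, 1)
      sample(pool, cfg$n_bioassay_targets, prob = w)
    } else character()
  })
  structure(list(essential = essential,
                 drug_targets = drug_targets,
                 disease_genes = disease_genes,
                 bioassay_targets = bioassay_targets),
            class = "marker_sets")
}

#' Generate a clustered synthetic activity table
#'
#' Emulates a sparse screening campaign with community structure: assays and
#' compounds are assigned round-robin to `n_clusters` clusters and a pair
#' (assay, compound) is active with probability `p_in` within the same
#' cluster and `p_out` otherwise.  The Jaccard projection of such a table
#' recovers the clusters, mirroring real screening data where assays with
#' the same purpose share active compounds.  A `frac_target_based` fraction
#' of assays is annotated target-based, with target symbols drawn from
#' `markers$bioassay_targets` when marker sets are supplied.
#'
#' @param cfg A [synthetic_config()].
#' @param markers Optional [gen_markers()] output supplying bioassay-target
#'   symbols for the assay metadata.
#'
#' @return An [activity_table()].
#' @export
gen_activity <- function(cfg, markers = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  assay_ids <- sprintf("A%04d", seq_len(cfg$n_assays))
  compound_ids <- sprintf("C%06d", seq_len(cfg$n_compounds))
  assay_cluster <- rep_len(seq_len(cfg$n_clusters), cfg$n_assays)
  compound_cluster <- rep_len(seq_len(cfg$n_clusters), cfg$n_compounds)

  withr::with_seed(cfg$rng_seed, {
    same <- outer(assay_cluster, compound_cluster, "==")
    p <- ifelse(same, cfg$p_in, cfg$p_out)
    hit <- matrix(stats::runif(length(p)) < p, nrow = cfg$n_assays)
    idx <- which(hit, arr.ind = TRUE)
    pairs <- data.frame(assay_id = assay_ids[idx[, 1]],
                        compound_id = compound_ids[idx[, 2]],
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$assay_id, pairs$compound_id), , drop = FALSE]
    rownames(pairs) <- NULL

    n_tb <- round(cfg$frac_target_based * cfg$n_assays)
    target_based <- assay_ids %in% sample(assay_ids, n_tb)
    symbol_pool <- if (!is.null(markers) &&
                       length(markers$bioassay_targets) > 0)
      markers$bioassay_targets else synthetic_symbols(cfg$n_proteins)
    target_symbol <- rep(NA_character_, cfg$n_assays)
    target_symbol[target_based] <- sample(symbol_pool, n_tb, replace = TRUE)
  })
  meta <- data.frame(assay_id = assay_ids,
                     assay_type = ifelse(target_based, "target_based",
                                         "cell_based"),
                     target_symbol = target_symbol,
                     cluster = assay_cluster,
                     stringsAsFactors = FALSE)
  activity_table(pairs, meta)
}
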