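test_that("synthetic_config validates its invariants", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_proteins = 3, attach_m = 3), "attach_m")
  expect_error(synthetic_config(p_in = 0.1, p_out = 0.2), "p_out")
  expect_error(synthetic_config(n_essential = 1900, n_drug_targets = 200),
               "exceeds")
  expect_error(synthetic_config(proximity_rho = 0.5), "proximity_rho")
  expect_error(synthetic_config(n_clusters = 60, n_assays = 50),
               "n_clusters")
})

test_that("gen_ppi builds a connected simple named graph, deterministically", {
  g1 <- gen_ppi(100, 2, rng_seed = 1)
  g2 <- gen_ppi(100, 2, rng_seed = 1)
  expect_equal(igraph::vcount(g1), 100)
  expect_true(igraph::is_connected(g1))
  expect_true(igraph::is_simple(g1))
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  g3 <- gen_ppi(100, 2, rng_seed = 2)
  expect_false(identical(igraph::as_edgelist(g1), igraph::as_edgelist(g3)))
  expect_error(gen_ppi(5, 5), "attach_m")
})

test_that("preferential attachment yields a heavy-tailed degree slope", {
  g <- gen_ppi(2000, 3, rng_seed = 7)
  fit <- fit_power_law(degree_distribution(g))
  expect_gt(fit$exponent, -3.5)
  expect_lt(fit$exponent, -1.5)
})

test_that("gen_markers plants proximity enrichment and honors set rules", {
  cfg <- synthetic_config(rng_seed = 11)
  g <- gen_ppi(cfg$n_proteins, cfg$attach_m, cfg$rng_seed)
  m <- gen_markers(g, cfg)
  expect_length(m$essential, cfg$n_essential)
  expect_length(m$bioassay_targets, cfg$n_bioassay_targets)
  expect_length(intersect(m$bioassay_targets, m$drug_targets), 0)
  expect_true(all(unlist(m) %in% igraph::V(g)$name))

  # degree bias of essential genes: mean degree well above the network mean
  expect_gt(mean(igraph::degree(g, m$essential)),
            mean(igraph::degree(g)))

  # degenerate: zero-size set allowed
  m0 <- gen_markers(g, synthetic_config(n_bioassay_targets = 0))
  expect_length(m0$bioassay_targets, 0)

  # oversized request errors
  expect_error(gen_markers(gen_ppi(50, 2), synthetic_config(n_essential = 99)),
               "larger")
})

test_that("rho > 1 concentrates bioassay targets near essential genes", {
  g <- gen_ppi(2000, 3, rng_seed = 5)
  near_frac <- function(cfg) {
    m <- gen_markers(g, cfg)
    near <- union(m$essential,
                  igraph::V(g)$name[unique(unlist(
                    igraph::adjacent_vertices(g, m$essential)))])
    mean(m$bioassay_targets %in% near)
  }
  wins <- vapply(1:40, function(i) {
    f10 <- near_frac(synthetic_config(proximity_rho = 10,
                                      rng_seed = 100 + i))
    f1 <- near_frac(synthetic_config(proximity_rho = 1,
                                     rng_seed = 100 + i))
    f10 > f1
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("rho = 1 matches the uniform null on adjacency fractions", {
  g <- gen_ppi(1000, 3, rng_seed = 2)
  nodes <- igraph::V(g)$name
  n_bt <- synthetic_config(n_proteins = 1000)$n_bioassay_targets
  fr <- vapply(1:50, function(i) {
    cfg <- synthetic_config(n_proteins = 1000, proximity_rho = 1,
                            rng_seed = 300 + i)
    m <- gen_markers(g, cfg)
    near <- union(m$essential,
                  nodes[unique(unlist(
                    igraph::adjacent_vertices(g, m$essential)))])
    c(obs = mean(m$bioassay_targets %in% near),
      exp = length(setdiff(near, m$drug_targets)) /
        length(setdiff(nodes, m$drug_targets)))
  }, numeric(2))
  n_draws <- 50 * n_bt
  p <- mean(fr["exp", ])
  se <- sqrt(p * (1 - p) / n_draws)
  expect_lt(abs(mean(fr["obs", ]) - p), 3 * se)
})

test_that("gen_activity respects cluster structure and probabilities", {
  cfg <- synthetic_config(n_assays = 50, n_compounds = 500, n_clusters = 5,
                          p_in = 0.3, p_out = 0.005, rng_seed = 3)
  tab <- gen_activity(cfg)
  expect_s3_class(tab, "activity_table")
  # determinism
  tab2 <- gen_activity(cfg)
  expect_identical(tab, tab2)

  # within-cluster mean Jaccard exceeds between-cluster
  sets <- split(tab$pairs$compound_id, tab$pairs$assay_id)
  cl <- tab$assay_meta$cluster[match(names(sets), tab$assay_meta$assay_id)]
  ids <- names(sets)
  jw <- jb <- c()
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    jac <- jaccard(sets[[i]], sets[[j]])
    if (cl[i] == cl[j]) jw <- c(jw, jac) else jb <- c(jb, jac)
  }
  expect_gt(mean(jw), mean(jb))

  # p_in=1, p_out=0 with 2 clusters: projection = exactly 2 components
  cfg2 <- synthetic_config(n_assays = 10, n_compounds = 40, n_clusters = 2,
                           p_in = 1, p_out = 0, rng_seed = 1)
  g <- project(build_bipartite(gen_activity(cfg2)), min_jaccard = 0.5)
  expect_equal(igraph::count_components(g), 2)

  # p_in ~ 0, p_out = 0: no active pairs
  cfg3 <- synthetic_config(p_in = 1e-9, p_out = 0, n_assays = 5,
                           n_compounds = 10, n_clusters = 2, rng_seed = 1)
  expect_equal(nrow(gen_activity(cfg3)$pairs), 0)
})
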