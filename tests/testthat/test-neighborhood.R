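test_that("map_symbols reports unmapped symbols in order", {
  g <- igraph::make_graph(~ TP53 - MDM2 - EGFR)
  r <- map_symbols(c("TP53", "nope1", "EGFR", "nope2", "tp53"), g)
  expect_setequal(r$mapped, c("TP53", "EGFR"))
  expect_identical(r$unmapped, c("nope1", "nope2", "tp53"))
  expect_identical(map_symbols(character(), g),
                   list(mapped = character(), unmapped = character()))
})

test_that("bfs_distances gives shortest paths, dropping unreachable nodes", {
  g <- igraph::make_graph(~ a - b - c)
  expect_equal(bfs_distances(g, "a"), c(a = 0L, b = 1L, c = 2L))
  iso <- g + igraph::vertices("z")
  expect_equal(bfs_distances(iso, "z"), c(z = 0L))
  expect_error(bfs_distances(g, "missing"), "unknown source")
})

test_that("bfs matches Floyd-Warshall on random graphs", {
  set.seed(53)
  for (trial in 1:40) {
    g <- random_test_graph(sample(8:50, 1), stats::runif(1, 0.05, 0.3))
    D <- fw_distances(g)
    src <- sample(igraph::V(g)$name, 1)
    row <- D[src, ]
    row <- row[is.finite(row)]
    got <- bfs_distances(g, src)
    expect_equal(got[order(names(got))],
                 as.integer(row)[order(names(row))],
                 ignore_attr = TRUE)
    expect_setequal(names(got), names(row))
  }
})

test_that("fraction_profile counts markers per distance shell", {
  star <- igraph::make_star(9, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:8))
  fp <- fraction_profile(star, "hub", paste0("leaf", 1:3))
  expect_equal(fp, c("1" = 0.375))

  g <- igraph::make_graph(~ a - b - c - d)
  expect_equal(fraction_profile(g, "a", c("a", "b", "c", "d")),
               c("1" = 1, "2" = 1, "3" = 1))  # self excluded at d = 0
  expect_equal(fraction_profile(g, "a", character()),
               c("1" = 0, "2" = 0, "3" = 0))
})

test_that("shell counts partition the reachable nodes", {
  set.seed(61)
  for (trial in 1:20) {
    g <- random_test_graph(sample(10:40, 1), stats::runif(1, 0.08, 0.3))
    src <- sample(igraph::V(g)$name, 1)
    d <- bfs_distances(g, src)
    expect_equal(sum(table(d[d >= 1])), length(d) - 1)
    fp <- fraction_profile(g, src, sample(igraph::V(g)$name, 5))
    expect_true(all(fp >= 0 & fp <= 1))
  }
})

test_that("enrichment validates inputs and reports coherent fields", {
  g <- gen_ppi(300, 2, rng_seed = 9)
  nodes <- igraph::V(g)$name
  expect_error(enrichment(g, character(), nodes[1:5]), "seeds")
  expect_error(enrichment(g, nodes[1:5], character()), "markers")

  er <- enrichment(g, nodes[1:20], nodes[50:80], n_random = 200,
                   rng_seed = 4)
  expect_true(all(er$mean_fraction >= 0 & er$mean_fraction <= 1,
                  na.rm = TRUE))
  expect_true(all(er$p_value > 0 & er$p_value <= 1, na.rm = TRUE))
  expect_equal(er$n_seeds, 20)
  # seedable determinism
  er2 <- enrichment(g, nodes[1:20], nodes[50:80], n_random = 200,
                    rng_seed = 4)
  expect_identical(er$p_value, er2$p_value)
})

test_that("uniform-marker mean fractions concentrate on the global rate", {
  g <- gen_ppi(800, 3, rng_seed = 15)
  nodes <- igraph::V(g)$name
  set.seed(73)
  markers <- sample(nodes, 120)
  rate <- length(markers) / length(nodes)
  dev <- function(n_seeds) {
    seeds <- sample(nodes, n_seeds)
    er <- enrichment(g, seeds, markers, n_random = 50, rng_seed = 1)
    abs(er$mean_fraction[1] - rate)
  }
  few <- mean(replicate(20, dev(5)))
  many <- mean(replicate(20, dev(80)))
  expect_lt(many, few)
})

test_that("degree_cdf is a non-increasing percentage curve", {
  g <- igraph::graph_from_literal(a - b, b - c, c - d, b - d)  # degrees 1,3,2,2
  cdf <- degree_cdf(g, c("a", "b", "c"), k_max = 4)  # degrees 1, 3, 2
  expect_equal(unname(cdf), c(100, 200 / 3, 100 / 3, 0))
  expect_true(all(diff(cdf) <= 0))
  expect_error(degree_cdf(g, character()), "empty")

  set.seed(83)
  for (trial in 1:10) {
    gg <- random_test_graph(30, 0.15)
    cc <- degree_cdf(gg, sample(igraph::V(gg)$name, 10), k_max = 20)
    expect_true(all(diff(cc) <= 0))
  }
})

test_that("ranksum matches the stated exact and asymptotic behavior", {
  expect_equal(ranksum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(ranksum(c(5, 5, 5), c(5, 5, 5)), 1)
  set.seed(97)
  x <- stats::rnorm(200)
  expect_lt(ranksum(x, x + 2), 1e-10)
})

test_that("ranksum agrees with exact enumeration for all 4+4 partitions", {
  vals <- c(1.3, 2.1, 3.7, 4.2, 5.9, 6.4, 7.8, 8.1)
  picks <- utils::combn(8, 4)
  for (i in seq_len(ncol(picks))) {
    x <- vals[picks[, i]]
    y <- vals[-picks[, i]]
    expect_equal(ranksum(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("ranksum tracks the tie-corrected normal approximation", {
  set.seed(101)
  for (trial in 1:30) {
    x <- sample(1:6, sample(8:25, 1), replace = TRUE)
    y <- sample(1:7, sample(8:25, 1), replace = TRUE)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(ranksum(x, y), ref, tolerance = 1e-10)
  }
})
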