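test_that("charge_profile counts shells with self-exclusion", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  p <- charge_profile(star, "hub", paste0("leaf", 1:4))
  expect_equal(p$f, c("1" = 1))
  expect_equal(p$charged_set_size, 4)
  expect_equal(p$reachable_fraction, 1)

  path <- igraph::make_graph(~ a - b - c - d)
  p <- charge_profile(path, "a", c("b", "d"))
  expect_equal(p$f, c("1" = 0.5, "3" = 0.5))

  # target inside the charged set: excluded from both sides
  p <- charge_profile(path, "a", c("a", "b"))
  expect_equal(p$f, c("1" = 1))
  expect_equal(p$charged_set_size, 1)
  expect_error(charge_profile(path, "a", "a"), "empty")
})

test_that("unreachable charge weakens the field unless reachable_only", {
  g <- igraph::graph_from_literal(a - b, x - y)
  p <- charge_profile(g, "a", c("b", "y"))
  expect_equal(p$f, c("1" = 0.5))
  expect_equal(p$reachable_fraction, 0.5)
  expect_equal(characteristic_distance(p), sqrt(2))
  p2 <- charge_profile(g, "a", c("b", "y"), reachable_only = TRUE)
  expect_equal(p2$f, c("1" = 1))
  expect_equal(characteristic_distance(p2), 1)
})

test_that("characteristic distance obeys its closed forms", {
  # single shell at k gives exactly k
  for (k in 1:8)
    expect_equal(characteristic_distance(
      stats::setNames(1, as.character(k))), k)
  # direct evaluation: f = {1: .5, 2: .5} -> E = .625
  expect_equal(characteristic_distance(c("1" = 0.5, "2" = 0.5)),
               0.625^(-0.5))
  # empty profile -> infinite distance
  expect_equal(characteristic_distance(stats::setNames(
    numeric(), character())), Inf)
})

test_that("moving charge inward strictly decreases d-hat", {
  set.seed(107)
  for (trial in 1:30) {
    d <- sort(sample(1:10, 4))
    f <- as.numeric(stats::runif(4)); f <- f / sum(f)
    base <- stats::setNames(f, d)
    j <- sample(2:4, 1); i <- sample(seq_len(j - 1), 1)
    eps <- f[j] * stats::runif(1, 0.1, 0.9)
    shifted <- f
    shifted[j] <- shifted[j] - eps
    shifted[i] <- shifted[i] + eps
    expect_lt(characteristic_distance(stats::setNames(shifted, d)),
              characteristic_distance(base))
  }
})

test_that("d-hat depends only on the normalized profile", {
  f <- c("1" = 0.25, "2" = 0.5, "4" = 0.25)
  expect_equal(characteristic_distance(f),
               characteristic_distance(f))  # trivially stable
  # the same shape from charged sets of different sizes
  path <- igraph::make_graph(~ a - b - c - d - e)
  small <- charge_profile(path, "a", c("b", "c"))
  # duplicate every charge at the same distances in a bigger graph
  g2 <- igraph::graph_from_literal(a - b1, a - b2, b1 - c1, b2 - c2)
  big <- charge_profile(g2, "a", c("b1", "b2", "c1", "c2"))
  expect_equal(characteristic_distance(small),
               characteristic_distance(big))
})

test_that("vectorized characteristic distances agree with the profile route", {
  g <- gen_ppi(200, 2, rng_seed = 19)
  nodes <- igraph::V(g)$name
  set.seed(109)
  charged <- sample(nodes, 30)
  targets <- sample(nodes, 15)
  got <- characteristic_distances(g, targets, charged)
  for (t in targets)
    expect_equal(unname(got[t]),
                 characteristic_distance(charge_profile(g, t, charged)))
})

test_that("prioritize reproduces the published top-10 ordering", {
  rows <- published_target_distances()
  ranked <- prioritize(rows, bin_width = 0.5, min_degree = 17)
  expect_identical(ranked$gene,
                   c("SULT1E1", "WEE1", "RGS7", "SMN2", "RNGTT", "STK16",
                     "PAK7", "NEK2", "YWHAG", "MAPK10"))
  expect_identical(ranked$rank, 1:10)
  # bins: [1.0,1.5) then [1.5,2.0)
  expect_identical(ranked$bin_index, c(rep(2, 3), rep(3, 7)))
})

test_that("prioritize applies tie-breaks, exclusions and the degree floor", {
  rows <- data.frame(gene = c("B", "A", "C"),
                     d_essential = 1.2, d_drug = 3.0,
                     degree = c(20, 20, 20))
  expect_identical(prioritize(rows)$gene, c("A", "B", "C"))

  rows2 <- data.frame(gene = c("X", "Y"), d_essential = 1.2, d_drug = 3,
                      degree = c(17, 16))
  expect_identical(prioritize(rows2)$gene, "X")

  rows3 <- data.frame(gene = c("X", "Y"), d_essential = 1.2, d_drug = 3,
                      degree = 20)
  expect_identical(prioritize(rows3, exclude = "Y")$gene, "X")
})

test_that("prioritization is a permutation of the retained genes", {
  set.seed(113)
  rows <- data.frame(gene = sprintf("G%03d", 1:50),
                     d_essential = stats::runif(50, 0.5, 4),
                     d_drug = stats::runif(50, 1, 6),
                     degree = sample(1:100, 50, replace = TRUE))
  excl <- sample(rows$gene, 5)
  ranked <- prioritize(rows, min_degree = 10, exclude = excl)
  keep <- rows$gene[!(rows$gene %in% excl) & rows$degree >= 10]
  expect_setequal(ranked$gene, keep)
  expect_false(anyDuplicated(ranked$gene) > 0)
  expect_identical(ranked$rank, seq_len(nrow(ranked)))
  # within each bin, d_drug is non-increasing
  for (b in unique(ranked$bin_index)) {
    dd <- ranked$d_drug[ranked$bin_index == b]
    expect_true(all(diff(dd) <= 0))
  }
  # bins ascend
  expect_true(all(diff(ranked$bin_index) >= 0))
})
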