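test_that("fourfold correlation equals Pearson on binary vectors", {
  expect_equal(fourfold_correlation(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(fourfold_correlation(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  expect_equal(fourfold_correlation(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_error(fourfold_correlation(c(1, 0), c(1, 0, 1)), "equal length")
  expect_warning(z <- fourfold_correlation(c(1, 1, 1), c(1, 0, 1)), "constant")
  expect_equal(z, 0)

  # property: contingency formula == mean-centred Pearson, 1000 seeded pairs
  set.seed(42)
  for (k in 1:1000) {
    l <- sample(2:50, 1)
    x <- rbinom(l, 1, runif(1, 0.2, 0.8))
    y <- rbinom(l, 1, runif(1, 0.2, 0.8))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(fourfold_correlation(x, y), oracle_pearson(x, y),
                 tolerance = 1e-12)
  }
})

test_that("pairwise correlations enumerate and rank all pairs", {
  set.seed(5)
  inc <- matrix(rbinom(5 * 12, 1, 0.4), 5, 12,
                dimnames = list(paste0("J", 1:5), sprintf("p%02d", 1:12)))
  ds <- formula_dataset(inc)
  pairs <- pairwise_correlations(ds)
  expect_equal(nrow(pairs), choose(5, 2))
  # brute force over all pairs
  ids <- rownames(inc)
  for (r in seq_len(nrow(pairs))) {
    expect_equal(pairs$corr[r],
                 oracle_pearson(inc[pairs$i[r], ], inc[pairs$j[r], ]),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(pairs$corr) <= 1e-15))
  expect_true(all(pairs$i < pairs$j))

  inc2 <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                 dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(nrow(pairwise_correlations(formula_dataset(inc2))), 1L)
})

test_that("pair-count and top-fraction arithmetic match the published sizes", {
  expect_equal(n_formula_pairs(3138), 4921953)
  expect_equal(top_fraction_count(4921953, 0.007), 34454L)
  expect_equal(top_fraction_count(4921953, 0.005), 24610L)
  expect_equal(top_fraction_count(4921953, 0.003), 14766L)
  expect_error(top_fraction_count(10, 0), "fraction")
  expect_error(top_fraction_count(10, 1.2), "fraction")
})

test_that("top-fraction selection respects the ranking boundary", {
  sim <- generate_formulas(synthetic_spec(n_classes = 3, formulas_per_class = 8,
                                          n_background_plants = 20, seed = 11))
  pairs <- pairwise_correlations(sim$dataset)
  sel <- select_top_fraction(pairs, 0.05)
  expect_equal(nrow(sel), as.integer(round_half_up(0.05 * nrow(pairs))))
  expect_gte(min(sel$corr), max(pairs$corr[-seq_len(nrow(sel))]))
  expect_equal(attr(sel, "min_corr"), min(sel$corr))
  expect_identical(select_top_fraction(pairs, 1)$corr, pairs$corr)
})

test_that("network construction yields a simple graph over incident nodes", {
  tri <- data.frame(i = c("a", "b", "c"), j = c("b", "c", "a"))
  g <- build_network(tri)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)

  dup <- data.frame(i = c("a", "b", "a"), j = c("b", "a", "b"))
  g2 <- build_network(dup)
  expect_equal(igraph::ecount(g2), 1)

  sim <- generate_formulas(synthetic_spec(n_classes = 3, formulas_per_class = 8,
                                          n_background_plants = 20, seed = 2))
  sel <- select_top_fraction(pairwise_correlations(sim$dataset), 0.03)
  g3 <- build_network(sel)
  expect_setequal(igraph::V(g3)$name, unique(c(sel$i, sel$j)))
  expect_equal(sum(igraph::degree(g3)), 2 * igraph::ecount(g3))
})

test_that("network statistics match brute-force oracles on random graphs", {
  # hand-checked cases
  tri <- build_network(data.frame(i = c("a", "b", "c"), j = c("b", "c", "a")))
  st <- network_statistics(tri)
  expect_equal(st$avg_degree, 2)
  expect_equal(st$mean_clustering_coefficient, 1)
  expect_equal(st$n_components, 1)
  expect_equal(st$diameter, 1)
  expect_equal(st$density, 1)

  path4 <- build_network(data.frame(i = c("a", "b", "c"), j = c("b", "c", "d")))
  stp <- network_statistics(path4)
  expect_equal(stp$avg_degree, 1.5)
  expect_equal(stp$mean_clustering_coefficient, 0)
  expect_equal(stp$diameter, 3)

  # property: agreement with BFS/loop oracles on graphs up to 50 nodes
  for (s in 1:20) {
    g <- random_test_graph(n = sample(5:50, 1), p = runif(1, 0.05, 0.4),
                           seed = 1000 + s)
    A <- adj_of(g)
    st <- network_statistics(g)
    expect_equal(st$mean_clustering_coefficient, oracle_mean_clustering(A),
                 tolerance = 1e-12)
    expect_equal(st$n_components, oracle_components(A))
    expect_equal(st$diameter, oracle_diameter(A))
    expect_equal(st$avg_degree, sum(A) / nrow(A))
  }
})

test_that("degree histogram is exact and conserves the node count", {
  star <- build_network(data.frame(i = c("h", "h", "h"), j = c("a", "b", "c")))
  tab <- degree_distribution_table(star)
  expect_equal(tab, data.frame(degree = c(1L, 3L), frequency = c(3L, 1L)))

  for (s in 1:5) {
    g <- random_test_graph(30, 0.15, seed = 2000 + s)
    tab <- degree_distribution_table(g)
    expect_equal(sum(tab$frequency), igraph::vcount(g))
    brute <- table(rowSums(adj_of(g)))
    expect_equal(tab$frequency, as.integer(brute))
  }
})

test_that("average degree of the published 0.7% network is reproduced", {
  expect_equal(round(2 * 34454 / 2779, 1), 24.8)
})
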