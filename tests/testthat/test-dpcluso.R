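graph_from_pairs <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  build_network(data.frame(i = m[, 1], j = m[, 2]))
}

test_that("edge and node weights count common neighbours", {
  tri <- graph_from_pairs("a","b", "b","c", "c","a")
  w <- edge_node_weights(tri)
  expect_true(all(w$edge_weights$weight == 1))
  expect_true(all(w$node_weights == 2))

  star <- graph_from_pairs("h","a", "h","b", "h","c")
  ws <- edge_node_weights(star)
  expect_true(all(ws$edge_weights$weight == 0))

  k4 <- graph_from_pairs("a","b","a","c","a","d","b","c","b","d","c","d")
  wk <- edge_node_weights(k4)
  expect_true(all(wk$edge_weights$weight == 2))
  expect_true(all(wk$node_weights == 6))

  # brute force on a random graph
  g <- random_test_graph(25, 0.2, seed = 31)
  A <- adj_of(g)
  wg <- edge_node_weights(g)
  for (r in seq_len(nrow(wg$edge_weights))) {
    i <- wg$edge_weights$i[r]; j <- wg$edge_weights$j[r]
    expect_equal(wg$edge_weights$weight[r],
                 sum(A[i, ] == 1 & A[j, ] == 1))
  }
})

test_that("cluster growth respects density and periphery thresholds", {
  # complete graph: everything joins
  k5 <- graph_from_pairs("a","b","a","c","a","d","a","e","b","c",
                         "b","d","b","e","c","d","c","e","d","e")
  cl <- grow_cluster(k5, "a")
  expect_setequal(cl$members, c("a","b","c","d","e"))
  expect_equal(cl$density, 1)

  # two triangles joined by a bridge: growth stays on the seed side
  g2 <- graph_from_pairs("a1","a2","a2","a3","a3","a1",
                         "b1","b2","b2","b3","b3","b1", "a3","b1")
  cl2 <- grow_cluster(g2, "a1")
  expect_setequal(cl2$members, c("a1","a2","a3"))

  # star hub: only one leaf can join before density collapses
  star <- graph_from_pairs("h","a", "h","b", "h","c")
  cl3 <- grow_cluster(star, "h")
  expect_setequal(cl3$members, c("a", "h"))  # lowest-id leaf wins the tie
  expect_error(grow_cluster(star, "zz"), "not in network")
})

test_that("coverage clustering recovers planted cliques and covers all nodes", {
  two_tri <- graph_from_pairs("a","b","b","c","c","a",
                              "x","y","y","z","z","x")
  cs <- cluster_network(two_tri)
  expect_equal(length(cs$clusters), 2)
  expect_setequal(unlist(lapply(cs$clusters, `[[`, "size")), c(3, 3))

  # isolated nodes become singleton clusters (coverage guarantee)
  iso <- igraph::make_empty_graph(n = 3, directed = FALSE)
  igraph::V(iso)$name <- c("u", "v", "w")
  cs2 <- cluster_network(iso)
  expect_equal(length(cs2$clusters), 3)
  expect_true(all(vapply(cs2$clusters, `[[`, integer(1), "size") == 1))

  # planted cliques: 5 cliques of 6 nodes, sparse inter-clique edges
  set.seed(77)
  members <- split(sprintf("v%02d", 1:30), rep(1:5, each = 6))
  intra <- do.call(rbind, lapply(members, function(m) t(combn(m, 2))))
  inter <- t(vapply(1:6, function(k) {
    cls <- sample(5, 2)
    c(sample(members[[cls[1]]], 1), sample(members[[cls[2]]], 1))
  }, character(2)))
  g <- build_network(data.frame(i = c(intra[, 1], inter[, 1]),
                                j = c(intra[, 2], inter[, 2])))
  cs3 <- filter_clusters(cluster_network(g), 3)
  planted <- lapply(members, sort)
  found <- lapply(cs3$clusters, `[[`, "members")
  for (p in planted)
    expect_true(any(vapply(found, function(f) identical(f, p), logical(1))))
})

test_that("cluster invariants hold on 100 seeded random graphs", {
  params <- dpcluso_params()
  for (s in 1:100) {
    g <- random_test_graph(n = sample(8:30, 1), p = runif(1, 0.1, 0.5),
                           seed = 4000 + s)
    cs <- cluster_network(g, params)
    sizes <- vapply(cs$clusters, `[[`, integer(1), "size")
    dens <- vapply(cs$clusters, `[[`, numeric(1), "density")
    # every multi-node cluster meets the density threshold
    expect_true(all(dens[sizes >= 2] >= params$d_in - 1e-9))
    # pre-filter coverage: every node in at least one cluster
    expect_setequal(unique(unlist(lapply(cs$clusters, `[[`, "members"))),
                    igraph::V(g)$name)
    # no cluster is a subset of an earlier one
    for (k in seq_along(cs$clusters)) {
      if (k == 1) next
      for (e in seq_len(k - 1))
        expect_false(all(cs$clusters[[k]]$members %in%
                           cs$clusters[[e]]$members))
    }
  }
})

test_that("clustering is deterministic and independent of edge order", {
  g <- random_test_graph(20, 0.3, seed = 55)
  el <- igraph::as_edgelist(g)
  perm <- sample(nrow(el))
  g2 <- build_network(data.frame(i = el[perm, 2], j = el[perm, 1]))
  cs1 <- cluster_network(g)
  cs2 <- cluster_network(g2)
  expect_identical(lapply(cs1$clusters, `[[`, "members"),
                   lapply(cs2$clusters, `[[`, "members"))
})

test_that("raising the density threshold never grows a larger cluster", {
  for (s in 1:30) {
    g <- random_test_graph(n = 20, p = 0.3, seed = 6000 + s)
    seed_node <- igraph::V(g)$name[1]
    lo <- grow_cluster(g, seed_node, dpcluso_params(d_in = 0.7))
    hi <- grow_cluster(g, seed_node, dpcluso_params(d_in = 0.9))
    expect_lte(hi$size, lo$size)
  }
})

test_that("size filtering keeps clusters at or above the cutoff", {
  sizes <- function(cs) vapply(cs$clusters, `[[`, integer(1), "size")
  g <- graph_from_pairs("a","b", "c","d", "x","y","y","z","z","x")
  cs <- cluster_network(g)
  expect_setequal(sizes(cs), c(2, 2, 3))
  expect_equal(sizes(filter_clusters(cs, 3)), 3)
  expect_setequal(sizes(filter_clusters(cs, 1)), sizes(cs))
})
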