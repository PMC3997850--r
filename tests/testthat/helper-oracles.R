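# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package: adjacency-matrix
# loops and BFS only.

# Pearson correlation of two numeric vectors, via stats::cor.
oracle_pearson <- function(x, y) suppressWarnings(stats::cor(x, y))

# Adjacency matrix of an igraph as a plain 0/1 matrix.
adj_of <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  storage.mode(A) <- "integer"
  A
}

# Mean local clustering coefficient by direct neighbour-pair counting;
# nodes with degree < 2 contribute 0.
oracle_mean_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- sum(A[nb, nb]) / 2
    cc[v] <- 2 * e / (k * (k - 1))
  }
  mean(cc)
}

# All-pairs shortest-path lengths by BFS from every node (Inf if unreachable).
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# Diameter = longest finite shortest path (max over components); 0 for
# edgeless graphs.
oracle_diameter <- function(A) {
  D <- oracle_distances(A)
  f <- D[is.finite(D)]
  if (!length(f)) 0 else max(f)
}

# Number of connected components by BFS sweeps.
oracle_components <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  comp <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1
    frontier <- s; seen[s] <- TRUE
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(A[v, ] == 1))
        if (!seen[w]) { seen[w] <- TRUE; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
  }
  comp
}

# Erdos-Renyi style random test graph with named vertices.
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# Tiny deterministic labeled dataset for assignment tests.
toy_dataset <- function() {
  inc <- matrix(0L, 5, 4,
                dimnames = list(paste0("J", 1:5), paste0("p", 1:4)))
  inc["J1", c("p1", "p2")] <- 1L
  inc["J2", c("p1", "p2")] <- 1L
  inc["J3", c("p1", "p3")] <- 1L
  inc["J4", c("p2", "p4")] <- 1L
  inc["J5", c("p1")] <- 1L
  formula_dataset(inc, labels = list(J1 = 1L, J2 = 1L, J3 = 1L,
                                     J4 = 2L, J5 = 3L))
}
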