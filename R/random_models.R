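#' Erdos-Renyi G(n, m) random graph
#'
#' Exactly m distinct edges sampled uniformly without replacement among the
#' n(n-1)/2 possible ones. The fixed-edge-count variant is used (rather
#' than G(n, p)) so that size-matched baselines reproduce the observed
#' average degree with zero replicate variance.
#'
#' @param n number of nodes.
#' @param m number of edges.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return an undirected simple `igraph` with n nodes and m edges.
#' @export
er_gnm <- function(n, m, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (m > n * (n - 1) / 2) stop("m exceeds the number of possible edges")
  with_seed(seed, igraph::sample_gnm(n, m, directed = FALSE))
}

#' Barabasi-Albert preferential-attachment graph matched to an edge count
#'
#' Growth starts from a complete graph on `m_per_node + 1` nodes, where
#' `m_per_node = round(m_target / n)`; each arriving node attaches
#' `m_per_node` edges preferentially by degree. The construction is
#' connected by design. The achieved edge count is
#' `(n - m_per_node) * m_per_node + choose(m_per_node, 2)`, i.e. it can
#' exceed a naive `(n - m_per_node) * m_per_node` by up to
#' `choose(m_per_node, 2)` because of the dense seed; the residual
#' mismatch versus `m_target` is attached as attribute `edge_mismatch`.
#'
#' @param n number of nodes (>= 3).
#' @param m_target desired edge count.
#' @param seed integer seed, or NULL.
#' @return an undirected simple `igraph`.
#' @export
ba_network <- function(n, m_target, seed = NULL) {
  if (n < 3) stop("n must be >= 3")
  mpn <- as.integer(round_half_up(m_target / n))
  if (mpn < 1) stop("m_target/n rounds below 1 edge per node")
  g <- with_seed(seed, igraph::sample_pa(
    n, power = 1, m = mpn, directed = FALSE,
    start.graph = igraph::make_full_graph(mpn + 1)
  ))
  attr(g, "edge_mismatch") <- igraph::ecount(g) - m_target
  g
}

#' Connecting-nearest-neighbour (CNN) growth graph
#'
#' Vazquez-style growth that yields high clustering: the process maintains
#' a pool of "potential edges" (pairs of nodes at graph distance 2 when
#' pooled). At each step, with probability `u` a uniformly chosen potential
#' edge is converted into a real edge; otherwise a new node arrives, links
#' to a uniformly chosen existing node, and potential edges are created
#' between the newcomer and that node's neighbours. Conversions therefore
#' only ever close triangles. After the n-th node arrives, conversions
#' continue until `m_target` edges exist or the pool is exhausted (then a
#' warning is raised and the achieved count stands).
#'
#' Every growth step adds exactly one edge, so the expected edge count at
#' the moment the n-th node arrives is n / (1 - u); `u` is solved from that
#' relation as `1 - n / m_target` (clamped to [0, 0.99]) when not given,
#' and is attached as attribute `u`.
#'
#' @param n number of nodes (>= 3).
#' @param m_target desired edge count (>= n - 1).
#' @param seed integer seed, or NULL.
#' @param u conversion probability; NULL to derive it from `m_target`.
#' @return a connected undirected simple `igraph` with n nodes.
#' @export
cnn_network <- function(n, m_target, seed = NULL, u = NULL) {
  if (n < 3) stop("n must be >= 3")
  if (is.null(u)) u <- max(0, min(0.99, 1 - n / m_target))
  g <- with_seed(seed, cnn_grow(n, m_target, u))
  attr(g, "u") <- u
  g
}

# Growth engine for cnn_network; uses the current RNG state.
cnn_grow <- function(n, m_target, u) {
  nbr <- vector("list", n)        # adjacency lists over node indices
  # potential-edge pool: 2-column matrix with an active-row counter;
  # rows are unique by construction (one endpoint is always brand new).
  pool <- matrix(0L, nrow = 256L, ncol = 2L)
  npool <- 0L
  pool_push <- function(a, b) {
    if (npool == nrow(pool)) pool <<- rbind(pool, matrix(0L, nrow(pool), 2L))
    npool <<- npool + 1L
    pool[npool, ] <<- c(a, b)
  }
  edges <- matrix(0L, nrow = max(m_target, 16L), ncol = 2L)
  nedges <- 0L
  add_edge <- function(a, b) {
    if (nedges == nrow(edges)) edges <<- rbind(edges, matrix(0L, nrow(edges), 2L))
    nedges <<- nedges + 1L
    edges[nedges, ] <<- c(a, b)
    nbr[[a]] <<- c(nbr[[a]], b)
    nbr[[b]] <<- c(nbr[[b]], a)
  }
  convert_one <- function() {
    k <- sample.int(npool, 1L)
    a <- pool[k, 1L]; b <- pool[k, 2L]
    pool[k, ] <<- pool[npool, ]   # swap-remove
    npool <<- npool - 1L
    add_edge(a, b)
  }
  nnode <- 2L
  add_edge(1L, 2L)
  while (nnode < n) {
    if (npool > 0L && stats::runif(1) < u) {
      convert_one()
    } else {
      target <- sample.int(nnode, 1L)
      nnode <- nnode + 1L
      for (w in nbr[[target]]) pool_push(nnode, w)
      add_edge(nnode, target)
    }
  }
  while (nedges < m_target && npool > 0L) convert_one()
  if (nedges < m_target)
    warning("potential-edge pool exhausted at ", nedges, " of ", m_target, " edges")
  g <- igraph::graph_from_edgelist(edges[seq_len(nedges), , drop = FALSE],
                                   directed = FALSE)
  igraph::simplify(g)
}

#' Replicate statistics of a random-graph baseline
#'
#' Generates `replicates` seeded graphs from one of the three models and
#' summarises the five network statistics as mean and standard deviation,
#' the shape in which size-matched baselines are usually reported next to
#' an observed network. Per-replicate seeds are drawn deterministically
#' from `seed`.
#'
#' @param model one of "ER", "BA", "CNN".
#' @param n,m_target node and edge counts to match.
#' @param replicates number of replicate graphs (default 10).
#' @param seed master integer seed.
#' @return list with `summary` (data.frame: statistic, mean, sd) and
#'   `per_replicate` (data.frame of raw values).
#' @export
replicate_statistics <- function(model = c("ER", "BA", "CNN"), n, m_target,
                                 replicates = 10, seed = 1) {
  model <- match.arg(model)
  if (replicates < 1) stop("replicates must be >= 1")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, replicates))
  gen <- switch(model,
    ER = function(s) er_gnm(n, m_target, seed = s),
    BA = function(s) ba_network(n, m_target, seed = s),
    CNN = function(s) cnn_network(n, m_target, seed = s))
  stats_names <- c("avg_degree", "mean_clustering_coefficient",
                   "n_components", "diameter", "density")
  vals <- t(vapply(seeds, function(s) {
    st <- network_statistics(gen(s))
    unlist(st[stats_names])
  }, numeric(length(stats_names))))
  per <- as.data.frame(vals)
  list(
    summary = data.frame(
      statistic = stats_names,
      mean = colMeans(per),
      sd = apply(per, 2, stats::sd)
    ),
    per_replicate = per
  )
}
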