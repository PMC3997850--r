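#' Fourfold point correlation (phi coefficient) of two binary vectors
#'
#' For 0/1 ingredient vectors the Pearson correlation reduces to the
#' fourfold point correlation
#' \deqn{\phi = \frac{ad - bc}{\sqrt{(a+b)(a+c)(b+d)(c+d)}}}
#' where, over the l plants, a counts plants present in both formulas, b
#' only in the first, c only in the second, and d in neither. When either
#' vector is constant the denominator vanishes; the correlation is then
#' reported as 0 with a warning (such pairs can never reach the top of the
#' ranking, so the convention is harmless downstream).
#'
#' @param x,y 0/1 vectors of equal length (at least 2).
#' @return correlation in [-1, 1].
#' @export
fourfold_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2) stop("need at least 2 positions")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("inputs must be binary 0/1 vectors")
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  den <- sqrt(as.numeric(a + b) * (a + c_) * (b + d) * (c_ + d))
  if (den == 0) {
    warning("constant vector: correlation undefined, returning 0")
    return(0)
  }
  (as.numeric(a) * d - as.numeric(b) * c_) / den
}

#' All pairwise ingredient correlations of a formula dataset
#'
#' Computes the phi coefficient for every unordered pair of formulas using
#' contingency counts derived from the incidence matrix cross-product, and
#' returns the pairs sorted by correlation, descending, ties broken by the
#' (i, j) id pair lexicographically (so the ranking is a total order and
#' top-fraction selection is reproducible). Pairs involving a constant
#' ingredient vector (no plants, or all plants) get correlation 0 with one
#' summary warning.
#'
#' @param ds a `formula_dataset` with at least two formulas.
#' @return data.frame with columns `i`, `j` (formula ids, `i < j`) and
#'   `corr`; exactly K(K-1)/2 rows.
#' @export
pairwise_correlations <- function(ds) {
  X <- ds$incidence
  K <- nrow(X); l <- ncol(X)
  if (K < 2) stop("need at least two formulas")
  A <- tcrossprod(X)            # a: plants in both
  r <- rowSums(X)
  iu <- which(upper.tri(A), arr.ind = TRUE)
  a <- A[iu]
  b <- r[iu[, 1]] - a
  cc <- r[iu[, 2]] - a
  d <- l - a - b - cc
  den <- sqrt((a + b) * (a + cc) * (b + d) * (cc + d))
  corr <- ifelse(den == 0, 0, (a * d - b * cc) / den)
  if (any(den == 0))
    warning(sum(den == 0), " pair(s) involve a constant ingredient vector; correlation set to 0")
  ids <- rownames(X)
  out <- data.frame(i = ids[iu[, 1]], j = ids[iu[, 2]], corr = corr)
  swap <- out$i > out$j
  if (any(swap)) out[swap, c("i", "j")] <- out[swap, c("j", "i")]
  out <- out[order(-out$corr, out$i, out$j), ]
  rownames(out) <- NULL
  out
}

#' Number of unordered formula pairs
#'
#' K formulas give K(K-1)/2 candidate pairs (e.g. 3138 formulas give
#' 4,921,953).
#'
#' @param K number of formulas.
#' @return pair count.
#' @export
n_formula_pairs <- function(K) choose(K, 2)

#' Size of a top-fraction selection
#'
#' The number of retained pairs is `fraction * n_pairs` rounded half up,
#' which reproduces the selection sizes 34,454 / 24,610 / 14,766 for the
#' 0.7% / 0.5% / 0.3% fractions of 4,921,953 pairs.
#'
#' @param n_pairs total number of ranked pairs.
#' @param fraction fraction in (0, 1].
#' @return integer count.
#' @export
top_fraction_count <- function(n_pairs, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  as.integer(round_half_up(fraction * n_pairs))
}

#' Keep the top fraction of a ranked pair list
#'
#' @param pairs data.frame from [pairwise_correlations()] (already sorted
#'   descending).
#' @param fraction fraction in (0, 1] of pairs to keep.
#' @return the first `top_fraction_count()` rows; the minimum retained
#'   correlation is attached as attribute `min_corr`.
#' @export
select_top_fraction <- function(pairs, fraction) {
  n_keep <- top_fraction_count(nrow(pairs), fraction)
  out <- pairs[seq_len(n_keep), , drop = FALSE]
  attr(out, "min_corr") <- if (n_keep > 0) min(out$corr) else NA_real_
  out
}

#' Build the formula similarity network from selected pairs
#'
#' Nodes are the formulas incident to at least one selected edge (formulas
#' that survive in no pair are not isolated vertices but absent). The
#' result is a simple undirected igraph: duplicate input pairs collapse to
#' one edge and self-pairs are dropped. Vertices are arranged in
#' lexicographic id order so the object is independent of edge input order.
#'
#' @param edges data.frame with columns `i`, `j` and optionally `corr`.
#' @return an undirected simple `igraph` object; edge attribute `corr` is
#'   kept when present.
#' @export
build_network <- function(edges) {
  df <- data.frame(from = as.character(edges$i), to = as.character(edges$j))
  if ("corr" %in% names(edges)) df$corr <- edges$corr
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  g
}

#' The five summary statistics of a network
#'
#' Average degree 2m/n; mean local clustering coefficient (a node with
#' degree < 2 contributes 0); number of connected components; diameter
#' (for a disconnected graph, the maximum over component diameters;
#' unweighted shortest paths); and density m / (n(n-1)/2).
#'
#' @param net an undirected simple `igraph`.
#' @return list with `n_nodes`, `n_edges`, `avg_degree`,
#'   `mean_clustering_coefficient`, `n_components`, `diameter`, `density`.
#' @export
network_statistics <- function(net) {
  n <- igraph::vcount(net); m <- igraph::ecount(net)
  if (n < 1) stop("network has no nodes")
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  list(
    n_nodes = n,
    n_edges = m,
    avg_degree = 2 * m / n,
    mean_clustering_coefficient = mean(cc),
    n_components = igraph::components(net)$no,
    diameter = if (m == 0) 0 else igraph::diameter(net, unconnected = TRUE),
    density = if (n < 2) 0 else m / (n * (n - 1) / 2)
  )
}

#' Exact degree histogram of a network
#'
#' @param net an `igraph`.
#' @return data.frame with columns `degree` and `frequency`; frequencies
#'   sum to the node count. Plot on log-log axes to inspect the heavy tail.
#' @export
degree_distribution_table <- function(net) {
  d <- igraph::degree(net)
  tab <- table(d)
  data.frame(degree = as.integer(names(tab)), frequency = as.integer(tab))
}

#' Write a network as an edge-list TSV
#'
#' @param net an `igraph` (edge attribute `corr` is written when present).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("i", "j")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in GraphML for external viewers
#'
#' @param net an `igraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
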