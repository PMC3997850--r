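#' Parameters for density-periphery cluster extraction
#'
#' `d_in` is the minimum cluster density 2E/(N(N-1)) that must hold after
#' every admission; `cp_in` is the minimum cluster property (periphery)
#' value |E_nk| / (d_k * N_k) a candidate node must reach against the
#' current cluster. The defaults 0.9 and 0.5 are the operating point used
#' throughout the package; `min_report_size` is the size below which
#' clusters are regarded as trivial and dropped by [filter_clusters()].
#'
#' @param d_in density threshold in (0, 1].
#' @param cp_in cluster-property threshold in (0, 1].
#' @param min_report_size minimum reported cluster size.
#' @return a `dpcluso_params` list.
#' @export
dpcluso_params <- function(d_in = 0.9, cp_in = 0.5, min_report_size = 3) {
  if (d_in <= 0 || d_in > 1) stop("d_in must be in (0, 1]")
  if (cp_in <= 0 || cp_in > 1) stop("cp_in must be in (0, 1]")
  structure(list(d_in = d_in, cp_in = cp_in,
                 min_report_size = as.integer(min_report_size)),
            class = "dpcluso_params")
}

#' Edge and node weights for cluster seeding
#'
#' The weight of an edge is the number of common neighbours of its two
#' endpoints; the weight of a node is the sum of the weights of its
#' incident edges. High-weight nodes sit in locally dense neighbourhoods
#' and are preferred as growth seeds.
#'
#' @param net an undirected simple `igraph`.
#' @return list with `edge_weights` (data.frame `i`, `j`, `weight`) and
#'   `node_weights` (named numeric vector over all vertices).
#' @keywords graphs
#' @export
edge_node_weights <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE))
  W <- (A %*% A) * A              # common-neighbour count, masked to edges
  el <- igraph::as_edgelist(net, names = TRUE)
  w <- if (nrow(el)) W[cbind(match(el[, 1], rownames(W)),
                             match(el[, 2], colnames(W)))] else numeric(0)
  list(
    edge_weights = data.frame(i = el[, 1], j = el[, 2], weight = as.numeric(w)),
    node_weights = structure(rowSums(W), names = rownames(W))
  )
}

# Internal: dense adjacency + weight matrices with vertex names.
dpcluso_matrices <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE))
  storage.mode(A) <- "double"
  W <- (A %*% A) * A
  list(A = A, W = W, ids = rownames(A))
}

# Internal: grow one cluster over precomputed matrices from a seed index.
grow_cluster_idx <- function(A, W, ids, seed_idx, d_in, cp_in) {
  eps <- 1e-9
  members <- seed_idx
  in_cl <- logical(nrow(A)); in_cl[seed_idx] <- TRUE
  E_k <- 0
  repeat {
    N <- length(members)
    adj_sum <- if (N == 1) A[, members] else rowSums(A[, members, drop = FALSE])
    cand <- which(!in_cl & adj_sum > 0)
    if (!length(cand)) break
    e_nk <- adj_sum[cand]
    w_nk <- if (N == 1) W[cand, members] else rowSums(W[cand, members, drop = FALSE])
    ord <- cand[order(-e_nk, -w_nk, ids[cand])]
    d_k <- if (N >= 2) 2 * E_k / (N * (N - 1)) else 1
    admitted <- FALSE
    for (v in ord) {
      e_v <- unname(adj_sum[v])
      dens_new <- 2 * (E_k + e_v) / ((N + 1) * N)
      if (dens_new < d_in - eps) next
      cp_ok <- if (N == 1) e_v >= 1 else e_v / (d_k * N) >= cp_in - eps
      if (!cp_ok) next
      members <- c(members, v)
      in_cl[v] <- TRUE
      E_k <- E_k + e_v
      admitted <- TRUE
      break
    }
    if (!admitted) break
  }
  N <- length(members)
  list(members = sort(ids[members]), seed = ids[seed_idx], size = N,
       n_edges = E_k,
       density = if (N >= 2) 2 * E_k / (N * (N - 1)) else 1)
}

#' Grow one density-periphery cluster from a seed node
#'
#' Starting from the singleton {seed}, the neighbours of the current
#' cluster are ranked by (number of edges into the cluster, descending;
#' then sum of common-neighbour edge weights into the cluster, descending;
#' then node id, ascending) and the best-ranked candidate whose admission
#' keeps the density at or above `d_in` and whose cluster property
#' |E_nk| / (d_k * N_k) reaches `cp_in` is admitted. For a singleton
#' cluster the cluster property degenerates, and the requirement reduces
#' to adjacency to the seed. Growth stops when no candidate qualifies.
#'
#' @param net an undirected simple `igraph`.
#' @param seed_node vertex name to start from.
#' @param params a [dpcluso_params()] object.
#' @return list with `members` (sorted vertex names), `seed`, `size`,
#'   `n_edges`, `density`.
#' @export
grow_cluster <- function(net, seed_node, params = dpcluso_params()) {
  mats <- dpcluso_matrices(net)
  idx <- match(as.character(seed_node), mats$ids)
  if (is.na(idx)) stop("seed node not in network: ", seed_node)
  grow_cluster_idx(mats$A, mats$W, mats$ids, idx, params$d_in, params$cp_in)
}

#' Extract overlapping dense clusters covering the whole network
#'
#' Repeatedly seeds [grow_cluster()] at the not-yet-covered node of highest
#' node weight (ties: higher degree, then id ascending) and grows over the
#' intact graph, so already-covered nodes may join again - this is what
#' produces overlapping clusters - until every node is covered by at least
#' one cluster. A cluster whose member set is a subset of an earlier one
#' would add no information and is discarded. The procedure is fully
#' deterministic: identical graph and parameters give an identical cluster
#' set, independent of edge input order.
#'
#' @param net an undirected simple `igraph`.
#' @param params a [dpcluso_params()] object.
#' @return a `cluster_set`: list with `clusters` (list of cluster records
#'   as from [grow_cluster()], each with a `cluster_id`) and `coverage`
#'   (named list: vertex name -> cluster ids containing it).
#' @export
cluster_network <- function(net, params = dpcluso_params()) {
  mats <- dpcluso_matrices(net)
  n <- length(mats$ids)
  if (n == 0) return(structure(list(clusters = list(), coverage = list()),
                               class = "cluster_set"))
  nw <- rowSums(mats$W)
  deg <- rowSums(mats$A)
  covered <- logical(n)
  clusters <- list()
  while (!all(covered)) {
    unc <- which(!covered)
    seed <- unc[order(-nw[unc], -deg[unc], mats$ids[unc])][1]
    cl <- grow_cluster_idx(mats$A, mats$W, mats$ids, seed,
                           params$d_in, params$cp_in)
    covered[match(cl$members, mats$ids)] <- TRUE
    is_subset <- any(vapply(clusters,
                            function(old) all(cl$members %in% old$members),
                            logical(1)))
    if (!is_subset) clusters[[length(clusters) + 1]] <- cl
  }
  for (k in seq_along(clusters))
    clusters[[k]]$cluster_id <- sprintf("C%04d", k)
  structure(list(clusters = clusters,
                 coverage = coverage_map(clusters, mats$ids)),
            class = "cluster_set")
}

coverage_map <- function(clusters, ids) {
  cov <- lapply(ids, function(v)
    unlist(lapply(clusters, function(cl)
      if (v %in% cl$members) cl$cluster_id else NULL)))
  names(cov) <- ids
  cov
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, `[[`, integer(1), "size")
  cat("cluster_set:", length(x$clusters), "clusters; sizes",
      if (length(sizes)) paste0("[", min(sizes), "..", max(sizes), "]") else "[]",
      "\n")
  invisible(x)
}

#' Drop trivial clusters below a size cutoff
#'
#' Clusters of fewer than `min_size` formulas (by default the
#' `min_report_size` of the parameter object, 3) carry little evidence for
#' a dominant disease and are removed before the supervised stage. After
#' filtering, full node coverage is no longer guaranteed; the coverage map
#' is recomputed over the surviving clusters.
#'
#' @param cs a `cluster_set`.
#' @param min_size minimum member count to keep.
#' @return the filtered `cluster_set`.
#' @export
filter_clusters <- function(cs, min_size = 3) {
  keep <- vapply(cs$clusters, function(cl) cl$size >= min_size, logical(1))
  clusters <- cs$clusters[keep]
  ids <- sort(unique(unlist(lapply(clusters, `[[`, "members"))))
  structure(list(clusters = clusters, coverage = coverage_map(clusters, ids)),
            class = "cluster_set")
}

#' Write a cluster set as JSON and flat TSV
#'
#' @param cs a `cluster_set`.
#' @param json_path,tsv_path output paths (NULL to skip either).
#' @return invisible NULL.
#' @export
write_clusters <- function(cs, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    rec <- lapply(cs$clusters, function(cl)
      list(cluster_id = cl$cluster_id, seed = cl$seed, size = cl$size,
           density = cl$density, members = cl$members))
    jsonlite::write_json(rec, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    flat <- do.call(rbind, lapply(cs$clusters, function(cl)
      data.frame(cluster_id = cl$cluster_id, node_id = cl$members)))
    if (is.null(flat)) flat <- data.frame(cluster_id = character(0),
                                          node_id = character(0))
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
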