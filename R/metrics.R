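# Graph-theoretic characterization of effective networks. Standard
# algorithms (BFS shortest paths, betweenness, Louvain) are delegated to
# igraph; global efficiency and the modularity formulas are evaluated here.

as_adjacency <- function(x) {
  a <- if (inherits(x, "effective_network")) x$adjacency else x
  if (!is.matrix(a) || nrow(a) != ncol(a)) stopf("adjacency must be square")
  if (!all(a %in% c(0, 1))) stopf("adjacency must be binary")
  a
}

as_digraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "directed")
}

#' Node degrees of a directed network
#'
#' @param network an `effective_network` or binary adjacency matrix.
#' @return data.frame with per-node `k_in` (column sum), `k_out` (row sum)
#'   and total `k = k_in + k_out`.
#' @export
node_degrees <- function(network) {
  a <- as_adjacency(network)
  data.frame(node = seq_len(nrow(a)), k_in = colSums(a), k_out = rowSums(a),
             k = colSums(a) + rowSums(a))
}

#' Directed shortest-path lengths (hop counts)
#'
#' Minimum number of effective connections between every ordered node pair,
#' from breadth-first search (the unweighted case of Dijkstra's algorithm).
#' Unreachable pairs are `Inf`; the diagonal is 0.
#'
#' @param network an `effective_network` or binary adjacency matrix.
#' @return numeric matrix of distances.
#' @export
shortest_path_lengths <- function(network) {
  a <- as_adjacency(network)
  igraph::distances(as_digraph(a), mode = "out", algorithm = "unweighted")
}

#' Global efficiency
#'
#' `Geff = 1/(N(N-1)) * sum_{i != j} 1/d_ij`, with `1/Inf = 0`: the mean
#' inverse shortest-path length over ordered pairs. 1 for all-to-all
#' connectivity (swift information flow), 0 for isolated nodes. Optionally
#' computed on the subgraph with `exclude` nodes removed, which keeps
#' pre/post-damage networks size-matched.
#'
#' @param network an `effective_network` or binary adjacency matrix.
#' @param exclude optional node indices to drop before the computation.
#' @return Geff in `[0, 1]`.
#' @export
global_efficiency <- function(network, exclude = NULL) {
  a <- as_adjacency(network)
  if (length(exclude)) a <- a[-exclude, -exclude, drop = FALSE]
  n <- nrow(a)
  if (n < 2) stopf("global efficiency needs at least 2 nodes")
  d <- shortest_path_lengths(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Louvain community detection
#'
#' Greedy modularity optimization on the symmetrized graph (an undirected
#' edge wherever a connection exists in either direction). Deterministic
#' given `seed`.
#'
#' @param network an `effective_network` or binary adjacency matrix.
#' @param seed integer seed.
#' @return integer vector of community labels (contiguous from 1).
#' @export
louvain_communities <- function(network, seed = 1) {
  a <- as_adjacency(network)
  g <- igraph::graph_from_adjacency_matrix((a + t(a)) > 0, mode = "undirected")
  memb <- with_seed(seed, igraph::membership(igraph::cluster_louvain(g)))
  as.integer(memb)
}

#' Modularity Q of a partition
#'
#' The excess of within-community connections over the degree-preserving
#' expectation: `Q = 1/(2m) * sum_ij (A_ij - k_i k_j / (2m)) delta(c_i, c_j)`
#' evaluated on the symmetrized graph (the printed undirected form), where m
#' is the undirected edge count. 0 when the whole network is one community,
#' approaching 1 for fully segregated modules; Q >~ 0.3 indicates modular
#' organization. `directed = TRUE` instead evaluates the directed variant
#' `Q = 1/m * sum_ij (A_ij - k_i^out k_j^in / m) delta(c_i, c_j)`.
#'
#' @param network an `effective_network` or binary adjacency matrix.
#' @param partition integer/character vector of community labels covering
#'   all nodes.
#' @param directed use the directed-modularity variant (default FALSE).
#' @return Q.
#' @export
modularity_q <- function(network, partition, directed = FALSE) {
  a <- as_adjacency(network)
  n <- nrow(a)
  if (length(partition) != n) stopf("partition must cover all nodes")
  memb <- as.integer(factor(partition))
  if (directed) {
    m <- sum(a)
    if (m == 0) stopf("modularity undefined on a graph with no connections")
    same <- outer(memb, memb, "==")
    return(sum((a - outer(rowSums(a), colSums(a)) / m) * same) / m)
  }
  und <- ((a + t(a)) > 0) * 1
  if (sum(und) == 0) stopf("modularity undefined on a graph with no connections")
  g <- igraph::graph_from_adjacency_matrix(und, mode = "undirected")
  igraph::modularity(g, memb)
}

#' Betweenness centrality
#'
#' `BC_i = sum_{j != k} n_jk(i) / n_jk` over ordered pairs of other nodes,
#' where `n_jk` counts directed shortest paths from j to k and `n_jk(i)`
#' those passing through i. Unnormalized; identifies the ROIs that route
#' most of the network's communication.
#'
#' @param network an `effective_network` or binary adjacency matrix.
#' @return numeric vector of BC values (>= 0).
#' @export
betweenness_centrality <- function(network) {
  a <- as_adjacency(network)
  as.numeric(igraph::betweenness(as_digraph(a), directed = TRUE,
                                 normalized = FALSE))
}

#' Full metric report for an effective network
#'
#' Bundles degrees, global efficiency, Louvain communities with their
#' modularity, and betweenness centrality.
#'
#' @param network an `effective_network` or binary adjacency matrix.
#' @param seed seed for the Louvain sweep.
#' @return a `metric_report` list: `degrees`, `geff`, `q`, `communities`,
#'   `bc`.
#' @export
metric_report <- function(network, seed = 1) {
  a <- as_adjacency(network)
  comm <- louvain_communities(a, seed = seed)
  q <- if (sum(a) > 0) modularity_q(a, comm) else NA_real_
  structure(list(degrees = node_degrees(a),
                 geff = global_efficiency(a),
                 q = q,
                 communities = comm,
                 bc = betweenness_centrality(a)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: N = %d, Geff = %.3f, Q = %.3f, %d communities>\n",
              nrow(x$degrees), x$geff, x$q, length(unique(x$communities))))
  invisible(x)
}
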