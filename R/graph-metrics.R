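# Topological measures on one binary network: degree, clustering, shortest
# paths, random-benchmark normalization (gamma, lambda, sigma) and Newman
# modularity maximized by the Louvain heuristic. Graph primitives (BFS
# distances, local clustering, G(n,m) sampling, Louvain) are delegated to
# igraph; the Q evaluation of a given partition is implemented here so that it
# can be tested against an exhaustive-partition oracle.

as_igraph <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Node degrees
#'
#' @param net A `binary_network`.
#' @return Integer vector `k_i`, one entry per node.
#' @export
degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  as.integer(rowSums(net$adjacency))
}

#' Clustering coefficient
#'
#' `C_i` is the proportion of a node's neighbor pairs that are themselves
#' connected, 0 by convention when the degree is below 2; `C` is the mean
#' over all nodes.
#'
#' @param net A `binary_network`.
#' @return List with `C` (scalar) and `C_i` (vector).
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net)
  c_i <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(C = mean(c_i), C_i = c_i)
}

#' Characteristic path length
#'
#' Unweighted (breadth-first) shortest paths. `L_i` is node i's mean distance
#' to the nodes reachable from it; `L` is the mean over all ordered reachable
#' pairs. Unreachable pairs are excluded with a warning stating how many were
#' dropped; a node with no reachable partner gets `L_i = NA`.
#'
#' @param net A `binary_network` with at least one edge.
#' @return List with `L` (scalar) and `L_i` (vector).
#' @export
characteristic_path_length <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  if (sum(net$adjacency) == 0L) {
    stop("network has no edges; path length undefined", call. = FALSE)
  }
  d <- igraph::distances(as_igraph(net))
  diag(d) <- NA
  n_unreachable <- sum(is.infinite(d))
  if (n_unreachable > 0L) {
    warning(sprintf("%d ordered node pairs are unreachable and were excluded",
                    n_unreachable), call. = FALSE)
    d[is.infinite(d)] <- NA
  }
  l_i <- rowMeans(d, na.rm = TRUE)
  l_i[is.nan(l_i)] <- NA_real_
  list(L = mean(d, na.rm = TRUE), L_i = l_i)
}

#' Random benchmark networks
#'
#' Means of L and C over uniform random graphs with the same number of nodes
#' and edges as the input network.
#'
#' @param net A `binary_network` with at least one edge.
#' @param n_realizations Number of random graphs; default 100.
#' @param seed Seed making the benchmark deterministic.
#' @return List of class `random_benchmark` with `n_realizations`, `L_r`,
#'   `C_r`, `seed`.
#' @export
random_benchmark <- function(net, n_realizations = 100L, seed = 1L) {
  stopifnot(inherits(net, "binary_network"))
  n <- nrow(net$adjacency)
  m <- net$n_edges
  if (m < 1L) stop("network has no edges", call. = FALSE)
  if (n_realizations < 1L) stop("n_realizations must be >= 1", call. = FALSE)
  res <- withr::with_seed(seed, {
    vapply(seq_len(n_realizations), function(r) {
      g <- igraph::sample_gnm(n, m)
      d <- igraph::distances(g)
      diag(d) <- NA
      d[is.infinite(d)] <- NA
      c(L = mean(d, na.rm = TRUE),
        C = mean(igraph::transitivity(g, type = "local", isolates = "zero")))
    }, c(L = 0, C = 0))
  })
  structure(list(n_realizations = as.integer(n_realizations),
                 L_r = mean(res["L", ]), C_r = mean(res["C", ]),
                 seed = as.integer(seed)),
            class = "random_benchmark")
}

#' Small-world indices
#'
#' `gamma = C / C_r`, `lambda = L / L_r`, and the small-worldness
#' `sigma = gamma / lambda = C * L_r / (C_r * L)`.
#'
#' @param C,L Clustering coefficient and characteristic path length.
#' @param benchmark A `random_benchmark`.
#' @return List with `gamma`, `lambda`, `sigma`.
#' @export
small_worldness <- function(C, L, benchmark) {
  stopifnot(inherits(benchmark, "random_benchmark"))
  if (benchmark$C_r <= 0 || benchmark$L_r <= 0) {
    stop("benchmark C_r and L_r must be positive", call. = FALSE)
  }
  gamma <- C / benchmark$C_r
  lambda <- L / benchmark$L_r
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Newman modularity of a given partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` where `e_c` counts intra-community
#' edges, `d_c` is the community's total degree and `m` the edge count.
#'
#' @param net A `binary_network` with at least one edge.
#' @param membership Integer community label per node.
#' @return Q.
#' @export
modularity_value <- function(net, membership) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  m <- sum(a) / 2
  if (m == 0) stop("network has no edges; modularity undefined", call. = FALSE)
  if (length(membership) != nrow(a)) {
    stop("membership length must equal the node count", call. = FALSE)
  }
  k <- rowSums(a)
  q <- 0
  for (com in unique(membership)) {
    idx <- membership == com
    e_c <- sum(a[idx, idx, drop = FALSE]) / 2
    d_c <- sum(k[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Modularity maximization (Louvain heuristic)
#'
#' Runs Louvain with a fixed seed and evaluates the resulting partition with
#' [modularity_value()], so the reported Q always matches the package's own
#' Newman-formula evaluation.
#'
#' @param net A `binary_network` with at least one edge.
#' @param seed Seed; the heuristic is randomized.
#' @return List with `Q` and `partition` (integer membership per node).
#' @export
modularity <- function(net, seed = 1L) {
  stopifnot(inherits(net, "binary_network"))
  if (sum(net$adjacency) == 0L) {
    stop("network has no edges; modularity undefined", call. = FALSE)
  }
  comm <- withr::with_seed(seed, igraph::cluster_louvain(as_igraph(net)))
  membership <- as.integer(igraph::membership(comm))
  list(Q = modularity_value(net, membership), partition = membership)
}

#' All topological measures for one subject's network
#'
#' Bundles degree, clustering, path length, the random benchmark, small-world
#' indices and Louvain modularity. The per-node table includes the node-wise
#' small-world analog `sigma_i = C_i * L_r / (C_r * L_i)`, computed against
#' the network-level benchmark.
#'
#' @param net A `binary_network`.
#' @param n_realizations Benchmark realizations.
#' @param seed Seed used for the benchmark and the Louvain run.
#' @return A list of class `subject_graph_metrics`: scalars `L`, `C`,
#'   `gamma`, `lambda`, `sigma`, `Q`, the `benchmark`, the modularity
#'   `partition`, and `per_node` (data.frame `node_id`, `k`, `C_i`, `L_i`,
#'   `sigma_i`).
#' @export
subject_metrics <- function(net, n_realizations = 100L, seed = 1L) {
  k <- degree(net)
  cl <- clustering_coefficient(net)
  pl <- characteristic_path_length(net)
  bench <- random_benchmark(net, n_realizations, seed = seed)
  sw <- small_worldness(cl$C, pl$L, bench)
  mod <- modularity(net, seed = seed)
  per_node <- data.frame(
    node_id = 0:(length(k) - 1L),
    k = k,
    C_i = cl$C_i,
    L_i = pl$L_i,
    sigma_i = cl$C_i * bench$L_r / (bench$C_r * pl$L_i)
  )
  structure(list(subject_id = net$subject_id, L = pl$L, C = cl$C,
                 gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
                 Q = mod$Q, benchmark = bench, partition = mod$partition,
                 per_node = per_node),
            class = "subject_graph_metrics")
}
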