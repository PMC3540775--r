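# Small graph fixtures and independent brute-force oracles. Everything here
# deliberately avoids igraph and the package's own metric implementations so
# tests compare two independent routes.

as_net <- function(adj, subject_id = "fixture") {
  adj <- (adj + t(adj) > 0) * 1L
  diag(adj) <- 0L
  n <- nrow(adj)
  structure(list(adjacency = adj, n_edges = sum(adj) / 2,
                 edge_density = sum(adj) / 2 / (n * (n - 1) / 2),
                 subject_id = subject_id),
            class = "binary_network")
}

complete_net <- function(n) as_net(matrix(1L, n, n))

path_net <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- 1L
  as_net(adj)
}

star_net <- function(n) {
  adj <- matrix(0L, n, n)
  adj[1, 2:n] <- 1L
  as_net(adj)
}

cycle_net <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- 1L
  adj[1, n] <- 1L
  as_net(adj)
}

k4_minus_edge_net <- function() {
  adj <- matrix(1L, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 0L
  as_net(adj)
}

two_k4_net <- function() {
  adj <- matrix(0L, 8, 8)
  adj[1:4, 1:4] <- 1L
  adj[5:8, 5:8] <- 1L
  as_net(adj)
}

# Two dense cliques joined by a single bridge: a strongly modular,
# small-world-like test network.
bridged_cliques_net <- function(clique_size = 20) {
  n <- 2 * clique_size
  adj <- matrix(0L, n, n)
  adj[1:clique_size, 1:clique_size] <- 1L
  adj[(clique_size + 1):n, (clique_size + 1):n] <- 1L
  adj[clique_size, clique_size + 1] <- 1L
  as_net(adj)
}

# --- brute-force oracles ---------------------------------------------------

bf_clustering <- function(adj) {
  n <- nrow(adj)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      links <- links + adj[nb[a], nb[b]]
    }
    c_i[i] <- links / (k * (k - 1) / 2)
  }
  list(C = mean(c_i), C_i = c_i)
}

# All-pairs shortest paths by repeated relaxation (Floyd-Warshall).
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bf_path_length <- function(adj) {
  d <- bf_distances(adj)
  diag(d) <- NA
  d[is.infinite(d)] <- NA
  mean(d, na.rm = TRUE)
}

# Newman Q of a partition, written independently of the package.
bf_q <- function(adj, membership) {
  m <- sum(adj) / 2
  k <- rowSums(adj)
  q <- 0
  for (com in unique(membership)) {
    idx <- membership == com
    q <- q + sum(adj[idx, idx]) / 2 / m - (sum(k[idx]) / (2 * m))^2
  }
  q
}

# Enumerate all set partitions of 1..n (restricted-growth strings) and return
# the maximum Q over them.
bf_best_q <- function(adj) {
  n <- nrow(adj)
  best <- -Inf
  recurse <- function(labels, next_label) {
    i <- length(labels) + 1
    if (i > n) {
      q <- bf_q(adj, labels)
      if (q > best) best <<- q
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      recurse(c(labels, lab), max(next_label, lab + 1))
    }
  }
  recurse(integer(0), 1)
  best
}

# Brute-force BH step-up: literal sort, cap, cumulative minimum from the top.
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(p[ord] * m / seq_len(m), 1)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
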