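# Spatial statistics and hub/seed profiling: Euclidean distance between
# connected regions as an approximation of connection reach, degree-based hub
# ranking and cross-subject hub frequencies, and the connection profile of a
# chosen seed region across the two groups.

#' Mean Euclidean distance from each node to its connected neighbors
#'
#' @param net A `binary_network`.
#' @param node_table Node table with centroid columns `x_mm`, `y_mm`, `z_mm`.
#' @return A data.frame `node_id`, `mean_neighbor_distance` (mm; `NA` for
#'   isolated nodes), `defined_flag`.
#' @export
neighbor_mean_distance <- function(net, node_table) {
  stopifnot(inherits(net, "binary_network"))
  n <- nrow(net$adjacency)
  if (nrow(node_table) != n) {
    stop("node table does not match the network's node count", call. = FALSE)
  }
  xyz <- as.matrix(node_table[, c("x_mm", "y_mm", "z_mm")])
  d <- as.matrix(stats::dist(xyz))
  k <- rowSums(net$adjacency)
  total <- rowSums(d * net$adjacency)
  md <- ifelse(k > 0, total / k, NA_real_)
  data.frame(node_id = node_table$node_id, mean_neighbor_distance = md,
             defined_flag = k > 0)
}

#' Top hubs by degree
#'
#' Nodes sorted by degree descending, ties broken by node id ascending.
#'
#' @param k Degree vector (ordered by node id).
#' @param hub_set_size How many hubs to return; default 15.
#' @param node_ids 0-based ids matching `k`.
#' @return Ordered vector of node ids.
#' @export
top_hubs <- function(k, hub_set_size = 15L, node_ids = seq_along(k) - 1L) {
  if (hub_set_size > length(k)) {
    stop("hub_set_size exceeds the number of nodes", call. = FALSE)
  }
  node_ids[order(-k, node_ids)][seq_len(hub_set_size)]
}

#' Hub occurrence frequency per node and group
#'
#' For each node, the fraction of a group's subjects in which the node ranks
#' among the top `hub_set_size` hubs. Each subject contributes exactly
#' `hub_set_size` memberships, so per group the fractions sum to
#' `hub_set_size`.
#'
#' @param degree_matrix Subjects x nodes matrix of degrees.
#' @param groups Group label per subject (`"control"` / `"case"`).
#' @param hub_set_size Size of the hub set; default 15.
#' @return A data.frame `node_id`, `freq_control`, `freq_case`.
#' @export
hub_frequency <- function(degree_matrix, groups, hub_set_size = 15L) {
  stopifnot(nrow(degree_matrix) == length(groups))
  n_nodes <- ncol(degree_matrix)
  counts <- matrix(0, n_nodes, 2L, dimnames = list(NULL, c("control", "case")))
  for (s in seq_len(nrow(degree_matrix))) {
    hubs <- top_hubs(degree_matrix[s, ], hub_set_size)
    counts[hubs + 1L, groups[s]] <- counts[hubs + 1L, groups[s]] + 1
  }
  n_control <- sum(groups == "control")
  n_case <- sum(groups == "case")
  data.frame(node_id = 0:(n_nodes - 1L),
             freq_control = if (n_control > 0) counts[, "control"] / n_control else NA_real_,
             freq_case = if (n_case > 0) counts[, "case"] / n_case else NA_real_)
}

#' Seed-region connection profile across groups
#'
#' Counts, per node, in how many subjects of each group the node is connected
#' to the seed. A connection is attributed to a group when its within-group
#' frequency reaches `attribution_threshold` (default: present in at least
#' one subject). Nodes attributed in one group and connected in zero subjects
#' of the other are group-specific; nodes connected in both groups are
#' shared. Nodes never connected to the seed are dropped.
#'
#' @param networks List of `binary_network`, one per subject.
#' @param groups Group label per subject.
#' @param seed_node_id 0-based id of the seed node.
#' @param attribution_threshold Minimum within-group frequency for
#'   attribution; default `1 / group size` (one subject).
#' @return A data.frame of class `seed_profile`: `node_id`, `count_control`,
#'   `count_case`, `freq_control`, `freq_case`, `status` in
#'   `{control_specific, case_specific, shared, unattributed}`; group sizes
#'   are attached as attributes `n_control`, `n_case`.
#' @export
seed_profile <- function(networks, groups, seed_node_id,
                         attribution_threshold = NULL) {
  stopifnot(length(networks) == length(groups))
  n_nodes <- nrow(networks[[1L]]$adjacency)
  if (seed_node_id < 0L || seed_node_id >= n_nodes) {
    stop("seed node id out of range", call. = FALSE)
  }
  n1 <- sum(groups == "control")
  n2 <- sum(groups == "case")
  counts <- matrix(0L, n_nodes, 2L, dimnames = list(NULL, c("control", "case")))
  for (s in seq_along(networks)) {
    nb <- networks[[s]]$adjacency[seed_node_id + 1L, ]
    counts[, groups[s]] <- counts[, groups[s]] + nb
  }
  thr_control <- if (is.null(attribution_threshold)) {
    if (n1 > 0) 1 / n1 else Inf
  } else attribution_threshold
  thr_case <- if (is.null(attribution_threshold)) {
    if (n2 > 0) 1 / n2 else Inf
  } else attribution_threshold

  freq_control <- if (n1 > 0) counts[, "control"] / n1 else rep(NA_real_, n_nodes)
  freq_case <- if (n2 > 0) counts[, "case"] / n2 else rep(NA_real_, n_nodes)
  attr_control <- !is.na(freq_control) & freq_control >= thr_control
  attr_case <- !is.na(freq_case) & freq_case >= thr_case

  status <- rep("unattributed", n_nodes)
  status[attr_control & counts[, "case"] == 0L] <- "control_specific"
  status[attr_case & counts[, "control"] == 0L] <- "case_specific"
  status[counts[, "control"] > 0L & counts[, "case"] > 0L] <- "shared"

  keep <- counts[, "control"] > 0L | counts[, "case"] > 0L
  keep[seed_node_id + 1L] <- FALSE
  out <- data.frame(node_id = (0:(n_nodes - 1L))[keep],
                    count_control = counts[keep, "control"],
                    count_case = counts[keep, "case"],
                    freq_control = freq_control[keep],
                    freq_case = freq_case[keep],
                    status = status[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_control") <- n1
  attr(out, "n_case") <- n2
  attr(out, "seed_node_id") <- seed_node_id
  class(out) <- c("seed_profile", "data.frame")
  out
}

#' Pooled two-proportion z for shared seed connections
#'
#' For each node connected to the seed in both groups, tests the difference
#' of within-group connection frequencies with the pooled two-proportion z:
#' `z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))`,
#' `phat = (x1 + x2) / (n1 + n2)`. Connections present in only one group are
#' excluded; `z` is `NA` (flagged undefined) when the pooled frequency is 0
#' or 1. Significance is declared at `|z| > 2`.
#'
#' @param profile A `seed_profile`.
#' @param n1,n2 Group sizes; default the sizes recorded in the profile.
#' @return The shared rows of the profile with `z`, `z_defined` and
#'   `significant` columns appended.
#' @export
seed_frequency_z <- function(profile,
                             n1 = attr(profile, "n_control"),
                             n2 = attr(profile, "n_case")) {
  stopifnot(inherits(profile, "seed_profile"))
  shared <- profile[profile$status == "shared", , drop = FALSE]
  if (nrow(shared) == 0L) {
    shared$z <- numeric(0)
    shared$z_defined <- logical(0)
    shared$significant <- logical(0)
    return(as.data.frame(shared))
  }
  x1 <- shared$count_control
  x2 <- shared$count_case
  p1 <- x1 / n1
  p2 <- x2 / n2
  phat <- (x1 + x2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- ifelse(phat %in% c(0, 1), NA_real_, (p1 - p2) / se)
  shared$z <- z
  shared$z_defined <- !is.na(z)
  shared$significant <- !is.na(z) & abs(z) > 2
  as.data.frame(shared)
}
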