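# From a subject's region x time matrix to correlation-matrix variants and a
# binary network at fixed edge density. The processing order is demean ->
# remove_global_signal -> correlation_matrix; the diagonal is stored as 1 but
# excluded from every summary.

#' Remove each row's mean
#'
#' @param series Region x time numeric matrix with at least 2 columns.
#' @return Matrix of the same shape with every row mean exactly 0.
#' @export
demean <- function(series) {
  series <- as.matrix(series)
  if (ncol(series) < 2L) stop("need at least 2 volumes", call. = FALSE)
  if (!all(is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  series - rowMeans(series)
}

#' Subtract the across-node mean time course (global signal removal)
#'
#' The mean over nodes at each time point is subtracted from every node's
#' series, so the output's column means are exactly zero. Note the residual
#' rows sum to zero at every time point: a signal component loaded equally on
#' all nodes is removed exactly.
#'
#' @param series Region x time numeric matrix with at least 2 rows.
#' @return Matrix of the same shape.
#' @export
remove_global_signal <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 2L) {
    stop("global signal removal needs at least 2 nodes", call. = FALSE)
  }
  if (!all(is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  sweep(series, 2L, colMeans(series))
}

new_connectivity_matrix <- function(values, variant, subject_id) {
  structure(list(values = values, variant = variant, subject_id = subject_id),
            class = "connectivity_matrix")
}

#' Pearson correlation matrix of a subject's series
#'
#' @param series Region x time matrix; every row must have nonzero variance
#'   and there must be at least 3 volumes.
#' @param subject_id Identifier stored in the result.
#' @return A `connectivity_matrix` with `variant = "raw"`.
#' @export
correlation_matrix <- function(series, subject_id = NA_character_) {
  series <- as.matrix(series)
  if (ncol(series) < 3L) stop("need at least 3 volumes", call. = FALSE)
  if (!all(is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  v <- apply(series, 1L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    labels <- if (!is.null(rownames(series))) rownames(series)[bad] else bad - 1L
    stop("zero-variance series at node(s): ", paste(labels, collapse = ", "),
         call. = FALSE)
  }
  cm <- stats::cor(t(series))
  diag(cm) <- 1
  new_connectivity_matrix(cm, "raw", subject_id)
}

#' Zero out negative correlations
#'
#' @param cm A raw `connectivity_matrix`.
#' @return A `connectivity_matrix` with `variant = "nonnegative"`; negative
#'   off-diagonal entries replaced by 0, the diagonal untouched.
#' @export
zero_negatives <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (cm$variant != "raw") {
    stop("zero_negatives expects a raw connectivity matrix", call. = FALSE)
  }
  vals <- cm$values
  d <- diag(vals)
  vals[vals < 0] <- 0
  diag(vals) <- d
  new_connectivity_matrix(vals, "nonnegative", cm$subject_id)
}

# Upper-triangle pairs ordered by correlation descending, ties broken by
# (smaller i, then smaller j); only strictly positive values are eligible.
ranked_positive_pairs <- function(values) {
  n <- nrow(values)
  pairs <- upper_pairs(n)
  vals <- values[pairs]
  keep <- vals > 0
  pairs <- pairs[keep, , drop = FALSE]
  vals <- vals[keep]
  ord <- order(-vals, pairs[, 1L], pairs[, 2L])
  list(pairs = pairs[ord, , drop = FALSE], values = vals[ord])
}

#' Proportional thresholding to a binary network
#'
#' Ranks the upper-triangle correlations descending and retains the top
#' `floor(density * n(n-1)/2)` node pairs as edges. Only strictly positive
#' correlations are eligible; ties at the cutoff are broken by node-index
#' order. If fewer positive values exist than edges requested, all positive
#' values are retained and a warning is issued (the realized density is
#' recorded in the result).
#'
#' @param cm A `connectivity_matrix` (raw or nonnegative).
#' @param density Target edge density in (0, 1]; default 0.20, the proportion
#'   of strongest correlations treated as functionally connected.
#' @return A list of class `binary_network` with `adjacency` (0/1 symmetric,
#'   zero diagonal), `edge_density` (realized), `n_edges`, `subject_id`.
#' @export
threshold_by_density <- function(cm, density = 0.20) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!cm$variant %in% c("raw", "nonnegative")) {
    stop("threshold_by_density expects a raw or nonnegative matrix", call. = FALSE)
  }
  stopifnot_scalar_number(density, "density")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]", call. = FALSE)
  n <- nrow(cm$values)
  n_pairs <- n * (n - 1L) / 2
  m_target <- floor(density * n_pairs)
  ranked <- ranked_positive_pairs(cm$values)
  if (nrow(ranked$pairs) < m_target) {
    warning(sprintf(paste0("only %d positive correlations available for %d ",
                           "requested edges; retaining all positive values"),
                    nrow(ranked$pairs), m_target), call. = FALSE)
    m_keep <- nrow(ranked$pairs)
  } else {
    m_keep <- m_target
  }
  adj <- matrix(0L, n, n)
  if (m_keep > 0L) {
    kept <- ranked$pairs[seq_len(m_keep), , drop = FALSE]
    adj[kept] <- 1L
    adj[kept[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  dimnames(adj) <- dimnames(cm$values)
  structure(list(adjacency = adj, edge_density = m_keep / n_pairs,
                 n_edges = m_keep, subject_id = cm$subject_id),
            class = "binary_network")
}

#' Grand mean of a correlation matrix
#'
#' Mean of the `n(n-1)/2` upper-triangle off-diagonal entries; the diagonal
#' (self-correlations) is disregarded.
#'
#' @param cm A `connectivity_matrix` of any variant.
#' @return A single number.
#' @export
grand_mean <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  mean(upper_values(cm$values))
}

#' Threshold value and mean of retained correlations
#'
#' At the given density, reports the smallest correlation retained as an edge
#' (the effective correlation threshold) and the mean over retained
#' correlations.
#'
#' @inheritParams threshold_by_density
#' @return A list with `threshold_value` and `mean_retained` (both `NA` if no
#'   positive correlations exist).
#' @export
retained_correlation_summary <- function(cm, density = 0.20) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!cm$variant %in% c("raw", "nonnegative")) {
    stop("retained_correlation_summary expects a raw or nonnegative matrix",
         call. = FALSE)
  }
  if (density <= 0 || density > 1) stop("density must be in (0, 1]", call. = FALSE)
  n <- nrow(cm$values)
  m_target <- floor(density * n * (n - 1L) / 2)
  ranked <- ranked_positive_pairs(cm$values)
  if (nrow(ranked$pairs) < m_target) {
    warning(sprintf(paste0("only %d positive correlations available for %d ",
                           "requested edges; retaining all positive values"),
                    nrow(ranked$pairs), m_target), call. = FALSE)
    m_keep <- nrow(ranked$pairs)
  } else {
    m_keep <- m_target
  }
  if (m_keep == 0L) {
    return(list(threshold_value = NA_real_, mean_retained = NA_real_))
  }
  retained <- ranked$values[seq_len(m_keep)]
  list(threshold_value = min(retained), mean_retained = mean(retained))
}

#' Write / read a square correlation matrix as TSV
#'
#' Square TSV with node ids as header row and first column.
#'
#' @param cm A `connectivity_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_connectivity_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  n <- nrow(cm$values)
  df <- data.frame(node_id = 0:(n - 1L), cm$values)
  names(df) <- c("node_id", paste0("n", 0:(n - 1L)))
  write_tsv(df, path)
}

#' Write a binary network as a two-column edge list (i < j, 0-based)
#'
#' @param net A `binary_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "binary_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  write_tsv(data.frame(node_i = idx[, 1L] - 1L, node_j = idx[, 2L] - 1L), path)
}

#' Read an edge list back into a binary network
#'
#' @param path Edge-list TSV written by [write_edge_list()].
#' @param n_nodes Number of nodes of the network.
#' @param subject_id Identifier stored in the result.
#' @return A `binary_network`.
#' @export
read_edge_list <- function(path, n_nodes, subject_id = NA_character_) {
  df <- read_tsv(path)
  adj <- matrix(0L, n_nodes, n_nodes)
  if (nrow(df) > 0L) {
    idx <- cbind(df$node_i + 1L, df$node_j + 1L)
    adj[idx] <- 1L
    adj[idx[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  n_pairs <- n_nodes * (n_nodes - 1L) / 2
  structure(list(adjacency = adj, edge_density = nrow(df) / n_pairs,
                 n_edges = nrow(df), subject_id = subject_id),
            class = "binary_network")
}
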