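# Group-level inference: pooled two-sample t-tests for global measures,
# label-permutation tests with Benjamini-Hochberg FDR for node-wise measures,
# and the Pearson correlation test between metrics. Classical tests call the
# stats implementations; the permutation machinery is implemented here.

GLOBAL_MEASURES <- c("grand_mean_raw", "grand_mean_nonnegative",
                     "L", "C", "gamma", "lambda", "sigma", "Q")

#' Pooled-variance two-sample t-test
#'
#' Classical independent-samples t with `n_a + n_b - 2` degrees of freedom
#' and a two-sided p-value.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  pooled_var <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    stop("zero pooled variance with unequal means; t undefined", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

# Vectorized pooled t statistics across columns of a subjects x nodes matrix,
# for one or many label permutations. perm_idx is a permutations x subjects
# matrix of row indices. Zero pooled variance yields t = 0 when the group
# means agree and +/-Inf otherwise.
pooled_t_matrix <- function(x, is_group1, perm_idx) {
  n <- nrow(x)
  n1 <- sum(is_group1)
  n2 <- n - n1
  x2 <- x^2
  # Indicator matrix (permutations x subjects) for group 1 membership.
  ind <- matrix(0, nrow(perm_idx), n)
  ind[cbind(rep(seq_len(nrow(perm_idx)), n1),
            as.vector(perm_idx[, seq_len(n1), drop = FALSE]))] <- 1
  sum_all <- colSums(x)
  sumsq_all <- colSums(x2)
  s1 <- ind %*% x
  sq1 <- ind %*% x2
  s2 <- matrix(sum_all, nrow(ind), ncol(x), byrow = TRUE) - s1
  sq2 <- matrix(sumsq_all, nrow(ind), ncol(x), byrow = TRUE) - sq1
  m1 <- s1 / n1
  m2 <- s2 / n2
  ss1 <- sq1 - n1 * m1^2
  ss2 <- sq2 - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  sp2[sp2 < 0] <- 0  # numerical guard
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t_mat <- diff / se
  t_mat[se == 0 & diff == 0] <- 0
  t_mat[se == 0 & diff != 0] <- sign(diff[se == 0 & diff != 0]) * Inf
  t_mat
}

#' Node-wise label-permutation test
#'
#' Per node, the statistic is the pooled two-sample t; the null distribution
#' is built by permuting the subject labels, the same permutation applied to
#' every node. The two-sided p-value uses the add-one estimator
#' `(1 + #{|t_perm| >= |t_obs|}) / (n_perm + 1)`.
#'
#' @param node_values Subjects x nodes numeric matrix.
#' @param labels Group label per subject (`"control"` / `"case"`), each group
#'   with at least 2 subjects.
#' @param n_perm Number of permutations; default 5000.
#' @param seed Seed; results are deterministic given it.
#' @return List with `t` (observed per-node t, control minus case), `p`
#'   (per-node permutation p), `n_perm`.
#' @export
permutation_test_nodewise <- function(node_values, labels, n_perm = 5000L,
                                      seed = 1L) {
  node_values <- as.matrix(node_values)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (nrow(node_values) != length(labels)) {
    stop("labels length must match the number of subject rows", call. = FALSE)
  }
  is1 <- labels == "control"
  if (sum(is1) < 2L || sum(!is1) < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  n <- nrow(node_values)
  n1 <- sum(is1)
  # Observed statistic: "identity permutation" listing group-1 rows first.
  obs_idx <- matrix(c(which(is1), which(!is1)), nrow = 1L)
  t_obs <- drop(pooled_t_matrix(node_values, is1, obs_idx))
  perm_idx <- withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(p) sample.int(n), integer(n)))
  })
  t_perm <- pooled_t_matrix(node_values, is1, perm_idx)
  exceed <- colSums(abs(t_perm) >= matrix(abs(t_obs), n_perm, ncol(node_values),
                                          byrow = TRUE))
  list(t = t_obs, p = (1 + exceed) / (n_perm + 1), n_perm = as.integer(n_perm))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with significance flags at the given level.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q_level FDR level; default 0.05.
#' @return List with `q` and `significant`.
#' @export
fdr_bh <- function(p, q_level = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q <= q_level)
}

#' Pearson correlation test
#'
#' Pearson r with the t-test on `n - 2` degrees of freedom,
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)`, two-sided.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return List with `r`, `t`, `df`, `p`, and `degenerate` (`TRUE` when
#'   `|r| = 1`, where p is exactly 0).
#' @export
pearson_correlation_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("x and y must have nonzero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) == 1) {
    return(list(r = r, t = sign(r) * Inf, df = length(x) - 2L, p = 0,
                degenerate = TRUE))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value, degenerate = FALSE)
}

#' Compare global measures between groups
#'
#' For each global measure (grand means of the raw and non-negative
#' correlation matrices, mean retained correlation of the thresholded
#' matrices, L, C, gamma, lambda, sigma, Q): per-group mean and SD, pooled t,
#' p, significance at `alpha`, and direction. The within-group Pearson test
#' of C against Q is appended as two correlation rows.
#'
#' @param metrics_df Data.frame with columns `subject_id`, `group`, and one
#'   column per measure in `measures`.
#' @param measures Measure columns to compare; defaults to the standard
#'   battery (those present in `metrics_df`).
#' @param alpha Significance threshold for the t-tests; default 0.05.
#' @return Data.frame with `scope` (`global_metric` / `correlation`),
#'   `identifier`, group means/SDs, `t`, `p`, `r`, `significant`,
#'   `direction`.
#' @export
compare_global_metrics <- function(metrics_df,
                                   measures = intersect(
                                     c(GLOBAL_MEASURES, "grand_mean_thresholded"),
                                     names(metrics_df)),
                                   alpha = 0.05) {
  stopifnot(all(c("subject_id", "group") %in% names(metrics_df)))
  a <- metrics_df[metrics_df$group == "control", , drop = FALSE]
  b <- metrics_df[metrics_df$group == "case", , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  rows <- lapply(measures, function(m) {
    tt <- two_sample_t(a[[m]], b[[m]])
    data.frame(scope = "global_metric", identifier = m,
               mean_control = mean(a[[m]]), sd_control = stats::sd(a[[m]]),
               mean_case = mean(b[[m]]), sd_case = stats::sd(b[[m]]),
               t = tt$t, p = tt$p, r = NA_real_,
               significant = tt$p < alpha,
               direction = ifelse(mean(b[[m]]) >= mean(a[[m]]),
                                  "case_higher", "control_higher"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(c("C", "Q") %in% names(metrics_df))) {
    cq <- lapply(list(control = a, case = b), function(gd) {
      ct <- pearson_correlation_test(gd$C, gd$Q)
      data.frame(scope = "correlation",
                 identifier = paste0("C_vs_Q_",
                                     unique(gd$group)),
                 mean_control = NA_real_, sd_control = NA_real_,
                 mean_case = NA_real_, sd_case = NA_real_,
                 t = ct$t, p = ct$p, r = ct$r,
                 significant = ct$p < alpha,
                 direction = NA_character_,
                 stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, cq))
  }
  rownames(out) <- NULL
  out
}

#' Compare node-wise measures between groups
#'
#' Runs the label-permutation test per node within each metric family and
#' applies BH-FDR at `fdr_level` within the family.
#'
#' @param node_matrices Named list of subjects x nodes matrices (e.g., `k`,
#'   `C_i`, `L_i`, `mean_neighbor_distance`).
#' @param labels Group label per subject.
#' @param n_perm Permutations per family; default 5000.
#' @param seed Master seed; each family uses a seed derived from it.
#' @param fdr_level FDR level; default 0.05.
#' @return Long data.frame: `metric`, `node_id`, group means, `t`, `p_perm`,
#'   `q`, `significant`, `direction`.
#' @export
compare_node_metrics <- function(node_matrices, labels, n_perm = 5000L,
                                 seed = 1L, fdr_level = 0.05) {
  stopifnot(is.list(node_matrices), length(names(node_matrices)) ==
              length(node_matrices))
  is1 <- labels == "control"
  out <- lapply(seq_along(node_matrices), function(fam) {
    x <- as.matrix(node_matrices[[fam]])
    # NA per-node values (e.g., path length of an isolated node) are imputed
    # with the node's cross-subject mean so the permutation stays balanced.
    if (anyNA(x)) {
      for (j in which(colSums(is.na(x)) > 0L)) {
        x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
      }
      x[is.na(x)] <- 0
    }
    pt <- permutation_test_nodewise(x, labels, n_perm = n_perm,
                                    seed = derive_seed(seed, fam))
    adj <- fdr_bh(pt$p, q_level = fdr_level)
    m1 <- colMeans(x[is1, , drop = FALSE])
    m2 <- colMeans(x[!is1, , drop = FALSE])
    data.frame(metric = names(node_matrices)[fam],
               node_id = 0:(ncol(x) - 1L),
               mean_control = m1, mean_case = m2,
               t = pt$t, p_perm = pt$p, q = adj$q,
               significant = adj$significant,
               direction = ifelse(m2 >= m1, "case_higher", "control_higher"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
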