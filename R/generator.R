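# Synthetic cohort generator: a latent-factor model of parcellated resting-state
# signals. Each node's series mixes a shared global fluctuation, a module-level
# fluctuation, an optional long-range fluctuation shared by spatially distant
# nodes, and node-specific noise. All latent innovations are AR(1)-smoothed and
# re-standardized to unit variance, so the coupling weights translate directly
# into expected Pearson correlations (see expected_correlation()).

SUBCORTICAL_NAMES <- c("thalamus", "caudate", "putamen", "pallidum",
                       "amygdala", "accumbens", "hippocampus")

#' Configuration for the synthetic cohort generator
#'
#' The defaults encode the study conditions emulated throughout the package:
#' a 110-region parcellation (48 cortical plus 7 subcortical regions per
#' hemisphere), 128 volumes per subject, and a cohort of 16 controls and
#' 14 cases. Case subjects differ from controls in two calibrated ways: a
#' stronger coupling to the shared global signal (raising the cohort-mean
#' pairwise correlation) and a stronger long-range coupling at a subset of
#' nodes placed in spatially distant modules (lengthening the Euclidean
#' distance of their retained connections).
#'
#' @param n_nodes Number of regions; must be even (hemisphere mirroring).
#' @param n_volumes Number of time points per subject.
#' @param n_modules Number of bilateral modules; at most `n_nodes / 2`.
#' @param n_controls,n_cases Group sizes.
#' @param global_coupling_control,global_coupling_case Weight of the shared
#'   global signal per group (g).
#' @param module_coupling Weight of the module-level signal (w).
#' @param longrange_coupling_control,longrange_coupling_case Weight of the
#'   long-range shared signal at flagged nodes (b).
#' @param longrange_node_fraction Fraction of nodes flagged long-range, drawn
#'   from the most spatially separated modules.
#' @param noise_sd Standard deviation of node-specific noise.
#' @param temporal_smoothing AR(1) coefficient in `[0, 1)` applied to every
#'   latent innovation, then re-standardized to unit variance.
#' @param random_seed Master seed; all randomness derives from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_nodes = 110L,
                             n_volumes = 128L,
                             n_modules = 8L,
                             n_controls = 16L,
                             n_cases = 14L,
                             global_coupling_control = 0.3,
                             global_coupling_case = 0.45,
                             module_coupling = 0.8,
                             longrange_coupling_control = 0.3,
                             longrange_coupling_case = 0.9,
                             longrange_node_fraction = 0.15,
                             noise_sd = 1,
                             temporal_smoothing = 0.3,
                             random_seed = 42L) {
  cfg <- list(n_nodes = as.integer(n_nodes),
              n_volumes = as.integer(n_volumes),
              n_modules = as.integer(n_modules),
              n_controls = as.integer(n_controls),
              n_cases = as.integer(n_cases),
              global_coupling_control = global_coupling_control,
              global_coupling_case = global_coupling_case,
              module_coupling = module_coupling,
              longrange_coupling_control = longrange_coupling_control,
              longrange_coupling_case = longrange_coupling_case,
              longrange_node_fraction = longrange_node_fraction,
              noise_sd = noise_sd,
              temporal_smoothing = temporal_smoothing,
              random_seed = as.integer(random_seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_nodes < 2L || cfg$n_nodes %% 2L != 0L) {
    stop("n_nodes must be an even count >= 2 (hemisphere mirroring)", call. = FALSE)
  }
  if (cfg$n_modules < 1L || cfg$n_modules > cfg$n_nodes %/% 2L) {
    stop("n_modules must be between 1 and n_nodes/2", call. = FALSE)
  }
  if (cfg$n_volumes < 2L) stop("n_volumes must be >= 2", call. = FALSE)
  if (cfg$n_controls < 0L || cfg$n_cases < 0L) {
    stop("group sizes must be nonnegative", call. = FALSE)
  }
  for (nm in c("global_coupling_control", "global_coupling_case",
               "module_coupling", "longrange_coupling_control",
               "longrange_coupling_case")) {
    stopifnot_scalar_number(cfg[[nm]], nm, lower = 0)
  }
  stopifnot_scalar_number(cfg$longrange_node_fraction, "longrange_node_fraction",
                          lower = 0, upper = 1)
  stopifnot_scalar_number(cfg$noise_sd, "noise_sd")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  stopifnot_scalar_number(cfg$temporal_smoothing, "temporal_smoothing", lower = 0)
  if (cfg$temporal_smoothing >= 1) {
    stop("temporal_smoothing must be in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a generator configuration from YAML or JSON
#'
#' Field names in the file mirror the arguments of [generator_config()]
#' exactly; missing fields take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown generator config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(generator_config, raw)
}

#' Build the node table for a synthetic parcellation
#'
#' Nodes come in mirrored left/right pairs assigned to bilateral modules.
#' Module centers are placed at distinct positions inside a +/-70 mm box
#' (right-hemisphere x in (0, 70]; the left centroid mirrors x). Node
#' centroids are the module center plus isotropic jitter (sd 8 mm), shared
#' within a pair and mirrored in x. A fraction of nodes, taken from the most
#' spatially separated modules, is flagged long-range. With the default
#' 55 pairs, the last 7 pairs carry subcortical names (thalamus, caudate,
#' putamen, pallidum, amygdala, accumbens, hippocampus); the rest are
#' `cortical_NN`.
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns `node_id` (0-based), `name`,
#'   `hemisphere`, `module_id`, `longrange_flag`, `x_mm`, `y_mm`, `z_mm`.
#' @export
make_node_table <- function(config) {
  validate_generator_config(config)
  n <- config$n_nodes
  n_pairs <- n %/% 2L
  m <- config$n_modules

  withr::with_seed(config$random_seed, {
    centers <- sample_module_centers(m)
    jitter <- matrix(stats::rnorm(3L * n_pairs, sd = 8), ncol = 3L)
  })

  # Contiguous, near-equal blocks of pairs per module.
  pair_module <- sort(rep_len(seq_len(m), n_pairs))

  pair_names <- if (n_pairs >= length(SUBCORTICAL_NAMES) + 1L) {
    c(sprintf("cortical_%02d", seq_len(n_pairs - length(SUBCORTICAL_NAMES))),
      SUBCORTICAL_NAMES)
  } else {
    sprintf("region_%02d", seq_len(n_pairs))
  }

  long_pairs <- flag_longrange_pairs(centers, pair_module,
                                     config$longrange_node_fraction, n)

  pair_xyz <- centers[pair_module, , drop = FALSE] + jitter
  # Interleave left/right: pair p occupies node ids 2p-2 (L) and 2p-1 (R).
  tab <- data.frame(
    node_id = 0:(n - 1L),
    name = paste0(rep(pair_names, each = 2L), rep(c("_L", "_R"), n_pairs)),
    hemisphere = rep(c("L", "R"), n_pairs),
    module_id = rep(pair_module, each = 2L),
    longrange_flag = rep(long_pairs, each = 2L),
    x_mm = as.vector(rbind(-pair_xyz[, 1L], pair_xyz[, 1L])),
    y_mm = rep(pair_xyz[, 2L], each = 2L),
    z_mm = rep(pair_xyz[, 3L], each = 2L),
    stringsAsFactors = FALSE
  )
  tab
}

# Distinct module centers in the right hemisphere: x in [15, 65], y/z in
# [-70, 70], resampled until all pairwise distances are >= 30 mm.
sample_module_centers <- function(m, min_sep = 30, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    centers <- cbind(stats::runif(m, 15, 65),
                     stats::runif(m, -70, 70),
                     stats::runif(m, -70, 70))
    if (m == 1L || min(stats::dist(centers)) >= min_sep) return(centers)
  }
  stop("could not place distinct module centers; too many modules for the box",
       call. = FALSE)
}

# Flag whole pairs spread across a mutually distant set of modules (greedy
# max-min selection over module-center distances, round-robin allocation), so
# that every flagged node gains distant partners when long-range coupling
# rises and its retained connections lengthen.
flag_longrange_pairs <- function(centers, pair_module, fraction, n_nodes) {
  n_pairs <- length(pair_module)
  n_long_pairs <- round(fraction * n_nodes / 2)
  flags <- rep(FALSE, n_pairs)
  if (n_long_pairs == 0L) return(flags)
  m <- nrow(centers)
  if (m == 1L) {
    flags[seq_len(min(n_long_pairs, n_pairs))] <- TRUE
    return(flags)
  }
  d <- as.matrix(stats::dist(centers))
  n_spread <- max(2L, min(m, n_long_pairs, 4L))
  # Greedy max-min: seed with the farthest module pair, then add the module
  # maximizing its minimum distance to the chosen set.
  start <- which(d == max(d), arr.ind = TRUE)[1L, ]
  chosen <- as.integer(start)
  while (length(chosen) < n_spread) {
    rest <- setdiff(seq_len(m), chosen)
    min_d <- apply(d[rest, chosen, drop = FALSE], 1L, min)
    chosen <- c(chosen, rest[which.max(min_d)])
  }
  flagged <- 0L
  repeat {
    progressed <- FALSE
    for (mod in chosen) {
      if (flagged >= n_long_pairs) break
      idx <- which(pair_module == mod & !flags)
      if (length(idx) > 0L) {
        flags[idx[1L]] <- TRUE
        flagged <- flagged + 1L
        progressed <- TRUE
      }
    }
    if (flagged >= n_long_pairs || !progressed) break
  }
  if (flagged < n_long_pairs) {
    # Chosen modules exhausted; fill from the remaining pairs in id order.
    idx <- which(!flags)
    flags[idx[seq_len(min(length(idx), n_long_pairs - flagged))]] <- TRUE
  }
  flags
}

# Unit-variance AR(1) series: white innovations recursively filtered with
# coefficient phi from a stationary start, then scaled by sqrt(1 - phi^2).
ar1_unit <- function(n, phi) {
  e <- stats::rnorm(n)
  if (phi == 0) return(e)
  init <- stats::rnorm(1L) / sqrt(1 - phi^2)
  as.numeric(stats::filter(e, phi, method = "recursive", init = init)) *
    sqrt(1 - phi^2)
}

#' Simulate one subject's region-by-time signal matrix
#'
#' Node i's series is
#' `x_i(t) = g * s(t) + w * u_m(i)(t) + b * rho_i * v(t) + noise_sd * e_i(t)`
#' where `s` (global), `u_c` (one per module), `v` (long-range) and `e_i`
#' are mutually independent unit-variance AR(1)-smoothed innovations,
#' `rho_i` is the node's long-range flag, and `g`, `b` take the group's
#' values from the configuration.
#'
#' @param config A [generator_config()].
#' @param node_table Output of [make_node_table()].
#' @param group `"control"` or `"case"`.
#' @param seed Integer seed; the subject is deterministic given it.
#' @param subject_id Optional identifier stored in the record.
#' @return A list of class `subject_record` with fields `subject_id`,
#'   `group`, `seed` and `series` (n_nodes x n_volumes matrix).
#' @export
simulate_subject <- function(config, node_table, group, seed,
                             subject_id = paste0(group, "_", seed)) {
  validate_generator_config(config)
  if (!group %in% c("control", "case")) {
    stop("unknown group label: ", group, call. = FALSE)
  }
  n <- config$n_nodes
  tt <- config$n_volumes
  phi <- config$temporal_smoothing
  g <- if (group == "control") config$global_coupling_control else config$global_coupling_case
  b <- if (group == "control") config$longrange_coupling_control else config$longrange_coupling_case
  w <- config$module_coupling
  rho <- as.numeric(node_table$longrange_flag)
  mod <- node_table$module_id

  series <- withr::with_seed(seed, {
    s <- ar1_unit(tt, phi)
    u <- t(vapply(seq_len(config$n_modules), function(c) ar1_unit(tt, phi),
                  numeric(tt)))
    v <- ar1_unit(tt, phi)
    eps <- t(vapply(seq_len(n), function(i) ar1_unit(tt, phi), numeric(tt)))
    g * matrix(s, n, tt, byrow = TRUE) +
      w * u[mod, , drop = FALSE] +
      (b * rho) %o% v +
      config$noise_sd * eps
  })
  rownames(series) <- node_table$name
  structure(list(subject_id = subject_id, group = group, seed = as.integer(seed),
                 series = series),
            class = "subject_record")
}

#' Simulate a full two-group cohort
#'
#' Controls come first, then cases; each subject's seed derives from the
#' configuration's `random_seed` by a fixed scheme, so the cohort is exactly
#' reproducible.
#'
#' @param config A [generator_config()].
#' @return A list of class `fc_cohort` with `subjects` (list of
#'   `subject_record`), `node_table`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  validate_generator_config(config)
  node_table <- make_node_table(config)
  groups <- c(rep("control", config$n_controls), rep("case", config$n_cases))
  ids <- c(sprintf("control_%02d", seq_len(config$n_controls)),
           sprintf("case_%02d", seq_len(config$n_cases)))
  subjects <- lapply(seq_along(groups), function(i) {
    simulate_subject(config, node_table, groups[i],
                     seed = stage_seed(config$random_seed, "simulate", i),
                     subject_id = ids[i])
  })
  structure(list(subjects = subjects, node_table = node_table, config = config),
            class = "fc_cohort")
}

#' Expected pairwise correlation under the generator model
#'
#' Closed form for the correlation of two distinct nodes' series before
#' global-signal removal:
#' `(g^2 + w^2 * same_module + b^2 * rho_i * rho_j) / sqrt((g^2 + w^2 + b^2 * rho_i + s^2) (g^2 + w^2 + b^2 * rho_j + s^2))`
#' with `s = noise_sd`. Global-signal removal changes correlations; use
#' [expected_correlation_empirical()] for the post-removal oracle.
#'
#' @param config A [generator_config()].
#' @param node_table Output of [make_node_table()].
#' @param i,j 0-based node ids, `i != j`.
#' @param group `"control"` or `"case"`.
#' @return Expected Pearson correlation.
#' @export
expected_correlation <- function(config, node_table, i, j, group) {
  if (i == j) stop("expected_correlation is undefined for i == j", call. = FALSE)
  if (!group %in% c("control", "case")) {
    stop("unknown group label: ", group, call. = FALSE)
  }
  g <- if (group == "control") config$global_coupling_control else config$global_coupling_case
  b <- if (group == "control") config$longrange_coupling_control else config$longrange_coupling_case
  w <- config$module_coupling
  ri <- node_table[node_table$node_id == i, ]
  rj <- node_table[node_table$node_id == j, ]
  if (nrow(ri) != 1L || nrow(rj) != 1L) stop("node id out of range", call. = FALSE)
  same_mod <- as.numeric(ri$module_id == rj$module_id)
  rho_i <- as.numeric(ri$longrange_flag)
  rho_j <- as.numeric(rj$longrange_flag)
  num <- g^2 + w^2 * same_mod + b^2 * rho_i * rho_j
  den <- sqrt((g^2 + w^2 + b^2 * rho_i + config$noise_sd^2) *
              (g^2 + w^2 + b^2 * rho_j + config$noise_sd^2))
  if (den == 0) return(0)
  num / den
}

#' Empirical correlation oracle at large T
#'
#' Simulates one long subject (default 1e5 volumes), optionally applies
#' global-signal removal, and returns the full Pearson correlation matrix.
#' Used to calibrate the generator: without removal it converges on
#' [expected_correlation()]; with removal it is the post-removal reference.
#'
#' @param config A [generator_config()].
#' @param node_table Output of [make_node_table()].
#' @param group `"control"` or `"case"`.
#' @param n_volumes Simulation length.
#' @param seed Seed for the simulated subject.
#' @param remove_global Apply global-signal removal before correlating.
#' @return n_nodes x n_nodes correlation matrix.
#' @export
expected_correlation_empirical <- function(config, node_table, group,
                                           n_volumes = 1e5, seed = 1L,
                                           remove_global = TRUE) {
  cfg <- config
  cfg$n_volumes <- as.integer(n_volumes)
  rec <- simulate_subject(cfg, node_table, group, seed = seed,
                          subject_id = "oracle")
  x <- demean(rec$series)
  if (remove_global) x <- remove_global_signal(x)
  stats::cor(t(x))
}
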