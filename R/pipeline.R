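# End-to-end orchestration: simulate (or load) a cohort, build connectivity
# matrices and binary networks, compute topological and spatial metrics, and
# run the group comparisons. Every stage's randomness derives from one master
# seed by a fixed scheme, so a run is exactly reproducible and stages can be
# re-run in isolation.

#' Pipeline run configuration
#'
#' @param generator A [generator_config()] for a simulated cohort, or a path
#'   to a `manifest.json` of an existing cohort.
#' @param density Edge density for proportional thresholding; default 0.20.
#' @param hub_set_size Hub set size; default 15.
#' @param seed_node Seed region for the connection profile: a node name
#'   (default `"caudate_R"`, the right-caudate analog of the default node
#'   table) or a 0-based node id.
#' @param n_perm Permutations for node-wise tests; default 5000.
#' @param fdr_level FDR level; default 0.05.
#' @param benchmark_realizations Random benchmark graphs per subject;
#'   default 100.
#' @param remove_global_signal Apply global-signal removal before
#'   correlating; default `TRUE`. The pre-removal grand mean is recorded
#'   either way.
#' @param output_dir Directory for all artifacts.
#' @param master_seed Master seed for benchmark, Louvain and permutation
#'   stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       density = 0.20,
                       hub_set_size = 15L,
                       seed_node = "caudate_R",
                       n_perm = 5000L,
                       fdr_level = 0.05,
                       benchmark_realizations = 100L,
                       remove_global_signal = TRUE,
                       output_dir = tempfile("fcnet_run_"),
                       master_seed = 1L) {
  if (!inherits(generator, "generator_config") && !is.character(generator)) {
    stop("generator must be a generator_config or a manifest path", call. = FALSE)
  }
  if (density <= 0 || density > 1) stop("density must be in (0, 1]", call. = FALSE)
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must be in (0, 1)", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (benchmark_realizations < 1L) stop("benchmark_realizations must be >= 1", call. = FALSE)
  structure(list(generator = generator, density = density,
                 hub_set_size = as.integer(hub_set_size),
                 seed_node = seed_node, n_perm = as.integer(n_perm),
                 fdr_level = fdr_level,
                 benchmark_realizations = as.integer(benchmark_realizations),
                 remove_global_signal = isTRUE(remove_global_signal),
                 output_dir = output_dir,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level fields mirror [run_config()] arguments; the `generator` field
#' may be a nested mapping of [generator_config()] fields or a manifest
#' path.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$generator) && is.list(raw$generator)) {
    raw$generator <- do.call(generator_config, raw$generator)
  }
  do.call(run_config, raw)
}

#' Per-subject connectivity for a whole cohort
#'
#' For each subject: demean, optionally remove the global signal, build the
#' raw correlation matrix, its non-negative variant and the thresholded
#' binary network, and summarize grand means. The grand mean of the raw
#' correlations computed before global-signal removal is recorded alongside
#' (`grand_mean_preremoval`), since removal annihilates any signal component
#' loaded equally on all nodes.
#'
#' @param cohort An `fc_cohort`.
#' @param density Edge density for thresholding.
#' @param remove_global Apply global-signal removal; default `TRUE`.
#' @return List with `summary` (one row per subject: grand means, threshold
#'   value, mean retained correlation, edge counts), `networks` (list of
#'   `binary_network`), `raw_cms` (list of `connectivity_matrix`), `groups`.
#' @export
cohort_connectivity <- function(cohort, density = 0.20, remove_global = TRUE) {
  stopifnot(inherits(cohort, "fc_cohort"))
  res <- lapply(cohort$subjects, function(rec) {
    x <- demean(rec$series)
    cm_pre <- correlation_matrix(x, rec$subject_id)
    if (remove_global) x <- remove_global_signal(x)
    cm <- correlation_matrix(x, rec$subject_id)
    nn <- zero_negatives(cm)
    net <- threshold_by_density(cm, density)
    ret <- retained_correlation_summary(cm, density)
    list(summary = data.frame(subject_id = rec$subject_id, group = rec$group,
                              grand_mean_preremoval = grand_mean(cm_pre),
                              grand_mean_raw = grand_mean(cm),
                              grand_mean_nonnegative = grand_mean(nn),
                              grand_mean_thresholded = ret$mean_retained,
                              threshold_r = ret$threshold_value,
                              n_edges = net$n_edges,
                              edge_density = net$edge_density,
                              stringsAsFactors = FALSE),
         network = net, raw_cm = cm)
  })
  list(summary = do.call(rbind, lapply(res, `[[`, "summary")),
       networks = lapply(res, `[[`, "network"),
       raw_cms = lapply(res, `[[`, "raw_cm"),
       groups = vapply(cohort$subjects, function(s) s$group, ""))
}

#' Topological metrics for a whole cohort
#'
#' @param connectivity Output of [cohort_connectivity()].
#' @param master_seed Master seed; each subject's benchmark/Louvain seed
#'   derives from it.
#' @param benchmark_realizations Random graphs per subject benchmark.
#' @return List with `global` (one row per subject: L, C, gamma, lambda,
#'   sigma, Q), `per_node` (long data.frame), and node matrices `k`, `C_i`,
#'   `L_i`, `sigma_i` (subjects x nodes).
#' @export
cohort_graph_metrics <- function(connectivity, master_seed = 1L,
                                 benchmark_realizations = 100L) {
  nets <- connectivity$networks
  metrics <- lapply(seq_along(nets), function(i) {
    subject_metrics(nets[[i]], n_realizations = benchmark_realizations,
                    seed = stage_seed(master_seed, "benchmark", i))
  })
  global <- do.call(rbind, lapply(seq_along(metrics), function(i) {
    m <- metrics[[i]]
    data.frame(subject_id = m$subject_id,
               group = connectivity$groups[i],
               L = m$L, C = m$C, gamma = m$gamma, lambda = m$lambda,
               sigma = m$sigma, Q = m$Q, stringsAsFactors = FALSE)
  }))
  per_node <- do.call(rbind, lapply(seq_along(metrics), function(i) {
    cbind(data.frame(subject_id = metrics[[i]]$subject_id,
                     group = connectivity$groups[i],
                     stringsAsFactors = FALSE),
          metrics[[i]]$per_node)
  }))
  mat_of <- function(col) {
    do.call(rbind, lapply(metrics, function(m) m$per_node[[col]]))
  }
  list(global = global, per_node = per_node,
       k = mat_of("k"), C_i = mat_of("C_i"), L_i = mat_of("L_i"),
       sigma_i = mat_of("sigma_i"))
}

resolve_seed_node <- function(seed_node, node_table) {
  if (is.character(seed_node)) {
    hit <- node_table$node_id[node_table$name == seed_node]
    if (length(hit) != 1L) {
      stop("seed node name not found in node table: ", seed_node, call. = FALSE)
    }
    return(hit)
  }
  id <- as.integer(seed_node)
  if (!id %in% node_table$node_id) stop("seed node id out of range", call. = FALSE)
  id
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> connectivity -> topological and spatial metrics
#' -> group comparisons -> hub and seed profiling, writing all tables as TSV
#' under `config$output_dir` plus a JSON report. All tabular outputs are
#' bit-reproducible given the same configuration (the report additionally
#' records per-stage elapsed time, which is not).
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly; also written as `report.json`
#'   and `report.txt`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  elapsed <- c()
  timer <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    list(res = res, dt = proc.time()[["elapsed"]] - t0)
  }
  log_stage <- function(stage, ...) {
    message(sprintf("[fcnet] stage=%s %s", stage, sprintf(...)))
  }

  # --- cohort -------------------------------------------------------------
  st <- timer({
    if (is.character(config$generator)) {
      cohort <- load_cohort(config$generator)
      log_stage("load", "manifest=%s subjects=%d", config$generator,
                length(cohort$subjects))
    } else {
      cohort <- simulate_cohort(config$generator)
      write_cohort(cohort, file.path(out, "cohort"))
      log_stage("simulate", "seed=%d subjects=%d nodes=%d",
                config$generator$random_seed, length(cohort$subjects),
                nrow(cohort$node_table))
    }
    cohort
  })
  cohort <- st$res
  elapsed["cohort"] <- st$dt
  groups <- vapply(cohort$subjects, function(s) s$group, "")
  warnings_log <- character(0)

  # --- connectivity -------------------------------------------------------
  st <- timer(withCallingHandlers(
    cohort_connectivity(cohort, density = config$density,
                        remove_global = config$remove_global_signal),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  conn <- st$res
  elapsed["connectivity"] <- st$dt
  write_tsv(conn$summary, file.path(out, "connectivity_summary.tsv"))
  net_dir <- file.path(out, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (net in conn$networks) {
    write_edge_list(net, file.path(net_dir, paste0(net$subject_id, "_edges.tsv")))
  }
  log_stage("connectivity", "subjects=%d edges_per_subject=%d",
            nrow(conn$summary), conn$networks[[1L]]$n_edges)

  # --- topological metrics ------------------------------------------------
  st <- timer(cohort_graph_metrics(conn, master_seed = config$master_seed,
                                   benchmark_realizations = config$benchmark_realizations))
  gm <- st$res
  elapsed["graph_metrics"] <- st$dt
  write_tsv(gm$global, file.path(out, "global_metrics.tsv"))
  write_tsv(gm$per_node, file.path(out, "node_metrics.tsv"))
  log_stage("graph_metrics", "benchmark_realizations=%d seed=%d",
            config$benchmark_realizations, config$master_seed)

  # --- spatial metrics ----------------------------------------------------
  st <- timer({
    ed <- do.call(rbind, lapply(conn$networks, function(net) {
      neighbor_mean_distance(net, cohort$node_table)$mean_neighbor_distance
    }))
    ed
  })
  ed_matrix <- st$res
  elapsed["spatial"] <- st$dt

  # --- group comparisons --------------------------------------------------
  st <- timer({
    global_in <- merge(conn$summary[, c("subject_id", "group", "grand_mean_raw",
                                        "grand_mean_nonnegative",
                                        "grand_mean_thresholded")],
                       gm$global, by = c("subject_id", "group"), sort = FALSE)
    global_cmp <- compare_global_metrics(global_in)
    node_cmp <- compare_node_metrics(
      list(k = gm$k, C_i = gm$C_i, L_i = gm$L_i, sigma_i = gm$sigma_i,
           mean_neighbor_distance = ed_matrix),
      labels = groups, n_perm = config$n_perm,
      seed = stage_seed(config$master_seed, "permutation"),
      fdr_level = config$fdr_level)
    node_cmp <- merge(node_cmp,
                      cohort$node_table[, c("node_id", "name")],
                      by = "node_id", sort = FALSE)
    node_cmp <- node_cmp[order(match(node_cmp$metric, unique(node_cmp$metric)),
                               node_cmp$node_id), ]
    list(global_cmp = global_cmp, node_cmp = node_cmp)
  })
  cmp <- st$res
  elapsed["comparison"] <- st$dt
  write_tsv(cmp$global_cmp, file.path(out, "global_comparison.tsv"))
  write_tsv(cmp$node_cmp, file.path(out, "node_comparison.tsv"))
  log_stage("comparison", "n_perm=%d fdr_level=%g", config$n_perm,
            config$fdr_level)

  # --- hubs and seed profile ----------------------------------------------
  st <- timer({
    hub_freq <- hub_frequency(gm$k, groups, config$hub_set_size)
    hub_freq <- merge(hub_freq, cohort$node_table[, c("node_id", "name")],
                      by = "node_id", sort = FALSE)
    hub_tab <- do.call(rbind, lapply(c("control", "case"), function(grp) {
      mean_k <- colMeans(gm$k[groups == grp, , drop = FALSE])
      hubs <- top_hubs(mean_k, config$hub_set_size)
      data.frame(group = grp, rank = seq_len(config$hub_set_size),
                 node_id = hubs,
                 name = cohort$node_table$name[match(hubs, cohort$node_table$node_id)],
                 mean_k = mean_k[hubs + 1L], stringsAsFactors = FALSE)
    }))
    seed_id <- resolve_seed_node(config$seed_node, cohort$node_table)
    prof <- seed_profile(conn$networks, groups, seed_id)
    zt <- seed_frequency_z(prof)
    prof_df <- as.data.frame(prof)
    prof_df$name <- cohort$node_table$name[match(prof_df$node_id,
                                                 cohort$node_table$node_id)]
    zt$name <- cohort$node_table$name[match(zt$node_id, cohort$node_table$node_id)]
    list(hub_freq = hub_freq, hub_tab = hub_tab, prof = prof_df, zt = zt,
         seed_id = seed_id)
  })
  hubs <- st$res
  elapsed["hubs_seed"] <- st$dt
  write_tsv(hubs$hub_freq, file.path(out, "hub_frequency.tsv"))
  write_tsv(hubs$hub_tab, file.path(out, "hub_table.tsv"))
  write_tsv(hubs$prof, file.path(out, "seed_profile.tsv"))
  write_tsv(hubs$zt, file.path(out, "seed_z.tsv"))
  log_stage("hubs_seed", "seed_node=%d hub_set_size=%d", hubs$seed_id,
            config$hub_set_size)

  # --- report -------------------------------------------------------------
  cfg_echo <- unclass(config)
  if (inherits(cfg_echo$generator, "generator_config")) {
    cfg_echo$generator <- unclass(cfg_echo$generator)
  }
  report <- list(
    config = cfg_echo,
    n_subjects = length(cohort$subjects),
    n_nodes = nrow(cohort$node_table),
    stage_rows = list(connectivity_summary = nrow(conn$summary),
                      global_metrics = nrow(gm$global),
                      node_metrics = nrow(gm$per_node),
                      global_comparison = nrow(cmp$global_cmp),
                      node_comparison = nrow(cmp$node_cmp),
                      hub_frequency = nrow(hubs$hub_freq),
                      seed_profile = nrow(hubs$prof),
                      seed_z = nrow(hubs$zt)),
    files = c("connectivity_summary.tsv", "global_metrics.tsv",
              "node_metrics.tsv", "global_comparison.tsv",
              "node_comparison.tsv", "hub_frequency.tsv", "hub_table.tsv",
              "seed_profile.tsv", "seed_z.tsv"),
    warnings = warnings_log,
    version = as.character(utils::packageVersion("fcnet")),
    elapsed_sec = as.list(round(elapsed, 3))
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  summary_lines <- c(
    "fcnet pipeline run",
    sprintf("subjects: %d (%d control, %d case); nodes: %d",
            report$n_subjects, sum(groups == "control"), sum(groups == "case"),
            report$n_nodes),
    sprintf("edge density: %.3f (%d edges/subject)", config$density,
            conn$networks[[1L]]$n_edges),
    sprintf("global measures flagged significant: %s",
            paste(cmp$global_cmp$identifier[cmp$global_cmp$significant],
                  collapse = ", ")),
    sprintf("node-wise discoveries at FDR %.2f: %d", config$fdr_level,
            sum(cmp$node_cmp$significant)),
    sprintf("seed node %d: %d case-specific, %d control-specific, %d shared",
            hubs$seed_id, sum(hubs$prof$status == "case_specific"),
            sum(hubs$prof$status == "control_specific"),
            sum(hubs$prof$status == "shared"))
  )
  writeLines(summary_lines, file.path(out, "report.txt"))
  report$global_comparison <- cmp$global_cmp
  report$node_comparison <- cmp$node_cmp
  report$hub_frequency <- hubs$hub_freq
  report$hub_table <- hubs$hub_tab
  report$seed_profile <- hubs$prof
  report$seed_z <- hubs$zt
  report$connectivity_summary <- conn$summary
  report$global_metrics <- gm$global
  invisible(report)
}
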