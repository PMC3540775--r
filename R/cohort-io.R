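# On-disk cohort format: one tab-separated series file per subject (rows =
# nodes, columns = volumes, no header), a node table TSV, and a JSON manifest
# binding subject ids to group labels and files. Numbers carry 17 significant
# digits so a written cohort reads back losslessly.

#' Write a cohort to a directory
#'
#' @param cohort An `fc_cohort` (from [simulate_cohort()] or [load_cohort()]).
#' @param dir Output directory; created if needed.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  node_path <- file.path(dir, "node_table.tsv")
  node_out <- cohort$node_table
  for (col in c("x_mm", "y_mm", "z_mm")) {
    node_out[[col]] <- format_full(node_out[[col]])
  }
  write_tsv(node_out, node_path)
  entries <- lapply(cohort$subjects, function(rec) {
    file <- paste0(rec$subject_id, ".tsv")
    mat <- apply(rec$series, c(1L, 2L), format_full)
    utils::write.table(mat, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    list(subject_id = rec$subject_id, group = rec$group, file = file,
         seed = if (is.null(rec$seed)) NA_integer_ else rec$seed)
  })
  manifest <- list(
    groups = list(control = "control", case = "case"),
    node_table = "node_table.tsv",
    subjects = entries
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}

#' Load a cohort from a manifest
#'
#' Validates every series file against the node table (row count, numeric,
#' finite) and maps the manifest's two declared group labels onto
#' control/case. Any other label, a duplicate subject id, or an empty
#' manifest is an error.
#'
#' @param manifest_path Path to `manifest.json` written by [write_cohort()]
#'   (or hand-authored in the same schema).
#' @return An `fc_cohort`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  if (is.null(manifest$subjects) || length(manifest$subjects) == 0L) {
    stop("manifest lists no subjects", call. = FALSE)
  }
  if (is.null(manifest$groups) || length(manifest$groups) != 2L ||
      !setequal(names(manifest$groups), c("control", "case"))) {
    stop("manifest must declare exactly two group labels under 'groups' ",
         "(control and case)", call. = FALSE)
  }
  label_map <- c(stats::setNames("control", manifest$groups$control),
                 stats::setNames("case", manifest$groups$case))

  node_path <- file.path(dir, manifest$node_table)
  if (!file.exists(node_path)) {
    stop("node table not found: ", node_path, call. = FALSE)
  }
  node_table <- read_tsv(node_path)
  required <- c("node_id", "name", "hemisphere", "module_id", "longrange_flag",
                "x_mm", "y_mm", "z_mm")
  if (!all(required %in% names(node_table))) {
    stop("node table is missing columns: ",
         paste(setdiff(required, names(node_table)), collapse = ", "),
         call. = FALSE)
  }
  n_nodes <- nrow(node_table)

  ids <- vapply(manifest$subjects, function(e) as.character(e$subject_id), "")
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id in manifest: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  raw_labels <- vapply(manifest$subjects, function(e) as.character(e$group), "")
  unknown <- setdiff(unique(raw_labels), names(label_map))
  if (length(unknown) > 0L) {
    stop("manifest group label(s) not declared under 'groups': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  subjects <- lapply(manifest$subjects, function(e) {
    path <- file.path(dir, e$file)
    if (!file.exists(path)) {
      stop("series file not found: ", path, call. = FALSE)
    }
    mat <- tryCatch(
      as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                  colClasses = "numeric")),
      error = function(err) {
        stop(sprintf("series file %s is not numeric: %s", path,
                     conditionMessage(err)), call. = FALSE)
      })
    if (nrow(mat) != n_nodes) {
      stop(sprintf("series file %s has %d rows; node table has %d nodes",
                   path, nrow(mat), n_nodes), call. = FALSE)
    }
    if (!all(is.finite(mat))) {
      bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
      stop(sprintf("series file %s has a non-finite value at row %d, column %d",
                   path, bad[1L], bad[2L]), call. = FALSE)
    }
    dimnames(mat) <- list(node_table$name, NULL)
    structure(list(subject_id = as.character(e$subject_id),
                   group = unname(label_map[as.character(e$group)]),
                   seed = if (is.null(e$seed) || is.na(suppressWarnings(as.integer(e$seed)))) NA_integer_ else as.integer(e$seed),
                   series = mat),
              class = "subject_record")
  })

  n_vol <- unique(vapply(subjects, function(s) ncol(s$series), 0L))
  if (length(n_vol) != 1L) {
    stop("subjects have differing numbers of volumes: ",
         paste(n_vol, collapse = ", "), call. = FALSE)
  }
  structure(list(subjects = subjects, node_table = node_table, config = NULL),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$group, "")
  cat(sprintf("fc_cohort: %d subjects (%d control, %d case), %d nodes, %d volumes\n",
              length(x$subjects), sum(groups == "control"), sum(groups == "case"),
              nrow(x$node_table), ncol(x$subjects[[1L]]$series)))
  invisible(x)
}
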