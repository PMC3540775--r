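# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Derive a stage- or subject-level seed from a master seed. Offsets are fixed so
# individual stages can be re-run in isolation; results stay below 2^31 - 1.
derive_seed <- function(master_seed, offset) {
  as.integer((as.numeric(master_seed) %% 1e6 + 1009 * as.numeric(offset)) %% 2147483647)
}

STAGE_OFFSETS <- c(simulate = 1L, benchmark = 100000L, louvain = 200000L,
                   permutation = 300000L)

stage_seed <- function(master_seed, stage, index = 0L) {
  offset <- STAGE_OFFSETS[[stage]]
  derive_seed(master_seed, offset + index)
}

# Upper-triangle (i < j) index pairs of an n x n matrix, as a 2-column matrix.
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

upper_values <- function(m) {
  m[upper.tri(m)]
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Numbers are written with 17 significant digits so that series round-trip
# through text losslessly.
format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}
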