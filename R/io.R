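#' Write an abundance or count matrix as TSV
#'
#' Tab-separated, first column `taxon` holding the taxon identifier, one
#' column per sample named `<subject>_<group>_<timepoint>`.  Integer count
#' matrices round-trip losslessly through [read_matrix_tsv()].
#'
#' @param mat Taxa x samples matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(taxon = rownames(mat) %||% taxon_ids(nrow(mat)),
                   unclass(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance or count matrix from TSV
#'
#' @param path File written by [write_matrix_tsv()] (or any taxa x samples
#'   TSV whose first column is the taxon identifier).
#' @return Numeric matrix with taxon rownames; integer when all entries
#'   are whole numbers.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (all(mat == round(mat))) storage.mode(mat) <- "integer"
  mat
}

#' Write a square distance matrix as TSV
#'
#' @param d A [stats::dist] or square matrix over samples.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Snapshot a configuration to JSON
#'
#' @param config A [default_config()] list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a configuration snapshot
#'
#' Unknown keys are rejected, so a snapshot always reproduces a valid
#' configuration.
#'
#' @param path JSON file written by [write_config()].
#' @return A `"compo_config"` list.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, vals)
}

#' Write experiment results as long-format TSV files
#'
#' Writes `errors.tsv` (one row per scenario x iteration x representation)
#' and, when present, `variance.tsv` (one row per scenario x iteration x
#' representation x metric), plus a `config.json` snapshot, into a
#' directory.
#'
#' @param experiment A `"compo_experiment"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "compo_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(experiment$errors, file.path(dir, "errors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(experiment$variance)) {
    utils::write.table(experiment$variance, file.path(dir, "variance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_config(experiment$config, file.path(dir, "config.json"))
  meta <- list(direction = experiment$direction,
               n_iterations = experiment$n_iterations,
               seed = experiment$seed)
  jsonlite::write_json(meta, file.path(dir, "run.json"), auto_unbox = TRUE)
  invisible(dir)
}
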