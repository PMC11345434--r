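#' Write / read a labelled matrix as TSV
#'
#' Matrices are stored as tab-separated text with a header row of region ids
#' and one row per matrix row (row ids in the first column). Values are
#' written with 17 significant digits so a write/read round trip is exact.
#'
#' @param m numeric matrix with region ids as dimnames (or supply
#'   `region_ids`).
#' @param path file path.
#' @param region_ids optional labels overriding the dimnames.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the labelled matrix.
#' @export
write_matrix_tsv <- function(m, path, region_ids = NULL) {
  if (!is.matrix(m) || length(m) == 0)
    stop("`m` must be a non-empty matrix", call. = FALSE)
  if (!is.null(region_ids)) dimnames(m) <- list(region_ids, region_ids)
  if (is.null(colnames(m)))
    dimnames(m) <- rep(list(sprintf("n%02d", seq_len(ncol(m)))), 2)
  df <- data.frame(id = rownames(m),
                   apply(m, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE)
  names(df) <- c("id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file has no value columns", call. = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)) || anyDuplicated(ids))
    stop("duplicated region id in matrix header", call. = FALSE)
  if (nrow(m) != ncol(m) || !identical(as.character(ids), colnames(m)))
    stop("matrix header/shape mismatch: rows and columns must carry the same ",
         "ids in the same order", call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write / read a region time series with a metadata sidecar
#'
#' The series is stored as TSV (header of region ids, one row per sample) and
#' the metadata (`dt`, optional `seed`) in a YAML sidecar at `<path>.yaml`.
#'
#' @param ts a [region_ts()].
#' @param path file path for the TSV.
#' @param seed optional seed to record in the sidecar.
#' @return `write_region_ts` returns `path` invisibly; `read_region_ts`
#'   returns a [region_ts()].
#' @export
write_region_ts <- function(ts, path, seed = NULL) {
  stopifnot(inherits(ts, "region_ts"))
  df <- as.data.frame(apply(ts$values, 2, function(x) sprintf("%.17g", x)))
  names(df) <- ts$region_ids
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(dt = ts$dt, n_samples = nrow(ts$values))
  if (!is.null(seed)) meta$seed <- seed
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_region_ts
#' @export
read_region_ts <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  region_ts(as.matrix(df), dt = meta$dt, region_ids = colnames(df))
}

#' Write a run manifest
#'
#' Records the configuration snapshot, per-stage seeds, package version, stage
#' timings and output files of a pipeline run as YAML — enough to re-run the
#' deterministic stages bit-identically.
#'
#' @param manifest named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$software_version <-
    as.character(utils::packageVersion("hopfec"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}
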