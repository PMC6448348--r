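# Plain-text serialization: leadfields and epochs as CSV, cluster results
# as JSON. CSV keeps the artifacts portable and diffable; large recordings
# should be regenerated from seeds rather than stored.

#' Write a leadfield to a directory of CSV files
#'
#' Writes `L.csv` (gain matrix), `sensors.csv`, `vertices.csv` (positions +
#' orientations) and `roi.csv` (vertex indices).
#'
#' @param lf a `leadfield`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_leadfield_csv <- function(lf, dir) {
  stopifnot(inherits(lf, "leadfield"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(lf$L, file.path(dir, "L.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(lf$geometry$sensor_positions),
                   file.path(dir, "sensors.csv"), row.names = FALSE)
  vdf <- cbind(as.data.frame(lf$geometry$vertex_positions),
               as.data.frame(lf$geometry$vertex_orientations))
  names(vdf) <- c("x", "y", "z", "ox", "oy", "oz")
  utils::write.csv(vdf, file.path(dir, "vertices.csv"), row.names = FALSE)
  utils::write.csv(data.frame(roi = lf$geometry$roi_vertices),
                   file.path(dir, "roi.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a leadfield written by [write_leadfield_csv()]
#'
#' Also accepts a bare gain-matrix CSV (a single `L.csv`-style file path)
#' when no geometry is needed, in which case sensor/vertex positions are
#' absent and downstream geometric operations are unavailable.
#'
#' @param path directory (full geometry) or single CSV file (matrix only).
#' @return a `leadfield` (matrix-only reads carry a minimal placeholder
#'   geometry flagged with attribute `matrix_only`).
#' @export
read_leadfield_csv <- function(path) {
  if (dir.exists(path)) {
    L <- as.matrix(utils::read.csv(file.path(path, "L.csv")))
    sens <- as.matrix(utils::read.csv(file.path(path, "sensors.csv")))
    vdf <- utils::read.csv(file.path(path, "vertices.csv"))
    roi <- utils::read.csv(file.path(path, "roi.csv"))$roi
    geom <- geometry(sens, as.matrix(vdf[, c("x", "y", "z")]),
                     as.matrix(vdf[, c("ox", "oy", "oz")]), roi)
    dimnames(L) <- NULL
    return(structure(list(L = L, geometry = geom), class = "leadfield"))
  }
  L <- as.matrix(utils::read.csv(path))
  dimnames(L) <- NULL
  lf <- structure(list(L = L, geometry = NULL), class = "leadfield")
  attr(lf, "matrix_only") <- TRUE
  lf
}

#' Write epoched trials to CSV
#'
#' Long format with one row per (trial, channel) and sample values in
#' columns; sampling rate and onset travel in a sidecar `meta.csv`.
#'
#' @param epochs list of N x T matrices (or a `trial_set`).
#' @param fs sampling rate in Hz.
#' @param path output file; `<path>.meta.csv` is written alongside.
#' @param onset epoch onset in seconds.
#' @return `path`, invisibly.
#' @export
write_epochs_csv <- function(epochs, fs, path, onset = 0) {
  if (inherits(epochs, "trial_set")) { fs <- epochs$fs; epochs <- epochs$epochs }
  rows <- do.call(rbind, lapply(seq_along(epochs), function(tr)
    cbind(trial = tr, channel = seq_len(nrow(epochs[[tr]])), epochs[[tr]])))
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  utils::write.csv(data.frame(fs = fs, onset = onset),
                   paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}

#' Read epochs written by [write_epochs_csv()]
#'
#' @param path CSV file path.
#' @return list with `epochs` (list of matrices), `fs`, `onset`.
#' @export
read_epochs_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- utils::read.csv(paste0(path, ".meta.csv"))
  eps <- lapply(split(df, df$trial), function(d) {
    m <- as.matrix(d[order(d$channel), -(1:2)])
    dimnames(m) <- NULL
    m
  })
  names(eps) <- NULL
  list(epochs = eps, fs = meta$fs, onset = meta$onset)
}

#' Read a per-trial response vector (MEP amplitudes) from CSV
#'
#' Expects a column named `mep_mv`.
#'
#' @param path CSV file path.
#' @return numeric vector.
#' @export
read_mep_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"mep_mv" %in% names(df)) stop("CSV must contain a 'mep_mv' column")
  z <- df$mep_mv
  stopifnot(all(is.finite(z)))
  z
}

#' Write cluster test results to JSON
#'
#' Cluster spans are reported in seconds relative to the stimulus.
#'
#' @param result a `cluster_result`.
#' @param path output JSON path.
#' @param fs sampling rate of the tested window in Hz.
#' @param onset time of the first sample, seconds.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(result, path, fs, onset = 0) {
  stopifnot(inherits(result, "cluster_result"))
  cl <- result$clusters
  out <- list(
    n_permutations = result$n_perm,
    alpha_cluster_forming = result$alpha,
    seed = result$seed,
    clusters = lapply(seq_len(nrow(cl)), function(i) list(
      start_s = onset + (cl$start[i] - 1) / fs,
      end_s = onset + (cl$end[i] - 1) / fs,
      stat = cl$stat[i], p = cl$p[i], significant = cl$significant[i])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
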