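#' Write or read pixel trajectories as CSV
#'
#' Columns `point_id, frame, i, j` with zero-based `(i, j) = (column, row)`
#' pixel coordinates.
#'
#' @param traj `n x K x 2` trajectory array (as from [track_points()]).
#' @param path file path.
#' @export
write_trajectories_csv <- function(traj, path) {
  n <- dim(traj)[1]; K <- dim(traj)[2]
  df <- data.frame(point_id = rep(seq_len(n), each = K),
                   frame = rep(seq_len(K), n),
                   i = as.vector(t(traj[, , 1])),
                   j = as.vector(t(traj[, , 2])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @return `read_trajectories_csv` returns the `n x K x 2` array.
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path)
  n <- max(df$point_id); K <- max(df$frame)
  traj <- array(0, dim = c(n, K, 2))
  traj[cbind(df$point_id, df$frame, 1)] <- df$i
  traj[cbind(df$point_id, df$frame, 2)] <- df$j
  traj
}

#' Write smoothed or fused tracks as CSV
#'
#' One row per (track, frame) with the 10 state components
#' `xbar, x, xdot, ybar, y, ydot, zbar, z, zdot, omega` and provenance
#' columns (contributing view ids).
#'
#' @param tracks list of `view_track`/`fused_track` objects.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- list()
  cn <- c("xbar", "x", "xdot", "ybar", "y", "ydot", "zbar", "z", "zdot",
          "omega")
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    vids <- if (!is.null(tr$view_ids)) paste(tr$view_ids, collapse = "+")
            else as.character(tr$view_id)
    for (k in seq_along(tr$states)) {
      s <- stats::setNames(as.list(tr$states[[k]]$s), cn)
      rows[[length(rows) + 1L]] <-
        data.frame(track = ti, point_id = tr$point_id, frame = k,
                   views = vids, s)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write tracks with covariances as JSON
#'
#' Full serialization (state means and 10x10 covariances per frame) in a
#' plain-text JSON archive.
#'
#' @inheritParams write_tracks_csv
#' @export
write_tracks_json <- function(tracks, path) {
  enc <- lapply(tracks, function(tr) list(
    point_id = tr$point_id,
    views = if (!is.null(tr$view_ids)) tr$view_ids else tr$view_id,
    states = lapply(tr$states, function(st)
      list(s = st$s, P = st$P))))
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a cine frame stack from disk
#'
#' Accepts a NIfTI volume (frames along the third dimension; needs
#' \pkg{RNifti}), a multi-page TIFF (needs \pkg{tiff}), or a set of PNG
#' files given as a character vector of paths in frame order (needs
#' \pkg{png}). Intensities are rescaled to \[0, 1\].
#'
#' @param path file path or vector of PNG paths.
#' @return List of frame matrices.
#' @export
load_frames <- function(path) {
  rescale <- function(M) {
    r <- range(M)
    if (r[2] > r[1]) (M - r[1]) / (r[2] - r[1]) else M * 0
  }
  if (length(path) > 1L || grepl("\\.png$", path[1], ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("load_frames: package 'png' required for PNG input")
    return(lapply(path, function(p) rescale(png::readPNG(p)[, , 1])))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("load_frames: package 'RNifti' required for NIfTI input")
    vol <- RNifti::asNifti(RNifti::readNifti(path))
    return(lapply(seq_len(dim(vol)[3]), function(k) rescale(vol[, , k])))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("load_frames: package 'tiff' required for TIFF input")
    pages <- tiff::readTIFF(path, all = TRUE)
    return(lapply(pages, function(M)
      rescale(if (length(dim(M)) == 3L) M[, , 1] else M)))
  }
  stop("load_frames: unsupported input ", path[1])
}
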