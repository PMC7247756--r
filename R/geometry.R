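#' Plane geometry of a 2D image view in the patient frame
#'
#' Describes the pose of a 2D image plane in the patient-based 3D reference
#' coordinate system, using the conventions of the DICOM attributes
#' Image Position (Patient), Image Orientation (Patient) and Pixel Spacing.
#' Pixel indexing is zero-based with `(i, j) = (column, row)`, so `p = (0, 0)`
#' maps exactly onto `origin`.
#'
#' Direction cosines are validated against unit norm and mutual orthogonality
#' with tolerance `1e-4` and then re-orthogonalized by one Gram-Schmidt step
#' (real headers carry rounded cosines); deviations beyond `1e-2` are an error.
#'
#' @param origin 3-vector, mm: patient coordinates of pixel (0, 0).
#' @param row_cosine unit 3-vector: patient direction of increasing column
#'   index `i`.
#' @param col_cosine unit 3-vector: patient direction of increasing row
#'   index `j`.
#' @param spacing 2-vector, mm/pixel: spacing along `i` and `j`.
#' @param n_rows,n_cols image dimensions in pixels.
#' @param heart_rate_bpm optional heart rate, beats/min.
#' @param n_frames optional number of cine frames.
#' @return An object of class `plane_geometry` with an additional `normal`
#'   field (`row_cosine x col_cosine`).
#' @export
plane_geometry <- function(origin, row_cosine, col_cosine, spacing,
                           n_rows, n_cols,
                           heart_rate_bpm = NULL, n_frames = NULL) {
  origin <- as.numeric(origin)
  row_cosine <- as.numeric(row_cosine)
  col_cosine <- as.numeric(col_cosine)
  spacing <- as.numeric(spacing)
  stopifnot(length(origin) == 3L, length(row_cosine) == 3L,
            length(col_cosine) == 3L, length(spacing) == 2L)
  if (!all(is.finite(c(origin, row_cosine, col_cosine, spacing))))
    stop("plane_geometry: non-finite inputs")
  if (any(spacing <= 0))
    stop("plane_geometry: spacing components must be strictly positive")

  err <- max(abs(sqrt(sum(row_cosine^2)) - 1),
             abs(sqrt(sum(col_cosine^2)) - 1),
             abs(sum(row_cosine * col_cosine)))
  if (err > 1e-2)
    stop("plane_geometry: direction cosines deviate from orthonormality by ",
         format(err), " (> 1e-2)")
  if (err > 1e-4) {
    # one Gram-Schmidt step against rounded DICOM cosines
    row_cosine <- row_cosine / sqrt(sum(row_cosine^2))
    col_cosine <- col_cosine - sum(col_cosine * row_cosine) * row_cosine
    col_cosine <- col_cosine / sqrt(sum(col_cosine^2))
  } else {
    row_cosine <- row_cosine / sqrt(sum(row_cosine^2))
    col_cosine <- col_cosine / sqrt(sum(col_cosine^2))
  }
  normal <- c(row_cosine[2] * col_cosine[3] - row_cosine[3] * col_cosine[2],
              row_cosine[3] * col_cosine[1] - row_cosine[1] * col_cosine[3],
              row_cosine[1] * col_cosine[2] - row_cosine[2] * col_cosine[1])
  structure(list(origin = origin, row_cosine = row_cosine,
                 col_cosine = col_cosine, spacing = spacing,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 normal = normal,
                 heart_rate_bpm = heart_rate_bpm, n_frames = n_frames),
            class = "plane_geometry")
}

#' @export
print.plane_geometry <- function(x, ...) {
  cat("plane_geometry:", x$n_rows, "x", x$n_cols, "px @",
      paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  cat("  origin ", paste(signif(x$origin, 5), collapse = ", "), "\n")
  cat("  normal ", paste(signif(x$normal, 5), collapse = ", "), "\n")
  invisible(x)
}

as_point_matrix <- function(p, d) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = d)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != d) stop("expected ", d, "-column point input")
  p
}

#' Map pixel coordinates into the patient 3D frame
#'
#' Implements the image-to-patient coordinate transform: the pixel
#' `(i, j)` (zero-based column/row indices, sub-pixel allowed) maps to
#' `origin + i * spacing[1] * row_cosine + j * spacing[2] * col_cosine`.
#' Points need not lie inside the image bounds.
#'
#' @param g a [plane_geometry()].
#' @param p a length-2 vector `(i, j)` or an `n x 2` matrix of pixel
#'   coordinates.
#' @return An `n x 3` matrix of patient coordinates in mm (a plain 3-vector
#'   when `p` is a single point given as a vector).
#' @export
image_to_patient <- function(g, p) {
  single <- is.null(dim(p))
  p <- as_point_matrix(p, 2L)
  if (!all(is.finite(p))) stop("image_to_patient: non-finite pixel coordinates")
  q <- cbind(p[, 1] * g$spacing[1], p[, 2] * g$spacing[2]) %*%
    rbind(g$row_cosine, g$col_cosine)
  q <- sweep(q, 2, g$origin, `+`)
  if (single && nrow(q) == 1L) drop(q) else q
}

#' Project patient coordinates onto an image plane
#'
#' Orthogonally projects 3D patient points onto the plane of `g` and
#' expresses the in-plane part in zero-based pixel coordinates `(i, j)`.
#' The signed out-of-plane distance is the component along
#' `row_cosine x col_cosine`. Round-tripping in-plane points through
#' [image_to_patient()] is the identity to machine precision.
#'
#' @param g a [plane_geometry()].
#' @param q a 3-vector or `n x 3` matrix of patient coordinates, mm.
#' @return A list with `pixel` (`n x 2` matrix, `(i, j)`) and
#'   `out_of_plane` (length-`n` signed distances, mm).
#' @export
patient_to_image <- function(g, q) {
  q <- as_point_matrix(q, 3L)
  if (!all(is.finite(q))) stop("patient_to_image: non-finite coordinates")
  d <- sweep(q, 2, g$origin, `-`)
  list(pixel = cbind(i = drop(d %*% g$row_cosine) / g$spacing[1],
                     j = drop(d %*% g$col_cosine) / g$spacing[2]),
       out_of_plane = drop(d %*% g$normal))
}

#' Contour points shared with a second image plane
#'
#' Returns the indices of contour points (pixel coordinates in `g1`) whose
#' absolute out-of-plane distance to the plane of `g2` is at most `tol_mm`.
#' Used to establish which tracked points are shared by two views prior to
#' track-to-track fusion. Parallel, offset planes yield an empty result.
#'
#' @param g1,g2 [plane_geometry()] objects.
#' @param contour `n x 2` matrix of pixel coordinates in `g1`.
#' @param tol_mm distance tolerance, mm.
#' @return Integer vector of contour row indices.
#' @export
plane_intersection_points <- function(g1, g2, contour, tol_mm) {
  contour <- as_point_matrix(contour, 2L)
  if (nrow(contour) == 0L) stop("plane_intersection_points: empty contour")
  q <- image_to_patient(g1, contour)
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  d <- abs(patient_to_image(g2, q)$out_of_plane)
  which(d <= tol_mm)
}

#' Read or write a plane-geometry JSON sidecar
#'
#' The sidecar schema carries the DICOM-derived numbers for non-DICOM
#' fixtures: `{origin, row_cosine, col_cosine, spacing, shape,
#' heart_rate_bpm, n_frames}` with `shape = c(n_rows, n_cols)`.
#'
#' @param path file path.
#' @return `read_plane_json` returns a [plane_geometry()].
#' @export
read_plane_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  plane_geometry(x$origin, x$row_cosine, x$col_cosine, x$spacing,
                 n_rows = x$shape[1], n_cols = x$shape[2],
                 heart_rate_bpm = x$heart_rate_bpm, n_frames = x$n_frames)
}

#' @rdname read_plane_json
#' @param g a [plane_geometry()] to serialize.
#' @export
write_plane_json <- function(g, path) {
  jsonlite::write_json(
    list(origin = g$origin, row_cosine = g$row_cosine,
         col_cosine = g$col_cosine, spacing = g$spacing,
         shape = c(g$n_rows, g$n_cols),
         heart_rate_bpm = g$heart_rate_bpm, n_frames = g$n_frames),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
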