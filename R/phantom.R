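#' Specification of the deforming-ellipsoid phantom
#'
#' Analytic cyclic 3D motion of points on an ellipsoidal left-ventricular
#' surface (long axis along z, mid-ventricle at z = 0). Peak displacement of
#' each point is reached at half cycle and is composed of radial contraction
#' (fraction of the local short-axis radius), longitudinal shortening
#' (fraction of the distance to the equatorial plane) and a linearized twist
#' (tangential displacement growing linearly along the long axis). The
#' temporal profile is `w(t) = (1 - cos(omega t)) / 2`, so every Cartesian
#' axis of every point is a single-harmonic oscillation about its mean —
#' exactly the model class of the cyclic transition dynamics.
#'
#' An optional hypokinetic wedge scales the peak displacement of points whose
#' azimuth falls inside it (regional-abnormality simulations).
#'
#' @param semi_axes ellipsoid semi-axes `(a, b, c)`, mm (a = b short axis).
#' @param contraction peak radial contraction fraction, in \[0, 0.5\].
#' @param shortening peak longitudinal shortening fraction, in \[0, 0.5\].
#' @param twist_deg peak twist at the apical end, degrees.
#' @param heart_rate_bpm heart rate; the angular frequency is
#'   `2 pi heart_rate_bpm / 60`.
#' @param K frames per cycle (>= 8).
#' @param noise_sd measurement noise SD, mm.
#' @param seed RNG seed for all stochastic phantom stages.
#' @param hypo optional `list(center_deg, width_deg, scale)` hypokinetic
#'   wedge.
#' @param two_harmonic if `TRUE`, adds a second-harmonic term (model
#'   misspecification mode for robustness testing only).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes = c(25, 25, 60), contraction = 0.15,
                         shortening = 0.12, twist_deg = 8,
                         heart_rate_bpm = 60, K = 20L, noise_sd = 0.5,
                         seed = 1L, hypo = NULL, two_harmonic = FALSE) {
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0),
            contraction >= 0, contraction <= 0.5,
            shortening >= 0, shortening <= 0.5,
            K >= 8L, noise_sd >= 0, heart_rate_bpm > 0)
  structure(list(semi_axes = as.numeric(semi_axes),
                 contraction = contraction, shortening = shortening,
                 twist_deg = twist_deg, heart_rate_bpm = heart_rate_bpm,
                 omega = 2 * pi * heart_rate_bpm / 60,
                 K = as.integer(K), noise_sd = noise_sd,
                 seed = as.integer(seed), hypo = hypo,
                 two_harmonic = isTRUE(two_harmonic)),
            class = "phantom_spec")
}

#' Default myocardial surface points of the phantom
#'
#' Rings of points on the ellipsoid surface at the given z levels and
#' azimuths. The defaults place rings on the three default short-axis planes
#' and azimuths every 30 degrees, so that points fall on the intersection
#' lines with the default long-axis planes.
#'
#' @param spec a [phantom_spec()].
#' @param z_levels z coordinates of the rings, mm.
#' @param azimuths_deg ring azimuths, degrees.
#' @return `n x 3` matrix of frame-1 (end-diastolic) positions.
#' @export
phantom_points <- function(spec, z_levels = c(-10, 0, 10),
                           azimuths_deg = seq(0, 330, by = 30)) {
  a <- spec$semi_axes[1]; c_ax <- spec$semi_axes[3]
  pts <- do.call(rbind, lapply(z_levels, function(z0) {
    r <- a * sqrt(pmax(0, 1 - (z0 / c_ax)^2))
    th <- azimuths_deg * pi / 180
    cbind(r * cos(th), r * sin(th), z0)
  }))
  colnames(pts) <- c("x", "y", "z")
  pts
}

peak_displacement <- function(spec, p0) {
  # total displacement at half cycle; linear map D = A %*% p0 per point,
  # with twist linearized about the z axis
  th_pk <- spec$twist_deg * pi / 180
  c_ax <- spec$semi_axes[3]
  # longitudinal shortening is apex-fixed: displacement toward the apex
  # (z = -c) grows linearly from apex to base, as mitral-annular excursion
  D <- cbind(-spec$contraction * p0[, 1] - th_pk * (p0[, 3] / c_ax) * -p0[, 2],
             -spec$contraction * p0[, 2] + th_pk * (p0[, 3] / c_ax) * -p0[, 1],
             -spec$shortening * (p0[, 3] + c_ax))
  if (!is.null(spec$hypo)) {
    az <- atan2(p0[, 2], p0[, 1]) * 180 / pi
    delta <- ((az - spec$hypo$center_deg + 180) %% 360) - 180
    inside <- abs(delta) <= spec$hypo$width_deg / 2
    D[inside, ] <- D[inside, , drop = FALSE] * spec$hypo$scale
  }
  D
}

#' Generate ground-truth phantom motion
#'
#' Evaluates the analytic motion at the `K` frame times
#' `t_k = (k - 1) T`, `T = (60 / heart_rate_bpm) / K`:
#' `p(t) = p0 + w(t) D(p0)` with `w(t) = (1 - cos(omega t)) / 2`, i.e.
#' `p(t) = pbar + A cos(omega t)` with `pbar = p0 + D/2`, `A = -D/2` per
#' axis. Frame 1 is exactly the end-diastolic input configuration, and the
#' extrapolated frame `K + 1` equals frame 1 (periodicity).
#'
#' @param spec a [phantom_spec()].
#' @param points optional `n x 3` frame-1 positions; defaults to
#'   [phantom_points()].
#' @return A list of class `ground_truth`: `points0`, `pos` (`n x K x 3`
#'   array), `mean_pos`, `amplitude`, `omega`, `T`, `K`, `spec`.
#' @export
make_motion <- function(spec, points = NULL) {
  if (is.null(points)) points <- phantom_points(spec)
  points <- as.matrix(points)
  n <- nrow(points)
  T <- (60 / spec$heart_rate_bpm) / spec$K
  t_k <- (seq_len(spec$K) - 1) * T
  D <- peak_displacement(spec, points)
  w <- (1 - cos(spec$omega * t_k)) / 2
  pos <- array(0, dim = c(n, spec$K, 3))
  for (k in seq_len(spec$K)) {
    pos[, k, ] <- points + w[k] * D
    if (spec$two_harmonic)
      pos[, k, ] <- pos[, k, ] +
        0.15 * D * (1 - cos(2 * spec$omega * t_k[k])) / 2
  }
  structure(list(points0 = points, pos = pos,
                 mean_pos = points + D / 2, amplitude = -D / 2,
                 omega = spec$omega, T = T, K = spec$K, spec = spec),
            class = "ground_truth")
}

#' Default multi-view acquisition geometry for the phantom
#'
#' Three parallel short-axis planes (normal along the long axis, 10 mm
#' apart, matching clinical inter-slice distances of 8-10 mm) and three
#' long-axis planes rotated 0/60/120 degrees about the long axis
#' (2-, 3- and 4-chamber surrogates). 64 x 64 pixels at 1.25 mm spacing,
#' centered on the ventricle.
#'
#' @param spec a [phantom_spec()].
#' @param sa_z z positions of the short-axis planes, mm.
#' @param la_angles_deg rotations of the long-axis planes, degrees.
#' @param n_px image size in pixels.
#' @param spacing_mm pixel spacing, mm.
#' @return Named list of [plane_geometry()] objects
#'   (`SA1..`, `LA1..`).
#' @export
default_geometries <- function(spec, sa_z = c(-10, 0, 10),
                               la_angles_deg = c(0, 60, 120),
                               n_px = 64L, spacing_mm = 1.25) {
  half <- n_px * spacing_mm / 2
  g <- list()
  for (s in seq_along(sa_z))
    g[[paste0("SA", s)]] <- plane_geometry(
      origin = c(-half, -half, sa_z[s]),
      row_cosine = c(1, 0, 0), col_cosine = c(0, 1, 0),
      spacing = c(spacing_mm, spacing_mm), n_rows = n_px, n_cols = n_px,
      heart_rate_bpm = spec$heart_rate_bpm, n_frames = spec$K)
  for (l in seq_along(la_angles_deg)) {
    th <- la_angles_deg[l] * pi / 180
    u <- c(cos(th), sin(th), 0)
    g[[paste0("LA", l)]] <- plane_geometry(
      origin = -half * u + c(0, 0, -half),
      row_cosine = u, col_cosine = c(0, 0, 1),
      spacing = c(spacing_mm, spacing_mm), n_rows = n_px, n_cols = n_px,
      heart_rate_bpm = spec$heart_rate_bpm, n_frames = spec$K)
  }
  g
}

#' Sample noisy per-view observations of the phantom
#'
#' Projects the true 3D positions onto each plane, keeps the points whose
#' frame-1 out-of-plane distance is within `slice_tol_mm`, adds i.i.d.
#' Gaussian noise of `noise_sd` mm (converted to pixels via the plane
#' spacing) to the in-plane pixel coordinates, and maps the noisy pixels
#' back to 3D patient coordinates. The mapped 3D observation carries no
#' through-plane information: its out-of-plane component is pinned to the
#' plane, which is precisely what multi-view fusion must compensate.
#'
#' @param gt a [make_motion()] ground truth.
#' @param geometries named list of [plane_geometry()] objects.
#' @param noise_sd noise SD, mm; defaults to the phantom spec value.
#' @param seed RNG seed; defaults to the phantom spec value.
#' @param slice_tol_mm half slice thickness used for point selection, mm.
#' @return Named list per view: `geometry`, `point_ids`, `pix` and
#'   `pix_true` (`n x K x 2` arrays of pixel trajectories), `obs_3d`
#'   (`n x K x 3` array), `seeds` (frame-1 true pixels, for tracking).
#'   Views intersecting no points are returned empty with a warning.
#' @export
sample_views <- function(gt, geometries, noise_sd = NULL, seed = NULL,
                         slice_tol_mm = 2) {
  if (is.null(noise_sd)) noise_sd <- gt$spec$noise_sd
  if (is.null(seed)) seed <- gt$spec$seed
  set.seed(seed)
  n <- nrow(gt$points0); K <- gt$K
  out <- list()
  for (v in names(geometries)) {
    g <- geometries[[v]]
    pr1 <- patient_to_image(g, gt$points0)
    keep <- which(abs(pr1$out_of_plane) <= slice_tol_mm)
    if (!length(keep)) {
      warning("sample_views: no points intersect view ", v)
      out[[v]] <- list(geometry = g, point_ids = integer(0))
      next
    }
    m <- length(keep)
    pix_true <- array(0, dim = c(m, K, 2))
    for (k in seq_len(K))
      pix_true[, k, ] <-
        patient_to_image(g, matrix(gt$pos[keep, k, ], ncol = 3))$pixel
    noise <- array(stats::rnorm(m * K * 2, sd = noise_sd), dim = c(m, K, 2))
    pix <- pix_true + sweep(noise, 3, g$spacing, `/`)
    obs_3d <- array(0, dim = c(m, K, 3))
    for (k in seq_len(K))
      obs_3d[, k, ] <- image_to_patient(g, pix[, k, ])
    out[[v]] <- list(geometry = g, point_ids = keep,
                     pix = pix, pix_true = pix_true, obs_3d = obs_3d,
                     seeds = matrix(pix_true[, 1, ], ncol = 2))
  }
  out
}

smooth_noise_image <- function(nr, nc, sigma = 3) {
  gauss_blur(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
}

sa_motion_matrix <- function(spec, z0) {
  # in-plane linear peak-displacement map of a short-axis slice at z0
  th_pk <- spec$twist_deg * pi / 180 * (z0 / spec$semi_axes[3])
  matrix(c(-spec$contraction, -th_pk,
           th_pk, -spec$contraction), 2, 2)
}

#' Render phantom image sequences for a short-axis plane
#'
#' Frame 1 is a smooth random-blob texture, optionally masked to the
#' myocardial annulus; subsequent frames are produced by warping frame 1
#' with the analytic in-plane motion of the slice (the linear map
#' `I + w(t) A2` about the ventricular axis, `A2` combining radial
#' contraction and slice twist). The true adjacent-frame deformation fields
#' (in pixel units, mapping frame-k grid points to frame-(k+1)
#' coordinates) are returned for registration scoring.
#'
#' @param spec a [phantom_spec()].
#' @param geometry a short-axis [plane_geometry()] (column/row axes in the
#'   x-y plane).
#' @param z0 slice position along the long axis, mm.
#' @param texture_seed RNG seed for the texture.
#' @param annulus mask the texture to the myocardial annulus.
#' @return A list with `frames` (list of K matrices in \[0, 1\]),
#'   `true_fields` (list of K-1 `deformation_field`s) and `warp_fun(k)`
#'   giving the analytic frame-1 -> frame-k pixel map.
#' @export
render_images <- function(spec, geometry, z0 = 0, texture_seed = NULL,
                          annulus = TRUE) {
  if (is.null(texture_seed)) texture_seed <- spec$seed
  set.seed(texture_seed)
  nr <- geometry$n_rows; nc <- geometry$n_cols
  tex <- smooth_noise_image(nr, nc, sigma = 2)
  tex <- (tex - min(tex)) / (max(tex) - min(tex)) * 0.9 + 0.05
  # pixel grid -> in-plane mm about the ventricular axis (x, y) = (0, 0)
  # matrix convention: rows r = j + 1 (col cosine), cols c = i + 1 (row cosine)
  ij <- cbind(rep(seq_len(nc) - 1, each = nr), rep(seq_len(nr) - 1, nc))
  xy_mm <- image_to_patient(geometry, ij)[, 1:2]
  A2 <- sa_motion_matrix(spec, z0)
  T <- (60 / spec$heart_rate_bpm) / spec$K
  w <- (1 - cos(spec$omega * (seq_len(spec$K) - 1) * T)) / 2
  r_endo <- spec$semi_axes[1] * sqrt(pmax(0, 1 - (z0 / spec$semi_axes[3])^2))
  r_epi <- r_endo + 10
  if (annulus) {
    rad <- sqrt(rowSums(xy_mm^2))
    mask <- stats::plogis((rad - (r_endo - 2)) / 1.5) *
      stats::plogis(((r_epi + 2) - rad) / 1.5)
    tex <- matrix(as.vector(tex) * mask + 0.05 * (1 - mask), nr, nc)
  }
  mm_to_rc <- function(xy) {
    pr <- patient_to_image(geometry, cbind(xy, z0))$pixel
    cbind(pr[, 2] + 1, pr[, 1] + 1)  # (row, col) 1-based
  }
  frames <- vector("list", spec$K)
  frames[[1]] <- tex
  for (k in 2:spec$K) {
    Mk_inv <- solve(diag(2) + w[k] * A2)
    src <- mm_to_rc(xy_mm %*% t(Mk_inv))
    frames[[k]] <- matrix(interp_bilinear(tex, src[, 1], src[, 2]), nr, nc)
  }
  warp_fun <- function(k) {
    Mk <- diag(2) + w[k] * A2
    function(rc) {
      rc <- as_point_matrix(rc, 2L)
      pr <- image_to_patient(geometry, cbind(rc[, 2] - 1, rc[, 1] - 1))[, 1:2, drop = FALSE]
      mm_to_rc(pr %*% t(Mk))
    }
  }
  true_fields <- vector("list", spec$K - 1L)
  for (k in seq_len(spec$K - 1L)) {
    dst <- mm_to_rc((xy_mm %*% t(solve(diag(2) + w[k] * A2))) %*%
                      t(diag(2) + w[k + 1] * A2))
    # dst above maps frame-k pixel grid: grid xy are frame-k coords, so
    # invert frame-k map then apply frame-(k+1) map
    true_fields[[k]] <- deformation_field(matrix(dst[, 1], nr, nc),
                                          matrix(dst[, 2], nr, nc))
  }
  list(frames = frames, true_fields = true_fields, warp_fun = warp_fun,
       r_endo = r_endo, r_epi = r_epi)
}
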