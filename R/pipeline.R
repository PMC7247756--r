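#' Root-mean-square error between matched 2D point sets
#'
#' `sqrt(mean((xi_hat - xi_ref)^2 + (phi_hat - phi_ref)^2))` over the `N`
#' matched points, both sets expressed in the 2D image coordinates of the
#' target plane.
#'
#' @param estimates,references `N x 2` matrices (pixels).
#' @return Scalar RMSE in pixels.
#' @export
rmse_2d <- function(estimates, references) {
  estimates <- as_point_matrix(estimates, 2L)
  references <- as_point_matrix(references, 2L)
  if (nrow(estimates) != nrow(references))
    stop("rmse_2d: point sets must have equal length")
  stopifnot(nrow(estimates) >= 1L)
  sqrt(mean(rowSums((estimates - references)^2)))
}

rmse_3d <- function(estimates, references) {
  stopifnot(nrow(estimates) == nrow(references))
  sqrt(mean(rowSums((estimates - references)^2)))
}

#' Mid-wall points between endocardial and epicardial contours
#'
#' Pointwise midpoints of index-aligned contour samples; the evaluation
#' against tagged-image references is performed at these mid-wall points,
#' where harmonic-phase estimates are most reliable.
#'
#' @param endo,epi index-aligned `n x d` contour matrices.
#' @return `n x d` matrix of midpoints.
#' @export
midwall_points <- function(endo, epi) {
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  if (!all(dim(endo) == dim(epi)))
    stop("midwall_points: contours must be index-aligned")
  (endo + epi) / 2
}

#' Restrict a track to the first half of the cardiac cycle
#'
#' Truncates to the first `ceiling(K / 2)` frames (evaluation path only;
#' odd frame counts keep the middle frame). Idempotent once the input is
#' already truncated to that length.
#'
#' @param track a `view_track`/`fused_track`, a list of states, a `K x d`
#'   matrix of frames, or an array with frames along the second dimension.
#' @param K full cycle length; defaults to the track's own length.
#' @return The truncated object, same shape as the input.
#' @export
half_cycle_filter <- function(track, K = NULL) {
  has_states <- is.list(track) && !is.null(track$states)
  len <- function(x) {
    if (has_states) length(x$states)
    else if (is.matrix(x)) nrow(x)
    else if (is.array(x)) dim(x)[2]
    else length(x)
  }
  if (is.null(K)) K <- len(track)
  stopifnot(K >= 2L)
  m <- min(ceiling(K / 2), len(track))
  if (has_states) { track$states <- track$states[seq_len(m)]; track }
  else if (is.matrix(track)) track[seq_len(m), , drop = FALSE]
  else if (is.array(track)) track[, seq_len(m), , drop = FALSE]
  else track[seq_len(m)]
}

view_measurement_cov <- function(geometry, through_plane_sd = 5, r = NULL) {
  # isotropic in-plane tracking noise, inflated along the plane normal:
  # a single-view 3D observation carries no through-plane information
  if (is.null(r)) r <- (0.5 * max(geometry$spacing))^2
  n <- geometry$normal
  diag(rep(r, 3)) + through_plane_sd^2 * tcrossprod(n)
}

smooth_view <- function(obs_3d, geometry, heart_rate_bpm, dyn = list()) {
  # UKS per point of one view; obs_3d is n x K x 3
  n <- dim(obs_3d)[1]
  r <- if (!is.null(dyn$r)) dyn$r else (0.5 * max(geometry$spacing))^2
  tp <- if (!is.null(dyn$through_plane_sd)) dyn$through_plane_sd else 5
  R <- view_measurement_cov(geometry, tp, r)
  lapply(seq_len(n), function(p) {
    z <- matrix(obs_3d[p, , ], ncol = 3)
    init <- init_state(z, heart_rate_bpm)
    model <- do.call(model_spec, c(list(T = init$T, R = R),
                                   dyn[intersect(names(dyn),
                                                 c("q_pos", "q_mean_scale",
                                                   "q_omega", "alpha", "beta",
                                                   "kappa"))]))
    uks_smooth(z, model, init)
  })
}

#' Run the multi-view tracking, smoothing and fusion pipeline
#'
#' Executes per-view tracking, geometry mapping, per-view cyclic-dynamics
#' smoothing and track-to-track fusion, and (when ground truth is
#' available) evaluates per-view and fused 3D RMSE over the first half of
#' the cardiac cycle. Deterministic given `cfg$seed`.
#'
#' Configuration fields:
#' \describe{
#'   \item{phantom}{a [phantom_spec()]; phantom views are generated with
#'     [sample_views()] (noisy projected trajectories; the standard
#'     evaluation path) or, with `mode = "images"`, by registration-based
#'     tracking of rendered short-axis sequences.}
#'   \item{geometries}{named list of [plane_geometry()]; defaults to
#'     [default_geometries()].}
#'   \item{views}{alternatively, a pre-built [sample_views()]-style list.}
#'   \item{dynamics}{list: `q_pos`, `q_mean_scale`, `q_omega`, `r`,
#'     `through_plane_sd`, `alpha`, `beta`, `kappa`.}
#'   \item{fusion}{list: `tol_mm` correspondence tolerance.}
#'   \item{evaluate}{list: `half_cycle` (default `TRUE`).}
#'   \item{seed}{RNG seed for all stochastic stages.}
#' }
#'
#' @param cfg configuration list.
#' @return A list: `view_tracks` (flat list of [view_track()]), `fused`
#'   (list of fused tracks), `report` (per-view and fused RMSE when truth
#'   is known), `gt`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is.list(cfg))
  seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  set.seed(seed)
  dyn <- if (!is.null(cfg$dynamics)) cfg$dynamics else list()
  tol_mm <- if (!is.null(cfg$fusion$tol_mm)) cfg$fusion$tol_mm else 3
  half <- if (!is.null(cfg$evaluate$half_cycle)) cfg$evaluate$half_cycle else TRUE

  gt <- NULL; views <- cfg$views
  if (!is.null(cfg$phantom)) {
    spec <- cfg$phantom
    geoms <- if (!is.null(cfg$geometries)) cfg$geometries
             else default_geometries(spec)
    gt <- make_motion(spec)
    views <- sample_views(gt, geoms, seed = seed)
    if (identical(cfg$mode, "images")) {
      for (v in names(views)) {
        g <- views[[v]]$geometry
        if (abs(abs(g$normal[3]) - 1) > 1e-6) next  # rendered: SA planes only
        z0 <- g$origin[3]
        ri <- render_images(spec, g, z0 = z0, texture_seed = seed)
        tp <- track_points(ri$frames, views[[v]]$seeds,
                           opts = if (!is.null(cfg$register_opts))
                             cfg$register_opts else register_opts())
        views[[v]]$pix <- tp
        for (k in seq_len(dim(tp)[2]))
          views[[v]]$obs_3d[, k, ] <- image_to_patient(g, tp[, k, ])
      }
    }
  }
  if (is.null(views) || !length(views)) stop("run_pipeline: no views configured")

  hr <- NULL
  view_tracks <- list()
  for (v in names(views)) {
    vw <- views[[v]]
    if (!length(vw$point_ids)) next
    hr <- if (!is.null(vw$geometry$heart_rate_bpm)) vw$geometry$heart_rate_bpm
          else if (!is.null(cfg$phantom)) cfg$phantom$heart_rate_bpm else 60
    sm <- smooth_view(vw$obs_3d, vw$geometry, hr, dyn)
    for (p in seq_along(sm))
      view_tracks[[length(view_tracks) + 1L]] <-
        view_track(sm[[p]], view_id = v, geometry = vw$geometry,
                   point_id = vw$point_ids[p])
  }
  fused <- fuse_tracks(view_tracks, tol_mm = tol_mm)

  report <- NULL
  if (!is.null(gt)) {
    K <- gt$K
    frames_eval <- seq_len(if (half) ceiling(K / 2) else K)
    err_view <- list()
    for (tr in view_tracks) {
      est <- track_positions(tr)[frames_eval, , drop = FALSE]
      ref <- matrix(gt$pos[tr$point_id, frames_eval, ], ncol = 3)
      err_view[[tr$view_id]] <- rbind(err_view[[tr$view_id]], est - ref)
    }
    view_rmse <- vapply(err_view, function(e) sqrt(mean(rowSums(e^2))),
                        numeric(1))
    err_f <- NULL
    multi_pts <- integer(0)
    err_f_multi <- NULL
    for (ftr in fused) {
      est <- track_positions(ftr)[frames_eval, , drop = FALSE]
      ref <- matrix(gt$pos[ftr$point_id, frames_eval, ], ncol = 3)
      err_f <- rbind(err_f, est - ref)
      if (length(ftr$view_ids) > 1L) {
        multi_pts <- c(multi_pts, ftr$point_id)
        err_f_multi <- rbind(err_f_multi, est - ref)
      }
    }
    # like-for-like fusion benefit: restrict the per-view errors to the
    # points that are actually seen (and fused) in more than one view
    err_view_multi <- list()
    for (tr in view_tracks) {
      if (!(tr$point_id %in% multi_pts)) next
      est <- track_positions(tr)[frames_eval, , drop = FALSE]
      ref <- matrix(gt$pos[tr$point_id, frames_eval, ], ncol = 3)
      err_view_multi[[tr$view_id]] <- rbind(err_view_multi[[tr$view_id]],
                                            est - ref)
    }
    report <- list(view_rmse_mm = view_rmse,
                   fused_rmse_mm = sqrt(mean(rowSums(err_f^2))),
                   view_rmse_multi_mm = vapply(err_view_multi, function(e)
                     sqrt(mean(rowSums(e^2))), numeric(1)),
                   fused_rmse_multi_mm =
                     if (is.null(err_f_multi)) NA_real_
                     else sqrt(mean(rowSums(err_f_multi^2))),
                   n_fused_tracks = length(fused),
                   n_multi_view = length(multi_pts),
                   half_cycle = half)
  }
  list(view_tracks = view_tracks, fused = fused, report = report, gt = gt)
}

#' Entropy-feature table for a synthetic regional cohort
#'
#' Simulates a cohort of subjects from the phantom: each subject is a
#' mid-cavity endocardial ring tracked over one cycle with Gaussian
#' measurement noise. Abnormal subjects carry one hypokinetic wedge
#' (default 120 degrees at scale 0.3 of normal amplitude). Segments whose
#' points fall mostly inside the wedge are labeled abnormal; features are
#' the radial and area entropy features per segment.
#'
#' @param n_subjects number of subjects.
#' @param n_abnormal number of abnormal subjects.
#' @param level slice level (segment count).
#' @param K frames per cycle.
#' @param noise_sd in-plane measurement noise SD, mm.
#' @param hypo_scale amplitude scale inside the hypokinetic wedge.
#' @param hypo_width_deg wedge width, degrees.
#' @param n_points contour points per subject.
#' @param seed RNG seed.
#' @return Data frame: `subject`, `segment`, `sde_radial`, `sde_area`,
#'   `label`, `level`.
#' @export
cohort_features <- function(n_subjects = 20L, n_abnormal = 7L,
                            level = "mid", K = 20L, noise_sd = 0.3,
                            hypo_scale = 0.3, hypo_width_deg = 120,
                            n_points = 60L, seed = 1L) {
  set.seed(seed)
  abnormal_subj <- seq_len(n_abnormal)
  az <- seq(0, 360 - 360 / n_points, length.out = n_points)
  out <- list()
  for (subj in seq_len(n_subjects)) {
    hypo <- NULL
    if (subj %in% abnormal_subj)
      hypo <- list(center_deg = stats::runif(1, 0, 360),
                   width_deg = hypo_width_deg, scale = hypo_scale)
    spec <- phantom_spec(contraction = stats::rnorm(1, 0.15, 0.015),
                         shortening = 0, twist_deg = 0,
                         K = K, noise_sd = noise_sd,
                         seed = seed + subj, hypo = hypo)
    pts <- phantom_points(spec, z_levels = 0, azimuths_deg = az)
    gt <- make_motion(spec, pts)
    traj <- gt$pos[, , 1:2] +
      array(stats::rnorm(n_points * K * 2, sd = noise_sd),
            dim = c(n_points, K, 2))
    landmark <- pts[which.min(abs(((az - 120 + 180) %% 360) - 180)), 1:2]
    seg <- partition_contour(pts[, 1:2], landmark, level = level)
    centroids <- t(vapply(seq_len(K), function(k)
      colMeans(traj[, k, ]), numeric(2)))
    for (s in seq_len(seg$n_segments)) {
      idx <- which(seg$labels == s)
      lab <- "normal"
      if (!is.null(hypo)) {
        delta <- ((az[idx] - hypo$center_deg + 180) %% 360) - 180
        if (mean(abs(delta) <= hypo$width_deg / 2) > 0.5) lab <- "abnormal"
      }
      out[[length(out) + 1L]] <- data.frame(
        subject = subj, segment = s,
        sde_radial = radial_feature(traj[idx, , , drop = FALSE], centroids),
        sde_area = area_feature(traj[idx, , , drop = FALSE], centroids),
        label = lab, level = level)
    }
  }
  do.call(rbind, out)
}
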