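#' Maximum-likelihood fusion of two state estimates
#'
#' Combines two independent estimates of the same state under the
#' zero-cross-covariance assumption:
#' `s = P_b (P_a + P_b)^{-1} s_a + P_a (P_a + P_b)^{-1} s_b`.
#' The fused covariance is the Fisher information of the joint Gaussian
#' likelihood under the same assumption, `(P_a^{-1} + P_b^{-1})^{-1}`,
#' computed via linear solves as `P_a (P_a + P_b)^{-1} P_b`.
#'
#' @param s_a,s_b state mean vectors (equal length).
#' @param P_a,P_b positive-definite covariances.
#' @return A list with fused `s` and `P`.
#' @export
fuse_pair <- function(s_a, P_a, s_b, P_b) {
  s_a <- as.numeric(s_a); s_b <- as.numeric(s_b)
  n <- length(s_a)
  stopifnot(length(s_b) == n, all(dim(P_a) == n), all(dim(P_b) == n))
  S <- symmetrize(P_a + P_b)
  sol <- tryCatch(solve(S, cbind(s_a, s_b, P_b)),
                  error = function(e)
                    stop("numerical failure: singular P_a + P_b in fuse_pair"))
  s <- drop(P_b %*% sol[, 1L] + P_a %*% sol[, 2L])
  P <- symmetrize(P_a %*% sol[, -(1:2), drop = FALSE])
  dimnames(P) <- NULL
  list(s = unname(s), P = P)
}

#' General-form two-track fusion with cross-covariance
#'
#' Secondary path retaining the general fused mean
#' `(P_b - C^T)(P_a + P_b - C - C^T)^{-1} s_a +
#'  (P_a - C)(P_a + P_b - C - C^T)^{-1} s_b`
#' for a cross-covariance `C = cov(s_a, s_b)`. With `C = 0` it reduces to
#' [fuse_pair()]. Used as a cross-check; the pipeline always assumes
#' independent views (`C = 0`).
#'
#' @inheritParams fuse_pair
#' @param C cross-covariance matrix between the two estimates.
#' @return Fused mean vector.
#' @export
fuse_pair_general <- function(s_a, P_a, s_b, P_b, C) {
  S <- P_a + P_b - C - t(C)
  drop((P_b - t(C)) %*% solve(S, s_a) + (P_a - C) %*% solve(S, s_b))
}

#' Maximum-likelihood fusion of several state estimates
#'
#' Inverse-covariance (information-form) weighting:
#' `P = (sum_i P_i^{-1})^{-1}`, `s = P sum_i P_i^{-1} s_i`.
#' For two tracks this equals [fuse_pair()].
#'
#' @param tracks list of `list(s, P)` estimates (all positive definite).
#' @return A list with fused `s` and `P`.
#' @export
fuse_many <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  if (length(tracks) == 1L)
    return(list(s = as.numeric(tracks[[1]]$s), P = symmetrize(tracks[[1]]$P)))
  n <- length(tracks[[1]]$s)
  info <- matrix(0, n, n)
  iv <- numeric(n)
  for (tr in tracks) {
    sol <- tryCatch(solve(tr$P, cbind(diag(n), as.numeric(tr$s))),
                    error = function(e)
                      stop("numerical failure: singular covariance in fuse_many"))
    info <- info + sol[, 1:n]
    iv <- iv + sol[, n + 1L]
  }
  P <- symmetrize(solve(symmetrize(info)))
  dimnames(P) <- NULL
  list(s = unname(drop(P %*% iv)), P = P)
}

interp_states <- function(states, phase_out) {
  # linear interpolation of state means and covariances on normalized phase
  K <- length(states)
  phase_in <- (seq_len(K) - 1) / K
  smat <- t(vapply(states, function(st) as.numeric(st$s), numeric(10)))
  parr <- vapply(states, function(st) st$P, matrix(0, 10, 10))
  lapply(phase_out, function(ph) {
    ph <- min(max(ph, phase_in[1]), phase_in[K])
    k0 <- max(which(phase_in <= ph + 1e-12))
    if (k0 >= K) return(list(s = smat[K, ], P = parr[, , K]))
    a <- (ph - phase_in[k0]) / (phase_in[k0 + 1] - phase_in[k0])
    list(s = (1 - a) * smat[k0, ] + a * smat[k0 + 1, ],
         P = symmetrize((1 - a) * parr[, , k0] + a * parr[, , k0 + 1]))
  })
}

#' Resample a view track to a common phase grid
#'
#' Views may be acquired with different frame counts; state means and
#' covariances are linearly interpolated onto a normalized cardiac-phase
#' grid with `K_common` frames.
#'
#' @param track a [view_track()].
#' @param K_common target frame count.
#' @return A [view_track()] with `K_common` states.
#' @export
resample_track <- function(track, K_common) {
  if (length(track$states) == K_common) return(track)
  phase_out <- (seq_len(K_common) - 1) / K_common
  view_track(interp_states(track$states, phase_out),
             track$view_id, track$geometry, track$point_id)
}

match_tracks <- function(view_tracks, tol_mm = 3) {
  # greedy one-to-one grouping by frame-1 3D position across views,
  # gated by distance and (when geometry is known) plane proximity
  n <- length(view_tracks)
  p1 <- t(vapply(view_tracks, function(tr) measure(tr$states[[1]]$s), numeric(3)))
  vid <- vapply(view_tracks, function(tr) as.character(tr$view_id), character(1))
  unused <- rep(TRUE, n)
  groups <- list()
  for (i in seq_len(n)) {
    if (!unused[i]) next
    unused[i] <- FALSE
    grp <- i
    for (v in setdiff(unique(vid), vid[i])) {
      cand <- which(unused & vid == v)
      if (!length(cand)) next
      d <- sqrt(colSums((t(p1[cand, , drop = FALSE]) - p1[i, ])^2))
      j <- cand[which.min(d)]
      if (min(d) > tol_mm) next
      g <- view_tracks[[j]]$geometry
      if (!is.null(g) &&
          abs(patient_to_image(g, p1[i, ])$out_of_plane) > tol_mm) next
      unused[j] <- FALSE
      grp <- c(grp, j)
    }
    groups[[length(groups) + 1L]] <- grp
  }
  groups
}

#' Fuse corresponding per-view tracks into 3D tracks
#'
#' Frame-wise maximum-likelihood fusion ([fuse_many()]) over tracks of the
#' same myocardial point seen in different views. Tracks are first resampled
#' to a common phase grid (`max` frame count). When `correspondence` is not
#' given, tracks are grouped greedily by nearest frame-1 3D position within
#' `tol_mm`, requiring the candidate to lie within `tol_mm` of the partner
#' plane. Groups with a single contributing view pass through unchanged.
#'
#' @param view_tracks list of [view_track()] objects (all views pooled).
#' @param correspondence optional list of integer index vectors into
#'   `view_tracks`, one group per fused point.
#' @param tol_mm correspondence distance tolerance, mm.
#' @return A list of `fused_track` objects, each with `states`,
#'   `view_ids`, and `point_id` (taken from the first member).
#' @export
fuse_tracks <- function(view_tracks, correspondence = NULL, tol_mm = 3) {
  stopifnot(length(view_tracks) >= 1L)
  if (is.null(correspondence))
    correspondence <- match_tracks(view_tracks, tol_mm)
  if (!length(correspondence)) stop("fuse_tracks: empty correspondence")
  K_common <- max(vapply(view_tracks, function(tr) length(tr$states), 0L))
  lapply(correspondence, function(grp) {
    trs <- lapply(view_tracks[grp], resample_track, K_common = K_common)
    states <- lapply(seq_len(K_common), function(k)
      fuse_many(lapply(trs, function(tr) tr$states[[k]])))
    structure(list(states = states,
                   view_ids = vapply(trs, function(tr)
                     as.character(tr$view_id), character(1)),
                   point_id = trs[[1]]$point_id),
              class = "fused_track")
  })
}
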