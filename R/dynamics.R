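#' Cyclic-motion transition block
#'
#' The 3x3 per-axis transition matrix of the periodic tissue-dynamics model,
#' acting on `(mean position, position, velocity)`:
#' \deqn{F = \begin{pmatrix} 1 & 0 & 0 \\ 1-\cos\omega T & \cos\omega T &
#'  \sin(\omega T)/\omega \\ \omega\sin\omega T & -\omega\sin\omega T &
#'  \cos\omega T \end{pmatrix}}
#' For `omega * T < 1e-8` the analytic limit (constant-velocity block) is
#' returned. A full period (`omega * T = 2*pi`) is the identity.
#'
#' @param omega angular frequency, rad/s (>= 0).
#' @param T frame interval, s (> 0).
#' @return 3x3 matrix.
#' @export
transition_block <- function(omega, T) {
  if (!is.finite(T) || T <= 0) stop("transition_block: T must be > 0")
  if (!is.finite(omega) || omega < 0) stop("transition_block: omega must be >= 0")
  wt <- omega * T
  if (wt < 1e-8)
    return(matrix(c(1, 0, 0,
                    0, 1, T,
                    0, 0, 1), 3, 3, byrow = TRUE))
  cwt <- cos(wt); swt <- sin(wt)
  matrix(c(1,             0,          0,
           1 - cwt,       cwt,        swt / omega,
           omega * swt,  -omega * swt, cwt), 3, 3, byrow = TRUE)
}

#' Propagate a cyclic state one frame forward
#'
#' Applies `blkdiag(F, F, F, 1)` with `F = transition_block(s[10], T)` to the
#' 10-vector state `s = (xbar, x, xdot, ybar, y, ydot, zbar, z, zdot, omega)`.
#' The map is nonlinear in the state because `F` depends on the state's own
#' angular frequency component.
#'
#' @param s 10-vector state.
#' @param T frame interval, s.
#' @return 10-vector state at the next frame.
#' @export
propagate <- function(s, T) {
  s <- as.numeric(s)
  stopifnot(length(s) == 10L)
  F <- transition_block(abs(s[10]), T)
  out <- s
  for (a in 0:2) {
    idx <- 3 * a + 1:3
    out[idx] <- F %*% s[idx]
  }
  out
}

#' Measurement function of the cyclic state model
#'
#' Extracts the observed 3D position `(x, y, z)` (state elements 2, 5, 8).
#' Only the three position components are observed; the measurement-noise
#' covariance is 3x3.
#'
#' @param s 10-vector state.
#' @return 3-vector position, mm.
#' @export
measure <- function(s) as.numeric(s)[c(2L, 5L, 8L)]

measurement_matrix <- function() {
  H <- matrix(0, 3, 10)
  H[1, 2] <- 1; H[2, 5] <- 1; H[3, 8] <- 1
  H
}

#' Model specification for the cyclic-dynamics smoother
#'
#' Process noise `Q` is built per axis from a white-noise acceleration block
#' on `(position, velocity)` scaled by `q_pos`, a small drift variance
#' `q_mean_scale * q_pos` on the mean-position component, and a random-walk
#' variance `q_omega` on the angular frequency (the augmented frequency is
#' dynamic and must receive process noise). Measurement noise defaults to
#' `diag(r, r, r)`; a full 3x3 `R` (e.g. with the through-plane direction
#' inflated for a single-view observation) may be supplied instead.
#'
#' @param T frame interval, s.
#' @param q_pos process-noise intensity for position/velocity, mm^2/s^3.
#' @param q_mean_scale relative drift intensity of the mean-position
#'   components.
#' @param q_omega random-walk intensity of omega, rad^2/s^3.
#' @param r isotropic measurement variance, mm^2; default
#'   `(0.5 * max pixel spacing)^2` must be supplied by the caller via this
#'   argument.
#' @param R optional full 3x3 measurement covariance overriding `r`.
#' @param alpha,beta,kappa scaled-unscented-transform parameters.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(T, q_pos = 1, q_mean_scale = 1e-4, q_omega = 1e-2,
                       r = 0.25, R = NULL,
                       alpha = 0.1, beta = 2, kappa = 0) {
  stopifnot(T > 0, q_pos >= 0, q_omega >= 0, is.null(R) || all(dim(R) == 3L))
  axis_q <- matrix(0, 3, 3)
  axis_q[1, 1] <- q_mean_scale * q_pos * T
  axis_q[2:3, 2:3] <- q_pos * matrix(c(T^3 / 3, T^2 / 2, T^2 / 2, T), 2, 2)
  Q <- matrix(0, 10, 10)
  for (a in 0:2) Q[3 * a + 1:3, 3 * a + 1:3] <- axis_q
  Q[10, 10] <- q_omega * T
  if (is.null(R)) R <- diag(rep(r, 3))
  structure(list(T = T, Q = Q, R = (R + t(R)) / 2,
                 alpha = alpha, beta = beta, kappa = kappa),
            class = "model_spec")
}

#' Initial state from a raw 3D trajectory and heart rate
#'
#' Mean positions are the temporal means of the trajectory (the full record
#' is available retrospectively), positions are the frame-1 values,
#' velocities the first forward difference divided by `T`, and the initial
#' angular frequency is one oscillation per beat,
#' `omega0 = 2 * pi * heart_rate_bpm / 60`. The frame interval is the beat
#' duration divided by the frame count, `T = (60 / heart_rate_bpm) / K`.
#'
#' @param trajectory_3d `K x 3` matrix of raw positions, mm.
#' @param heart_rate_bpm heart rate, beats/min (> 0).
#' @param P0 optional 10x10 initial covariance; a broad default is used
#'   otherwise (variance 25 mm^2 on means/positions, 100 mm^2/s^2 on
#'   velocities, `(0.2 * omega0)^2` on omega).
#' @return A list with `s` (10-vector), `P` (10x10), `T` and `omega0`.
#' @export
init_state <- function(trajectory_3d, heart_rate_bpm, P0 = NULL) {
  trajectory_3d <- as.matrix(trajectory_3d)
  K <- nrow(trajectory_3d)
  stopifnot(K >= 3L, ncol(trajectory_3d) == 3L)
  if (!is.finite(heart_rate_bpm) || heart_rate_bpm <= 0)
    stop("init_state: heart rate must be > 0")
  T <- (60 / heart_rate_bpm) / K
  omega0 <- 2 * pi * heart_rate_bpm / 60
  mns <- colMeans(trajectory_3d)
  vel <- (trajectory_3d[2, ] - trajectory_3d[1, ]) / T
  s <- numeric(10)
  for (a in 1:3) s[3 * (a - 1) + 1:3] <- c(mns[a], trajectory_3d[1, a], vel[a])
  s[10] <- omega0
  if (is.null(P0))
    P0 <- diag(c(rep(c(25, 25, 100), 3), (0.2 * omega0)^2))
  list(s = s, P = P0, T = T, omega0 = omega0)
}

symmetrize <- function(P) (P + t(P)) / 2

repair_psd <- function(P, where = "covariance") {
  P <- symmetrize(P)
  for (k in 0:3) {
    ok <- tryCatch({ chol(P + diag(1e-300, nrow(P))); TRUE },
                   error = function(e) FALSE)
    if (ok) return(P)
    if (k == 3) break
    P <- P + diag(1e-9 * max(sum(diag(P)), 1e-12), nrow(P))
  }
  stop("numerical failure: covariance not positive definite after jitter repair at ",
       where)
}

mat_sqrt_cols <- function(P) {
  e <- eigen(symmetrize(P), symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), length(v))
}

ut_weights <- function(n, alpha, beta, kappa) {
  lambda <- alpha^2 * (n + kappa) - n
  wm <- c(lambda / (n + lambda), rep(1 / (2 * (n + lambda)), 2 * n))
  wc <- wm
  wc[1] <- wc[1] + 1 - alpha^2 + beta
  list(wm = wm, wc = wc, c = n + lambda)
}

sigma_points <- function(m, P, w) {
  n <- length(m)
  S <- mat_sqrt_cols(w$c * P)
  chi <- matrix(m, n, 2 * n + 1)
  chi[, 2:(n + 1)] <- chi[, 2:(n + 1)] + S
  chi[, (n + 2):(2 * n + 1)] <- chi[, (n + 2):(2 * n + 1)] - S
  # frequency sign is unidentifiable: reflect negative omega about 0
  chi[10, ] <- abs(chi[10, ])
  chi
}

ukf_step_predict <- function(m, P, model, w) {
  chi <- sigma_points(m, P, w)
  chi_p <- apply(chi, 2, propagate, T = model$T)
  m_pred <- drop(chi_p %*% w$wm)
  dm <- chi_p - m_pred
  P_pred <- dm %*% (w$wc * t(dm)) + model$Q
  dm0 <- chi - m
  C <- dm0 %*% (w$wc * t(dm))          # cross-covariance cov(s_k, s_{k+1|k})
  list(m = m_pred, P = symmetrize(P_pred), C = C)
}

as_observation_matrix <- function(observations) {
  if (is.list(observations) && !is.null(observations[[1]]$z))
    observations <- do.call(rbind, lapply(observations, function(o) o$z))
  z <- as.matrix(observations)
  stopifnot(ncol(z) == 3L)
  z
}

#' Unscented Kalman filter for the cyclic state model
#'
#' Standard scaled unscented filter: 21 sigma points are propagated through
#' the cyclic transition; because the measurement is linear in the state, the
#' update is the exact linear Kalman update. Covariances are symmetrized each
#' step and repaired by jitter if positive definiteness is lost.
#'
#' The first returned state is the update of `init` with the first
#' observation.
#'
#' @param observations `K x 3` matrix of 3D position observations, mm (or a
#'   list of `list(z = ...)`).
#' @param model a [model_spec()].
#' @param init initial state, as returned by [init_state()] (`s`, `P`).
#' @param keep_internals retain prediction quantities for the smoother.
#' @return A list of `K` filtered states, each `list(s, P)`; with internals
#'   attached as an attribute when requested.
#' @export
ukf_filter <- function(observations, model, init, keep_internals = FALSE) {
  z <- as_observation_matrix(observations)
  K <- nrow(z)
  stopifnot(K >= 2L)
  H <- measurement_matrix()
  w <- ut_weights(10L, model$alpha, model$beta, model$kappa)
  m <- init$s; P <- repair_psd(init$P, "init")
  filt <- vector("list", K)
  preds <- if (keep_internals) vector("list", K - 1L) else NULL
  for (k in seq_len(K)) {
    if (k > 1L) {
      pr <- tryCatch(ukf_step_predict(m, P, model, w),
                     error = function(e) stop("numerical failure at frame ", k,
                                              ": ", conditionMessage(e)))
      if (keep_internals) preds[[k - 1L]] <- pr
      m <- pr$m; P <- pr$P
    }
    S <- H %*% P %*% t(H) + model$R
    Kg <- t(solve(S, H %*% P))
    m <- m + drop(Kg %*% (z[k, ] - H %*% m))
    P <- repair_psd(P - Kg %*% S %*% t(Kg), paste0("frame ", k))
    filt[[k]] <- list(s = m, P = P)
  }
  if (keep_internals) attr(filt, "internals") <- list(preds = preds, w = w)
  filt
}

#' Unscented Rauch-Tung-Striebel smoother
#'
#' Fixed-interval smoothing: a backward pass over the forward
#' [ukf_filter()] output using the unscented RTS gain
#' `G_k = C_k P_{k+1|k}^{-1}`, where `C_k` is the sigma-point
#' cross-covariance between the filtered state at `k` and its prediction at
#' `k+1`. The smoothed state at every frame uses the full observation record
#' `z_{1:K}`.
#'
#' @inheritParams ukf_filter
#' @return A list of `K` smoothed states, each `list(s, P)`.
#' @export
uks_smooth <- function(observations, model, init) {
  filt <- ukf_filter(observations, model, init, keep_internals = TRUE)
  internals <- attr(filt, "internals")
  K <- length(filt)
  sm <- filt
  attr(sm, "internals") <- NULL
  for (k in (K - 1L):1L) {
    pr <- internals$preds[[k]]
    G <- t(solve(pr$P, t(pr$C)))
    s_s <- filt[[k]]$s + drop(G %*% (sm[[k + 1L]]$s - pr$m))
    P_s <- filt[[k]]$P + G %*% (sm[[k + 1L]]$P - pr$P) %*% t(G)
    sm[[k]] <- list(s = s_s, P = repair_psd(P_s, paste0("smoother frame ", k)))
  }
  sm
}

#' Assemble a per-view track of smoothed states
#'
#' Bundles smoothed states with their view and point identity for fusion.
#'
#' @param states list of `list(s, P)` smoothed states.
#' @param view_id view identifier.
#' @param geometry the view's [plane_geometry()].
#' @param point_id point identifier.
#' @return An object of class `view_track`.
#' @export
view_track <- function(states, view_id, geometry = NULL, point_id = NA) {
  structure(list(states = states, view_id = view_id,
                 geometry = geometry, point_id = point_id),
            class = "view_track")
}

#' Positions of a track as a matrix
#'
#' @param track a `view_track`/`fused_track` or plain list of states.
#' @return `K x 3` matrix of position components.
#' @export
track_positions <- function(track) {
  states <- if (!is.null(track$states)) track$states else track
  t(vapply(states, function(st) measure(st$s), numeric(3)))
}
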