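# Independent oracles and fixture builders shared across tests.

random_pd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(0.1, n)
}

# random plane geometry with orthonormal direction cosines
random_geometry <- function(spacing = c(1.5, 1.2), n = 64L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  plane_geometry(origin = rnorm(3, sd = 20), row_cosine = Q[, 1],
                 col_cosine = Q[, 2], spacing = spacing,
                 n_rows = n, n_cols = n)
}

blkdiag3 <- function(F3) {
  M <- diag(10)
  for (a in 0:2) M[3 * a + 1:3, 3 * a + 1:3] <- F3
  M
}

# classical linear Kalman filter with fixed transition matrix (oracle)
linear_kf <- function(z, Fm, H, Q, R, m0, P0) {
  K <- nrow(z)
  filt_m <- vector("list", K); filt_P <- vector("list", K)
  pred_m <- vector("list", K); pred_P <- vector("list", K)
  m <- m0; P <- P0
  for (k in seq_len(K)) {
    if (k > 1) { m <- drop(Fm %*% m); P <- Fm %*% P %*% t(Fm) + Q }
    pred_m[[k]] <- m; pred_P[[k]] <- P
    S <- H %*% P %*% t(H) + R
    Kg <- P %*% t(H) %*% solve(S)
    m <- m + drop(Kg %*% (z[k, ] - H %*% m))
    P <- P - Kg %*% S %*% t(Kg)
    P <- (P + t(P)) / 2
    filt_m[[k]] <- m; filt_P[[k]] <- P
  }
  list(filt_m = filt_m, filt_P = filt_P, pred_m = pred_m, pred_P = pred_P)
}

# classical RTS smoother on linear_kf output (oracle)
linear_rts <- function(kf, Fm) {
  K <- length(kf$filt_m)
  sm_m <- kf$filt_m; sm_P <- kf$filt_P
  for (k in (K - 1):1) {
    G <- kf$filt_P[[k]] %*% t(Fm) %*% solve(kf$pred_P[[k + 1]])
    sm_m[[k]] <- kf$filt_m[[k]] + drop(G %*% (sm_m[[k + 1]] - kf$pred_m[[k + 1]]))
    sm_P[[k]] <- kf$filt_P[[k]] +
      G %*% (sm_P[[k + 1]] - kf$pred_P[[k + 1]]) %*% t(G)
  }
  list(sm_m = sm_m, sm_P = sm_P)
}

# manufactured div-curl problem from analytic potentials on an n x n grid;
# returns mu, gamma and the analytic field at the staggered locations where
# the discrete components live
manufactured_divcurl <- function(n, A = 2) {
  f_p <- function(i, j) {
    u <- (i - 1) / (n - 1); v <- (j - 1) / (n - 1)
    A * (sin(pi * u) * sin(pi * v))^3
  }
  f_s <- function(i, j) {
    u <- (i - 1) / (n - 1); v <- (j - 1) / (n - 1)
    0.5 * A * (sin(pi * u) * sin(pi * v))^2 * sin(2 * pi * u)
  }
  I <- outer(seq_len(n), rep(1, n)); J <- t(I)
  d <- 1e-3
  gx <- function(f, i, j) (f(i + d, j) - f(i - d, j)) / (2 * d)
  gy <- function(f, i, j) (f(i, j + d) - f(i, j - d)) / (2 * d)
  lap <- function(f, i, j)
    (f(i + d, j) + f(i - d, j) + f(i, j + d) + f(i, j - d) - 4 * f(i, j)) / d^2
  mu <- 1 + lap(f_p, I, J)
  mu <- mu / mean(mu)
  list(mu = mu, gamma = -lap(f_s, I, J),
       rho_r = gx(f_p, I + 0.5, J) + gy(f_s, I, J - 0.5),
       rho_c = gy(f_p, I, J + 0.5) - gx(f_s, I - 0.5, J))
}

# smooth rho built from the package's own discrete operators (exactly
# representable), scaled to a target peak displacement
discrete_divcurl_fixture <- function(n, peak_px = 3, seed = 3) {
  set.seed(seed)
  I <- outer(seq_len(n), rep(1, n)); J <- t(I)
  win <- (sin(pi * (I - 1) / (n - 1)) * sin(pi * (J - 1) / (n - 1)))^2
  bump <- function(cx, cy, s) {
    u <- (I - 1) / (n - 1); v <- (J - 1) / (n - 1)
    exp(-((u - cx)^2 + (v - cy)^2) / s)
  }
  pf <- bump(0.45, 0.55, 0.08) * win^2
  psf <- 3 * bump(0.55, 0.45, 0.1) * win^2
  mk <- function(sc) {
    rho <- array(0, dim = c(n, n, 2))
    rho[, , 1] <- cinefuse:::d_fwd(pf * sc, 1) + cinefuse:::d_bwd(psf * sc, 2)
    rho[, , 2] <- cinefuse:::d_fwd(pf * sc, 2) - cinefuse:::d_bwd(psf * sc, 1)
    rho[c(1, n), , ] <- 0; rho[, c(1, n), ] <- 0
    rho
  }
  r0 <- mk(1)
  sc <- peak_px / max(sqrt(r0[, , 1]^2 + r0[, , 2]^2))
  rho <- mk(sc)
  mu <- 1 + cinefuse:::div_field(rho)
  mu <- mu / mean(mu)
  list(rho = rho, mu = mu, gamma = cinefuse:::curl_field(rho))
}

smooth_texture <- function(n, seed = 3) {
  set.seed(seed)
  tex <- cinefuse:::smooth_noise_image(n, n, 2)
  (tex - min(tex)) / (max(tex) - min(tex))
}

# forward-Euler fine-step integration of the moving-mesh flow (oracle)
euler_flow <- function(rho, mu, n_steps = 1000L) {
  nr <- dim(rho)[1]; nc <- dim(rho)[2]
  pr <- rep(seq_len(nr), nc); pc <- rep(seq_len(nc), each = nr)
  rr <- rho[, , 1]; rc_ <- rho[, , 2]
  h <- 1 / n_steps
  t <- 0
  for (s in seq_len(n_steps)) {
    den <- t + (1 - t) * cinefuse:::interp_bilinear(mu, pr, pc)
    pr2 <- pr + h * cinefuse:::interp_bilinear(rr, pr, pc) / den
    pc2 <- pc + h * cinefuse:::interp_bilinear(rc_, pr, pc) / den
    pr <- pmin(pmax(pr2, 1), nr); pc <- pmin(pmax(pc2, 1), nc)
    t <- t + h
  }
  list(phi_r = matrix(pr, nr, nc), phi_c = matrix(pc, nr, nc))
}
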