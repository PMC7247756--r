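## Diffeomorphic moving-mesh registration.
##
## The transformation between adjacent frames is parameterized by a monitor
## function mu (the prescribed Jacobian determinant, mean 1 over the grid)
## and a curl field gamma. A vector field rho with div rho = mu - 1 and
## curl rho = gamma (rho = 0 on the boundary) is turned into a velocity
## field nu_t = rho / (t + (1 - t) mu) whose flow over t in [0, 1] yields
## the transformation phi with det J_phi ~ mu. The L2 image dissimilarity
## is minimized by gradient descent on (mu, gamma) with a monotone
## step-halving line search.

# ---- grid utilities ---------------------------------------------------------

#' Bilinear interpolation on a matrix grid
#'
#' Samples `M` at continuous (row, col) positions (1-based), clamping
#' coordinates to the grid.
#'
#' @param M numeric matrix.
#' @param r,c coordinate vectors.
#' @return Vector of sampled values.
#' @keywords internal
interp_bilinear <- function(M, r, c) {
  nr <- nrow(M); nc <- ncol(M)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  M <- as.vector(M)
  (M[i00] * (1 - fr) + M[i00 + 1] * fr) * (1 - fc) +
    (M[i00 + nr] * (1 - fr) + M[i00 + nr + 1] * fr) * fc
}

gauss_kernel <- function(sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k / sum(k)
}

conv1_reflect <- function(M, k, along) {
  rad <- (length(k) - 1L) / 2L
  n <- if (along == 1L) nrow(M) else ncol(M)
  idx <- seq_len(n)
  out <- 0
  for (s in -rad:rad) {
    j <- idx + s
    j <- ifelse(j < 1L, 2L - j, ifelse(j > n, 2L * n - j, j))
    out <- out + k[s + rad + 1L] *
      (if (along == 1L) M[j, , drop = FALSE] else M[, j, drop = FALSE])
  }
  out
}

gauss_blur <- function(M, sigma) {
  if (sigma <= 0) return(M)
  k <- gauss_kernel(sigma)
  conv1_reflect(conv1_reflect(M, k, 1L), k, 2L)
}

image_gradient <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  gr <- (M[c(2:nr, nr), ] - M[c(1, 1:(nr - 1)), ]) /
    matrix(c(1, rep(2, nr - 2), 1), nr, nc)
  gc <- (M[, c(2:nc, nc)] - M[, c(1, 1:(nc - 1))]) /
    matrix(c(1, rep(2, nc - 2), 1), nr, nc, byrow = TRUE)
  list(gr = gr, gc = gc)
}

# forward/backward first differences (unit spacing) and their adjoints
d_fwd <- function(M, along) {
  n <- if (along == 1L) nrow(M) else ncol(M)
  if (along == 1L) rbind(M[2:n, , drop = FALSE] - M[1:(n - 1), , drop = FALSE],
                         matrix(0, 1, ncol(M)))
  else cbind(M[, 2:n, drop = FALSE] - M[, 1:(n - 1), drop = FALSE],
             matrix(0, nrow(M), 1))
}

d_bwd <- function(M, along) {
  n <- if (along == 1L) nrow(M) else ncol(M)
  if (along == 1L) rbind(M[1, , drop = FALSE],
                         M[2:n, , drop = FALSE] - M[1:(n - 1), , drop = FALSE])
  else cbind(M[, 1, drop = FALSE],
             M[, 2:n, drop = FALSE] - M[, 1:(n - 1), drop = FALSE])
}

adj_d_fwd <- function(G, along) {
  n <- if (along == 1L) nrow(G) else ncol(G)
  if (along == 1L) rbind(-G[1, , drop = FALSE],
                         G[1:(n - 2), , drop = FALSE] - G[2:(n - 1), , drop = FALSE],
                         G[n - 1, , drop = FALSE])
  else cbind(-G[, 1, drop = FALSE],
             G[, 1:(n - 2), drop = FALSE] - G[, 2:(n - 1), drop = FALSE],
             G[, n - 1, drop = FALSE])
}

adj_d_bwd <- function(G, along) {
  n <- if (along == 1L) nrow(G) else ncol(G)
  if (along == 1L) rbind(G[1:(n - 1), , drop = FALSE] - G[2:n, , drop = FALSE],
                         G[n, , drop = FALSE])
  else cbind(G[, 1:(n - 1), drop = FALSE] - G[, 2:n, drop = FALSE],
             G[, n, drop = FALSE])
}

div_field <- function(rho) d_bwd(rho[, , 1], 1L) + d_bwd(rho[, , 2], 2L)
curl_field <- function(rho) d_fwd(rho[, , 2], 1L) - d_fwd(rho[, , 1], 2L)

# ---- div-curl solver --------------------------------------------------------

lap1_neumann <- function(n)
  Matrix::bandSparse(n, n, k = -1:1,
                     diagonals = list(rep(1, n - 1),
                                      c(-1, rep(-2, n - 2), -1),
                                      rep(1, n - 1)))

lap1_dirichlet <- function(n)
  Matrix::bandSparse(n, n, k = -1:1,
                     diagonals = list(rep(1, n - 1), rep(-2, n),
                                      rep(1, n - 1)))

.ops_cache <- new.env(parent = emptyenv())

divcurl_ops <- function(nr, nc) {
  key <- paste(nr, nc, sep = "x")
  if (!is.null(.ops_cache[[key]])) return(.ops_cache[[key]])
  AN <- Matrix::kronecker(Matrix::Diagonal(nc), lap1_neumann(nr)) +
    Matrix::kronecker(lap1_neumann(nc), Matrix::Diagonal(nr))
  # pin node 1 symmetrically to remove the constant nullspace
  AN[1, ] <- 0; AN[, 1] <- 0; AN[1, 1] <- -1
  chN <- Matrix::Cholesky(Matrix::forceSymmetric(-AN), LDL = FALSE)
  AD <- Matrix::kronecker(Matrix::Diagonal(nc - 2), lap1_dirichlet(nr - 2)) +
    Matrix::kronecker(lap1_dirichlet(nc - 2), Matrix::Diagonal(nr - 2))
  chD <- Matrix::Cholesky(Matrix::forceSymmetric(-AD), LDL = FALSE)
  ops <- list(
    nr = nr, nc = nc,
    solve_neumann = function(b) {       # A_N x = b (b mean-compatible)
      b <- as.vector(b); b[1] <- 0
      matrix(as.vector(Matrix::solve(chN, -b)), nr, nc)
    },
    solve_dirichlet = function(b_int) { # A_D x = b on the interior grid
      x <- matrix(0, nr, nc)
      x[2:(nr - 1), 2:(nc - 1)] <-
        matrix(as.vector(Matrix::solve(chD, -as.vector(b_int))),
               nr - 2, nc - 2)
      x
    })
  .ops_cache[[key]] <- ops
  ops
}

#' Monitor-field pair for the moving-mesh transformation
#'
#' Validates the monitor function `mu` (strictly positive, grid mean 1 —
#' the discrete form of the area constraint) and the curl field `gamma`.
#'
#' @param mu,gamma numeric matrices of equal size.
#' @param tol tolerance on `mean(mu) - 1`.
#' @return A list of class `monitor_field`.
#' @export
monitor_field <- function(mu, gamma = NULL, tol = 1e-6) {
  mu <- as.matrix(mu)
  if (is.null(gamma)) gamma <- matrix(0, nrow(mu), ncol(mu))
  gamma <- as.matrix(gamma)
  stopifnot(all(dim(mu) == dim(gamma)))
  if (any(mu <= 0)) stop("monitor_field: mu must be strictly positive")
  if (abs(mean(mu) - 1) > tol)
    stop("monitor_field: mean(mu) = ", format(mean(mu)), " incompatible with ",
         "the area constraint (|mean - 1| > ", tol, ")")
  structure(list(mu = mu, gamma = gamma), class = "monitor_field")
}

#' Solve the div-curl system of the moving-mesh method
#'
#' Returns the vector field `rho` with `div rho = mu - 1`,
#' `curl rho = gamma` and `rho = 0` on the boundary, via the Helmholtz
#' split `rho = grad p + curl psi` with `lap p = mu - 1` (Neumann) and
#' `lap psi = -gamma` (Dirichlet). The discrete gradient/divergence and
#' curl pairs are chosen so that both compositions collapse to exact
#' 5-point Laplacians: away from the boundary ring the discrete system is
#' satisfied to solver precision.
#'
#' @param mu monitor function (matrix, mean 1 within `tol`).
#' @param gamma curl field (matrix, same size).
#' @param tol compatibility tolerance on `mean(mu) - 1`.
#' @return An `nr x nc x 2` array (components along rows and columns of the
#'   grid) with attributes `residual_div` and `residual_curl` (interior RMS,
#'   measured two nodes in from the boundary).
#' @export
solve_div_curl <- function(mu, gamma, tol = 1e-6) {
  mf <- monitor_field(mu, gamma, tol = tol)
  mu <- mf$mu; gamma <- mf$gamma
  nr <- nrow(mu); nc <- ncol(mu)
  stopifnot(nr >= 5L, nc >= 5L)
  ops <- divcurl_ops(nr, nc)
  p <- ops$solve_neumann(mu - mean(mu))
  psi <- ops$solve_dirichlet(-gamma[2:(nr - 1), 2:(nc - 1)])
  rho <- array(0, dim = c(nr, nc, 2))
  rho[, , 1] <- d_fwd(p, 1L) + d_bwd(psi, 2L)
  rho[, , 2] <- d_fwd(p, 2L) - d_bwd(psi, 1L)
  rho[c(1, nr), , ] <- 0
  rho[, c(1, nc), ] <- 0
  int_r <- 3:(nr - 2); int_c <- 3:(nc - 2)
  rd <- (div_field(rho) - (mu - 1))[int_r, int_c]
  rc <- (curl_field(rho) - gamma)[int_r, int_c]
  attr(rho, "residual_div") <- sqrt(mean(rd^2))
  attr(rho, "residual_curl") <- sqrt(mean(rc^2))
  rho
}

#' Velocity field of the moving-mesh flow at artificial time t
#'
#' `nu_t(x) = rho(x) / (t + (1 - t) mu(x))` pointwise; at `t = 1` the
#' velocity equals `rho`.
#'
#' @param rho `nr x nc x 2` vector field.
#' @param mu monitor function (strictly positive).
#' @param t artificial time in \[0, 1\].
#' @return `nr x nc x 2` velocity field.
#' @export
velocity_at <- function(rho, mu, t) {
  if (any(mu <= 0)) stop("velocity_at: mu must be strictly positive")
  den <- t + (1 - t) * mu
  out <- rho
  out[, , 1] <- rho[, , 1] / den
  out[, , 2] <- rho[, , 2] / den
  out
}

#' Dense deformation field on the pixel grid
#'
#' Stores per-pixel target coordinates (1-based row/col, sub-pixel) of a
#' map of the grid into itself, with the Jacobian determinant from centered
#' finite differences.
#'
#' @param phi_r,phi_c matrices of target row/col coordinates.
#' @return Object of class `deformation_field` with `phi_r`, `phi_c`,
#'   `jacobian_det`.
#' @export
deformation_field <- function(phi_r, phi_c) {
  cgrad <- function(M, along) {
    n <- if (along == 1L) nrow(M) else ncol(M)
    h <- c(1, rep(2, n - 2), 1)
    if (along == 1L) (M[c(2:n, n), ] - M[c(1, 1:(n - 1)), ]) / h
    else t(t(M[, c(2:n, n)] - M[, c(1, 1:(n - 1))]) / h)
  }
  jd <- cgrad(phi_r, 1L) * cgrad(phi_c, 2L) - cgrad(phi_r, 2L) * cgrad(phi_c, 1L)
  structure(list(phi_r = phi_r, phi_c = phi_c, jacobian_det = jd),
            class = "deformation_field")
}

identity_field <- function(nr, nc)
  deformation_field(matrix(seq_len(nr), nr, nc),
                    matrix(seq_len(nc), nr, nc, byrow = TRUE))

#' Apply a deformation field to sub-pixel points
#'
#' @param field a [deformation_field()].
#' @param rc `n x 2` matrix of (row, col) 1-based coordinates.
#' @return `n x 2` matrix of mapped coordinates.
#' @export
apply_field <- function(field, rc) {
  rc <- as_point_matrix(rc, 2L)
  cbind(interp_bilinear(field$phi_r, rc[, 1], rc[, 2]),
        interp_bilinear(field$phi_c, rc[, 1], rc[, 2]))
}

#' Integrate the moving-mesh flow into a deformation field
#'
#' Solves `d psi / dt = nu_t(psi)`, `psi(x, 0) = x`, over `t` in \[0, 1\]
#' with classical RK4 and bilinear sampling of the fields, returning
#' `phi(x) = psi(x, 1)`. Trajectories are clamped to the grid (the velocity
#' vanishes on the boundary by construction). The Jacobian determinant of
#' the result approximates `mu`.
#'
#' @param rho `nr x nc x 2` field from [solve_div_curl()].
#' @param mu monitor function.
#' @param n_steps number of RK4 steps (>= 1).
#' @return A [deformation_field()].
#' @export
integrate_flow <- function(rho, mu, n_steps = 10L) {
  stopifnot(n_steps >= 1L)
  if (any(mu <= 0)) stop("integrate_flow: mu must be strictly positive")
  nr <- dim(rho)[1]; nc <- dim(rho)[2]
  pr <- rep(seq_len(nr), nc)
  pc <- rep(seq_len(nc), each = nr)
  rr <- rho[, , 1]; rc_ <- rho[, , 2]
  vel <- function(r, c, t) {
    den <- t + (1 - t) * interp_bilinear(mu, r, c)
    list(vr = interp_bilinear(rr, r, c) / den,
         vc = interp_bilinear(rc_, r, c) / den)
  }
  h <- 1 / n_steps
  t <- 0
  for (s in seq_len(n_steps)) {
    k1 <- vel(pr, pc, t)
    k2 <- vel(pr + h / 2 * k1$vr, pc + h / 2 * k1$vc, t + h / 2)
    k3 <- vel(pr + h / 2 * k2$vr, pc + h / 2 * k2$vc, t + h / 2)
    k4 <- vel(pr + h * k3$vr, pc + h * k3$vc, t + h)
    pr <- pr + h / 6 * (k1$vr + 2 * k2$vr + 2 * k3$vr + k4$vr)
    pc <- pc + h / 6 * (k1$vc + 2 * k2$vc + 2 * k3$vc + k4$vc)
    out <- pr < 1 | pr > nr | pc < 1 | pc > nc
    if (any(out)) {
      pr <- pmin(pmax(pr, 1), nr)
      pc <- pmin(pmax(pc, 1), nc)
    }
    t <- t + h
  }
  deformation_field(matrix(pr, nr, nc), matrix(pc, nr, nc))
}

# ---- registration -----------------------------------------------------------

resize_bilinear <- function(M, nr2, nc2) {
  nr <- nrow(M); nc <- ncol(M)
  r <- 1 + (seq_len(nr2) - 1) * (nr - 1) / (nr2 - 1)
  c <- 1 + (seq_len(nc2) - 1) * (nc - 1) / (nc2 - 1)
  matrix(interp_bilinear(M, rep(r, nc2), rep(c, each = nr2)), nr2, nc2)
}

downsample2 <- function(M)
  gauss_blur(M, 1)[seq(1, nrow(M), by = 2), seq(1, ncol(M), by = 2)]

#' Options for the pairwise moving-mesh registration
#'
#' @param n_levels coarse-to-fine pyramid levels.
#' @param n_steps RK4 steps of the flow integration.
#' @param max_iter maximum accepted iterations per level.
#' @param tol relative energy-change convergence threshold.
#' @param mu_min,mu_max clamp range of the monitor function (diffeomorphism
#'   margin).
#' @param gamma_free optimize the curl field (`FALSE` keeps `gamma = 0`).
#' @param sigma Gaussian smoothing per pyramid level, px.
#' @param step0 initial line-search step.
#' @param max_bad_steps step halvings before the line search gives up.
#' @return Options list.
#' @export
register_opts <- function(n_levels = 3L, n_steps = 10L, max_iter = 200L,
                          tol = 1e-4, mu_min = 0.5, mu_max = 2,
                          gamma_free = TRUE, sigma = 1, step0 = 0.1,
                          max_bad_steps = 25L) {
  as.list(environment())
}

project_mu <- function(mu, mu_min, mu_max) {
  for (i in 1:3) {
    mu <- pmin(pmax(mu, mu_min), mu_max)
    mu <- mu / mean(mu)
  }
  mu
}

#' Pairwise diffeomorphic registration of adjacent frames
#'
#' Finds the moving-mesh transformation `phi` (forward map: frame-k
#' coordinates to frame-(k+1) coordinates) minimizing the mean squared
#' dissimilarity `|T_next(phi(x)) - T_k(x)|^2` over the grid, by gradient
#' descent on the monitor/curl parameterization with a 3-level
#' coarse-to-fine pyramid and a monotone step-halving line search. After
#' every step `mu` is clamped to `[mu_min, mu_max]` and rescaled to mean 1,
#' preserving the diffeomorphism margin.
#'
#' @param img_k,img_next frames on a common grid, intensities in \[0, 1\].
#' @param opts a [register_opts()] list.
#' @return A [deformation_field()] with attributes `mu`, `gamma`,
#'   `energy_initial`, `energy_final`, `energy_ratio`, `diverged`.
#' @export
register_pair <- function(img_k, img_next, opts = register_opts()) {
  img_k <- as.matrix(img_k); img_next <- as.matrix(img_next)
  stopifnot(all(dim(img_k) == dim(img_next)), all(is.finite(img_k)),
            all(is.finite(img_next)))
  rng <- range(img_k, img_next)
  if (rng[2] > rng[1]) {
    img_k <- (img_k - rng[1]) / (rng[2] - rng[1])
    img_next <- (img_next - rng[1]) / (rng[2] - rng[1])
  }
  nr <- nrow(img_k); nc <- ncol(img_k)

  pyr_k <- list(img_k); pyr_n <- list(img_next)
  for (l in seq_len(opts$n_levels - 1L)) {
    if (min(dim(pyr_k[[l]])) < 12L) break
    pyr_k[[l + 1L]] <- downsample2(pyr_k[[l]])
    pyr_n[[l + 1L]] <- downsample2(pyr_n[[l]])
  }
  n_levels <- length(pyr_k)

  mu <- NULL; gamma <- NULL
  diverged <- FALSE
  E0_full <- NA_real_
  for (l in n_levels:1) {
    Tk <- gauss_blur(pyr_k[[l]], opts$sigma)
    Tn <- gauss_blur(pyr_n[[l]], opts$sigma)
    lr <- nrow(Tk); lc <- ncol(Tk)
    if (is.null(mu)) {
      mu <- matrix(1, lr, lc); gamma <- matrix(0, lr, lc)
    } else {
      mu <- project_mu(resize_bilinear(mu, lr, lc), opts$mu_min, opts$mu_max)
      gamma <- resize_bilinear(gamma, lr, lc)
    }
    ops <- divcurl_ops(lr, lc)
    gradT <- image_gradient(Tn)
    npix <- lr * lc

    eval_energy <- function(mu, gamma) {
      p <- ops$solve_neumann(mu - mean(mu))
      psi <- ops$solve_dirichlet(-gamma[2:(lr - 1), 2:(lc - 1)])
      rho <- array(0, dim = c(lr, lc, 2))
      rho[, , 1] <- d_fwd(p, 1L) + d_bwd(psi, 2L)
      rho[, , 2] <- d_fwd(p, 2L) - d_bwd(psi, 1L)
      rho[c(1, lr), , ] <- 0; rho[, c(1, lc), ] <- 0
      fld <- integrate_flow(rho, mu, opts$n_steps)
      warped <- matrix(interp_bilinear(Tn, as.vector(fld$phi_r),
                                       as.vector(fld$phi_c)), lr, lc)
      list(E = mean((warped - Tk)^2), field = fld, warped = warped)
    }

    cur <- eval_energy(mu, gamma)
    if (l == n_levels) E0_coarse <- cur$E
    if (l == 1L) E0_full <- cur$E
    if (cur$E < 1e-14) next  # identical (or constant) frames: identity
    step <- opts$step0
    for (it in seq_len(opts$max_iter)) {
      resid <- cur$warped - Tk
      g_r <- 2 / npix * resid *
        matrix(interp_bilinear(gradT$gr, as.vector(cur$field$phi_r),
                               as.vector(cur$field$phi_c)), lr, lc)
      g_c <- 2 / npix * resid *
        matrix(interp_bilinear(gradT$gc, as.vector(cur$field$phi_r),
                               as.vector(cur$field$phi_c)), lr, lc)
      g_r[c(1, lr), ] <- 0; g_r[, c(1, lc)] <- 0
      g_c[c(1, lr), ] <- 0; g_c[, c(1, lc)] <- 0
      dE_dp <- adj_d_fwd(g_r, 1L) + adj_d_fwd(g_c, 2L)
      d_mu <- ops$solve_neumann(dE_dp - mean(dE_dp))
      d_gamma <- matrix(0, lr, lc)
      if (opts$gamma_free) {
        dE_dpsi <- adj_d_bwd(g_r, 2L) - adj_d_bwd(g_c, 1L)
        d_gamma <- -ops$solve_dirichlet(dE_dpsi[2:(lr - 1), 2:(lc - 1)])
      }
      scale <- max(abs(d_mu), abs(d_gamma), 1e-12)
      d_mu <- d_mu / scale; d_gamma <- d_gamma / scale

      accepted <- FALSE
      for (h in seq_len(opts$max_bad_steps)) {
        mu_c <- project_mu(mu - step * d_mu, opts$mu_min, opts$mu_max)
        ga_c <- gamma - step * d_gamma
        cand <- eval_energy(mu_c, ga_c)
        if (cand$E < cur$E) {
          accepted <- TRUE
          rel <- (cur$E - cand$E) / max(cur$E, 1e-14)
          mu <- mu_c; gamma <- ga_c; cur <- cand
          step <- min(step * 2, 10)
          if (rel < opts$tol) it <- opts$max_iter  # converged
          break
        }
        step <- step / 2
      }
      if (!accepted) { diverged <- diverged || (it == 1L); break }
      if (it == opts$max_iter) break
    }
  }

  final <- {
    p <- divcurl_ops(nr, nc)  # finest-level ops (cached)
    eval_final <- function() {
      pm <- p$solve_neumann(mu - mean(mu))
      psi <- p$solve_dirichlet(-gamma[2:(nr - 1), 2:(nc - 1)])
      rho <- array(0, dim = c(nr, nc, 2))
      rho[, , 1] <- d_fwd(pm, 1L) + d_bwd(psi, 2L)
      rho[, , 2] <- d_fwd(pm, 2L) - d_bwd(psi, 1L)
      rho[c(1, nr), , ] <- 0; rho[, c(1, nc), ] <- 0
      integrate_flow(rho, mu, opts$n_steps)
    }
    eval_final()
  }
  warped <- matrix(interp_bilinear(img_next, as.vector(final$phi_r),
                                   as.vector(final$phi_c)), nr, nc)
  Ef <- mean((warped - img_k)^2)
  if (is.na(E0_full)) E0_full <- Ef
  attr(final, "mu") <- mu
  attr(final, "gamma") <- gamma
  attr(final, "energy_initial") <- mean((img_next - img_k)^2)
  attr(final, "energy_final") <- Ef
  attr(final, "energy_ratio") <- Ef / max(mean((img_next - img_k)^2), 1e-14)
  attr(final, "diverged") <- diverged
  if (diverged) warning("register_pair: line search stalled; returning best iterate")
  final
}

#' Track seed points through a frame sequence
#'
#' Registers every adjacent frame pair and advances the seeds through the
#' composed forward maps with bilinear sub-pixel sampling of each field:
#' `trajectory[p, k + 1, ] = phi_k(trajectory[p, k, ])`.
#'
#' @param frames list of `K >= 2` frames on a common grid.
#' @param seeds `n x 2` matrix of zero-based `(i, j) = (column, row)` pixel
#'   coordinates on frame 1 (inside the grid).
#' @param opts a [register_opts()] list.
#' @param return_fields also return the per-pair deformation fields.
#' @return An `n x K x 2` array of zero-based `(i, j)` trajectories, with
#'   the fields in `attr(, "fields")` when requested.
#' @export
track_points <- function(frames, seeds, opts = register_opts(),
                         return_fields = FALSE) {
  K <- length(frames)
  stopifnot(K >= 2L)
  seeds <- as_point_matrix(seeds, 2L)
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  if (any(seeds[, 1] < 0 | seeds[, 1] > nc - 1 |
          seeds[, 2] < 0 | seeds[, 2] > nr - 1))
    stop("track_points: seed outside the image grid")
  n <- nrow(seeds)
  traj <- array(0, dim = c(n, K, 2))
  traj[, 1, ] <- seeds
  cur <- cbind(seeds[, 2] + 1, seeds[, 1] + 1)  # (row, col) 1-based
  fields <- if (return_fields) vector("list", K - 1L) else NULL
  for (k in seq_len(K - 1L)) {
    fld <- register_pair(frames[[k]], frames[[k + 1L]], opts)
    if (return_fields) fields[[k]] <- fld
    cur <- apply_field(fld, cur)
    traj[, k + 1L, ] <- cbind(cur[, 2] - 1, cur[, 1] - 1)
  }
  if (return_fields) attr(traj, "fields") <- fields
  traj
}
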