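test_that("transition block has the cyclic-oscillator structure", {
  expect_equal(transition_block(2 * pi, 1), diag(3), tolerance = 1e-12)
  # omega -> 0 limit is the constant-velocity block
  expect_equal(transition_block(1e-12, 0.05),
               matrix(c(1, 0, 0, 0, 1, 0.05, 0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(transition_block(1e-6, 0.05),
               matrix(c(1, 0, 0, 0, 1, 0.05, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-6)
  # half period reflects about the mean and reverses velocity
  expect_equal(transition_block(pi, 1),
               matrix(c(1, 0, 0, 2, -1, 0, 0, 0, -1), 3, 3, byrow = TRUE),
               tolerance = 1e-12)
  # eigenvalues {1, exp(+-i omega T)} for random omega, T
  set.seed(1)
  for (i in 1:20) {
    om <- runif(1, 0.5, 12); T <- runif(1, 0.01, 0.3)
    ev <- eigen(transition_block(om, T))$values
    expect_equal(sort(Mod(ev)), rep(1, 3), tolerance = 1e-9)
    expect_equal(sort(Arg(ev)), sort(c(-om * T, 0, om * T) %% (2 * pi) -
                                     2 * pi * (c(-om * T, 0, om * T) %% (2 * pi) > pi)),
                 tolerance = 1e-9)
  }
  expect_error(transition_block(1, 0), "T must be")
})

test_that("propagation matches the explicit formula and conserves the oscillator invariant", {
  # direct formula oracle on a random state
  set.seed(2)
  s <- c(rnorm(9, sd = 5), 4.2)
  T <- 0.04
  out <- propagate(s, T)
  wt <- s[10] * T
  for (a in 0:2) {
    xb <- s[3 * a + 1]; x <- s[3 * a + 2]; v <- s[3 * a + 3]
    expect_equal(out[3 * a + 1], xb)
    expect_equal(out[3 * a + 2],
                 (1 - cos(wt)) * xb + cos(wt) * x + sin(wt) / s[10] * v,
                 tolerance = 1e-12)
    expect_equal(out[3 * a + 3],
                 s[10] * sin(wt) * xb - s[10] * sin(wt) * x + cos(wt) * v,
                 tolerance = 1e-12)
  }
  expect_equal(out[10], s[10])

  # equilibrium is a fixed point
  eq <- c(1, 1, 0, -2, -2, 0, 5, 5, 0, 3)
  expect_equal(propagate(eq, 0.1), eq)

  # noise-free propagation conserves omega^2 (x - xbar)^2 + xdot^2
  s <- c(0, 3, 0, 1, 2, 4, -2, 0, 1, 5)
  inv0 <- s[10]^2 * (s[2] - s[1])^2 + s[3]^2
  cur <- s
  for (k in 1:1000) cur <- propagate(cur, 0.013)
  inv1 <- cur[10]^2 * (cur[2] - cur[1])^2 + cur[3]^2
  expect_equal(inv1, inv0, tolerance = 1e-9)

  # full period returns the state
  om <- 2 * pi; n <- 25; T <- 2 * pi / om / n
  cur <- c(0, 1, 0, 0, 0, 0, 0, 0, 0, om)
  for (k in seq_len(n)) cur <- propagate(cur, T)
  expect_equal(cur[2], 1, tolerance = 1e-9)
  expect_equal(cur[3], 0, tolerance = 1e-9)
})

test_that("measurement extracts the three position components", {
  s <- c(0, 1, 2, 0, 3, 4, 0, 5, 6, 1)
  expect_equal(measure(s), c(1, 3, 5))
  set.seed(3)
  s <- rnorm(10)
  expect_equal(measure(s), s[c(2, 5, 8)])
  eq <- c(1, 1, 0, 2, 2, 0, 3, 3, 0, 2)
  expect_equal(measure(propagate(eq, 0.1)), measure(eq))
})

test_that("init_state uses heart rate and frame count for T and omega", {
  traj <- matrix(rep(c(1, 2, 3), each = 20), ncol = 3)
  init <- init_state(traj, heart_rate_bpm = 60)
  expect_equal(init$T, 0.05)
  expect_equal(init$omega0, 2 * pi)
  expect_equal(init$s[c(1, 4, 7)], c(1, 2, 3))   # means
  expect_equal(init$s[c(3, 6, 9)], c(0, 0, 0))   # velocities
  # sinusoid temporal mean within amplitude / K of the true mean
  K <- 16
  x <- 2 + 1.5 * cos(2 * pi * (seq_len(K) - 1) / K + 0.3)
  init <- init_state(cbind(x, 0, 0), 75)
  expect_lt(abs(init$s[1] - 2), 1.5 / K + 1e-9)
  expect_error(init_state(traj, -5), "heart rate")
})

test_that("with frozen omega the UKF/UKS equal the linear KF/RTS oracle", {
  set.seed(4)
  om <- 2 * pi; T <- 0.05; K <- 20
  Fm <- blkdiag3(transition_block(om, T))
  truth <- matrix(0, K, 10)
  truth[1, ] <- c(0, 2, 0, 1, 3, 5, -1, 0, 3, om)
  for (k in 2:K) truth[k, ] <- propagate(truth[k - 1, ], T)
  z <- truth[, c(2, 5, 8)] + matrix(rnorm(3 * K, sd = 0.4), K, 3)

  model <- model_spec(T = T, q_pos = 1, q_omega = 0, r = 0.16)
  # frozen omega: (numerically) zero frequency variance makes the model linear
  P0 <- diag(c(rep(c(4, 4, 25), 3), 1e-12))
  init <- list(s = truth[1, ] + c(rnorm(9, sd = 0.3), 0), P = P0)

  H <- cinefuse:::measurement_matrix()
  kf <- linear_kf(z, Fm, H, model$Q, model$R, init$s, P0)
  filt <- ukf_filter(z, model, init)
  for (k in c(1, 5, 10, 20)) {
    expect_equal(filt[[k]]$s, kf$filt_m[[k]], tolerance = 1e-6)
    expect_equal(filt[[k]]$P, kf$filt_P[[k]], tolerance = 1e-6)
  }
  rts <- linear_rts(kf, Fm)
  sm <- uks_smooth(z, model, init)
  for (k in c(1, 7, 19)) {
    expect_equal(sm[[k]]$s, rts$sm_m[[k]], tolerance = 1e-6)
    expect_equal(sm[[k]]$P, rts$sm_P[[k]], tolerance = 1e-6)
  }
})

test_that("the filter locks onto noise-free model-generated data", {
  om <- 5; T <- 0.06; K <- 15
  truth <- matrix(0, K, 10)
  truth[1, ] <- c(1, 3, 0, -2, -2, 4, 0, 1, -1, om)
  for (k in 2:K) truth[k, ] <- propagate(truth[k - 1, ], T)
  z <- truth[, c(2, 5, 8)]
  model <- model_spec(T = T, q_pos = 1e-10, q_omega = 1e-12, r = 1e-10)
  init <- list(s = truth[1, ], P = diag(rep(1e-8, 10)))
  filt <- ukf_filter(z, model, init)
  for (k in 4:K)
    expect_lt(max(abs(measure(filt[[k]]$s) - z[k, ])), 1e-3)
})

test_that("a repeatedly observed stationary point drives the state to equilibrium", {
  K <- 40
  z <- matrix(rep(c(4, -1, 2), each = K), K, 3)
  model <- model_spec(T = 0.05, q_pos = 0.1, r = 0.01)
  init <- list(s = c(0, 5, 3, 0, 0, 3, 0, 0, 3, 2 * pi),
               P = diag(c(rep(c(25, 25, 100), 3), 1)))
  filt <- ukf_filter(z, model, init)
  sf <- filt[[K]]$s
  expect_equal(measure(sf), c(4, -1, 2), tolerance = 0.05)
  expect_lt(max(abs(sf[c(3, 6, 9)])), 0.5)  # velocities decay
})

test_that("smoothing tightens covariances and recovers omega on phantom tracks", {
  spec <- phantom_spec(K = 20, noise_sd = 0, seed = 9)
  gt <- make_motion(spec)
  z <- matrix(gt$pos[14, , ], ncol = 3)
  init <- init_state(z, spec$heart_rate_bpm)
  model <- model_spec(T = init$T, r = 0.25)
  filt <- ukf_filter(z, model, init)
  sm <- uks_smooth(z, model, init)
  for (k in seq_len(19))
    expect_lte(sum(diag(sm[[k]]$P)), sum(diag(filt[[k]]$P)) + 1e-9)
  om_sm <- stats::median(vapply(sm, function(s) s$s[10], numeric(1)))
  expect_lt(abs(om_sm - gt$omega) / gt$omega, 0.05)

  # constant-position noiseless track: velocities vanish
  zc <- matrix(rep(c(2, 3, 4), each = 20), 20, 3)
  initc <- init_state(zc, 60)
  mc <- model_spec(T = initc$T, q_pos = 1e-12, q_omega = 1e-12, r = 1e-12)
  smc <- uks_smooth(zc, mc, initc)
  for (k in c(1, 10, 20))
    expect_lt(max(abs(smc[[k]]$s[c(3, 6, 9)])), 1e-6)
})

test_that("smoothed covariances are close to calibrated on Monte-Carlo tracks", {
  # coverage check: for a calibrated smoother the position NEES follows a
  # chi-square(3); its 95% interval should cover ~95% of the samples.
  # A mild overconfidence is tolerated (coverage >= 0.90).
  spec <- phantom_spec(K = 20, noise_sd = 0.5, seed = 60)
  gt <- make_motion(spec)
  truth <- matrix(gt$pos[14, , ], ncol = 3)
  set.seed(60)
  M <- 200
  vals <- numeric(M * 20)
  for (m in seq_len(M)) {
    z <- truth + matrix(rnorm(60, sd = 0.5), ncol = 3)
    init <- init_state(z, spec$heart_rate_bpm)
    sm <- uks_smooth(z, model_spec(T = init$T, r = 0.25), init)
    for (k in 1:20) {
      e <- measure(sm[[k]]$s) - truth[k, ]
      vals[(m - 1) * 20 + k] <-
        drop(t(e) %*% solve(sm[[k]]$P[c(2, 5, 8), c(2, 5, 8)], e))
    }
  }
  iv <- qchisq(c(0.025, 0.975), df = 3)
  expect_gte(mean(vals >= iv[1] & vals <= iv[2]), 0.90)
  expect_lt(mean(vals), 4.5)   # mean NEES near the chi-square mean of 3
})
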