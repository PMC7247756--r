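circle_contour <- function(n = 60, r = 25, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

test_that("contour partition yields the level's segment count, evenly", {
  ctr <- circle_contour(60)
  seg <- partition_contour(ctr, landmark = ctr[1, ], level = "mid")
  expect_equal(seg$n_segments, 6L)
  counts <- table(factor(seg$labels, levels = 1:6))
  expect_true(all(abs(counts - 10) <= 1))

  seg_a <- partition_contour(ctr, landmark = ctr[1, ], level = "apical")
  expect_equal(seg_a$n_segments, 4L)
  expect_setequal(unique(seg_a$labels), 1:4)
  seg_b <- partition_contour(ctr, landmark = ctr[1, ], level = "basal")
  expect_equal(seg_b$n_segments, 6L)

  # rotating the landmark by one sector rotates the labels cyclically
  # (contour phased off the sector boundaries to avoid boundary ties)
  th2 <- seq(0, 2 * pi, length.out = 61)[-61] + 0.02
  ctr2 <- cbind(25 * cos(th2), 25 * sin(th2))
  lm_a <- c(25, 0)
  lm_b <- c(25 * cos(pi / 3), 25 * sin(pi / 3))
  seg_a <- partition_contour(ctr2, lm_a, level = "mid")
  seg_b <- partition_contour(ctr2, lm_b, level = "mid")
  expect_equal(seg_b$labels, ((seg_a$labels - 1 - 1) %% 6) + 1)
})

test_that("3D contours are accepted when coplanar with the landmark", {
  ctr2 <- circle_contour(40)
  R <- qr.Q(qr(matrix(c(1, 2, 0.5, -1, 0.3, 2, 0.2, 1, -1), 3)))
  ctr3 <- cbind(ctr2, 0) %*% t(R) + 5
  lm3 <- drop(c(ctr2[1, ], 0) %*% t(R)) + 5
  seg3 <- partition_contour(ctr3, lm3, level = "mid")
  expect_equal(sort(unique(seg3$labels)), 1:6)
  expect_error(partition_contour(ctr3, lm3 + R[, 3] * 5, level = "mid"),
               "off the contour plane")
})

test_that("the entropy estimator matches the Gaussian closed form", {
  set.seed(40)
  for (sigma in c(0.05, 0.3)) {
    x <- rnorm(1000, mean = 1, sd = sigma)
    h_true <- 0.5 * log(2 * pi * exp(1) * sigma^2)
    expect_equal(shannon_entropy(x), h_true, tolerance = 0.15)
    expect_equal(shannon_entropy(x, method = "kde"), h_true, tolerance = 0.15)
  }
  expect_equal(shannon_entropy(rep(2, 50)), -10)  # degenerate floor
})

test_that("radial feature is normalization-invariant and flags degeneracy", {
  set.seed(41)
  K <- 20
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  r_t <- 1 - 0.15 * (1 - cos(2 * pi * (seq_len(K) - 1) / K)) / 2
  traj <- array(0, dim = c(10, K, 2))
  for (k in seq_len(K))
    traj[, k, ] <- cbind(25 * r_t[k] * cos(th), 25 * r_t[k] * sin(th)) +
      matrix(rnorm(20, sd = 0.1), 10, 2)
  centroids <- matrix(0, K, 2)
  f1 <- radial_feature(traj, centroids)
  f2 <- radial_feature(traj * 3, centroids)  # uniform scaling
  expect_equal(f1, f2, tolerance = 0.05)
  expect_true(is.finite(f1))
  # constant radius -> degenerate floor
  traj_c <- array(rep(cbind(25 * cos(th), 25 * sin(th)), K),
                  dim = c(10, 2, K))
  traj_c <- aperm(traj_c, c(1, 3, 2))
  expect_equal(radial_feature(traj_c, centroids), -10)
  expect_error(radial_feature(traj * 0, centroids), "zero radius")
})

test_that("area feature uses the exact shoelace area and tracks scaling", {
  # convex quadrilateral with known area
  quad <- rbind(c(0, 0), c(4, 0), c(4, 3), c(0, 3))
  expect_equal(cinefuse:::shoelace_area(quad), 12)

  K <- 12
  th <- seq(0.1, pi / 3, length.out = 8)
  s_t <- 1 - 0.2 * (1 - cos(2 * pi * (seq_len(K) - 1) / K)) / 2
  traj <- array(0, dim = c(8, K, 2))
  for (k in seq_len(K))
    traj[, k, ] <- cbind(20 * s_t[k] * cos(th), 20 * s_t[k] * sin(th))
  centroids <- matrix(0, K, 2)
  # area scales as s(t)^2: entropy of areas equals entropy of s^2 sequence
  f_area <- area_feature(traj, centroids)
  expect_equal(f_area, shannon_entropy(s_t^2 / s_t[1]^2), tolerance = 1e-9)

  # rigid translation leaves per-frame areas constant -> degenerate floor
  traj_t <- traj
  for (k in seq_len(K)) traj_t[, k, ] <- traj[, 1, ] + (k - 1) * 0.5
  centroids_t <- cbind((seq_len(K) - 1) * 0.5, (seq_len(K) - 1) * 0.5)
  expect_equal(area_feature(traj_t, centroids_t), -10)
})

test_that("Bhattacharyya measure behaves as a separability coefficient", {
  f <- c(0.2, 0.5, 0.3, 0)
  expect_equal(bhattacharyya(f, f), 0)
  expect_equal(bhattacharyya(c(1, 0, 0, 0), c(0, 0, 0.5, 0.5)), 1)
  g <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(bhattacharyya(f, g), bhattacharyya(g, f))
  expect_gte(bhattacharyya(f, g), 0); expect_lte(bhattacharyya(f, g), 1)
  expect_error(bhattacharyya(c(-0.1, 1.1), c(0.5, 0.5)), "negative")
  expect_error(bhattacharyya(c(0.2, 0.2), c(0.5, 0.5)), "sum to 1")

  # binned unit-variance Gaussians, means 0 and 2, vs quadrature oracle
  br <- seq(-8, 10, length.out = 257)
  mids <- (br[-1] + br[-257]) / 2; w <- diff(br)[1]
  fn <- dnorm(mids, 0, 1) * w; fa <- dnorm(mids, 2, 1) * w
  fn <- fn / sum(fn); fa <- fa / sum(fa)
  b_binned <- bhattacharyya(fn, fa)
  # continuous coefficient: int sqrt(f g) = exp(-(mu1-mu2)^2/8) for unit sd
  b_cont <- sqrt(1 - exp(-4 / 8))
  expect_equal(b_binned, b_cont, tolerance = 1e-3)
})

test_that("naive Bayes boundary sits midway between symmetric classes", {
  set.seed(42)
  n <- 4000
  d <- data.frame(
    sde_radial = c(rnorm(n, -1, 0.5), rnorm(n, 1, 0.5)),
    sde_area = c(rnorm(n, -1, 0.5), rnorm(n, 1, 0.5)),
    label = rep(c("normal", "abnormal"), each = n))
  clf <- fit_classifier(d)
  probe <- data.frame(sde_radial = seq(-1, 1, by = 0.01), sde_area = 0)
  sc <- predict(clf, probe)
  boundary <- probe$sde_radial[which.min(abs(sc - 0.5))]
  expect_lt(abs(boundary - 0), 0.1)

  # perfectly separated clusters: training accuracy 1
  d2 <- data.frame(sde_radial = c(rnorm(20, -5, 0.1), rnorm(20, 5, 0.1)),
                   sde_area = c(rnorm(20, -5, 0.1), rnorm(20, 5, 0.1)),
                   label = rep(c("normal", "abnormal"), each = 20))
  clf2 <- fit_classifier(d2)
  expect_equal(as.character(predict(clf2, d2, type = "class")),
               as.character(d2$label))

  # permutation invariance of the fitted boundary
  perm <- d2[sample(nrow(d2)), ]
  clf3 <- fit_classifier(perm)
  expect_equal(predict(clf2, d2), predict(clf3, d2), tolerance = 1e-9)

  expect_error(fit_classifier(d2[d2$label == "normal", ]), "each class")
})

test_that("ROC/AUC machinery is calibrated and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(43)
  lab <- factor(rep(c("normal", "abnormal"), each = 1000),
                levels = c("normal", "abnormal"))
  sc_random <- runif(2000)
  roc_r <- cinefuse:::roc_points(sc_random, lab)
  expect_equal(cinefuse:::trapezoid_auc(roc_r), 0.5, tolerance = 0.03)
  expect_true(all(diff(roc_r[, "fpr"]) >= 0))
  expect_true(all(diff(roc_r[, "tpr"]) >= 0))

  sc_perfect <- ifelse(lab == "abnormal", 1, 0) + runif(2000, 0, 0.01)
  expect_equal(cinefuse:::trapezoid_auc(cinefuse:::roc_points(sc_perfect, lab)), 1)

  sc_mid <- ifelse(lab == "abnormal", rnorm(2000, 1), rnorm(2000, 0))
  auc_own <- cinefuse:::trapezoid_auc(cinefuse:::roc_points(sc_mid, lab))
  auc_ref <- as.numeric(pROC::auc(pROC::roc(lab, sc_mid, quiet = TRUE,
                                            levels = c("normal", "abnormal"),
                                            direction = "<")))
  expect_equal(auc_own, auc_ref, tolerance = 1e-6)
})

test_that("leave-one-subject-out separates the synthetic cohort", {
  feat <- cohort_features(n_subjects = 12, n_abnormal = 5, seed = 44)
  ev <- evaluate_loso(feat)
  expect_gt(ev$accuracy, 0.85)
  expect_gt(ev$auc, 0.9)
  # abnormal (hypokinetic) segments have lower feature entropy
  expect_lt(mean(feat$sde_radial[feat$label == "abnormal"]),
            mean(feat$sde_radial[feat$label == "normal"]))
})
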