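#' Partition an endocardial contour into AHA slice segments
#'
#' Assigns every contour point to one of the equal-angle sectors of the
#' standardized regional model: 4 segments on apical slices, 6 on
#' mid-cavity and basal slices (the apex-cap segment has no short-axis
#' extent and is not represented). Sectors start at the anterior septal
#' insertion landmark and proceed counterclockwise about the cavity
#' centroid.
#'
#' @param contour `n x 2` in-plane coordinates of the frame-1 contour, or
#'   `n x 3` coplanar 3D points (projected internally; the landmark must lie
#'   on the same plane).
#' @param landmark the anterior septal insertion point (same coordinate
#'   space as `contour`).
#' @param level one of `"apical"`, `"mid"`, `"basal"`.
#' @param plane_tol_mm coplanarity tolerance for 3D input.
#' @return A list of class `regional_segments`: `labels` (integer sector per
#'   point, 1-based, counterclockwise from the landmark), `n_segments`,
#'   `level`, `centroid`, `theta0`.
#' @export
partition_contour <- function(contour, landmark,
                              level = c("mid", "basal", "apical"),
                              plane_tol_mm = 1) {
  level <- match.arg(level)
  n_seg <- if (level == "apical") 4L else 6L
  contour <- as.matrix(contour)
  landmark <- as.numeric(landmark)
  if (ncol(contour) == 3L) {
    ctr <- colMeans(contour)
    sv <- svd(sweep(contour, 2, ctr))
    normal <- sv$v[, 3]
    if (abs(sum((landmark - ctr) * normal)) > plane_tol_mm)
      stop("partition_contour: landmark is off the contour plane")
    basis <- sv$v[, 1:2]
    contour <- sweep(contour, 2, ctr) %*% basis
    landmark <- drop((landmark - ctr) %*% basis)
  }
  stopifnot(ncol(contour) == 2L, length(landmark) == 2L)
  centroid <- colMeans(contour)
  theta0 <- atan2(landmark[2] - centroid[2], landmark[1] - centroid[1])
  th <- atan2(contour[, 2] - centroid[2], contour[, 1] - centroid[1])
  rel <- (th - theta0) %% (2 * pi)
  labels <- pmin(floor(rel / (2 * pi / n_seg)) + 1L, n_seg)
  structure(list(labels = as.integer(labels), n_segments = n_seg,
                 level = level, centroid = centroid, theta0 = theta0),
            class = "regional_segments")
}

#' Shannon differential entropy of a sample
#'
#' Histogram estimator with Freedman-Diaconis bin width:
#' `H = -sum p_i log p_i + log(width)` in nats. Degenerate samples (zero
#' spread) return the configured floor, standing in for the point-mass
#' limit of `-Inf`. A Gaussian kernel-density alternative
#' (`method = "kde"`) estimates `H = -mean(log fhat(x_i))`.
#'
#' @param x numeric sample.
#' @param method `"hist"` (default) or `"kde"`.
#' @param floor value returned for degenerate distributions, nats.
#' @return Entropy estimate in nats.
#' @export
shannon_entropy <- function(x, method = c("hist", "kde"), floor = -10) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 2L)
  if (stats::sd(x) < 1e-12 * max(abs(x), 1)) return(floor)
  if (method == "kde") {
    d <- stats::density(x)
    f <- stats::approx(d$x, d$y, xout = x, rule = 2)$y
    return(max(-mean(log(pmax(f, 1e-300))), floor))
  }
  bw <- 2 * stats::IQR(x) / n^(1 / 3)
  if (bw <= 0) bw <- 3.49 * stats::sd(x) / n^(1 / 3)  # Scott fallback
  rng <- range(x)
  nb <- max(2L, ceiling(diff(rng) / bw))
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  width <- diff(breaks)[1]
  p <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nb) / n
  p <- p[p > 0]
  max(-sum(p * log(p)) + log(width), floor)
}

segment_array <- function(seg_traj) {
  if (length(dim(seg_traj)) == 2L)
    seg_traj <- array(seg_traj, dim = c(1L, dim(seg_traj)))
  stopifnot(length(dim(seg_traj)) == 3L, dim(seg_traj)[3] == 2L)
  seg_traj
}

#' Entropy feature of the normalized radial distance
#'
#' Per frame, the mean distance of the segment's tracked points to the
#' cavity centroid, normalized by the frame-1 value; the feature is the
#' Shannon differential entropy of the `K` normalized values. Invariant to
#' global translation/rotation and to uniform scaling of the contour.
#'
#' @param seg_traj `n_pts x K x 2` array of one segment's tracked in-plane
#'   positions (an `K x 2` matrix is treated as a single point).
#' @param centroids `K x 2` matrix of per-frame cavity centroids.
#' @param ... passed to [shannon_entropy()].
#' @return Scalar entropy, nats.
#' @export
radial_feature <- function(seg_traj, centroids, ...) {
  seg_traj <- segment_array(seg_traj)
  K <- dim(seg_traj)[2]
  stopifnot(K >= 8L, nrow(centroids) == K)
  rad <- vapply(seq_len(K), function(k)
    mean(sqrt((seg_traj[, k, 1] - centroids[k, 1])^2 +
              (seg_traj[, k, 2] - centroids[k, 2])^2)), numeric(1))
  if (rad[1] < 1e-9) stop("radial_feature: degenerate contour (zero radius)")
  shannon_entropy(rad / rad[1], ...)
}

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Entropy feature of the normalized segment area
#'
#' Per frame, the area of the sector polygon formed by the cavity centroid
#' and the segment's points (in angular order, shoelace formula),
#' normalized by the frame-1 value; the feature is the Shannon differential
#' entropy of the `K` normalized areas.
#'
#' @inheritParams radial_feature
#' @return Scalar entropy, nats.
#' @export
area_feature <- function(seg_traj, centroids, ...) {
  seg_traj <- segment_array(seg_traj)
  K <- dim(seg_traj)[2]
  stopifnot(K >= 8L, nrow(centroids) == K, dim(seg_traj)[1] >= 2L)
  areas <- vapply(seq_len(K), function(k) {
    p <- cbind(seg_traj[, k, 1], seg_traj[, k, 2])
    th <- atan2(p[, 2] - centroids[k, 2], p[, 1] - centroids[k, 1])
    o <- order(((th - th[1]) %% (2 * pi)))
    shoelace_area(rbind(centroids[k, ], p[o, , drop = FALSE]))
  }, numeric(1))
  if (areas[1] < 1e-9) stop("area_feature: degenerate segment (zero area)")
  shannon_entropy(areas / areas[1], ...)
}

#' Bhattacharyya separability of two discrete distributions
#'
#' `B = sqrt(1 - sum_r sqrt(f_N(r) f_A(r)))` over a shared support; 0 for
#' identical distributions, 1 for disjoint supports, symmetric in its
#' arguments. Higher values indicate better class separability.
#'
#' @param f_n,f_a nonnegative vectors on the same bins, each summing to 1
#'   (within `1e-6`).
#' @return Scalar in \[0, 1\].
#' @export
bhattacharyya <- function(f_n, f_a) {
  f_n <- as.numeric(f_n); f_a <- as.numeric(f_a)
  stopifnot(length(f_n) == length(f_a))
  if (any(f_n < 0) || any(f_a < 0)) stop("bhattacharyya: negative mass")
  if (abs(sum(f_n) - 1) > 1e-6 || abs(sum(f_a) - 1) > 1e-6)
    stop("bhattacharyya: distributions must sum to 1")
  sqrt(max(0, 1 - sum(sqrt(f_n * f_a))))
}

#' Bhattacharyya separability from two samples
#'
#' Bins both samples on a shared equal-width grid spanning their pooled
#' range and applies [bhattacharyya()].
#'
#' @param x,y numeric samples.
#' @param n_bins number of shared bins.
#' @return Scalar in \[0, 1\].
#' @export
bhattacharyya_samples <- function(x, y, n_bins = 32L) {
  rng <- range(x, y)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  b <- function(v) tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                         all.inside = TRUE), n_bins) / length(v)
  bhattacharyya(b(x), b(y))
}

#' Fit the regional naive-Bayes classifier
#'
#' Gaussian-class-conditional naive Bayes on the two entropy features,
#' fitted separately per slice level when a `level` column is present
#' (decision boundaries differ between apical, mid-cavity and basal
#' slices). The positive class is `"abnormal"`.
#'
#' @param samples data frame with columns `sde_radial`, `sde_area`,
#'   `label` (factor or character, `"normal"`/`"abnormal"`), optionally
#'   `level`.
#' @return An object of class `regional_classifier`; use [predict()] with
#'   `type = "score"` for posterior abnormality probabilities or
#'   `type = "class"` for labels.
#' @export
fit_classifier <- function(samples) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("sde_radial", "sde_area", "label") %in% names(samples)))
  samples$label <- factor(as.character(samples$label),
                          levels = c("normal", "abnormal"))
  fit_one <- function(d) {
    if (length(unique(d$label)) < 2L || min(table(d$label)) < 2L)
      stop("fit_classifier: need >= 2 samples of each class")
    e1071::naiveBayes(label ~ sde_radial + sde_area, data = d)
  }
  models <- if ("level" %in% names(samples))
    lapply(split(samples, samples$level), fit_one)
  else list(all = fit_one(samples))
  structure(list(models = models, by_level = "level" %in% names(samples)),
            class = "regional_classifier")
}

#' @export
predict.regional_classifier <- function(object, newdata,
                                        type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  lev <- if (object$by_level) as.character(newdata$level)
         else rep("all", nrow(newdata))
  score <- numeric(nrow(newdata))
  for (l in unique(lev)) {
    m <- object$models[[l]]
    if (is.null(m)) stop("predict: unseen level ", l)
    idx <- which(lev == l)
    pr <- predict(m, newdata[idx, , drop = FALSE], type = "raw")
    score[idx] <- pr[, "abnormal"]
  }
  if (type == "score") score
  else factor(ifelse(score > 0.5, "abnormal", "normal"),
              levels = c("normal", "abnormal"))
}

roc_points <- function(score, label) {
  # threshold sweep; abnormal is the positive class
  pos <- label == "abnormal"
  o <- order(score, decreasing = TRUE)
  tpr <- cumsum(pos[o]) / sum(pos)
  fpr <- cumsum(!pos[o]) / sum(!pos)
  cbind(fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc[, "fpr"]) * (utils::head(roc[, "tpr"], -1) +
                            utils::tail(roc[, "tpr"], -1)) / 2)
}

#' Leave-one-subject-out evaluation of the regional classifier
#'
#' For each subject, fits the classifier on all other subjects and scores
#' the held-out samples; predictions are pooled across subjects. Reports
#' accuracy, sensitivity and specificity at the 0.5 posterior threshold
#' (abnormal positive), the ROC curve from a threshold sweep, and the
#' trapezoid AUC.
#'
#' @param samples data frame as in [fit_classifier()] plus a `subject`
#'   column (>= 2 subjects).
#' @return A list: `accuracy`, `sensitivity`, `specificity`, `auc`, `roc`
#'   (matrix of `fpr`/`tpr` points), `scores`, `labels`.
#' @export
evaluate_loso <- function(samples) {
  samples <- as.data.frame(samples)
  stopifnot("subject" %in% names(samples),
            length(unique(samples$subject)) >= 2L)
  samples$label <- factor(as.character(samples$label),
                          levels = c("normal", "abnormal"))
  score <- numeric(nrow(samples))
  for (subj in unique(samples$subject)) {
    test <- samples$subject == subj
    clf <- fit_classifier(samples[!test, , drop = FALSE])
    score[test] <- predict(clf, samples[test, , drop = FALSE], type = "score")
  }
  pred <- score > 0.5
  truth <- samples$label == "abnormal"
  roc <- roc_points(score, samples$label)
  list(accuracy = mean(pred == truth),
       sensitivity = if (any(truth)) mean(pred[truth]) else NA_real_,
       specificity = if (any(!truth)) mean(!pred[!truth]) else NA_real_,
       auc = trapezoid_auc(roc), roc = roc,
       scores = score, labels = samples$label)
}
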