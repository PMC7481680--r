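#' Least-squares rigid transform between paired landmark sets
#'
#' Landmark-based registration: centroids give the translation, and the
#' rotation comes from the singular value decomposition of the covariance
#' (cross-dispersion) matrix of the centred landmarks, with the usual sign
#' correction so the result is a proper rotation (det = +1), never a
#' reflection. Minimizes the mean squared distance between `R src + t` and
#' `dst`.
#'
#' @param src,dst N x 3 matrices of paired landmark positions (metres),
#'   N >= 3 and non-collinear.
#' @return object of class `rigid_transform` with fields `rotation` (3 x 3)
#'   and `translation` (length 3), and the RMS residual as `rms`.
#' @export
fit_rigid_transform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 3L, ncol(dst) == 3L, nrow(src) == nrow(dst))
  if (nrow(src) < 3L) stop("need at least 3 paired landmarks")
  cs <- colMeans(src); cd <- colMeans(dst)
  a <- sweep(src, 2, cs); b <- sweep(dst, 2, cd)
  h <- crossprod(a, b)                      # 3 x 3 cross-dispersion
  sv <- svd(h)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate landmark set: landmarks are collinear or coincident")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cd - as.numeric(rot %*% cs)
  fitted <- sweep(src %*% t(rot), 2, tr, "+")
  rms <- sqrt(mean(rowSums((fitted - dst)^2)))
  structure(list(rotation = rot, translation = tr, rms = rms),
            class = "rigid_transform")
}

#' Build a rigid transform from rotation and translation
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 numeric.
#' @return `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with det +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rms = NA_real_),
            class = "rigid_transform")
}

#' Rotation about the vertical (y) axis
#' @param angle_deg rotation angle in degrees (right-handed about +y).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

#' Compose two rigid transforms (apply `first`, then `second`)
#' @param second,first `rigid_transform`s.
#' @return their composition as a `rigid_transform`.
#' @export
compose_transform <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rinv <- t(transform$rotation)
  rigid_transform(rinv, -as.numeric(rinv %*% transform$translation))
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param points N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
transform_points <- function(transform, points) {
  points <- as.matrix(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Apply a rigid transform to a skeleton stream
#'
#' Positions are mapped by `R x + t`; head yaw is shifted by the transform's
#' heading change (its rotation about the vertical axis); pitch and roll are
#' untouched. Distances between any two points are preserved.
#'
#' @param transform a `rigid_transform`.
#' @param stream a [skeleton_stream()] or `uniform_stream`.
#' @return stream of the same class in the target frame.
#' @export
apply_transform <- function(transform, stream) {
  out <- stream
  out$joints <- lapply(stream$joints, function(m) {
    res <- transform_points(transform, m)
    colnames(res) <- c("x", "y", "z")
    res
  })
  fwd <- as.numeric(transform$rotation %*% c(0, 0, 1))
  dyaw <- atan2(fwd[1], fwd[3]) * 180 / pi
  out$orient[, 1] <- wrap_deg(stream$orient[, 1] + dyaw)
  out
}

#' Estimate the clock shift between two sensors from speed traces
#'
#' Normalized cross-correlation of the two speed series of the same
#' participant as seen by both sensors; the returned shift (seconds) is the
#' lag of the global correlation maximum within `max_shift`. A positive
#' shift means `speed_b` lags `speed_a`; shifting b earlier by the result
#' makes zero-lag the maximum.
#'
#' @param speed_a,speed_b speed series on a common uniform grid (m/s).
#' @param rate sampling rate (Hz).
#' @param max_shift largest shift searched, in seconds.
#' @return list with `shift_s`, `peak_r` and `low_confidence`; a warning is
#'   emitted when the peak correlation is below 0.2.
#' @export
temporal_realign <- function(speed_a, speed_b, rate, max_shift = 5) {
  stopifnot(length(speed_a) == length(speed_b))
  n <- length(speed_a)
  ml <- as.integer(round(max_shift * rate))
  if (n < 10L * ml) warning("short overlap relative to max_shift")
  lags <- -ml:ml
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      u <- speed_a[1:(n - l)]; v <- speed_b[(1 + l):n]
    } else {
      u <- speed_a[(1 - l):n]; v <- speed_b[1:(n + l)]
    }
    ok <- !is.na(u) & !is.na(v)
    if (sum(ok) < 10L || sd(u[ok]) < 1e-12 || sd(v[ok]) < 1e-12) {
      return(NA_real_)
    }
    cor(u[ok], v[ok])
  }, numeric(1))
  if (all(is.na(r))) stop("no overlapping valid samples")
  best <- which.max(r)
  peak <- r[best]
  low <- is.na(peak) || peak < 0.2
  if (low) warning("low-confidence realignment: peak correlation below 0.2")
  list(shift_s = lags[best] / rate, peak_r = peak, low_confidence = low)
}

#' Fit the between-sensor transform of a session
#'
#' Uses the four registration joints of the participant co-visible in both
#' sensors, restricted to time windows where both sensors report valid
#' tracking, and fits one global rigid transform mapping `from_sensor`
#' coordinates into `to_sensor` coordinates.
#'
#' @param session a [dyad_session()].
#' @param participant participant tracked by both sensors.
#' @param from_sensor,to_sensor sensor ids.
#' @param joints landmark joints (default head, neck, right shoulder,
#'   spine at the shoulder).
#' @param rate resampling rate used to put both sensors on a common grid.
#' @return a `rigid_transform`.
#' @export
register_sensors <- function(session, participant, from_sensor, to_sensor,
                             joints = c("head", "neck", "shoulder_right",
                                        "spine_shoulder"),
                             rate = 10) {
  sa <- session$streams[[participant]][[from_sensor]]
  sb <- session$streams[[participant]][[to_sensor]]
  if (is.null(sa) || is.null(sb)) stop("participant not tracked by both sensors")
  ua <- resample_uniform(sa, rate)
  ub <- resample_uniform(sb, rate)
  t0 <- max(ua$t[1], ub$t[1]); t1 <- min(tail(ua$t, 1), tail(ub$t, 1))
  ga <- ua$t >= t0 & ua$t <= t1
  gb <- ub$t >= t0 & ub$t <= t1
  n <- min(sum(ga), sum(gb))
  ia <- which(ga)[seq_len(n)]; ib <- which(gb)[seq_len(n)]
  covis <- ua$valid[ia] & ub$valid[ib]
  if (sum(covis) < 3L) stop("too few co-visible samples for registration")
  joints <- intersect(joints, intersect(names(ua$joints), names(ub$joints)))
  src <- do.call(rbind, lapply(joints, function(j) {
    ua$joints[[j]][ia[covis], , drop = FALSE]
  }))
  dst <- do.call(rbind, lapply(joints, function(j) {
    ub$joints[[j]][ib[covis], , drop = FALSE]
  }))
  ok <- complete.cases(src) & complete.cases(dst)
  fit_rigid_transform(src[ok, , drop = FALSE], dst[ok, , drop = FALSE])
}

#' Train an identity model for participant relabelling
#'
#' After occlusions, sensors may re-assign participant identities at random.
#' The identity model maps per-frame joint-position feature vectors to the
#' participant label, trained on frames with known identity; seating
#' geometry dominates, so a kernel max-margin classifier separates the two
#' seats essentially perfectly.
#'
#' @param features n x p matrix of per-frame joint positions (e.g.
#'   concatenated head/neck/shoulders/spine coordinates).
#' @param labels participant identity per frame (two classes).
#' @param seed RNG seed (tie-breaking inside the fit is made deterministic).
#' @return object of class `identity_model`.
#' @export
train_identity_model <- function(features, labels, seed = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("training error: single-class training data")
  set.seed(seed)
  fit <- e1071::svm(x = as.matrix(features), y = labels, kernel = "radial",
                    scale = TRUE)
  structure(list(fit = fit, classes = levels(labels),
                 n_features = ncol(as.matrix(features))),
            class = "identity_model")
}

#' Relabel frames with a trained identity model
#' @param model an `identity_model`.
#' @param features n x p matrix of per-frame features.
#' @return factor of predicted identities, one per frame.
#' @export
relabel_participants <- function(model, features) {
  stopifnot(inherits(model, "identity_model"))
  predict(model$fit, as.matrix(features))
}

#' Frame features for identity relabelling from a stream
#' @param stream a `skeleton_stream` or `uniform_stream`.
#' @param joints joints whose 3D positions are concatenated per frame.
#' @return n x (3 * length(joints)) matrix.
#' @export
identity_features <- function(stream,
                              joints = c("head", "neck", "shoulder_left",
                                         "shoulder_right", "spine_shoulder")) {
  joints <- intersect(joints, names(stream$joints))
  do.call(cbind, lapply(joints, function(j) stream$joints[[j]]))
}
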