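#' Inter-head distance series
#'
#' Pointwise Euclidean distance between the two participants' heads on a
#' common uniform grid.
#'
#' @param head_1,head_2 n x 3 position matrices (m).
#' @return numeric vector of distances (m); `NA` where either head is
#'   untracked.
#' @export
interhead_distance <- function(head_1, head_2) {
  head_1 <- as.matrix(head_1); head_2 <- as.matrix(head_2)
  stopifnot(nrow(head_1) == nrow(head_2))
  sqrt(rowSums((head_1 - head_2)^2))
}

#' Gaze direction vector from head yaw and pitch
#'
#' Unit vector of the facing direction in the scene frame: yaw rotates about
#' the vertical (y) axis, pitch about the lateral axis; roll does not change
#' a direction vector and is ignored. Convention anchors: (yaw 0, pitch 0)
#' -> (0, 0, 1) straight ahead; yaw 90 -> (1, 0, 0); pitch 90 -> (0, 1, 0).
#'
#' @param yaw,pitch angles in degrees (vectors of equal length).
#' @return n x 3 matrix of unit vectors.
#' @export
gaze_vector <- function(yaw, pitch) {
  y <- yaw * pi / 180; p <- pitch * pi / 180
  cbind(x = cos(p) * sin(y), y = sin(p), z = cos(p) * cos(y))
}

#' Relational yaw toward the partner
#'
#' Unsigned angle, in the horizontal plane, between a participant's facing
#' direction and the direction from their head to the partner's head.
#' 0 degrees means facing the partner; 180 means facing directly away.
#'
#' @param facing n x 3 facing direction vectors (any norm).
#' @param own_head,partner_head n x 3 head positions (m).
#' @return numeric vector of angles in \[0, 180\]; `NA` where heads
#'   (horizontally) coincide or the facing vector has no horizontal
#'   component.
#' @export
relative_yaw <- function(facing, own_head, partner_head) {
  facing <- as.matrix(facing); own_head <- as.matrix(own_head)
  partner_head <- as.matrix(partner_head)
  f <- facing; f[, 2] <- 0
  d <- partner_head - own_head; d[, 2] <- 0
  nf <- sqrt(rowSums(f^2)); nd <- sqrt(rowSums(d^2))
  cosang <- rowSums(f * d) / (nf * nd)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  ang[nf < 1e-9 | nd < 1e-9] <- NA_real_
  ang
}

#' Body direction from the shoulder line
#'
#' Horizontal unit normal of the line connecting the shoulders, with the
#' sign chosen toward the chest-reference point, i.e. pointing out of the
#' chest. Shoulders tilted out of the horizontal plane are first projected
#' onto it.
#'
#' @param shoulder_left,shoulder_right,chest_reference n x 3 position
#'   matrices (m); the chest reference is any point on the chest side of
#'   the shoulder line (the tracked spine-at-shoulder point in this
#'   pipeline's conventions).
#' @return n x 3 matrix of horizontal unit vectors; `NA` rows where the
#'   shoulders horizontally coincide.
#' @export
body_direction <- function(shoulder_left, shoulder_right, chest_reference) {
  sl <- as.matrix(shoulder_left); sr <- as.matrix(shoulder_right)
  cr <- as.matrix(chest_reference)
  d <- sr - sl; d[, 2] <- 0
  normal <- cbind(-d[, 3], 0, d[, 1])
  mid <- (sl + sr) / 2
  toward <- cr - mid; toward[, 2] <- 0
  flip <- rowSums(normal * toward) < 0
  normal[flip, ] <- -normal[flip, , drop = FALSE]
  nn <- sqrt(rowSums(normal^2))
  out <- normal / nn
  out[nn < 1e-9, ] <- NA_real_
  colnames(out) <- c("x", "y", "z")
  out
}

#' Relational orientation series of a dyad
#'
#' Per-time-point pair of unsigned relational yaw angles, one per
#' participant, from either the face (head orientation) or the body
#' (shoulder-line normal) channel.
#'
#' @param stream_1,stream_2 preprocessed `uniform_stream`s of the two
#'   participants in a common frame and on a common grid (equal length).
#' @param channel `"face"` or `"body"`.
#' @return data.frame with `t`, `theta_1`, `theta_2` (degrees in
#'   \[0, 180\]) and attribute `channel`; rows with either participant
#'   untracked carry `NA`.
#' @export
relational_orientation <- function(stream_1, stream_2,
                                   channel = c("face", "body")) {
  channel <- match.arg(channel)
  stopifnot(length(stream_1$t) == length(stream_2$t))
  h1 <- stream_1$joints[["head"]]; h2 <- stream_2$joints[["head"]]
  facing <- function(s) {
    if (channel == "face") {
      gaze_vector(s$orient[, 1], s$orient[, 2])
    } else {
      body_direction(s$joints[["shoulder_left"]],
                     s$joints[["shoulder_right"]],
                     s$joints[["spine_shoulder"]])
    }
  }
  out <- data.frame(t = stream_1$t,
                    theta_1 = relative_yaw(facing(stream_1), h1, h2),
                    theta_2 = relative_yaw(facing(stream_2), h2, h1))
  attr(out, "channel") <- channel
  out
}

#' Joint orientation histogram
#'
#' 2D distribution (% of total valid time) of the two participants'
#' simultaneous relational yaw angles over \[0, 180\]^2.
#'
#' @param theta_1,theta_2 relational yaw angles (degrees in \[0, 180\]);
#'   `NA` samples are excluded from the denominator.
#' @param bin_width bin width in degrees (default 1).
#' @return object of class `orientation_histogram`: a matrix (rows =
#'   participant-1 bins, columns = participant-2 bins) summing to 100, with
#'   attributes `bin_width`, `breaks`, `smoothing_sigma`.
#' @export
joint_orientation_histogram <- function(theta_1, theta_2, bin_width = 1) {
  ok <- !is.na(theta_1) & !is.na(theta_2)
  if (!any(ok)) stop("data error: zero valid samples")
  breaks <- seq(0, 180, by = bin_width)
  if (tail(breaks, 1) < 180) breaks <- c(breaks, 180)
  nb <- length(breaks) - 1L
  idx <- function(th) pmin(pmax(findInterval(th, breaks,
                                             rightmost.closed = TRUE), 1L), nb)
  h <- matrix(0, nb, nb)
  tab <- table(factor(idx(theta_1[ok]), levels = seq_len(nb)),
               factor(idx(theta_2[ok]), levels = seq_len(nb)))
  h[] <- as.numeric(tab)
  h <- 100 * h / sum(h)
  structure(h, class = "orientation_histogram", bin_width = bin_width,
            breaks = breaks, smoothing_sigma = 0)
}

# Separable 1D Gaussian smoothing of matrix rows/columns with edge
# renormalization (divide by the smoothed all-ones matrix).
smooth_matrix_gaussian <- function(m, sigma_bins) {
  if (sigma_bins == 0) return(m)
  r <- ceiling(4 * sigma_bins)
  k <- dnorm(seq(-r, r), sd = sigma_bins)
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    padded <- c(rep(0, r), x, rep(0, r))
    out <- stats::filter(padded, k, method = "convolution", sides = 2)
    as.numeric(out)[(r + 1L):(r + n)]
  }
  num <- apply(apply(m, 2, conv1), 1, conv1)      # cols then rows (transposed)
  ones <- matrix(1, nrow(m), ncol(m))
  den <- apply(apply(ones, 2, conv1), 1, conv1)
  t(num / den)
}

#' Smooth an orientation histogram
#'
#' 2D Gaussian smoothing with edge renormalization; total mass stays at
#' exactly 100%.
#'
#' @param histogram an `orientation_histogram`.
#' @param sigma kernel standard deviation in degrees (default 5).
#' @return smoothed `orientation_histogram`.
#' @export
smooth_histogram <- function(histogram, sigma = 5) {
  stopifnot(inherits(histogram, "orientation_histogram"))
  if (sigma < 0) stop("parameter error: sigma must be non-negative")
  bw <- attr(histogram, "bin_width")
  sm <- smooth_matrix_gaussian(unclass(histogram), sigma / bw)
  sm <- 100 * sm / sum(sm)
  structure(sm, class = "orientation_histogram", bin_width = bw,
            breaks = attr(histogram, "breaks"), smoothing_sigma = sigma)
}

#' Per-cell condition contrasts of orientation heatmaps
#'
#' For every heatmap cell, a one-way repeated-measures ANOVA across
#' conditions (dyad as the repeated unit) followed by per-cell paired
#' t-tests for the requested condition pairs, with significance masks at an
#' uncorrected threshold gated by the ANOVA.
#'
#' @param histograms_by_dyad list (one element per dyad) of named lists
#'   (condition -> `orientation_histogram`); every dyad must cover every
#'   condition.
#' @param pairs list of 2-vectors of condition names to contrast (default:
#'   all pairs).
#' @param alpha significance threshold (uncorrected, default 0.05).
#' @return list with `conditions`, per-cell matrices `F` and `p_anova`, the
#'   ANOVA gate mask `sig_anova`, and per-pair lists `t`, `p`, `sig`
#'   (gated by the ANOVA mask).
#' @export
compare_heatmaps <- function(histograms_by_dyad, pairs = NULL, alpha = 0.05) {
  n <- length(histograms_by_dyad)
  if (n < 3L) stop("insufficient data: need at least 3 dyads")
  conds <- names(histograms_by_dyad[[1]])
  dims <- dim(histograms_by_dyad[[1]][[1]])
  y <- array(NA_real_, c(n, length(conds), prod(dims)))
  for (i in seq_len(n)) {
    stopifnot(setequal(names(histograms_by_dyad[[i]]), conds))
    for (j in seq_along(conds)) {
      y[i, j, ] <- as.numeric(histograms_by_dyad[[i]][[conds[j]]])
    }
  }
  an <- rm_anova_cells(y)
  fmat <- matrix(an$F, dims[1], dims[2])
  pmat <- matrix(an$p, dims[1], dims[2])
  gate <- pmat < alpha & !is.na(pmat)
  if (is.null(pairs)) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
  }
  pair_res <- lapply(pairs, function(pr) {
    tt <- paired_t_cells(y[, match(pr[1], conds), ], y[, match(pr[2], conds), ])
    tm <- matrix(tt$t, dims[1], dims[2])
    pm <- matrix(tt$p, dims[1], dims[2])
    list(pair = pr, t = tm, p = pm, sig = (pm < alpha) & gate & !is.na(pm))
  })
  names(pair_res) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  list(conditions = conds, F = fmat, p_anova = pmat, sig_anova = gate,
       pairs = pair_res, alpha = alpha)
}
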