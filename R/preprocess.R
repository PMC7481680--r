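#' Resample a skeleton stream onto a uniform grid
#'
#' Linearly interpolates all position and orientation channels of the valid
#' samples onto a uniform grid spanning the valid part of the stream. Spans
#' between consecutive valid samples longer than `gap_max` are masked rather
#' than interpolated, so long tracking dropouts never fabricate motion. Yaw
#' is unwrapped before interpolation so the 180/-180 seam is crossed
#' smoothly.
#'
#' @param stream a [skeleton_stream()].
#' @param rate target rate in Hz (default 10).
#' @param gap_max longest dropped span (seconds) that may be interpolated
#'   over (default 1).
#' @return an object of class `uniform_stream`: fields `t`, `rate`, `joints`
#'   (named list of n x 3 matrices), `orient`, `valid` (the gap mask;
#'   `FALSE` samples carry `NA`s), plus the source identifiers.
#' @export
resample_uniform <- function(stream, rate = 10, gap_max = 1) {
  stopifnot(inherits(stream, "skeleton_stream"))
  if (rate <= 0) stop("rate must be positive")
  tv <- stream$t[stream$valid]
  if (length(tv) < 2L) stop("data error: fewer than 2 valid samples")
  grid <- seq(tv[1], tv[length(tv)], by = 1 / rate)
  interp <- function(y) approx(tv, y, xout = grid, method = "linear",
                               rule = 1)$y
  joints <- lapply(stream$joints, function(m) {
    mv <- m[stream$valid, , drop = FALSE]
    cbind(x = interp(mv[, 1]), y = interp(mv[, 2]), z = interp(mv[, 3]))
  })
  ov <- stream$orient[stream$valid, , drop = FALSE]
  orient <- cbind(yaw = wrap_deg(interp(unwrap_deg(ov[, 1]))),
                  pitch = interp(ov[, 2]), roll = interp(ov[, 3]))
  valid <- rep(TRUE, length(grid))
  gaps <- which(diff(tv) > gap_max)
  for (g in gaps) {
    valid[grid > tv[g] & grid < tv[g + 1]] <- FALSE
  }
  for (j in names(joints)) joints[[j]][!valid, ] <- NA_real_
  orient[!valid, ] <- NA_real_
  structure(list(participant_id = stream$participant_id,
                 sensor_id = stream$sensor_id,
                 t = grid, rate = rate, joints = joints, orient = orient,
                 valid = valid),
            class = "uniform_stream")
}

# Mask-aware Gaussian smoothing of one channel: the kernel is renormalized
# over the valid support so edges and masked spans do not bleed mass.
smooth_masked <- function(x, valid, kernel) {
  n <- length(x)
  r <- (length(kernel) - 1L) / 2L
  x0 <- ifelse(valid & !is.na(x), x, 0)
  v0 <- as.numeric(valid & !is.na(x))
  pad <- function(z) c(rep(0, r), z, rep(0, r))
  num <- stats::filter(pad(x0), kernel, method = "convolution", sides = 2)
  den <- stats::filter(pad(v0), kernel, method = "convolution", sides = 2)
  num <- as.numeric(num)[(r + 1L):(r + n)]
  den <- as.numeric(den)[(r + 1L):(r + n)]
  out <- num / den
  out[den < 1e-12 | !valid] <- NA_real_
  out
}

gaussian_kernel <- function(sigma, rate) {
  r <- ceiling(4 * sigma * rate)
  k <- dnorm(seq(-r, r) / rate, sd = sigma)
  k / sum(k)
}

#' Gaussian low-pass filter of a uniform stream
#'
#' Convolves every channel with a normalized Gaussian kernel (truncated at
#' +/- 4 sigma). Masked samples are excluded and the kernel renormalized
#' over the valid support, so constants are preserved exactly and masked
#' spans stay masked.
#'
#' @param ustream a `uniform_stream` from [resample_uniform()].
#' @param sigma kernel standard deviation in seconds (default 0.5).
#' @return a `uniform_stream` with smoothed channels.
#' @export
gaussian_lowpass <- function(ustream, sigma = 0.5) {
  stopifnot(inherits(ustream, "uniform_stream"))
  if (sigma <= 0) stop("parameter error: sigma must be positive")
  k <- gaussian_kernel(sigma, ustream$rate)
  out <- ustream
  out$joints <- lapply(ustream$joints, function(m) {
    cbind(x = smooth_masked(m[, 1], ustream$valid, k),
          y = smooth_masked(m[, 2], ustream$valid, k),
          z = smooth_masked(m[, 3], ustream$valid, k))
  })
  yaw_u <- unwrap_deg_masked(ustream$orient[, 1], ustream$valid)
  out$orient <- cbind(yaw = wrap_deg(smooth_masked(yaw_u, ustream$valid, k)),
                      pitch = smooth_masked(ustream$orient[, 2],
                                            ustream$valid, k),
                      roll = smooth_masked(ustream$orient[, 3],
                                           ustream$valid, k))
  out
}

# Unwrap a degree series that may contain NA (masked) samples; unwrapping
# restarts across masked spans.
unwrap_deg_masked <- function(x, valid) {
  ok <- valid & !is.na(x)
  out <- x
  idx <- which(ok)
  if (length(idx) >= 2L) {
    out[idx] <- unwrap_deg(x[idx])
  }
  out
}

#' Movement speed from a uniformly sampled position series
#'
#' Central-difference velocity magnitude (one-sided at the ends), masked
#' wherever the sample itself or any contributing neighbour is masked.
#'
#' @param positions n x 3 matrix of positions (m) on a uniform grid.
#' @param rate sampling rate in Hz.
#' @param valid optional logical mask.
#' @return numeric vector of speeds (m/s) with `NA` at masked samples.
#' @export
compute_speed <- function(positions, rate, valid = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 3L) stop("data error: need at least 3 samples for speed")
  if (is.null(valid)) valid <- rep(TRUE, n)
  ok <- valid & apply(is.finite(positions), 1, all)
  dt <- 1 / rate
  vel <- matrix(NA_real_, n, 3)
  vel[2:(n - 1), ] <- (positions[3:n, ] - positions[1:(n - 2), ]) / (2 * dt)
  vel[1, ] <- (positions[2, ] - positions[1, ]) / dt
  vel[n, ] <- (positions[n, ] - positions[n - 1, ]) / dt
  speed <- sqrt(rowSums(vel^2))
  contrib_ok <- ok
  contrib_ok[2:(n - 1)] <- ok[1:(n - 2)] & ok[2:(n - 1)] & ok[3:n]
  contrib_ok[1] <- ok[1] & ok[2]
  contrib_ok[n] <- ok[n - 1] & ok[n]
  speed[!contrib_ok] <- NA_real_
  speed
}

#' Speed of one joint of a preprocessed stream
#'
#' @param ustream a `uniform_stream` (ideally after [gaussian_lowpass()]).
#' @param joint joint name (default `"head"`).
#' @return numeric speed series (m/s).
#' @export
joint_speed <- function(ustream, joint = "head") {
  stopifnot(inherits(ustream, "uniform_stream"))
  if (!joint %in% names(ustream$joints)) stop("joint not present: ", joint)
  compute_speed(ustream$joints[[joint]], ustream$rate, ustream$valid)
}

#' Per-trial means of a time series
#'
#' Clips the series to each annotated trial and averages the unmasked
#' samples, so trials of unequal length are never pooled sample-wise.
#'
#' @param values numeric series (may contain `NA`).
#' @param times timestamps of `values` (seconds).
#' @param annotations a [trial_annotations()] table.
#' @return data.frame with `trial_index`, `condition`, `value`, `n_samples`.
#' @export
trial_means <- function(values, times, annotations) {
  stopifnot(length(values) == length(times))
  out <- lapply(seq_len(nrow(annotations)), function(i) {
    sel <- times >= annotations$start_s[i] & times <= annotations$end_s[i]
    v <- values[sel]
    n_ok <- sum(!is.na(v))
    if (n_ok == 0L) {
      warning(sprintf("trial %d (%s) has no valid samples",
                      annotations$trial_index[i], annotations$condition[i]))
    }
    data.frame(trial_index = annotations$trial_index[i],
               condition = annotations$condition[i],
               value = if (n_ok) mean(v, na.rm = TRUE) else NA_real_,
               n_samples = n_ok)
  })
  do.call(rbind, out)
}

#' Aggregate per-trial values into per-condition means
#'
#' Condition-specific mean effects: each trial contributes one value
#' (computed first, over that trial only), and the condition mean is the
#' unweighted mean over its trials.
#'
#' @param trial_values data.frame with columns `trial_index`, `condition`,
#'   `value` (e.g. from [trial_means()]).
#' @return named numeric vector of per-condition means; conditions with zero
#'   trials are absent.
#' @export
aggregate_by_condition <- function(trial_values) {
  stopifnot(all(c("condition", "value") %in% names(trial_values)))
  ok <- !is.na(trial_values$value)
  if (!all(ok)) message("dropping ", sum(!ok), " empty trial(s)")
  tv <- trial_values[ok, , drop = FALSE]
  if (!nrow(tv)) return(setNames(numeric(), character()))
  tapply(tv$value, tv$condition, mean)[unique(tv$condition)]
}

#' Preprocess every stream of a session
#'
#' Applies [resample_uniform()] then [gaussian_lowpass()] to each
#' participant/sensor stream.
#'
#' @param session a [dyad_session()].
#' @param rate target rate (Hz).
#' @param sigma Gaussian smoothing sigma (s).
#' @param gap_max interpolation gap limit (s).
#' @return list shaped like `session$streams` but holding `uniform_stream`s.
#' @export
preprocess_session <- function(session, rate = 10, sigma = 0.5, gap_max = 1) {
  lapply(session$streams, function(per_sensor) {
    lapply(per_sensor, function(st) {
      gaussian_lowpass(resample_uniform(st, rate, gap_max), sigma)
    })
  })
}
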