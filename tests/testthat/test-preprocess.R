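test_that("resample_uniform interpolates linearly on irregular grids", {
  t <- c(0, 0.06, 0.11, 0.2, 0.32, 0.4, 0.5, 0.61, 0.7, 0.8, 0.9, 1.0)
  head <- cbind(2 * t, 1 + t, 3 - t)   # linear in t => exact interpolation
  s <- make_stream(t = t, head = head)
  u <- resample_uniform(s, rate = 10)
  expect_equal(u$t, seq(0, 1, by = 0.1))
  expect_equal(u$joints$head[, 1], 2 * u$t, tolerance = 1e-12)
  expect_equal(u$joints$head[, 3], 3 - u$t, tolerance = 1e-12)
})

test_that("gaps longer than gap_max are masked, shorter ones filled", {
  t <- seq(0, 10, by = 1 / 17)
  s <- make_stream(t = t)
  v <- rep(TRUE, length(t))
  v[t > 2 & t < 2.5] <- FALSE      # 0.5 s gap: interpolated
  v[t > 6 & t < 7.5] <- FALSE      # 1.5 s gap: masked
  s2 <- make_stream(t = t, valid = v)
  u <- resample_uniform(s2, rate = 10, gap_max = 1)
  expect_true(all(u$valid[u$t > 2.05 & u$t < 2.45]))
  expect_false(any(u$valid[u$t > 6.1 & u$t < 7.4]))
  expect_true(all(is.na(u$joints$head[!u$valid, ])))
})

test_that("yaw interpolation crosses the 180-degree seam smoothly", {
  t <- seq(0, 1, by = 0.05)
  n <- length(t)
  orient <- cbind(dyadmotion:::wrap_deg(170 + 20 * t), 0 * t, 0 * t)
  s <- skeleton_stream("p1", "k1", t, list(head = cbind(t, t, t)), orient)
  u <- resample_uniform(s, rate = 10)
  expected <- dyadmotion:::wrap_deg(170 + 20 * u$t)
  expect_equal(u$orient[, "yaw"], expected, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("gaussian_lowpass preserves constants and removes fast sine", {
  t <- seq(0, 20, by = 1 / 17)
  head <- cbind(1.5 + 0 * t, 0.7 + 0 * t, -2 + 0 * t)
  u <- resample_uniform(make_stream(t = t, head = head))
  g <- gaussian_lowpass(u, sigma = 0.5)
  expect_equal(g$joints$head[, 1], rep(1.5, length(g$t)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # 4 Hz sine is far above the ~0.3 Hz cutoff of a 0.5 s Gaussian
  head2 <- cbind(0.05 * sin(2 * pi * 4 * t), 0 * t, 0 * t)
  u2 <- resample_uniform(make_stream(t = t, head = head2))
  g2 <- gaussian_lowpass(u2, sigma = 0.5)
  mid <- g2$t > 2 & g2$t < 18
  expect_lt(max(abs(g2$joints$head[mid, 1])), 0.05 * 0.05)
  expect_error(gaussian_lowpass(u2, sigma = 0), "sigma")
})

test_that("smoothing is mask-aware: masked spans stay masked, no bleed", {
  t <- seq(0, 10, by = 1 / 17)
  v <- rep(TRUE, length(t)); v[t > 4 & t < 6] <- FALSE
  head <- cbind(1 + 0 * t, 2 + 0 * t, 3 + 0 * t)
  u <- resample_uniform(make_stream(t = t, head = head, valid = v))
  g <- gaussian_lowpass(u)
  expect_true(all(is.na(g$joints$head[!u$valid, 1])))
  # constant input stays exactly constant next to the mask (renormalization)
  expect_equal(g$joints$head[u$valid, 1], rep(1, sum(u$valid)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("compute_speed matches the analytic derivative", {
  rate <- 100
  t <- seq(0, 2, by = 1 / rate)
  pos <- cbind(sin(t), 0 * t, 0 * t)   # |v| = |cos(t)|
  sp <- compute_speed(pos, rate)
  inner <- 2:(length(t) - 1)
  expect_equal(sp[inner], abs(cos(t[inner])), tolerance = 1e-3)
  expect_error(compute_speed(pos[1:2, ], rate), "at least 3")
})

test_that("speed is masked where contributing samples are masked", {
  pos <- cbind(1:10, rep(0, 10), rep(0, 10))
  v <- rep(TRUE, 10); v[5] <- FALSE
  sp <- compute_speed(pos, 10, v)
  expect_true(all(is.na(sp[4:6])))
  expect_false(anyNA(sp[c(1:3, 7:10)]))
})

test_that("trial means come before condition aggregation", {
  tt <- seq(0, 30, by = 0.1)
  val <- ifelse(tt < 10, 1, ifelse(tt < 20, 3, 10))
  ann <- trial_annotations(1:3, c("cooperative", "cooperative", "pause"),
                           c(0, 10.05, 20.05), c(9.95, 19.95, 30))
  tm <- trial_means(val, tt, ann)
  expect_equal(tm$value, c(1, 3, 10), tolerance = 1e-9)
  agg <- aggregate_by_condition(tm)
  # unweighted mean of per-trial means, not a pooled sample mean
  expect_equal(unname(agg["cooperative"]), 2)
  expect_equal(unname(agg["pause"]), 10)
})

test_that("empty trials warn in trial_means and are dropped downstream", {
  tt <- seq(0, 10, by = 0.1)
  val <- rep(NA_real_, length(tt))
  val[tt <= 5] <- 1
  ann <- trial_annotations(1:2, c("pause", "pause"), c(0, 6), c(5, 10))
  expect_warning(tm <- trial_means(val, tt, ann), "no valid samples")
  expect_message(agg <- aggregate_by_condition(tm), "empty trial")
  expect_equal(unname(agg["pause"]), 1)
})
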