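test_that("generate_dyad is reproducible and respects the schedule", {
  g1 <- small_dyad(seed = 8)
  g2 <- small_dyad(seed = 8)
  expect_equal(g1$session$streams$p1$k1$joints$head,
               g2$session$streams$p1$k1$joints$head)
  expect_equal(g1$truth$states$state, g2$truth$states$state)
  g3 <- small_dyad(seed = 9)
  expect_false(identical(g1$session$streams$p1$k1$joints$head,
                         g3$session$streams$p1$k1$joints$head))
  expect_equal(nrow(g1$session$annotations), 4)
  total <- sum(short_schedule()$duration_s)
  expect_equal(max(g1$truth$states$t), total, tolerance = 0.1)
})

test_that("frame drops match the configured probability", {
  g <- small_dyad(seed = 10, drop_prob = 0.2)
  v <- g$session$streams$p1$k1$valid
  expect_lt(abs(mean(!v) - 0.2), 0.02)
})

test_that("band_limited_noise concentrates power in the band", {
  set.seed(70)
  n <- 4096; rate <- 17
  x <- dyadmotion:::band_limited_noise(n, rate, c(0.1, 1))
  expect_equal(sd(x), 1, tolerance = 1e-9)
  sp <- Mod(fft(x))^2
  freq <- (0:(n - 1)) * rate / n
  half <- freq <= rate / 2
  inband <- freq >= 0.08 & freq <= 1.05
  expect_gt(sum(sp[half & inband]), 0.99 * sum(sp[half]))
})

test_that("noise-free partner gaze gives exactly zero relational yaw", {
  g <- small_dyad(seed = 11, orientation_noise_sd = 0, sensor_noise_sd = 0,
                  drop_prob = 0)
  s <- g$session
  st1 <- s$streams$p1$k2; st2 <- s$streams$p2$k2
  gv <- gaze_vector(st1$orient[, 1], st1$orient[, 2])
  ry <- relative_yaw(gv, st1$joints$head, st2$joints$head)
  idx <- which(g$truth$states$p1_partner)
  # tolerance limited by acos() conditioning near cos = 1
  expect_lt(max(ry[idx], na.rm = TRUE), 1e-4)
})

test_that("away bouts point >= 30 degrees from partner and target", {
  g <- small_dyad(seed = 12, orientation_noise_sd = 0, sensor_noise_sd = 0,
                  drop_prob = 0)
  st1 <- g$session$streams$p1$k2
  states <- g$truth$states
  away <- which(states$state == "away" & !states$p1_partner &
                  !states$p1_target)
  gv <- gaze_vector(st1$orient[away, 1], st1$orient[away, 2])
  ry_partner <- relative_yaw(gv, st1$joints$head[away, ],
                             g$session$streams$p2$k2$joints$head[away, ])
  expect_gt(min(ry_partner, na.rm = TRUE), 25)   # 30 deg minus head sway
})

test_that("planted sensor transform and clock offset are encoded", {
  g <- small_dyad(seed = 13, sensor_noise_sd = 0, drop_prob = 0)
  s <- g$session
  k1 <- s$streams$p1$k1; k2 <- s$streams$p1$k2
  # k1 timestamps carry the clock offset
  expect_equal(k1$t - k2$t, rep(g$truth$clock_offset_s, length(k1$t)),
               tolerance = 1e-12)
  # positions differ by exactly the planted transform at equal sample index
  mapped <- transform_points(g$truth$transform, k2$joints$head)
  expect_equal(k1$joints$head, mapped, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("state occupancy tracks the configured dynamics", {
  dyn <- default_gaze_dynamics()
  sched <- data.frame(condition = "cooperative", duration_s = 1200)
  g <- generate_dyad(dyad_config(schedule = sched, seed = 14))
  occ <- as.numeric(g$truth$occupancy$cooperative)
  expect_lt(max(abs(occ - dyn$cooperative$occupancy)), 0.12)
})

test_that("coupled sways correlate at the planted lag on raw positions", {
  sched <- data.frame(condition = "cooperative", duration_s = 300)
  g <- generate_dyad(dyad_config(schedule = sched, seed = 15,
                                 coupling = list(lag_s = 1, strength = 0.8,
                                                 channel = "head"),
                                 sensor_noise_sd = 0, drop_prob = 0))
  x1 <- g$session$streams$p1$k2$joints$head[, 1]
  x2 <- g$session$streams$p2$k2$joints$head[, 1]
  cc <- ccf(x1, x2, lag.max = 40, plot = FALSE)
  best <- cc$lag[which.max(cc$acf)]
  expect_equal(best / 17, -1, tolerance = 0.1)  # x2 lags x1 by 1 s
  expect_gt(max(cc$acf), 0.6)
})

test_that("generate_scores respects instrument ranges", {
  set.seed(71)
  sc <- generate_scores(paste0("p", 1:200))
  for (col in c("relatedness", "enjoyment", "choice", "pressure", "effort")) {
    expect_true(all(sc[[col]] >= 1 & sc[[col]] <= 7))
  }
  expect_true(all(sc$aq >= 0 & sc$aq <= 50))
  expect_lt(abs(mean(sc$enjoyment) - 5.8), 0.25)
})

test_that("generate_cohort plants correlations near their targets", {
  co <- generate_cohort(cohort_config(n_dyads = 200, seed = 16))
  expect_lt(abs(cor(co$table$mean_distance_m, co$table$enjoyment) + 0.5),
            0.15)
  expect_lt(abs(cor(co$table$eye_contact_pct, co$table$effort) - 0.7), 0.12)
  expect_lt(abs(cor(co$table$synchrony_peak_r, co$table$age) - 0.5), 0.15)
  expect_error(cohort_config(n_dyads = 2), "at least 4")
})

test_that("cohort session mode realizes the planted summaries", {
  sched <- data.frame(condition = c("conversation", "cooperative"),
                      duration_s = c(60, 60))
  co <- generate_cohort(cohort_config(n_dyads = 4, sessions = TRUE,
                                      session_schedule = sched, seed = 17))
  expect_length(co$sessions, 4)
  for (i in 1:2) {
    s <- co$sessions[[i]]$session
    u1 <- resample_uniform(s$streams$p1$k2)
    u2 <- resample_uniform(s$streams$p2$k2)
    d <- mean(interhead_distance(u1$joints$head, u2$joints$head),
              na.rm = TRUE)
    expect_lt(abs(d - co$table$mean_distance_m[i]), 0.03)
    expect_equal(mean(s$scores$enjoyment), co$table$enjoyment[i],
                 tolerance = 1e-9)
  }
})

test_that("simulate_annotation_panel flips at the configured rate", {
  set.seed(72)
  n <- 20000
  truth <- data.frame(time_s = seq_len(n), participant = "p1",
                      looks_partner = sample(c(TRUE, FALSE), n, TRUE),
                      looks_target = sample(c(TRUE, FALSE), n, TRUE))
  rec <- simulate_annotation_panel(truth, error_rates = c(0.1, 0), seed = 1)
  r1 <- rec[rec$rater == "r1", ]
  flip_rate <- mean(c(r1$looks_partner != truth$looks_partner,
                      r1$looks_target != truth$looks_target))
  expect_lt(abs(flip_rate - 0.1), 0.01)
  # error-free raters agree with truth exactly
  r2 <- rec[rec$rater == "r2", ]
  expect_equal(r2$looks_partner, truth$looks_partner)
})

test_that("annotate_synthetic labels agree with the state truth", {
  g <- small_dyad(seed = 18)
  ann <- annotate_synthetic(g, n_per_condition = 40, error_rate = 0,
                            seed = 2)
  merged <- merge_annotations(ann$records)
  p1 <- merged[merged$participant == "p1", ]
  p2 <- merged[merged$participant == "p2", ]
  lab <- dyadic_gaze_label(p1$looks_partner, p1$looks_target,
                           p2$looks_partner, p2$looks_target)
  expect_equal(as.character(lab), as.character(ann$labels$label))
  expect_true(all(ann$labels$condition %in%
                    c("conversation", "cooperative", "competitive")))
  w <- capture_warnings(annotate_synthetic(g, n_per_condition = 1e6))
  expect_true(length(w) >= 1 && all(grepl("available", w)))
})
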