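test_that("gaze_vector anchors match the coordinate convention", {
  expect_equal(as.numeric(gaze_vector(0, 0)), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(as.numeric(gaze_vector(90, 0)), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(gaze_vector(0, 90)), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(gaze_vector(37, -21)^2)), 1, tolerance = 1e-12)
})

test_that("relative_yaw geometry anchors: 0, 90, 180 degrees", {
  own <- matrix(c(0, 1.2, 0), 1, 3)
  partner <- matrix(c(0, 1.2, 2), 1, 3)    # straight ahead (+z)
  expect_equal(relative_yaw(gaze_vector(0, 0), own, partner), 0,
               tolerance = 1e-9)
  expect_equal(relative_yaw(gaze_vector(90, 0), own, partner), 90,
               tolerance = 1e-9)
  expect_equal(relative_yaw(gaze_vector(180, 0), own, partner), 180,
               tolerance = 1e-9)
  # unsigned: -90 also maps to 90
  expect_equal(relative_yaw(gaze_vector(-90, 0), own, partner), 90,
               tolerance = 1e-9)
  # pitch does not affect the horizontal-plane angle
  expect_equal(relative_yaw(gaze_vector(0, 45), own, partner), 0,
               tolerance = 1e-9)
})

test_that("relative_yaw degenerate cases return NA", {
  own <- matrix(c(0, 1, 0), 1, 3)
  expect_true(is.na(relative_yaw(gaze_vector(0, 0), own, own)))
  # coincident horizontally, different heights
  above <- matrix(c(0, 2, 0), 1, 3)
  expect_true(is.na(relative_yaw(gaze_vector(0, 0), own, above)))
  # facing straight up: no horizontal component
  partner <- matrix(c(0, 1, 2), 1, 3)
  expect_true(is.na(relative_yaw(gaze_vector(0, 90), own, partner)))
})

test_that("3-4-5 scaled inter-head distance equals 0.5 m", {
  h1 <- matrix(c(0, 1.2, 0), 1, 3)
  h2 <- matrix(c(0.3, 1.2 + 0.4, 0), 1, 3)
  expect_equal(interhead_distance(h1, h2), 0.5, tolerance = 1e-12)
})

test_that("body_direction is the signed horizontal shoulder normal", {
  sl <- matrix(c(-0.2, 1, 0), 1, 3)
  sr <- matrix(c(0.2, 1, 0), 1, 3)
  chest_front <- matrix(c(0, 1, 0.1), 1, 3)
  chest_back <- matrix(c(0, 1, -0.1), 1, 3)
  expect_equal(as.numeric(body_direction(sl, sr, chest_front)), c(0, 0, 1),
               tolerance = 1e-12)
  expect_equal(as.numeric(body_direction(sl, sr, chest_back)), c(0, 0, -1),
               tolerance = 1e-12)
  # vertical shoulder offset is projected away
  sl2 <- matrix(c(-0.2, 1.1, 0), 1, 3)
  expect_equal(as.numeric(body_direction(sl2, sr, chest_front)), c(0, 0, 1),
               tolerance = 1e-12)
  expect_true(all(is.na(body_direction(sl, sl, chest_front))))
})

test_that("histograms sum to 100 before and after smoothing", {
  set.seed(20)
  th1 <- runif(5000, 0, 180); th2 <- runif(5000, 0, 180)
  h <- joint_orientation_histogram(th1, th2)
  expect_equal(sum(h), 100, tolerance = 1e-9)
  expect_equal(dim(h), c(180L, 180L))
  hs <- smooth_histogram(h, sigma = 5)
  expect_equal(sum(hs), 100, tolerance = 1e-9)
  # boundary values land in edge bins, never outside
  hb <- joint_orientation_histogram(c(0, 180), c(0, 180))
  expect_equal(sum(hb), 100, tolerance = 1e-9)
  expect_equal(hb[1, 1] + hb[180, 180], 100, tolerance = 1e-9)
})

test_that("histogram mass sits in the right cells and NA is excluded", {
  th1 <- c(10.5, 10.5, 90.5, NA)
  th2 <- c(20.5, 20.5, 120.5, 50)
  h <- joint_orientation_histogram(th1, th2)
  expect_equal(h[11, 21], 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(h[91, 121], 100 / 3, tolerance = 1e-9)
  expect_error(joint_orientation_histogram(NA_real_, NA_real_),
               "zero valid")
})

test_that("smoothing keeps mass near an edge (renormalized kernel)", {
  h <- joint_orientation_histogram(rep(0.5, 100), rep(0.5, 100))
  hs <- smooth_histogram(h, sigma = 5)
  expect_equal(sum(hs), 100, tolerance = 1e-9)
  expect_true(hs[1, 1] == max(hs))
})

test_that("relational_orientation face channel matches hand computation", {
  n <- 5
  t <- seq(0, 0.4, by = 0.1)
  h1 <- matrix(rep(c(0, 1.2, 0), each = n), n, 3)
  h2 <- matrix(rep(c(0, 1.2, 1), each = n), n, 3)
  mk <- function(h, yaw) {
    structure(list(t = t, rate = 10,
                   joints = list(head = h), orient = cbind(yaw, 0, 0),
                   valid = rep(TRUE, n)), class = "uniform_stream")
  }
  ro <- relational_orientation(mk(h1, rep(30, n)), mk(h2, rep(180, n)),
                               channel = "face")
  expect_equal(ro$theta_1, rep(30, n), tolerance = 1e-9)
  expect_equal(ro$theta_2, rep(0, n), tolerance = 1e-9)
})

test_that("compare_heatmaps gates pairwise maps by the ANOVA", {
  set.seed(21)
  n <- 6
  mk_hist <- function(shift) {
    th1 <- pmin(pmax(rnorm(800, 90 + shift, 20), 0), 180)
    th2 <- pmin(pmax(rnorm(800, 90 - shift, 20), 0), 180)
    smooth_histogram(joint_orientation_histogram(th1, th2, bin_width = 10))
  }
  hs <- lapply(seq_len(n), function(i) {
    list(conversation = mk_hist(0), cooperative = mk_hist(40))
  })
  res <- compare_heatmaps(hs)
  expect_gt(sum(res$sig_anova), 0)
  pr <- res$pairs[[1]]
  expect_true(all(!pr$sig[!res$sig_anova]))     # gate respected
  expect_gt(sum(pr$sig), 0)
  expect_error(compare_heatmaps(hs[1:2]), "at least 3")
})
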