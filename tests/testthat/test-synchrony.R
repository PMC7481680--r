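test_that("windowed_crosscorr equals the naive oracle to 1e-12", {
  set.seed(50)
  p <- wcc_params(window = 80, step = 11, max_lag = 25)
  for (rep in 1:3) {
    x <- cumsum(rnorm(600)) + 100
    y <- cumsum(rnorm(600)) - 40
    x[sample(600, 8)] <- NA
    a <- windowed_crosscorr(x, y, p)
    b <- naive_wcc(x, y, p)
    expect_identical(is.na(a), is.na(b))
    expect_lt(max(abs(a - b), na.rm = TRUE), 1e-12)
  }
})

test_that("ccf_xy(l) equals ccf_yx(-l) exactly", {
  set.seed(51)
  p <- wcc_params(window = 60, step = 5, max_lag = 20)
  x <- rnorm(400); y <- rnorm(400)
  a <- windowed_crosscorr(x, y, p)
  b <- windowed_crosscorr(y, x, p)
  expect_identical(unname(a), unname(b[, rev(seq_len(ncol(b)))]))
})

test_that("positive lag means participant 1 leads", {
  set.seed(52)
  x <- dyadmotion:::band_limited_noise(2000, 10, c(0.1, 1))
  lagn <- 12
  y <- c(rep(NA, lagn), x[1:(2000 - lagn)])   # y is x delayed: x leads
  p <- wcc_params(window = 300, step = 10, max_lag = 50)
  mc <- mean_ccf(windowed_crosscorr(x, y, p), rate = 10)
  expect_equal(mc$lag_s[which.max(mc$r)], lagn / 10, tolerance = 1e-9)
})

test_that("short trials give an empty matrix with a warning", {
  p <- wcc_params()
  expect_warning(m <- windowed_crosscorr(rnorm(100), rnorm(100), p),
                 "shorter than one window")
  expect_equal(nrow(m), 0)
  expect_error(mean_ccf(m), "zero windows")
  expect_error(wcc_params(window = 100, max_lag = 100), "smaller")
  expect_error(wcc_params(step = 0), "step")
})

test_that("constant and masked windows are NA", {
  p <- wcc_params(window = 50, step = 50, max_lag = 0)
  x <- c(rep(1, 60), rnorm(60))
  y <- rnorm(120)
  m <- windowed_crosscorr(x, y, p)
  expect_true(is.na(m[1, 1]))       # constant first window
  expect_false(is.na(m[2, 1]))
  x2 <- rnorm(120); x2[20] <- NA
  m2 <- windowed_crosscorr(x2, y, p)
  expect_true(is.na(m2[1, 1]))      # masked sample inside the window
})

test_that("pick_peak prefers the smallest-|lag| positive local maximum", {
  mk <- function(r, rate = 10) {
    lags <- seq_along(r) - (length(r) + 1) / 2
    structure(list(lag_s = lags / rate, r = r,
                   n_windows = rep(1, length(r))), class = "ccf_mean")
  }
  # maxima at lag indices -2 and +1 (samples): picks +1 (smaller |lag|)
  r <- c(0.1, 0.4, 0.2, 0.15, 0.2, 0.5, 0.1)
  pk <- pick_peak(mk(r))
  expect_equal(pk$lag_s, 0.2)
  expect_false(pk$fallback)
  # symmetric tie: prefers the positive lag
  r2 <- c(0.1, 0.4, 0.2, 0.1, 0.2, 0.4, 0.1)
  expect_equal(pick_peak(mk(r2))$lag_s, 0.2)
  # no positive local maximum: zero-lag fallback flagged
  r3 <- c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05, 0.0)
  pk3 <- pick_peak(mk(r3))
  expect_true(pk3$fallback)
  expect_equal(pk3$lag_s, 0)
})

test_that("estimate_coupling_lag interpolates to sub-sample precision", {
  lags <- -10:10
  true_lag <- 0.23
  r <- exp(-((lags / 10 - true_lag) / 0.4)^2)
  cc <- structure(list(lag_s = lags / 10, r = r,
                       n_windows = rep(1, 21)), class = "ccf_mean")
  est <- estimate_coupling_lag(cc)
  expect_lt(abs(est$lag_s - true_lag), 0.02)
})

test_that("shuffle_null never pairs the same dyad or same trial index", {
  set.seed(53)
  ts <- lapply(1:4, function(d) {
    lapply(1:3, function(tr) list(p1 = rnorm(400), p2 = rnorm(400)))
  })
  p <- wcc_params(window = 100, step = 20, max_lag = 30)
  sn <- shuffle_null(ts, p, n_perm = 50, seed = 1)
  expect_true(all(sn$pairings$dyad_1 != sn$pairings$dyad_2))
  expect_true(all(sn$pairings$trial_1 != sn$pairings$trial_2))
  expect_equal(dim(sn$null_r), c(50L, 61L))
  expect_equal(rownames(sn$envelope), c("p2.5", "p95", "p97.5"))
  # null of independent noise straddles zero
  expect_lt(sn$envelope["p2.5", 31], 0)
  expect_gt(sn$envelope["p97.5", 31], 0)
  expect_error(shuffle_null(ts[1:2], p), ">= 3 dyads")
})

test_that("dyad_synchrony summarizes per condition and skips pauses", {
  gen <- small_dyad(seed = 7, coupling = list(lag_s = 0.5, strength = 0.7,
                                              channel = "head"))
  pp <- preprocess_session(gen$session)
  ds <- dyad_synchrony(pp$p1$k2, pp$p2$k2, gen$session$annotations,
                       params = wcc_params(window = 200, step = 10,
                                           max_lag = 80))
  expect_false("pause" %in% ds$summary$condition)
  expect_true(all(c("conversation", "cooperative", "competitive") %in%
                    ds$summary$condition))
  expect_s3_class(ds$ccf$cooperative, "ccf_mean")
})

test_that("compare_ccf_conditions reports the % of significant lags", {
  set.seed(54)
  nlag <- 21
  mk <- function(r) structure(list(lag_s = seq(-1, 1, length.out = nlag),
                                   r = r, n_windows = rep(1, nlag)),
                              class = "ccf_mean")
  ccfs <- lapply(1:6, function(d) {
    base <- rnorm(nlag, 0, 0.02)
    list(conversation = mk(base + 0.3),   # clearly separated conditions
         cooperative = mk(base))
  })
  res <- compare_ccf_conditions(ccfs)
  expect_gt(res$frac_lags_significant, 90)
  expect_true(all(res$pairs[[1]]$sig[res$p_anova < 0.05]))
})
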