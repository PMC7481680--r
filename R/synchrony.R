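#' Windowed cross-correlation parameters
#'
#' Defaults follow the standard sliding-window settings for dyadic speed
#' series at 10 Hz: 30 s (300-sample) windows moved in 1 s (10-sample)
#' steps with up to 15 s (150-sample) lag in either direction.
#'
#' @param window window length in samples.
#' @param step step between window starts in samples.
#' @param max_lag maximum lag in samples (each direction).
#' @return list of validated parameters, class `wcc_params`.
#' @export
wcc_params <- function(window = 300L, step = 10L, max_lag = 150L) {
  window <- as.integer(window); step <- as.integer(step)
  max_lag <- as.integer(max_lag)
  if (step < 1L) stop("step must be >= 1")
  if (window <= 2L) stop("window must exceed 2 samples")
  if (max_lag >= window) stop("max lag must be smaller than the window")
  structure(list(window = window, step = step, max_lag = max_lag),
            class = "wcc_params")
}

# Rolling Pearson correlation of aligned vectors u, v over runs of length m.
# Values are NA where the run contains a missing sample or where either
# segment's sd is below sd_floor. Inputs should be pre-centred for
# numerical headroom; segment means are still removed per window.
rolling_pearson <- function(u, v, m, sd_floor = 1e-8) {
  n <- length(u)
  na <- is.na(u) | is.na(v)
  u0 <- ifelse(na, 0, u); v0 <- ifelse(na, 0, v)
  run <- function(z) {
    cz <- c(0, cumsum(z))
    cz[(m + 1L):(n + 1L)] - cz[1L:(n - m + 1L)]
  }
  nbad <- run(as.numeric(na))
  su <- run(u0); sv <- run(v0)
  suu <- run(u0 * u0); svv <- run(v0 * v0); suv <- run(u0 * v0)
  d1 <- suu - su^2 / m
  d2 <- svv - sv^2 / m
  var_floor <- sd_floor^2 * (m - 1)
  bad <- nbad > 0 | d1 < var_floor | d2 < var_floor
  denom <- sqrt(pmax(d1, 0) * pmax(d2, 0))
  denom[bad] <- 1                     # placeholder; masked below
  r <- (suv - su * sv / m) / denom
  r[bad] <- NA_real_
  r
}

#' Windowed cross-correlation matrix of two speed series
#'
#' For each sliding window and each lag, the Pearson correlation between
#' the overlapping segments of `x` and `y` offset by that lag, each segment
#' centred by its own mean over the n - |lag| overlapping samples. Positive
#' lags mean `x` (participant 1) leads. Windows never extend past the trial
#' end, and windows where either segment is (near-)constant or contains
#' masked samples yield `NA`.
#'
#' @param x,y speed series on a common uniform grid within one trial.
#' @param params a [wcc_params()].
#' @return matrix (windows x lags) with lag-in-samples column names; an
#'   empty matrix with a warning when the trial is shorter than one window.
#' @export
windowed_crosscorr <- function(x, y, params = wcc_params()) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  lags <- -params$max_lag:params$max_lag
  if (n < params$window) {
    warning("trial shorter than one window; empty correlation matrix")
    return(matrix(NA_real_, 0, length(lags),
                  dimnames = list(NULL, as.character(lags))))
  }
  starts <- seq.int(1L, n - params$window + 1L, by = params$step)
  out <- matrix(NA_real_, length(starts), length(lags),
                dimnames = list(NULL, as.character(lags)))
  xm <- x - mean(x, na.rm = TRUE)
  ym <- y - mean(y, na.rm = TRUE)
  for (li in seq_along(lags)) {
    l <- lags[li]
    if (l >= 0) {
      u <- xm[seq_len(n - l)]
      v <- ym[seq.int(1L + l, n)]
    } else {
      u <- xm[seq.int(1L - l, n)]
      v <- ym[seq_len(n + l)]
    }
    m <- params$window - abs(l)
    r <- rolling_pearson(u, v, m)
    out[, li] <- r[starts]
  }
  out
}

#' Mean windowed cross-correlation function
#'
#' Averages window x lag matrices (all windows of all trials of one
#' condition) into a single per-lag mean function.
#'
#' @param matrices a single matrix from [windowed_crosscorr()] or a list of
#'   them (same lag grid).
#' @param rate sampling rate (Hz), to express lags in seconds.
#' @param dyad,condition,channel metadata carried on the result.
#' @return object of class `ccf_mean`: `lag_s`, `r`, `n_windows` per lag.
#' @export
mean_ccf <- function(matrices, rate = 10, dyad = NA, condition = NA,
                     channel = NA) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  matrices <- Filter(function(m) nrow(m) > 0, matrices)
  if (!length(matrices)) stop("data error: zero windows")
  all_rows <- do.call(rbind, matrices)
  lags <- as.integer(colnames(all_rows))
  n_win <- colSums(!is.na(all_rows))
  r <- colMeans(all_rows, na.rm = TRUE)
  r[n_win == 0] <- NA_real_
  structure(list(lag_s = lags / rate, r = unname(r),
                 n_windows = unname(n_win), dyad = dyad,
                 condition = condition, channel = channel),
            class = "ccf_mean")
}

#' Pick the synchrony peak of a mean cross-correlation function
#'
#' Among strict local maxima with positive correlation, returns the one
#' with the smallest absolute lag (ties prefer the positive lag, i.e.
#' participant 1 leading). When no positive local maximum exists, falls
#' back to the zero-lag value with `fallback = TRUE`.
#'
#' @param ccf a `ccf_mean`.
#' @return list with `lag_s`, `r`, `zero_lag_r` and `fallback`.
#' @export
pick_peak <- function(ccf) {
  r <- ccf$r; lag <- ccf$lag_s
  if (all(is.na(r))) stop("data error: all-missing cross-correlation")
  zero_idx <- which.min(abs(lag))
  nl <- length(r)
  cand <- integer(0)
  if (nl >= 3L) {
    i <- 2:(nl - 1)
    is_max <- !is.na(r[i]) & !is.na(r[i - 1]) & !is.na(r[i + 1]) &
      r[i - 1] < r[i] & r[i] >= r[i + 1] & r[i] > 0
    cand <- i[is_max]
  }
  if (!length(cand)) {
    return(list(lag_s = lag[zero_idx], r = r[zero_idx],
                zero_lag_r = r[zero_idx], fallback = TRUE))
  }
  a <- abs(lag[cand])
  best <- cand[a == min(a)]
  if (length(best) > 1L) best <- best[which.max(lag[best])]
  list(lag_s = lag[best], r = r[best], zero_lag_r = r[zero_idx],
       fallback = FALSE)
}

#' Estimate the coupling lag from a mean cross-correlation function
#'
#' Global argmax of the mean function refined by quadratic (three-point
#' parabolic) interpolation around the peak, for sub-sample lag precision.
#'
#' @param ccf a `ccf_mean`.
#' @return list with `lag_s` (interpolated) and `r` at the discrete peak.
#' @export
estimate_coupling_lag <- function(ccf) {
  r <- ccf$r; lag <- ccf$lag_s
  if (all(is.na(r))) stop("data error: all-missing cross-correlation")
  i <- which.max(r)
  lag_hat <- lag[i]
  if (i > 1L && i < length(r) && !is.na(r[i - 1]) && !is.na(r[i + 1])) {
    denom <- r[i - 1] - 2 * r[i] + r[i + 1]
    if (abs(denom) > 1e-12) {
      delta <- 0.5 * (r[i - 1] - r[i + 1]) / denom
      if (abs(delta) <= 1) lag_hat <- lag[i] + delta * (lag[2] - lag[1])
    }
  }
  list(lag_s = lag_hat, r = r[i])
}

#' Per-dyad, per-condition synchrony of one channel
#'
#' Convenience wrapper: computes the windowed cross-correlation of the two
#' participants' joint speeds within each (non-pause) trial, averages to a
#' mean function per condition and summarizes with zero-lag and picked-peak
#' values.
#'
#' @param stream_1,stream_2 preprocessed `uniform_stream`s on a common grid.
#' @param annotations [trial_annotations()].
#' @param joint `"head"` or `"hand_dominant"`.
#' @param params [wcc_params()].
#' @return list with `ccf` (condition -> `ccf_mean`) and a `summary`
#'   data.frame (condition, zero_lag_r, peak_lag_s, peak_r, fallback).
#' @export
dyad_synchrony <- function(stream_1, stream_2, annotations, joint = "head",
                           params = wcc_params()) {
  s1 <- joint_speed(stream_1, joint)
  s2 <- joint_speed(stream_2, joint)
  tt <- stream_1$t
  conds <- setdiff(unique(annotations$condition), "pause")
  ccfs <- list()
  for (cd in conds) {
    rows <- which(annotations$condition == cd)
    mats <- lapply(rows, function(i) {
      sel <- tt >= annotations$start_s[i] & tt <= annotations$end_s[i]
      suppressWarnings(windowed_crosscorr(s1[sel], s2[sel], params))
    })
    mats <- Filter(function(m) nrow(m) > 0, mats)
    if (!length(mats)) next
    ccfs[[cd]] <- mean_ccf(mats, rate = stream_1$rate, condition = cd,
                           channel = joint)
  }
  summ <- do.call(rbind, lapply(names(ccfs), function(cd) {
    pk <- pick_peak(ccfs[[cd]])
    data.frame(condition = cd, zero_lag_r = pk$zero_lag_r,
               peak_lag_s = pk$lag_s, peak_r = pk$r, fallback = pk$fallback)
  }))
  list(ccf = ccfs, summary = summ)
}

#' Shuffled-dyad surrogate null for the mean cross-correlation
#'
#' Builds surrogate pairings in which participant 1 of one dyad/trial is
#' paired with participant 2 of a *different* dyad and a *different* trial
#' index, destroying any genuine coupling, and returns the surrogate mean
#' cross-correlation functions with percentile envelopes.
#'
#' @param trial_speeds nested list: dyad -> trial -> list(p1 =, p2 = speed
#'   vectors). Trial names/indices are matched across dyads by position.
#' @param params a [wcc_params()].
#' @param n_perm number of surrogate pairings (default 1000).
#' @param seed RNG seed.
#' @param rate sampling rate (Hz).
#' @param probs percentile levels of the envelope (default 2.5/95/97.5).
#' @return list with `null_r` (n_perm x lags matrix of surrogate mean
#'   functions), `lag_s`, `envelope` (percentile x lag), and the sampled
#'   `pairings`.
#' @export
shuffle_null <- function(trial_speeds, params = wcc_params(), n_perm = 1000,
                         seed = 1, rate = 10,
                         probs = c(0.025, 0.95, 0.975)) {
  nd <- length(trial_speeds)
  ntr <- vapply(trial_speeds, length, integer(1))
  if (nd < 3L || any(ntr < 2L)) {
    stop("need >= 3 dyads with >= 2 trials each for shuffled surrogates")
  }
  set.seed(seed)
  lags <- -params$max_lag:params$max_lag
  null_r <- matrix(NA_real_, n_perm, length(lags))
  pairings <- data.frame(dyad_1 = integer(n_perm), trial_1 = integer(n_perm),
                         dyad_2 = integer(n_perm), trial_2 = integer(n_perm))
  for (i in seq_len(n_perm)) {
    d1 <- sample.int(nd, 1)
    d2 <- sample(setdiff(seq_len(nd), d1), 1)
    t1 <- sample.int(ntr[d1], 1)
    t2 <- sample(setdiff(seq_len(ntr[d2]), t1), 1)
    x <- trial_speeds[[d1]][[t1]]$p1
    y <- trial_speeds[[d2]][[t2]]$p2
    nmin <- min(length(x), length(y))
    m <- suppressWarnings(
      windowed_crosscorr(x[seq_len(nmin)], y[seq_len(nmin)], params))
    if (nrow(m)) null_r[i, ] <- mean_ccf(m, rate = rate)$r
    pairings[i, ] <- c(d1, t1, d2, t2)
  }
  env <- apply(null_r, 2, quantile, probs = probs, na.rm = TRUE)
  if (is.null(dim(env))) env <- matrix(env, nrow = 1)
  rownames(env) <- paste0("p", probs * 100)
  list(null_r = null_r, lag_s = lags / rate, envelope = env,
       pairings = pairings)
}

#' Per-lag condition contrasts of mean cross-correlation functions
#'
#' Repeated-measures ANOVA across conditions at every lag (dyad as the
#' repeated unit) plus pairwise paired t-tests; reports the fraction of
#' lags with a significant condition main effect.
#'
#' @param ccf_by_dyad list (per dyad) of named lists (condition ->
#'   `ccf_mean`), every dyad covering every condition on one lag grid.
#' @param pairs list of condition pairs to contrast (default all).
#' @param alpha significance threshold (default 0.05).
#' @return list with `lag_s`, `F`, `p_anova`, `sig_anova`,
#'   `frac_lags_significant` (in percent), and per-pair `t`/`p`/`sig`.
#' @export
compare_ccf_conditions <- function(ccf_by_dyad, pairs = NULL, alpha = 0.05) {
  n <- length(ccf_by_dyad)
  if (n < 3L) stop("need >= 3 dyads")
  conds <- names(ccf_by_dyad[[1]])
  lag_s <- ccf_by_dyad[[1]][[1]]$lag_s
  y <- array(NA_real_, c(n, length(conds), length(lag_s)))
  for (i in seq_len(n)) {
    for (j in seq_along(conds)) {
      y[i, j, ] <- ccf_by_dyad[[i]][[conds[j]]]$r
    }
  }
  an <- rm_anova_cells(y)
  sig <- an$p < alpha & !is.na(an$p)
  if (is.null(pairs)) pairs <- utils::combn(conds, 2, simplify = FALSE)
  pair_res <- lapply(pairs, function(pr) {
    tt <- paired_t_cells(y[, match(pr[1], conds), , drop = TRUE],
                         y[, match(pr[2], conds), , drop = TRUE])
    list(pair = pr, t = tt$t, p = tt$p,
         sig = tt$p < alpha & sig & !is.na(tt$p))
  })
  names(pair_res) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  list(lag_s = lag_s, F = an$F, p_anova = an$p, sig_anova = sig,
       frac_lags_significant = 100 * mean(sig, na.rm = TRUE),
       pairs = pair_res, alpha = alpha)
}
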