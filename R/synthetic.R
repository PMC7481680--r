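# Band-limited unit-variance Gaussian noise via FFT masking.
band_limited_noise <- function(n, rate, band = c(0.1, 1)) {
  if (n < 8L) return(rnorm(n))
  w <- rnorm(n)
  f <- fft(w)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * rate / n
  keep <- freq >= band[1] & freq <= band[2]
  keep[1] <- FALSE
  if (!any(keep)) keep <- freq <= band[2] & freq > 0
  f[!keep] <- 0 + 0i
  x <- Re(fft(f, inverse = TRUE)) / n
  s <- sd(x)
  if (s < 1e-12) return(rnorm(n) * 0)
  x / s
}

#' Default task schedule of a recorded session
#'
#' Conversation, a practice round, six scored gameplay rounds alternating
#' cooperative/competitive, a closing conversation, and pauses in between,
#' with durations typical of the protocol (conversations a few minutes,
#' rounds ~2.5 min, pauses ~1 min).
#'
#' @return data.frame with `condition` and `duration_s`.
#' @export
default_schedule <- function() {
  data.frame(
    condition = c("conversation", "pause", "practice", "pause",
                  "cooperative", "pause", "competitive", "pause",
                  "cooperative", "pause", "competitive", "pause",
                  "cooperative", "pause", "competitive", "pause",
                  "conversation"),
    duration_s = c(210, 60, 120, 60, 150, 60, 150, 60, 150, 60, 150, 60,
                   150, 60, 150, 60, 210))
}

#' Default gaze-state dynamics per condition
#'
#' Stationary occupancy over the four dyadic gaze states and mean bout
#' dwell (seconds): conversation favours eye contact and other-oriented
#' gaze, gameplay favours joint attention on the stick bundle, pauses skew
#' toward looking away (at the experimenter).
#'
#' @return named list per condition with `occupancy` (length 4, ordered as
#'   eye_contact/joint_attention/other_oriented/away) and `dwell_s`.
#' @export
default_gaze_dynamics <- function() {
  list(
    conversation = list(occupancy = c(0.35, 0.05, 0.35, 0.25), dwell_s = 3),
    practice = list(occupancy = c(0.05, 0.55, 0.25, 0.15), dwell_s = 2),
    cooperative = list(occupancy = c(0.08, 0.62, 0.20, 0.10), dwell_s = 2.5),
    competitive = list(occupancy = c(0.08, 0.62, 0.20, 0.10), dwell_s = 2.5),
    pause = list(occupancy = c(0.10, 0.15, 0.20, 0.55), dwell_s = 3))
}

#' Configuration of the synthetic dyad generator
#'
#' Defaults emulate the recorded sessions: two participants seated
#' diagonally ~1 m apart across a table corner, a shared target at the
#' table centre, ~17 Hz native sampling with dropped frames, two sensor
#' views related by an unknown rigid transform and a small clock offset,
#' centimetre-scale seated head sway in the 0.1-1 Hz band, and
#' condition-dependent gaze-state switching.
#'
#' @param dyad_id identifier.
#' @param seat_1,seat_2 head rest positions (m).
#' @param target_position shared attention target (m).
#' @param schedule data.frame of `condition`, `duration_s`.
#' @param gaze_dynamics per-condition occupancy/dwell, see
#'   [default_gaze_dynamics()].
#' @param orientation_noise_sd head orientation noise sd (degrees).
#' @param sway_sd head sway amplitude (m, per horizontal axis).
#' @param sway_band sway bandwidth (Hz).
#' @param coupling list `lag_s`, `strength` in \[0, 1\], `channel`
#'   (`"head"` or `"hand"`).
#' @param native_rate sensor sampling rate (Hz).
#' @param drop_prob i.i.d. per-frame drop probability per sensor.
#' @param sensor_transform rigid transform from the reference (`k2`) frame
#'   into the second sensor (`k1`) frame.
#' @param sensor_noise_sd per-sensor position noise sd (m).
#' @param clock_offset_s clock offset of sensor `k1` (s).
#' @param scores optional [subject_scores()] table (generated when `NULL`).
#' @param seed RNG seed; identical seeds give bit-identical sessions.
#' @return config list of class `dyad_config`.
#' @export
dyad_config <- function(dyad_id = "dyad01",
                        seat_1 = c(-0.35, 1.20, -0.35),
                        seat_2 = c(0.35, 1.20, 0.35),
                        target_position = c(0, 0.95, 0),
                        schedule = default_schedule(),
                        gaze_dynamics = default_gaze_dynamics(),
                        orientation_noise_sd = 5,
                        sway_sd = 0.02,
                        sway_band = c(0.1, 1),
                        coupling = list(lag_s = 0, strength = 0,
                                        channel = "head"),
                        native_rate = 17,
                        drop_prob = 0.1,
                        sensor_transform = rigid_transform(rotation_y(35),
                                                           c(0.8, 0.02,
                                                             -0.6)),
                        sensor_noise_sd = 0.005,
                        clock_offset_s = 0.05,
                        scores = NULL,
                        seed = 1) {
  if (sqrt(sum((seat_1 - seat_2)^2)) < 0.2) {
    stop("config error: seats (near-)coincident")
  }
  stopifnot(coupling$strength >= 0, coupling$strength <= 1,
            drop_prob >= 0, drop_prob < 1)
  structure(as.list(environment()), class = "dyad_config")
}

# Sample a gaze-state bout sequence covering `duration` seconds.
sample_bouts <- function(duration, occupancy, dwell_s) {
  bouts <- list()
  t <- 0
  while (t < duration) {
    state <- sample(GAZE_LEVELS, 1, prob = occupancy)
    len <- stats::rexp(1, rate = 1 / dwell_s)
    len <- max(len, 0.2)
    bouts[[length(bouts) + 1L]] <- data.frame(
      state = state, start = t, end = min(t + len, duration))
    t <- t + len
  }
  do.call(rbind, bouts)
}

# Horizontal yaw (deg) of the direction from `from` to `to`.
yaw_toward <- function(from, to) {
  d <- to - from
  atan2(d[1], d[3]) * 180 / pi
}

# A look point clearly away from both the partner and the target: at least
# `min_offset` degrees of yaw from either, 2 m out, near eye level.
away_point <- function(head, partner, target, min_offset = 30) {
  yp <- yaw_toward(head, partner)
  yt <- yaw_toward(head, target)
  repeat {
    yaw <- runif(1, -180, 180)
    if (abs(wrap_deg(yaw - yp)) >= min_offset &&
        abs(wrap_deg(yaw - yt)) >= min_offset) break
  }
  dir <- gaze_vector(yaw, runif(1, -10, 10))[1, ]
  head + 2 * dir
}

#' Generate a synthetic dyad session with ground truth
#'
#' Produces two participants' skeleton streams (head, neck, shoulders,
#' spine-at-shoulder, dominant hand) whose head orientations follow a
#' sampled gaze-state sequence, whose head positions sway inside the
#' configured band, and whose movement is coupled across participants at
#' the configured lag and strength; frames are dropped i.i.d. and two
#' sensor views are emitted, related by the configured rigid transform,
#' sensor noise and clock offset.
#'
#' @param cfg a [dyad_config()].
#' @return list with `session` (a [dyad_session()]) and `truth` (state
#'   sequence with per-participant looking booleans, the true transform,
#'   coupling, seats and per-condition state occupancy).
#' @export
generate_dyad <- function(cfg) {
  stopifnot(inherits(cfg, "dyad_config"))
  set.seed(cfg$seed)
  rate <- cfg$native_rate
  sched <- cfg$schedule
  sched$end <- cumsum(sched$duration_s)
  sched$start <- sched$end - sched$duration_s
  total <- sum(sched$duration_s)
  tt <- seq(0, total, by = 1 / rate)
  n <- length(tt)

  # --- head sway with cross-participant coupling --------------------------
  lag_samp <- as.integer(round(cfg$coupling$lag_s * rate))
  a <- cfg$coupling$strength
  pad <- abs(lag_samp) + 8L
  mk_coupled <- function() {
    n1_ext <- band_limited_noise(n + 2L * pad, rate, cfg$sway_band)
    n1 <- n1_ext[(pad + 1L):(pad + n)]
    n1_del <- n1_ext[(pad + 1L - lag_samp):(pad + n - lag_samp)]
    n2 <- sqrt(1 - a^2) * band_limited_noise(n, rate, cfg$sway_band) +
      a * n1_del
    list(p1 = n1, p2 = n2)
  }
  head_couple <- cfg$coupling$channel == "head"
  sway <- lapply(1:3, function(ax) {
    if (head_couple) {
      mk_coupled()
    } else {
      list(p1 = band_limited_noise(n, rate, cfg$sway_band),
           p2 = band_limited_noise(n, rate, cfg$sway_band))
    }
  })
  amp <- cfg$sway_sd * c(1, 0.5, 1)    # vertical sway smaller
  head_pos <- list(
    p1 = cbind(cfg$seat_1[1] + amp[1] * sway[[1]]$p1,
               cfg$seat_1[2] + amp[2] * sway[[2]]$p1,
               cfg$seat_1[3] + amp[3] * sway[[3]]$p1),
    p2 = cbind(cfg$seat_2[1] + amp[1] * sway[[1]]$p2,
               cfg$seat_2[2] + amp[2] * sway[[2]]$p2,
               cfg$seat_2[3] + amp[3] * sway[[3]]$p2))

  # --- hand motion (larger amplitude, own coupling when configured) ------
  hand_base <- list(p1 = cfg$seat_1 * c(0.7, 0, 0.7) + c(0, 0.95, 0),
                    p2 = cfg$seat_2 * c(0.7, 0, 0.7) + c(0, 0.95, 0))
  hand_noise <- lapply(1:3, function(ax) {
    if (!head_couple) {
      mk_coupled()
    } else {
      list(p1 = band_limited_noise(n, rate, cfg$sway_band),
           p2 = band_limited_noise(n, rate, cfg$sway_band))
    }
  })
  hamp <- 0.05
  hand_pos <- lapply(c(p1 = "p1", p2 = "p2"), function(p) {
    cbind(hand_base[[p]][1] + hamp * hand_noise[[1]][[p]],
          hand_base[[p]][2] + hamp * hand_noise[[2]][[p]],
          hand_base[[p]][3] + hamp * hand_noise[[3]][[p]])
  })

  # --- gaze-state sequence and per-sample looking booleans ----------------
  state <- character(n)
  looks <- matrix(FALSE, n, 4,
                  dimnames = list(NULL, c("p1_partner", "p1_target",
                                          "p2_partner", "p2_target")))
  look_point <- list(p1 = matrix(NA_real_, n, 3), p2 = matrix(NA_real_, n, 3))
  for (bi in seq_len(nrow(sched))) {
    cond <- sched$condition[bi]
    dyn <- cfg$gaze_dynamics[[cond]]
    bouts <- sample_bouts(sched$duration_s[bi], dyn$occupancy, dyn$dwell_s)
    for (k in seq_len(nrow(bouts))) {
      sel <- which(tt >= sched$start[bi] + bouts$start[k] &
                   tt < sched$start[bi] + bouts$end[k])
      if (!length(sel)) next
      st <- bouts$state[k]
      state[sel] <- st
      mid1 <- colMeans(head_pos$p1[sel, , drop = FALSE])
      mid2 <- colMeans(head_pos$p2[sel, , drop = FALSE])
      tgt <- cfg$target_position
      assign_look <- function(p, mode) {
        own <- if (p == "p1") mid1 else mid2
        partner <- if (p == "p1") mid2 else mid1
        pt <- switch(mode,
                     partner = NULL,          # track the moving head
                     target = tgt,
                     away = away_point(own, partner, tgt))
        if (mode == "partner") {
          look_point[[p]][sel, ] <<- if (p == "p1") {
            head_pos$p2[sel, , drop = FALSE]
          } else {
            head_pos$p1[sel, , drop = FALSE]
          }
        } else {
          look_point[[p]][sel, ] <<- matrix(pt, length(sel), 3, byrow = TRUE)
        }
        looks[sel, paste0(p, "_partner")] <<- mode == "partner"
        looks[sel, paste0(p, "_target")] <<- mode == "target"
      }
      if (st == "eye_contact") {
        assign_look("p1", "partner"); assign_look("p2", "partner")
      } else if (st == "joint_attention") {
        assign_look("p1", "target"); assign_look("p2", "target")
      } else if (st == "other_oriented") {
        if (runif(1) < 0.5) {
          assign_look("p1", "partner"); assign_look("p2", "target")
        } else {
          assign_look("p1", "target"); assign_look("p2", "partner")
        }
      } else {
        u <- runif(1)
        if (u < 0.45) {
          assign_look("p1", "away")
          assign_look("p2", if (runif(1) < 0.5) "partner" else "target")
        } else if (u < 0.9) {
          assign_look("p1", if (runif(1) < 0.5) "partner" else "target")
          assign_look("p2", "away")
        } else {
          assign_look("p1", "away"); assign_look("p2", "away")
        }
      }
    }
  }

  # --- head orientation from look points plus smooth noise ----------------
  orient_noise <- function() {
    cbind(cfg$orientation_noise_sd *
            band_limited_noise(n, rate, cfg$sway_band),
          cfg$orientation_noise_sd *
            band_limited_noise(n, rate, cfg$sway_band),
          2 * band_limited_noise(n, rate, cfg$sway_band))
  }
  orient <- lapply(c(p1 = "p1", p2 = "p2"), function(p) {
    d <- look_point[[p]] - head_pos[[p]]
    nrm <- sqrt(rowSums(d^2))
    yaw <- atan2(d[, 1], d[, 3]) * 180 / pi
    pitch <- asin(pmin(1, pmax(-1, d[, 2] / nrm))) * 180 / pi
    nz <- orient_noise()
    cbind(yaw = wrap_deg(yaw + nz[, 1]), pitch = pitch + nz[, 2],
          roll = nz[, 3])
  })

  # --- remaining joints from seated geometry ------------------------------
  body_yaw <- c(p1 = yaw_toward(cfg$seat_1, cfg$target_position),
                p2 = yaw_toward(cfg$seat_2, cfg$target_position))
  joints_true <- lapply(c(p1 = "p1", p2 = "p2"), function(p) {
    hp <- head_pos[[p]]
    fwd <- gaze_vector(rep(body_yaw[[p]], n), rep(0, n))
    lat <- cbind(fwd[, 3], 0, -fwd[, 1])           # left-hand direction
    drop_y <- function(m, dy) m + matrix(c(0, dy, 0), nrow(m), 3,
                                         byrow = TRUE)
    mid <- drop_y(hp, -0.25) - 0.05 * fwd
    list(head = hp,
         neck = drop_y(hp, -0.12),
         shoulder_left = mid + 0.20 * lat,
         shoulder_right = mid - 0.20 * lat,
         spine_shoulder = mid + 0.06 * fwd,
         hand_dominant = hand_pos[[p]])
  })

  # --- sensor views -------------------------------------------------------
  sensor_stream <- function(p, sensor) {
    jt <- joints_true[[p]]
    or <- orient[[p]]
    if (sensor == "k1") {
      jt <- lapply(jt, function(m) transform_points(cfg$sensor_transform, m))
      fwdv <- as.numeric(cfg$sensor_transform$rotation %*% c(0, 0, 1))
      dyaw <- atan2(fwdv[1], fwdv[3]) * 180 / pi
      or <- cbind(yaw = wrap_deg(or[, "yaw"] + dyaw), pitch = or[, "pitch"],
                  roll = or[, "roll"])
      stamps <- tt + cfg$clock_offset_s
    } else {
      stamps <- tt
    }
    jt <- lapply(jt, function(m) {
      m + matrix(rnorm(length(m), sd = cfg$sensor_noise_sd), nrow(m), 3)
    })
    or <- or + matrix(rnorm(length(or), sd = cfg$orientation_noise_sd / 5),
                      n, 3)
    or[, 1] <- wrap_deg(or[, 1])
    valid <- runif(n) > cfg$drop_prob
    valid[1] <- valid[n] <- TRUE
    skeleton_stream(p, sensor, stamps, jt, or, valid)
  }
  streams <- list(
    p1 = list(k1 = sensor_stream("p1", "k1"),
              k2 = sensor_stream("p1", "k2")),
    p2 = list(k1 = sensor_stream("p2", "k1"),
              k2 = sensor_stream("p2", "k2")))

  ann <- trial_annotations(seq_len(nrow(sched)), sched$condition,
                           sched$start, sched$end - 1e-9)
  scores <- if (is.null(cfg$scores)) {
    generate_scores(c(paste0(cfg$dyad_id, "_p1"),
                      paste0(cfg$dyad_id, "_p2")))
  } else cfg$scores
  session <- dyad_session(cfg$dyad_id, streams, ann, scores,
                          native_rate = rate)
  occ <- lapply(split(state, cond_at(tt, ann)), function(s) {
    prop.table(table(factor(s, levels = GAZE_LEVELS)))
  })
  truth <- list(
    states = data.frame(t = tt, state = factor(state, levels = GAZE_LEVELS),
                        looks),
    transform = cfg$sensor_transform,
    clock_offset_s = cfg$clock_offset_s,
    coupling = cfg$coupling,
    seats = rbind(p1 = cfg$seat_1, p2 = cfg$seat_2),
    occupancy = occ)
  list(session = session, truth = truth)
}

# Condition label at each time point (NA outside any trial).
cond_at <- function(times, annotations) {
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(annotations))) {
    sel <- times >= annotations$start_s[i] & times <= annotations$end_s[i]
    out[sel] <- annotations$condition[i]
  }
  out
}

#' Generate plausible subject scores
#'
#' Draws intrinsic-motivation subscales, ACIPS, AQ and age from the typical
#' young-adult distributions of such cohorts (relatedness 5.2 +/- 0.9,
#' enjoyment 5.8 +/- 0.9, choice 4.3 +/- 1.2, pressure 2.2 +/- 0.7, effort
#' 4.7 +/- 1.1, ACIPS 85 +/- 9, AQ 15.5 +/- 5, age 26 +/- 5.6), clipped to
#' instrument ranges.
#'
#' @param participant_ids identifiers (one row each).
#' @return a [subject_scores()] table.
#' @export
generate_scores <- function(participant_ids) {
  k <- length(participant_ids)
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  subject_scores(
    participant_ids,
    relatedness = clip(rnorm(k, 5.2, 0.9), 1, 7),
    enjoyment = clip(rnorm(k, 5.8, 0.9), 1, 7),
    choice = clip(rnorm(k, 4.3, 1.2), 1, 7),
    pressure = clip(rnorm(k, 2.2, 0.7), 1, 7),
    effort = clip(rnorm(k, 4.7, 1.1), 1, 7),
    acips = clip(rnorm(k, 85.1, 9.3), 17, 119),
    aq = clip(round(rnorm(k, 15.5, 5.1)), 0, 50),
    age = clip(round(rnorm(k, 26, 5.6)), 18, 60))
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_dyads number of dyads (default 18).
#' @param distance_enjoyment_r planted population correlation between mean
#'   inter-head distance and dyad-mean enjoyment (default -0.5).
#' @param eyecontact_effort_r planted correlation between eye-contact
#'   occupancy and dyad-mean effort (default 0.7).
#' @param age_synchrony_r planted correlation between dyad-mean age and
#'   synchrony strength (default 0.5).
#' @param rating_noise_sd per-participant rating noise around the dyad
#'   latent, in rating units (default 0.4).
#' @param distance_base,distance_sd mean and spread of dyad mean inter-head
#'   distance (m).
#' @param sessions when `TRUE`, full dyad sessions are generated alongside
#'   the summary table (slower); when `FALSE` only the cohort table and
#'   ground truth are returned.
#' @param session_schedule schedule used when `sessions = TRUE`.
#' @param seed RNG seed.
#' @return config list of class `cohort_config`.
#' @export
cohort_config <- function(n_dyads = 18,
                          distance_enjoyment_r = -0.5,
                          eyecontact_effort_r = 0.7,
                          age_synchrony_r = 0.5,
                          rating_noise_sd = 0.4,
                          distance_base = 1.0,
                          distance_sd = 0.12,
                          sessions = FALSE,
                          session_schedule = default_schedule(),
                          seed = 1) {
  if (n_dyads < 4) stop("need at least 4 dyads")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort with planted behaviour-rating correlations
#'
#' Per-dyad latent traits (enjoyment, effort, age) are drawn on the
#' instrument scales; behavioural summaries (mean inter-head distance,
#' eye-contact occupancy, synchrony strength) are linear functions of the
#' emitted dyad-mean ratings, mixed so the planted population correlation
#' is exactly the configured one. When `sessions = TRUE`, a full synthetic
#' session is generated per dyad whose seat separation, eye-contact
#' occupancy and coupling strength realize the planted summaries.
#'
#' @param cfg a [cohort_config()].
#' @return list with `table` (one row per dyad: scores + behavioural
#'   summaries), `truth` (planted correlations and latents), and `sessions`
#'   (list of [generate_dyad()] results, or `NULL`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  nd <- cfg$n_dyads
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  latent <- data.frame(enjoyment = rnorm(nd), effort = rnorm(nd),
                       age = rnorm(nd))
  # per-participant ratings: dyad latent plus individual noise
  part_rating <- function(z, mean, sd, lo, hi) {
    cbind(clip(mean + sd * z + rnorm(nd, 0, cfg$rating_noise_sd), lo, hi),
          clip(mean + sd * z + rnorm(nd, 0, cfg$rating_noise_sd), lo, hi))
  }
  enj <- part_rating(latent$enjoyment, 5.8, 0.9, 1, 7)
  eff <- part_rating(latent$effort, 4.7, 1.1, 1, 7)
  age <- matrix(round(clip(26 + 5.6 * latent$age +
                             matrix(rnorm(2 * nd, 0, 1.5), nd, 2), 18, 60)),
                nd, 2)
  dyad_mean <- function(m) rowMeans(m)
  plant <- function(target_r, anchor, base, sdv) {
    z <- scale(anchor)[, 1]
    base + sdv * (target_r * z + sqrt(1 - target_r^2) * rnorm(nd))
  }
  distance <- plant(cfg$distance_enjoyment_r, dyad_mean(enj),
                    cfg$distance_base, cfg$distance_sd)
  distance <- pmax(distance, 0.4)
  eye_contact_pct <- clip(plant(cfg$eyecontact_effort_r, dyad_mean(eff),
                                22, 7), 1, 60)
  synchrony_r <- clip(plant(cfg$age_synchrony_r, dyad_mean(age), 0.3, 0.08),
                      0.02, 0.9)
  tab <- data.frame(
    dyad_id = sprintf("dyad%02d", seq_len(nd)),
    enjoyment = dyad_mean(enj), effort = dyad_mean(eff),
    age = dyad_mean(age),
    mean_distance_m = distance,
    eye_contact_pct = eye_contact_pct,
    synchrony_peak_r = synchrony_r)
  sessions <- NULL
  if (cfg$sessions) {
    sessions <- lapply(seq_len(nd), function(i) {
      half <- distance[i] / (2 * sqrt(2))
      dyn <- default_gaze_dynamics()
      ec <- eye_contact_pct[i] / 100
      for (cd in names(dyn)) {
        occ <- dyn[[cd]]$occupancy
        occ[1] <- ec
        occ[-1] <- occ[-1] * (1 - ec) / sum(occ[-1])
        dyn[[cd]]$occupancy <- occ
      }
      sc <- subject_scores(
        sprintf("dyad%02d_p%d", i, 1:2),
        enjoyment = enj[i, ], effort = eff[i, ], age = age[i, ])
      gen_cfg <- dyad_config(
        dyad_id = tab$dyad_id[i],
        seat_1 = c(-half, 1.2, -half), seat_2 = c(half, 1.2, half),
        schedule = cfg$session_schedule,
        gaze_dynamics = dyn,
        coupling = list(lag_s = 0.5, strength = synchrony_r[i],
                        channel = "head"),
        scores = sc,
        seed = cfg$seed + 1000L + i)
      generate_dyad(gen_cfg)
    })
  }
  list(table = tab,
       truth = list(planted = list(
                      distance_enjoyment_r = cfg$distance_enjoyment_r,
                      eyecontact_effort_r = cfg$eyecontact_effort_r,
                      age_synchrony_r = cfg$age_synchrony_r),
                    latent = latent),
       sessions = sessions)
}

# Flip logicals independently with the given error probability.
flip_with_error <- function(x, error_rate) {
  flips <- runif(length(x)) < error_rate
  xor(x, flips)
}

#' Simulate an annotation panel over ground-truth looking booleans
#'
#' Emits one record per rater for each truth row, flipping each binary
#' answer independently at that rater's error rate.
#'
#' @param truth data.frame with `time_s`, `participant`, `looks_partner`,
#'   `looks_target`.
#' @param error_rates named or positional vector of per-rater error
#'   probabilities; rater ids become `r1`, `r2`, ...
#' @param seed RNG seed.
#' @return records data.frame suitable for [merge_annotations()].
#' @export
simulate_annotation_panel <- function(truth, error_rates = c(0.016, 0.016, 0),
                                      seed = 1) {
  set.seed(seed)
  out <- lapply(seq_along(error_rates), function(i) {
    data.frame(time_s = truth$time_s, rater = paste0("r", i),
               participant = truth$participant,
               looks_partner = flip_with_error(as.logical(truth$looks_partner),
                                               error_rates[i]),
               looks_target = flip_with_error(as.logical(truth$looks_target),
                                              error_rates[i]))
  })
  do.call(rbind, out)
}

#' Agreement rate between the two primary raters
#'
#' Fraction of individual binary ratings (both questions, both
#' participants) on which the first two raters agree.
#'
#' @param records annotation records as produced by
#'   [simulate_annotation_panel()].
#' @return proportion in \[0, 1\].
#' @export
rater_agreement <- function(records) {
  raters <- sort(unique(records$rater))
  stopifnot(length(raters) >= 2L)
  sub <- function(r) {
    s <- records[records$rater == r, ]
    s[order(s$time_s, s$participant), ]
  }
  r1 <- sub(raters[1]); r2 <- sub(raters[2])
  mean(c(r1$looks_partner == r2$looks_partner,
         r1$looks_target == r2$looks_target))
}

#' Annotate a synthetic session from its ground truth
#'
#' Samples random time points per condition and produces simulated rater
#' records (two noisy primary raters plus an error-free tie-breaker) from
#' the generator's true looking booleans.
#'
#' @param generated result of [generate_dyad()].
#' @param n_per_condition annotated samples per condition (default 50,
#'   capped at the available samples with a warning).
#' @param error_rate per-rater, per-question flip probability (default
#'   0.016).
#' @param conditions conditions to annotate (default conversation,
#'   cooperative, competitive).
#' @param seed RNG seed.
#' @return list with `records` (rater annotations), `truth` (the true
#'   booleans and gaze labels at the sampled points).
#' @export
annotate_synthetic <- function(generated, n_per_condition = 50,
                               error_rate = 0.016,
                               conditions = c("conversation", "cooperative",
                                              "competitive"),
                               seed = 1) {
  set.seed(seed)
  st <- generated$truth$states
  cond <- cond_at(st$t, generated$session$annotations)
  rows <- integer(0)
  for (cd in conditions) {
    avail <- which(!is.na(cond) & cond == cd)
    take <- n_per_condition
    if (length(avail) < take) {
      warning("only ", length(avail), " samples available in ", cd)
      take <- length(avail)
    }
    rows <- c(rows, sample(avail, take))
  }
  rows <- sort(rows)
  truth <- rbind(
    data.frame(time_s = st$t[rows], participant = "p1",
               looks_partner = st$p1_partner[rows],
               looks_target = st$p1_target[rows]),
    data.frame(time_s = st$t[rows], participant = "p2",
               looks_partner = st$p2_partner[rows],
               looks_target = st$p2_target[rows]))
  truth <- truth[order(truth$time_s, truth$participant), ]
  records <- simulate_annotation_panel(truth,
                                       error_rates = c(error_rate,
                                                       error_rate, 0),
                                       seed = sample.int(2^30, 1))
  labels <- dyadic_gaze_label(st$p1_partner[rows], st$p1_target[rows],
                              st$p2_partner[rows], st$p2_target[rows])
  list(records = records,
       truth = cbind(truth, condition = rep(cond[rows], 2)),
       labels = data.frame(time_s = st$t[rows], condition = cond[rows],
                           label = labels))
}
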