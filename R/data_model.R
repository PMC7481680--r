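#' @importFrom stats approx sd cor cor.test pf pt pnorm dnorm quantile rnorm
#'   runif complete.cases var fft setNames rbinom predict rexp
#' @importFrom utils head tail
NULL

# Canonical joint set tracked for seated upper-body interaction.
SKELETON_JOINTS <- c("head", "neck", "shoulder_left", "shoulder_right",
                     "spine_shoulder", "hand_dominant")

CONDITIONS <- c("conversation", "practice", "cooperative", "competitive",
                "pause")

GAZE_LEVELS <- c("eye_contact", "joint_attention", "other_oriented", "away")

SCORE_COLS <- c("relatedness", "enjoyment", "choice", "pressure", "effort",
                "acips", "aq", "age")

#' Construct a skeleton stream
#'
#' A skeleton stream holds one participant's time-indexed 3D joint positions
#' (metres) and head orientation (yaw/pitch/roll, degrees) as reported by one
#' sensor, together with a per-sample validity flag marking tracked versus
#' dropped frames.
#'
#' @param participant_id,sensor_id identifiers.
#' @param timestamps strictly increasing numeric vector (seconds).
#' @param joints named list of n x 3 numeric matrices (columns x, y, z in
#'   metres); names drawn from the canonical joint set.
#' @param head_orientation n x 3 matrix with columns `yaw`, `pitch`, `roll`
#'   in degrees.
#' @param validity logical vector, `TRUE` where the frame was tracked.
#' @return an object of class `skeleton_stream`.
#' @export
skeleton_stream <- function(participant_id, sensor_id, timestamps, joints,
                            head_orientation, validity = NULL) {
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (n < 1L) stop("stream must contain at least one sample")
  if (any(diff(timestamps) <= 0)) {
    stop(sprintf("timestamps of stream %s/%s are not strictly increasing",
                 participant_id, sensor_id))
  }
  if (is.null(validity)) validity <- rep(TRUE, n)
  validity <- as.logical(validity)
  stopifnot(length(validity) == n)
  joints <- lapply(joints, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == n, ncol(m) == 3L)
    colnames(m) <- c("x", "y", "z")
    m
  })
  unknown <- setdiff(names(joints), SKELETON_JOINTS)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown joints: %s",
                    paste(unknown, collapse = ", ")))
    joints <- joints[setdiff(names(joints), unknown)]
  }
  ho <- as.matrix(head_orientation)
  stopifnot(nrow(ho) == n, ncol(ho) == 3L)
  colnames(ho) <- c("yaw", "pitch", "roll")
  for (j in names(joints)) {
    if (any(!is.finite(joints[[j]][validity, , drop = FALSE]))) {
      stop(sprintf("non-finite positions in joint '%s' at valid samples", j))
    }
  }
  structure(list(participant_id = as.character(participant_id),
                 sensor_id = as.character(sensor_id),
                 t = timestamps, joints = joints, orient = ho,
                 valid = validity),
            class = "skeleton_stream")
}

#' @export
print.skeleton_stream <- function(x, ...) {
  cat(sprintf("<skeleton_stream %s/%s: %d samples (%.1f%% valid), joints: %s>\n",
              x$participant_id, x$sensor_id, length(x$t),
              100 * mean(x$valid), paste(names(x$joints), collapse = ", ")))
  invisible(x)
}

#' Construct a trial annotation table
#'
#' @param trial_index integer trial numbers.
#' @param condition condition labels (conversation, practice, cooperative,
#'   competitive, pause).
#' @param start_s,end_s trial boundaries in seconds.
#' @return a validated `data.frame` of class `trial_annotations`.
#' @export
trial_annotations <- function(trial_index, condition, start_s, end_s) {
  df <- data.frame(trial_index = as.integer(trial_index),
                   condition = as.character(condition),
                   start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   stringsAsFactors = FALSE)
  bad <- setdiff(df$condition, CONDITIONS)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (any(df$start_s >= df$end_s)) stop("trial start must precede end")
  if (nrow(df) > 1L) {
    o <- order(df$start_s)
    so <- df[o, ]
    if (any(so$start_s[-1] < so$end_s[-nrow(so)])) {
      stop("trials overlap within the session")
    }
  }
  if (anyDuplicated(df$trial_index)) stop("duplicate trial_index")
  class(df) <- c("trial_annotations", "data.frame")
  df
}

#' Construct a subject-scores table
#'
#' One row per participant with intrinsic-motivation subscale means
#' (relatedness, enjoyment, choice, pressure, effort on a 1-7 scale), ACIPS
#' and AQ totals, and age. Missing scores are `NA` and are excluded from
#' correlations downstream.
#'
#' @param participant_id identifiers.
#' @param ... named numeric vectors among the known score columns.
#' @return data.frame of class `subject_scores`.
#' @export
subject_scores <- function(participant_id, ...) {
  sc <- list(...)
  df <- data.frame(participant_id = as.character(participant_id),
                   stringsAsFactors = FALSE)
  for (col in SCORE_COLS) {
    df[[col]] <- if (col %in% names(sc)) as.numeric(sc[[col]]) else NA_real_
  }
  subscales <- c("relatedness", "enjoyment", "choice", "pressure", "effort")
  for (col in subscales) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 1 | v > 7))) {
      stop(sprintf("subscale '%s' outside instrument range [1, 7]", col))
    }
  }
  class(df) <- c("subject_scores", "data.frame")
  df
}

#' Construct a dyad session
#'
#' Container for one dyad: per-participant, per-sensor skeleton streams,
#' trial annotations and subject scores.
#'
#' @param dyad_id identifier.
#' @param streams named list (by participant) of named lists (by sensor) of
#'   [skeleton_stream()] objects; exactly two participants, at least one
#'   stream each.
#' @param annotations a [trial_annotations()] table.
#' @param scores a [subject_scores()] table (optional).
#' @param native_rate nominal sensor sampling rate in Hz (metadata).
#' @return object of class `dyad_session`.
#' @export
dyad_session <- function(dyad_id, streams, annotations, scores = NULL,
                         native_rate = NA_real_) {
  if (length(streams) != 2L) stop("a dyad session has exactly two participants")
  if (is.null(names(streams)) || any(names(streams) == "")) {
    stop("streams must be named by participant")
  }
  for (p in names(streams)) {
    if (!length(streams[[p]])) stop("participant ", p, " has no streams")
    for (s in names(streams[[p]])) {
      st <- streams[[p]][[s]]
      stopifnot(inherits(st, "skeleton_stream"))
    }
  }
  stopifnot(inherits(annotations, "trial_annotations"))
  if (!is.null(scores)) stopifnot(inherits(scores, "subject_scores"))
  structure(list(dyad_id = as.character(dyad_id), streams = streams,
                 annotations = annotations, scores = scores,
                 native_rate = native_rate),
            class = "dyad_session")
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf("<dyad_session %s: participants %s; %d trials; scores: %s>\n",
              x$dyad_id, paste(names(x$streams), collapse = ", "),
              nrow(x$annotations),
              if (is.null(x$scores)) "none" else "present"))
  invisible(x)
}

#' List participant identifiers of a session
#' @param session a `dyad_session`.
#' @return character vector of length two.
#' @export
participants <- function(session) names(session$streams)

# Wrap degrees to (-180, 180].
wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Unwrap a degree series so that consecutive differences are in (-180, 180].
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- wrap_deg(diff(x))
  cumsum(c(x[1], d))
}
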