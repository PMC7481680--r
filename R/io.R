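#' Write a dyad session to a session directory
#'
#' The session dialect is a directory holding one long-format CSV per sensor
#' per participant (`stream_<participant>__<sensor>.csv` with columns
#' `time_s,joint,x_m,y_m,z_m,yaw_deg,pitch_deg,roll_deg,valid`), a
#' `trials.csv` (`trial_index,condition,start_s,end_s`), a `scores.csv`
#' (`participant_id` plus score columns) and a `meta.csv` with dyad id and
#' native sampling rate. Head orientation is repeated on every joint row of
#' a time point.
#'
#' @param session a [dyad_session()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "dyad_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)
  for (p in names(session$streams)) {
    for (s in names(session$streams[[p]])) {
      st <- session$streams[[p]][[s]]
      rows <- lapply(names(st$joints), function(j) {
        data.table::data.table(
          time_s = st$t, joint = j,
          x_m = st$joints[[j]][, 1], y_m = st$joints[[j]][, 2],
          z_m = st$joints[[j]][, 3],
          yaw_deg = st$orient[, 1], pitch_deg = st$orient[, 2],
          roll_deg = st$orient[, 3], valid = as.integer(st$valid))
      })
      dt <- data.table::rbindlist(rows)
      data.table::setorder(dt, time_s, joint)
      data.table::fwrite(dt, file.path(path,
        sprintf("stream_%s__%s.csv", p, s)))
    }
  }
  data.table::fwrite(as.data.frame(session$annotations),
                     file.path(path, "trials.csv"))
  if (!is.null(session$scores)) {
    data.table::fwrite(as.data.frame(session$scores),
                       file.path(path, "scores.csv"))
  }
  meta <- data.frame(key = c("dyad_id", "native_rate"),
                     value = c(session$dyad_id,
                               as.character(session$native_rate)))
  data.table::fwrite(meta, file.path(path, "meta.csv"))
  invisible(path)
}

#' Read a dyad session from a session directory
#'
#' Inverse of [write_session()]. Rows are sorted by timestamp so shuffled
#' files read back identically; unknown joints are dropped with a warning;
#' missing mandatory columns raise a format error and non-monotone
#' timestamps a data error naming the offending stream.
#'
#' @param path session directory.
#' @return a [dyad_session()].
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no session directory at ", path)
  meta_f <- file.path(path, "meta.csv")
  meta <- if (file.exists(meta_f)) {
    m <- data.table::fread(meta_f, colClasses = "character")
    setNames(m$value, m$key)
  } else c(dyad_id = basename(path), native_rate = NA)
  stream_files <- list.files(path, pattern = "^stream_.*\\.csv$",
                             full.names = TRUE)
  if (!length(stream_files)) stop("no stream files in ", path)
  needed <- c("time_s", "joint", "x_m", "y_m", "z_m",
              "yaw_deg", "pitch_deg", "roll_deg", "valid")
  streams <- list()
  for (f in stream_files) {
    ids <- sub("^stream_", "", sub("\\.csv$", "", basename(f)))
    parts <- strsplit(ids, "__", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed stream filename: ", basename(f))
    dt <- data.table::fread(f)
    miss <- setdiff(needed, names(dt))
    if (length(miss)) {
      stop(sprintf("format error in %s: missing column(s) %s",
                   basename(f), paste(miss, collapse = ", ")))
    }
    data.table::setorder(dt, time_s, joint)
    times <- sort(unique(dt$time_s))
    if (anyDuplicated(times)) {
      stop("non-monotone timestamps in stream ", ids)
    }
    joints <- list()
    orient <- NULL
    validity <- NULL
    for (j in unique(dt$joint)) {
      sub <- dt[dt$joint == j, ]
      if (nrow(sub) != length(times) || any(sub$time_s != times)) {
        stop(sprintf("data error in stream %s: joint '%s' does not cover ",
                     ids, j), "every time point exactly once")
      }
      joints[[j]] <- cbind(x = sub$x_m, y = sub$y_m, z = sub$z_m)
      if (is.null(orient)) {
        orient <- cbind(yaw = sub$yaw_deg, pitch = sub$pitch_deg,
                        roll = sub$roll_deg)
        validity <- as.logical(sub$valid)
      }
    }
    if (!"head" %in% names(joints)) {
      stop(sprintf("format error in stream %s: mandatory joint 'head' absent",
                   ids))
    }
    streams[[parts[1]]][[parts[2]]] <-
      skeleton_stream(parts[1], parts[2], times, joints, orient, validity)
  }
  trials_f <- file.path(path, "trials.csv")
  if (!file.exists(trials_f)) stop("format error: trials.csv absent")
  tr <- data.table::fread(trials_f)
  ann <- if (nrow(tr)) {
    trial_annotations(tr$trial_index, tr$condition, tr$start_s, tr$end_s)
  } else trial_annotations(integer(), character(), numeric(), numeric())
  scores <- NULL
  scores_f <- file.path(path, "scores.csv")
  if (file.exists(scores_f)) {
    sc <- as.data.frame(data.table::fread(scores_f))
    args <- c(list(participant_id = sc$participant_id),
              as.list(sc[intersect(SCORE_COLS, names(sc))]))
    scores <- do.call(subject_scores, args)
  }
  dyad_session(meta[["dyad_id"]], streams, ann, scores,
               native_rate = suppressWarnings(as.numeric(meta[["native_rate"]])))
}
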