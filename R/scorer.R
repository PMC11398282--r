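#' Scorer configuration
#'
#' Thresholds and time limits of the drowsiness evaluator. The defaults are
#' the algorithm's standard operating values: gaze limit 0.4; head-pose
#' limits pitch 180, yaw 30, roll 20 degrees; sustained-condition times of
#' 3 s (eyes closed), 3 s (mouth open), 4 s (off-centre gaze) and 6 s
#' (off-centre head); PERCLOS limit 0.2 (20%, i.e. 12 s of closure) over a
#' 60 s window. `ear_thresh` and `mar_thresh` are personalised by
#' calibration and therefore default to `NA` until set (or merged from a
#' `drowsiness_calibration` via [apply_calibration()]).
#'
#' Note that with the default `pitch_thresh = 180` the pitch axis can never
#' trigger the head-distraction alarm, since |pitch| <= 180 always; the
#' pitch axis is effectively disabled unless the limit is lowered.
#'
#' @param ear_thresh EAR below which the eyes count as closed.
#' @param mar_thresh MAR above which the mouth counts as wide open.
#' @param gaze_thresh gaze score above which the gaze is off centre.
#' @param pitch_thresh,yaw_thresh,roll_thresh head-angle limits in degrees.
#' @param ear_time_thresh,mar_time_thresh,gaze_time_thresh,pose_time_thresh
#'   seconds a condition must hold continuously before its alarm raises.
#' @param perclos_thresh fraction of a window spent closed above which the
#'   drowsy alarm raises.
#' @param perclos_time_period PERCLOS window length in seconds.
#' @param capture_fps frame rate; the per-frame time step is
#'   `1 / capture_fps`.
#' @return list of class `scorer_config` (includes the derived
#'   `delta_time_frame`).
#' @export
scorer_config <- function(ear_thresh = NA_real_, mar_thresh = NA_real_,
                          gaze_thresh = 0.4, pitch_thresh = 180,
                          yaw_thresh = 30, roll_thresh = 20,
                          ear_time_thresh = 3, mar_time_thresh = 3,
                          gaze_time_thresh = 4, pose_time_thresh = 6,
                          perclos_thresh = 0.2, perclos_time_period = 60,
                          capture_fps = 4) {
  stopifnot(capture_fps > 0, perclos_time_period > 0)
  structure(
    list(ear_thresh = ear_thresh, mar_thresh = mar_thresh,
         gaze_thresh = gaze_thresh, pitch_thresh = pitch_thresh,
         yaw_thresh = yaw_thresh, roll_thresh = roll_thresh,
         ear_time_thresh = ear_time_thresh,
         mar_time_thresh = mar_time_thresh,
         gaze_time_thresh = gaze_time_thresh,
         pose_time_thresh = pose_time_thresh,
         perclos_thresh = perclos_thresh,
         perclos_time_period = perclos_time_period,
         capture_fps = capture_fps,
         delta_time_frame = 1 / capture_fps),
    class = "scorer_config"
  )
}

#' Merge calibrated thresholds into a scorer configuration
#' @param cfg a [scorer_config()].
#' @param calib a `drowsiness_calibration` from [run_calibration()].
#' @return the configuration with `ear_thresh` and `mar_thresh` set.
#' @export
apply_calibration <- function(cfg, calib) {
  stopifnot(inherits(cfg, "scorer_config"),
            inherits(calib, "drowsiness_calibration"))
  cfg$ear_thresh <- calib$ear_thresh
  cfg$mar_thresh <- calib$mar_thresh
  cfg
}

#' Fresh PERCLOS accumulator state
#'
#' Holds the frame counter of the current window, the completed per-window
#' percentages, and the window origin. Windows are anchored at `start` and
#' advance by exactly one period when completed.
#'
#' @param start session time origin in seconds.
#' @return list of class `perclos_state`.
#' @export
perclos_state <- function(start = 0) {
  structure(
    list(prev_time = start, eye_closure_counter = 0L,
         minute_scores = numeric(), current_window_start = start),
    class = "perclos_state"
  )
}

#' Advance the PERCLOS accumulator by one frame
#'
#' Counts the frame as closed when `ear < cfg$ear_thresh` (a non-finite EAR
#' -- no valid face -- never counts as closed). When a full window has
#' elapsed, emits that window's percentage
#' `eye_closure_counter * delta_time_frame / perclos_time_period * 100`,
#' appends it to `minute_scores`, and resets counter and window. The frame
#' that completes a window is counted in the following window.
#'
#' @param state a [perclos_state()].
#' @param ear the frame's EAR value (may be `NA`).
#' @param t frame timestamp in seconds (non-decreasing).
#' @param cfg a [scorer_config()] with a finite `ear_thresh`.
#' @return list with the updated `state` and `minute_score` (the emitted
#'   percentage, or `NULL` when no window completed).
#' @export
update_perclos <- function(state, ear, t, cfg) {
  stopifnot(t >= state$prev_time - 1e-9)
  emitted <- NULL
  while (t - state$current_window_start >= cfg$perclos_time_period) {
    score <- state$eye_closure_counter * cfg$delta_time_frame /
      cfg$perclos_time_period * 100
    state$minute_scores <- c(state$minute_scores, score)
    if (is.null(emitted)) emitted <- score
    state$eye_closure_counter <- 0L
    state$current_window_start <-
      state$current_window_start + cfg$perclos_time_period
  }
  if (is.finite(ear) && is.finite(cfg$ear_thresh) && ear < cfg$ear_thresh) {
    state$eye_closure_counter <- state$eye_closure_counter + 1L
  }
  state$prev_time <- t
  list(state = state, minute_score = emitted)
}

#' Global PERCLOS over a session
#'
#' Arithmetic mean of the completed per-window percentages. A partial final
#' window is deliberately excluded (it is reported separately in the session
#' summary).
#'
#' @param state a [perclos_state()] after processing a stream.
#' @return percentage in `[0, 100]`.
#' @export
global_perclos <- function(state) {
  if (length(state$minute_scores) == 0L) {
    stop(structure(
      class = c("perclos_undefined_score", "error", "condition"),
      list(message = "no completed PERCLOS window yet", call = sys.call())
    ))
  }
  mean(state$minute_scores)
}

# ---- alarm state machine -------------------------------------------------

new_attention_state <- function(cfg, start = 0) {
  list(run_start = c(eye = NA_real_, mouth = NA_real_, pose = NA_real_,
                     gaze = NA_real_),
       perclos = perclos_state(start),
       drowsy = FALSE)
}

# one frame of the alarm evaluator; row is a single-row list/data.frame with
# the score_stream columns
update_attention <- function(state, row, cfg) {
  pc <- update_perclos(state$perclos, if (isTRUE(row$valid_face)) row$ear
                       else NA_real_, row$t, cfg)
  state$perclos <- pc$state
  if (!is.null(pc$minute_score)) {
    state$drowsy <- pc$minute_score > cfg$perclos_thresh * 100
  }

  conds <- c(
    eye = isTRUE(row$valid_face) && is.finite(row$ear) &&
      row$ear < cfg$ear_thresh,
    mouth = isTRUE(row$valid_face) && is.finite(row$mar) &&
      row$mar > cfg$mar_thresh,
    pose = isTRUE(row$valid_pose) &&
      (abs(row$roll) > cfg$roll_thresh || abs(row$yaw) > cfg$yaw_thresh ||
         abs(row$pitch) > cfg$pitch_thresh),
    gaze = isTRUE(row$valid_gaze) && is.finite(row$gaze) &&
      row$gaze > cfg$gaze_thresh
  )
  tt <- c(eye = cfg$ear_time_thresh, mouth = cfg$mar_time_thresh,
          pose = cfg$pose_time_thresh, gaze = cfg$gaze_time_thresh)
  sustained <- c(eye = FALSE, mouth = FALSE, pose = FALSE, gaze = FALSE)
  for (k in names(conds)) {
    if (conds[[k]]) {
      if (is.na(state$run_start[[k]])) state$run_start[[k]] <- row$t
      sustained[[k]] <- (row$t - state$run_start[[k]]) >= tt[[k]] - 1e-9
    } else {
      state$run_start[[k]] <- NA_real_
    }
  }
  distracted <- sustained[["pose"]]
  flags <- list(
    asleep = sustained[["eye"]],
    yawning = sustained[["mouth"]],
    distracted = distracted,
    gaze_distracted = sustained[["gaze"]] && !distracted,
    drowsy = state$drowsy
  )
  list(state = state, flags = flags,
       minute_score = pc$minute_score,
       perclos_current = state$perclos$eye_closure_counter *
         cfg$delta_time_frame / cfg$perclos_time_period * 100)
}

#' Evaluate alarms over a scored indicator stream
#'
#' Runs the temporal alarm evaluator frame by frame. An alarm raises when
#' its condition has held continuously for at least its time threshold:
#' `asleep` (EAR below threshold), `yawning` (MAR above threshold),
#' `distracted` (any head Euler angle beyond its limit),
#' `gaze_distracted` (gaze score above threshold while the head is *not*
#' distracted), and `drowsy` (latest completed PERCLOS window above the
#' limit). Flags clear as soon as their condition breaks and re-raise only
#' after a fresh continuous run. Frames whose validity flags are `FALSE`
#' break the corresponding runs: missing data never creates an alarm.
#'
#' @param scores data.frame from [score_stream()], time-ordered.
#' @param cfg a [scorer_config()] with calibrated `ear_thresh`/`mar_thresh`.
#' @param start session time origin for the PERCLOS windows (default: first
#'   frame time floor, 0 for streams starting at 0).
#' @return list with `flags` (data.frame: `t`, the five alarm booleans,
#'   `perclos_current`, `minute_score`), and the final `perclos` state.
#' @export
score_alarms <- function(scores, cfg, start = 0) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0L,
            !is.unsorted(scores$t, strictly = TRUE))
  if (!is.finite(cfg$ear_thresh) || !is.finite(cfg$mar_thresh)) {
    stop("`cfg` must carry calibrated ear/mar thresholds; ",
         "see apply_calibration()")
  }
  n <- nrow(scores)
  st <- new_attention_state(cfg, start)
  out <- data.frame(
    t = scores$t, asleep = logical(n), yawning = logical(n),
    distracted = logical(n), gaze_distracted = logical(n),
    drowsy = logical(n), perclos_current = numeric(n),
    minute_score = NA_real_
  )
  cols <- as.list(scores)  # avoid data.frame row extraction in the loop
  for (i in seq_len(n)) {
    row <- list(t = cols$t[i], ear = cols$ear[i], mar = cols$mar[i],
                gaze = cols$gaze[i], roll = cols$roll[i],
                pitch = cols$pitch[i], yaw = cols$yaw[i],
                valid_face = cols$valid_face[i],
                valid_gaze = cols$valid_gaze[i],
                valid_pose = cols$valid_pose[i])
    up <- update_attention(st, row, cfg)
    st <- up$state
    out$asleep[i] <- up$flags$asleep
    out$yawning[i] <- up$flags$yawning
    out$distracted[i] <- up$flags$distracted
    out$gaze_distracted[i] <- up$flags$gaze_distracted
    out$drowsy[i] <- up$flags$drowsy
    out$perclos_current[i] <- up$perclos_current
    if (!is.null(up$minute_score)) out$minute_score[i] <- up$minute_score
  }
  list(flags = out, perclos = st$perclos)
}

#' Alarm flags at the end of a history
#'
#' Convenience wrapper over [score_alarms()] returning only the flag state
#' after the final frame.
#'
#' @inheritParams score_alarms
#' @param history data.frame of time-ordered indicator scores.
#' @return named logical vector of the five alarms.
#' @export
evaluate_alarms <- function(history, cfg, start = 0) {
  res <- score_alarms(history, cfg, start)
  last <- res$flags[nrow(res$flags), ]
  c(asleep = last$asleep, yawning = last$yawning,
    distracted = last$distracted, gaze_distracted = last$gaze_distracted,
    drowsy = last$drowsy)
}

#' Extract alarm events from per-frame flags
#'
#' Converts the level-triggered flag series into discrete events: one event
#' per maximal run of `TRUE`, with onset at the first flagged frame and
#' duration spanning the run (one frame period for a single-frame run).
#'
#' @param flags data.frame from [score_alarms()]`$flags`.
#' @param delta_time_frame frame period in seconds.
#' @return data.frame with columns `kind`, `onset`, `duration`.
#' @export
alarm_events <- function(flags, delta_time_frame) {
  kinds <- c("asleep", "yawning", "distracted", "gaze_distracted", "drowsy")
  ev <- lapply(kinds, function(k) {
    r <- rle(flags[[k]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (length(on) == 0L) return(NULL)
    data.frame(
      kind = k,
      onset = flags$t[starts[on]],
      duration = flags$t[ends[on]] - flags$t[starts[on]] + delta_time_frame
    )
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev)) {
    ev <- data.frame(kind = character(), onset = numeric(),
                     duration = numeric())
  }
  ev[order(ev$onset, ev$kind), , drop = FALSE]
}

#' Detection bookkeeping
#'
#' Counts of processed frames and which detector found the face, used for
#' the session's detection-rate percentages.
#'
#' @param frames_total,detected_by_gradient,detected_by_cascade counts.
#' @return list of class `detection_stats` (with `frames_detected`).
#' @export
detection_stats <- function(frames_total = 0L, detected_by_gradient = 0L,
                            detected_by_cascade = 0L) {
  s <- list(frames_total = as.integer(frames_total),
            detected_by_gradient = as.integer(detected_by_gradient),
            detected_by_cascade = as.integer(detected_by_cascade))
  s$frames_detected <- s$detected_by_gradient + s$detected_by_cascade
  stopifnot(s$frames_detected <= s$frames_total)
  structure(s, class = "detection_stats")
}

# detection stats recounted from a stream / log's per-frame detector tags
count_detection <- function(detector_tags) {
  detection_stats(
    frames_total = length(detector_tags),
    detected_by_gradient = sum(detector_tags == "gradient"),
    detected_by_cascade = sum(detector_tags == "cascade")
  )
}

#' Summarise a scored session
#'
#' Builds the session report: calibration echo, per-window and global
#' PERCLOS (plus the partial final window, which is excluded from the
#' global average), alarm activation counts and the event list, and
#' detection-rate percentages.
#'
#' @param events data.frame from [alarm_events()].
#' @param state final [perclos_state()].
#' @param detection a [detection_stats()].
#' @param calibration optional `drowsiness_calibration` to embed.
#' @param cfg the [scorer_config()] used.
#' @return list of class `session_report`.
#' @export
summarize_session <- function(events, state, detection, calibration = NULL,
                              cfg = scorer_config()) {
  kinds <- c("asleep", "yawning", "distracted", "gaze_distracted", "drowsy")
  counts <- vapply(kinds, function(k) sum(events$kind == k), integer(1))
  partial_elapsed <- (state$prev_time - state$current_window_start) +
    cfg$delta_time_frame
  structure(
    list(
      calibration = calibration,
      perclos = list(
        per_minute = state$minute_scores,
        global = if (length(state$minute_scores)) {
          global_perclos(state)
        } else NA_real_,
        partial = list(
          elapsed = max(0, partial_elapsed),
          score = state$eye_closure_counter * cfg$delta_time_frame /
            cfg$perclos_time_period * 100
        )
      ),
      alarms = list(counts = as.list(counts), events = events),
      detection = list(
        face_rate = 100 * detection$frames_detected /
          max(1L, detection$frames_total),
        gradient_share = 100 * detection$detected_by_gradient /
          max(1L, detection$frames_detected),
        cascade_share = 100 * detection$detected_by_cascade /
          max(1L, detection$frames_detected)
      )
    ),
    class = "session_report"
  )
}

#' @export
print.session_report <- function(x, ...) {
  cat("Session report\n")
  if (length(x$perclos$per_minute)) {
    cat(sprintf("  PERCLOS: global %.2f%% over %d window(s) [%s]\n",
                x$perclos$global, length(x$perclos$per_minute),
                paste(sprintf("%.1f", x$perclos$per_minute),
                      collapse = ", ")))
  } else {
    cat("  PERCLOS: no completed window\n")
  }
  cat("  Alarms:",
      paste(sprintf("%s=%d", names(x$alarms$counts),
                    unlist(x$alarms$counts)), collapse = " "), "\n")
  cat(sprintf("  Face detection %.1f%% (gradient %.1f%%, cascade %.1f%%)\n",
              x$detection$face_rate, x$detection$gradient_share,
              x$detection$cascade_share))
  invisible(x)
}
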