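#' Run a full drowsiness-monitoring session
#'
#' The end-to-end pipeline: a landmark stream is scored frame by frame
#' (EAR, MAR, gaze, head pose), the first seconds personalise the EAR/MAR
#' thresholds, and the calibrated temporal evaluator accumulates PERCLOS
#' and raises the five alarms. Replaying the same saved stream is
#' bit-deterministic.
#'
#' @param source a `landmark_stream`, an [event_schedule()] (rendered on
#'   the fly), or a path to a landmark-stream file
#'   (see [read_landmark_stream()]).
#' @param config a [scorer_config()]; its `ear_thresh`/`mar_thresh` are
#'   overwritten by the calibration result.
#' @param calibration_duration initialisation window in seconds (default
#'   5; the subject is asked to hold the mouth open during it).
#' @param cam [camera_model()] used for head pose. The default matches the
#'   synthetic generator; set it from the image size for real footage.
#' @param mar_variant passed to the MAR computation.
#' @param log_path optional path for the frame log (CSV, self-describing
#'   header).
#' @param report_path optional path for the session report (JSON).
#' @return object of class `drowsiness_session` with fields `frame_log`,
#'   `report`, `calibration`, `config`, `scores`.
#' @export
run_session <- function(source, config = scorer_config(),
                        calibration_duration = 5, cam = camera_model(),
                        mar_variant = "symmetric", log_path = NULL,
                        report_path = NULL) {
  stream <- resolve_source(source)
  scores <- score_stream(stream, cam = cam, mar_variant = mar_variant)
  calib <- run_calibration(scores, duration = calibration_duration)
  cfg <- apply_calibration(config, calib)
  al <- score_alarms(scores, cfg, start = floor(scores$t[1]))
  events <- alarm_events(al$flags, cfg$delta_time_frame)
  stats <- count_detection(stream$detector)
  report <- summarize_session(events, al$perclos, stats, calib, cfg)

  frame_log <- data.frame(
    frame = seq_len(nrow(scores)) - 1L,
    scores[, c("t", "ear", "mar", "gaze", "roll", "pitch", "yaw")],
    perclos_current = al$flags$perclos_current,
    al$flags[, c("asleep", "yawning", "distracted", "gaze_distracted",
                 "drowsy")],
    scores[, c("valid_face", "valid_gaze", "valid_pose", "detector")]
  )

  out <- structure(
    list(frame_log = frame_log, report = report, calibration = calib,
         config = cfg, scores = scores),
    class = "drowsiness_session"
  )
  if (!is.null(log_path)) write_frame_log(out, log_path)
  if (!is.null(report_path)) write_session_report(report, report_path)
  out
}

resolve_source <- function(source) {
  if (inherits(source, "landmark_stream")) return(source)
  if (inherits(source, "event_schedule")) return(render_stream(source))
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) {
      stop(structure(
        class = c("perclos_io_error", "error", "condition"),
        list(message = paste0("cannot read source: ", source),
             call = sys.call(-1))
      ))
    }
    return(read_landmark_stream(source))
  }
  stop("`source` must be a landmark_stream, an event_schedule, or a path")
}

#' Write the frame log
#'
#' CSV with one record per processed frame, preceded by commented header
#' lines (`#config` / `#calibration` JSON) so a log replays without
#' external context.
#'
#' @param session a `drowsiness_session`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_log <- function(session, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#config ", jsonlite::toJSON(
    unclass(session$config), auto_unbox = TRUE, digits = NA)), con)
  writeLines(paste0("#calibration ", jsonlite::toJSON(
    unclass(session$calibration), auto_unbox = TRUE, digits = NA,
    null = "null")), con)
  utils::write.csv(session$frame_log, con, row.names = FALSE)
  invisible(path)
}

#' Read a frame log written by [write_frame_log()]
#'
#' @param path log path.
#' @return list with `frames` (data.frame), `config` (a [scorer_config()]
#'   or `NULL`) and `calibration`.
#' @export
read_frame_log <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list(config = NULL, calibration = NULL)
  for (i in hdr) {
    if (startsWith(lines[i], "#config ")) {
      v <- jsonlite::fromJSON(sub("^#config ", "", lines[i]))
      meta$config <- do.call(scorer_config,
                             v[setdiff(names(v), "delta_time_frame")])
      meta$config$ear_thresh <- v$ear_thresh %||% NA_real_
      meta$config$mar_thresh <- v$mar_thresh %||% NA_real_
    } else if (startsWith(lines[i], "#calibration ")) {
      v <- jsonlite::fromJSON(sub("^#calibration ", "", lines[i]))
      meta$calibration <- compute_thresholds(
        v$ear_mean, if (isTRUE(v$mar_from_default)) NULL else v$mar_mean,
        duration = v$duration
      )
    }
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  frames <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e) stop("malformed frame log: ", conditionMessage(e))
  )
  needed <- c("t", "ear", "mar", "gaze", "roll", "pitch", "yaw",
              "valid_face", "valid_gaze", "valid_pose")
  miss <- setdiff(needed, names(frames))
  if (length(miss)) {
    stop("malformed frame log (line ", length(hdr) + 1L,
         "): missing columns ", paste(miss, collapse = ", "))
  }
  if (is.unsorted(frames$t, strictly = TRUE)) {
    bad <- which(diff(frames$t) <= 0)[1] + 1L
    stop("malformed frame log (line ", length(hdr) + 1L + bad,
         "): timestamps not strictly increasing")
  }
  meta$frames <- frames
  meta
}

#' Re-score a saved frame log
#'
#' Recomputes PERCLOS and the alarms from the logged indicator values,
#' optionally under different thresholds, without touching any video or
#' landmark source. Replaying under the original configuration reproduces
#' the original report exactly; lowering a threshold can only add alarm
#' time.
#'
#' @param log path to a frame log, or the list from [read_frame_log()].
#' @param config optional [scorer_config()] overriding the one embedded in
#'   the log.
#' @return a `drowsiness_session` (with `calibration` taken from the log).
#' @export
replay_log <- function(log, config = NULL) {
  meta <- if (is.character(log)) read_frame_log(log) else log
  cfg <- config %||% meta$config
  if (is.null(cfg)) stop("no configuration embedded in the log; supply one")
  if ((!is.finite(cfg$ear_thresh) || !is.finite(cfg$mar_thresh)) &&
      !is.null(meta$calibration)) {
    cfg <- apply_calibration(cfg, meta$calibration)
  }
  scores <- meta$frames
  if (!"detector" %in% names(scores)) scores$detector <- "gradient"
  al <- score_alarms(scores, cfg, start = floor(scores$t[1]))
  events <- alarm_events(al$flags, cfg$delta_time_frame)
  stats <- count_detection(scores$detector)
  report <- summarize_session(events, al$perclos, stats, meta$calibration,
                              cfg)
  frame_log <- data.frame(
    frame = seq_len(nrow(scores)) - 1L,
    scores[, c("t", "ear", "mar", "gaze", "roll", "pitch", "yaw")],
    perclos_current = al$flags$perclos_current,
    al$flags[, c("asleep", "yawning", "distracted", "gaze_distracted",
                 "drowsy")],
    scores[, c("valid_face", "valid_gaze", "valid_pose", "detector")]
  )
  structure(
    list(frame_log = frame_log, report = report,
         calibration = meta$calibration, config = cfg,
         scores = scores),
    class = "drowsiness_session"
  )
}

#' Write a session report as JSON
#' @param report a `session_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session_report <- function(report, path) {
  x <- unclass(report)
  if (!is.null(x$calibration)) x$calibration <- unclass(x$calibration)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @export
print.drowsiness_session <- function(x, ...) {
  n <- nrow(x$frame_log)
  cat(sprintf("drowsiness_session: %d frames (%.1f s at %g fps)\n",
              n, diff(range(x$frame_log$t)) + x$config$delta_time_frame,
              x$config$capture_fps))
  if (!is.null(x$calibration)) {
    cat(sprintf("  thresholds: EAR < %.3f%s, MAR > %.3f%s\n",
                x$config$ear_thresh, "", x$config$mar_thresh,
                if (isTRUE(x$calibration$mar_from_default)) {
                  " (default)"
                } else ""))
  }
  print(x$report)
  invisible(x)
}

#' @export
summary.drowsiness_session <- function(object, ...) object$report

#' Plot the indicator traces and alarms of a session
#'
#' Three stacked panels: EAR with its calibrated threshold and asleep-alarm
#' shading, MAR with its threshold and yawning shading, and the per-minute
#' PERCLOS against the drowsiness limit.
#'
#' @param x a `drowsiness_session`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.drowsiness_session <- function(x, ...) {
  fl <- x$frame_log
  cfg <- x$config
  old <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))

  shade <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      graphics::rect(fl$t[starts[k]], graphics::par("usr")[3],
                     fl$t[ends[k]], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("red", 0.2), border = NA)
    }
  }
  plot(fl$t, fl$ear, type = "l", xlab = "", ylab = "EAR", main = "")
  graphics::abline(h = cfg$ear_thresh, lty = 2)
  shade(fl$asleep)
  plot(fl$t, fl$mar, type = "l", xlab = "", ylab = "MAR")
  graphics::abline(h = cfg$mar_thresh, lty = 2)
  shade(fl$yawning)
  pm <- x$report$perclos$per_minute
  if (length(pm)) {
    graphics::barplot(pm, names.arg = seq_along(pm),
                      xlab = "minute", ylab = "PERCLOS (%)")
    graphics::abline(h = cfg$perclos_thresh * 100, lty = 2)
  } else {
    plot.new()
    graphics::text(0.5, 0.5, "no completed PERCLOS window")
  }
  invisible(x)
}
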