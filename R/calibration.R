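#' Personalised EAR and MAR thresholds from calibration means
#'
#' Eye and mouth apertures are strongly person-dependent, so the alarm
#' thresholds are derived from a short initialisation routine rather than
#' fixed: the eye-closure threshold is three quarters of the subject's mean
#' EAR, and the wide-open-mouth threshold is half the mean MAR measured
#' while the subject holds the mouth open. When no usable mouth-open MAR is
#' available (e.g. replaying a recording where the routine was skipped) the
#' population default threshold 0.35 is used and flagged.
#'
#' @param ear_mean mean EAR over the calibration window (> 0).
#' @param mar_mean mean MAR over the calibration window, or `NULL` when the
#'   mouth was not held open.
#' @param duration calibration window length in seconds (metadata only).
#' @return object of class `drowsiness_calibration` with fields `ear_mean`,
#'   `mar_mean`, `ear_thresh` (= 0.75 * ear_mean), `mar_thresh`
#'   (= 0.5 * mar_mean, or 0.35), `mar_from_default`, `duration`.
#' @examples
#' compute_thresholds(0.28, 0.80)  # thresholds 0.21 and 0.40
#' @export
compute_thresholds <- function(ear_mean, mar_mean = NULL, duration = 5) {
  if (!is.numeric(ear_mean) || length(ear_mean) != 1L ||
      !is.finite(ear_mean) || ear_mean <= 0) {
    stop_calibration("ear_mean must be a single positive number")
  }
  if (!is.null(mar_mean) &&
      (!is.numeric(mar_mean) || length(mar_mean) != 1L ||
       !is.finite(mar_mean) || mar_mean <= 0)) {
    stop_calibration("mar_mean must be a single positive number when present")
  }
  mar_from_default <- is.null(mar_mean)
  structure(
    list(
      ear_mean = ear_mean,
      mar_mean = if (!mar_from_default) mar_mean,
      ear_thresh = ear_mean * 3 / 4,
      mar_thresh = if (mar_from_default) 0.35 else mar_mean / 2,
      mar_from_default = mar_from_default,
      duration = duration
    ),
    class = "drowsiness_calibration"
  )
}

#' Run the initialisation routine on scored frames
#'
#' Averages valid EAR and MAR over the first `duration` seconds of a scored
#' stream (the subject is asked to keep the mouth as open as possible during
#' this window) and derives the personalised thresholds via
#' [compute_thresholds()]. If the observed MAR never exceeds the 0.35
#' default during the window, the mouth is taken as not held open and the
#' MAR threshold falls back to 0.35.
#'
#' @param scores data.frame of per-frame indicators as produced by
#'   [score_stream()] (columns `t`, `ear`, `mar`, `valid_face`).
#' @param duration calibration window in seconds (default 5).
#' @return a `drowsiness_calibration` object.
#' @export
run_calibration <- function(scores, duration = 5) {
  stopifnot(is.data.frame(scores))
  if (nrow(scores) == 0L) stop_calibration("empty indicator stream")
  t0 <- scores$t[1]
  win <- scores[scores$t < t0 + duration & scores$valid_face, , drop = FALSE]
  win <- win[is.finite(win$ear) & is.finite(win$mar), , drop = FALSE]
  if (nrow(win) == 0L) {
    stop_calibration("no valid frames in the calibration window")
  }
  ear_mean <- mean(win$ear)
  mouth_opened <- max(win$mar) > 0.35
  compute_thresholds(
    ear_mean = ear_mean,
    mar_mean = if (mouth_opened) mean(win$mar),
    duration = duration
  )
}

#' @export
print.drowsiness_calibration <- function(x, ...) {
  cat("Calibration (", format(x$duration), " s window)\n", sep = "")
  cat(sprintf("  EAR mean %.4f -> threshold %.4f (x 3/4)\n",
              x$ear_mean, x$ear_thresh))
  if (x$mar_from_default) {
    cat("  MAR: mouth not held open; default threshold 0.35\n")
  } else {
    cat(sprintf("  MAR mean %.4f -> threshold %.4f (x 1/2)\n",
                x$mar_mean, x$mar_thresh))
  }
  invisible(x)
}

stop_calibration <- function(msg) {
  stop(structure(
    class = c("perclos_calibration_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
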