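#' Eye aspect ratio from a 6-point eye contour
#'
#' EAR is the ratio of the summed vertical lid separations to twice the
#' horizontal eye width,
#' \deqn{EAR = (\|p_2-p_6\| + \|p_3-p_5\|) / (2 \|p_1-p_4\|),}
#' where `p1` and `p4` are the horizontal eye corners, `p2`,`p3` the upper
#' lid and `p6`,`p5` the lower lid. EAR approaches 0 as the eye closes and
#' is invariant under translation, rotation and uniform scaling.
#'
#' @param eye numeric 6 x 2 matrix of (x, y) pixel coordinates, rows in the
#'   order p1..p6.
#' @return dimensionless aspect ratio (non-negative scalar).
#' @examples
#' eye <- rbind(c(0, 0), c(1, 1), c(3, 1), c(4, 0), c(3, -1), c(1, -1))
#' compute_ear(eye)  # 0.5
#' @export
compute_ear <- function(eye) {
  eye <- check_contour(eye, 6L, "eye")
  width <- enorm(eye[1, ] - eye[4, ])
  if (width <= 0) stop_invalid_geometry("eye corners coincide (zero width)")
  (enorm(eye[2, ] - eye[6, ]) + enorm(eye[3, ] - eye[5, ])) / (2 * width)
}

#' Mouth aspect ratio from the 8-point inner-lip contour
#'
#' MAR relates the vertical opening of the inner lips to the mouth width.
#' With corners `p1`, `p5` and vertical pairs (p2,p8), (p3,p7), (p4,p6):
#' \deqn{MAR = (\|p_2-p_8\| + \|p_3-p_7\| + \|p_4-p_6\|) / (2 \|p_1-p_5\|).}
#' The `"printed"` variant replaces the third numerator term by
#' \eqn{\|p_4-p_5\|}, i.e. measures the last pair against the mouth corner
#' instead of its opposing lip point; the symmetric form is the default
#' because it treats the three vertical pairs alike and vanishes exactly for
#' a closed mouth.
#'
#' @param mouth numeric 8 x 2 matrix, rows p1..p8 around the inner-lip ring
#'   (p1 and p5 are the corners).
#' @param variant `"symmetric"` (default) or `"printed"`.
#' @return dimensionless aspect ratio.
#' @examples
#' mouth <- rbind(c(0, 0), c(1, 1), c(2, 1), c(3, 1),
#'                c(4, 0), c(3, -1), c(2, -1), c(1, -1))
#' compute_mar(mouth)  # 0.75
#' @export
compute_mar <- function(mouth, variant = c("symmetric", "printed")) {
  variant <- match.arg(variant)
  mouth <- check_contour(mouth, 8L, "mouth")
  width <- enorm(mouth[1, ] - mouth[5, ])
  if (width <= 0) stop_invalid_geometry("mouth corners coincide (zero width)")
  third <- if (variant == "symmetric") {
    enorm(mouth[4, ] - mouth[6, ])
  } else {
    enorm(mouth[4, ] - mouth[5, ])
  }
  (enorm(mouth[2, ] - mouth[8, ]) + enorm(mouth[3, ] - mouth[7, ]) + third) /
    (2 * width)
}

#' Gaze score: normalised pupil offset from the eye centre
#'
#' Euclidean distance between the eye centre and the pupil centre, divided
#' by the eye width. The eye centre is the midpoint of the two corners
#' `p1`, `p4` (not the 6-point centroid), so the score stays defined while
#' the lids close mid-blink. 0 means a perfectly centred gaze; the pupil at
#' a corner scores 0.5.
#'
#' @param eye numeric 6 x 2 eye contour as in [compute_ear()].
#' @param pupil numeric length-2 pupil centre (x, y) in the same pixel frame.
#' @return dimensionless non-negative score.
#' @export
compute_gaze_score <- function(eye, pupil) {
  eye <- check_contour(eye, 6L, "eye")
  pupil <- as.numeric(pupil)
  if (length(pupil) != 2L || !all(is.finite(pupil))) {
    stop_invalid_geometry("pupil must be a finite (x, y) pair")
  }
  width <- enorm(eye[1, ] - eye[4, ])
  if (width <= 0) stop_invalid_geometry("eye corners coincide (zero width)")
  centre <- (eye[1, ] + eye[4, ]) / 2
  enorm(centre - pupil) / width
}

#' Construct a single landmark frame
#'
#' A timestamped set of 68 facial landmarks in the iBUG order, with optional
#' pupil centres and the tag of the detector that produced the face box.
#'
#' @param t timestamp in seconds (non-negative).
#' @param points numeric 68 x 2 matrix of pixel coordinates (origin top-left,
#'   x rightward, y downward).
#' @param pupil_left,pupil_right optional length-2 pupil centres.
#' @param detector one of `"gradient"`, `"cascade"`, `"none"`.
#' @return an object of class `landmark_frame`.
#' @export
landmark_frame <- function(t, points, pupil_left = NULL, pupil_right = NULL,
                           detector = "gradient") {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 68L || ncol(points) != 2L) {
    stop("`points` must be a numeric 68 x 2 matrix")
  }
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single non-negative number")
  }
  detector <- match.arg(detector, c("gradient", "cascade", "none"))
  structure(
    list(t = as.numeric(t), points = unname(points),
         pupil_left = if (!is.null(pupil_left)) as.numeric(pupil_left),
         pupil_right = if (!is.null(pupil_right)) as.numeric(pupil_right),
         detector = detector),
    class = "landmark_frame"
  )
}

#' Assemble landmark frames into a stream
#'
#' A `landmark_stream` stores n frames column-major: a time vector, a
#' `n x 68 x 2` coordinate array, per-eye pupil matrices (rows of `NA` where
#' pupils are absent) and a detector tag per frame. Timestamps must be
#' strictly increasing.
#'
#' @param frames list of [landmark_frame()] objects.
#' @return an object of class `landmark_stream`.
#' @export
landmark_stream <- function(frames) {
  stopifnot(length(frames) > 0L)
  n <- length(frames)
  t <- vapply(frames, function(f) f$t, numeric(1))
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  pts <- array(NA_real_, dim = c(n, 68L, 2L))
  pl <- matrix(NA_real_, n, 2L)
  pr <- matrix(NA_real_, n, 2L)
  det <- character(n)
  for (i in seq_len(n)) {
    f <- frames[[i]]
    pts[i, , ] <- f$points
    if (!is.null(f$pupil_left)) pl[i, ] <- f$pupil_left
    if (!is.null(f$pupil_right)) pr[i, ] <- f$pupil_right
    det[i] <- f$detector
  }
  new_landmark_stream(t, pts, pl, pr, det)
}

new_landmark_stream <- function(t, points, pupil_left, pupil_right,
                                detector) {
  structure(
    list(t = t, points = points, pupil_left = pupil_left,
         pupil_right = pupil_right, detector = detector),
    class = "landmark_stream"
  )
}

#' @export
length.landmark_stream <- function(x) length(x$t)

#' Extract one frame from a stream
#' @param stream a `landmark_stream`.
#' @param i frame index.
#' @return a [landmark_frame()].
#' @export
stream_frame <- function(stream, i) {
  landmark_frame(
    t = stream$t[i],
    points = stream$points[i, , ],
    pupil_left = if (all(is.finite(stream$pupil_left[i, ]))) {
      stream$pupil_left[i, ]
    },
    pupil_right = if (all(is.finite(stream$pupil_right[i, ]))) {
      stream$pupil_right[i, ]
    },
    detector = stream$detector[i]
  )
}

#' @export
print.landmark_stream <- function(x, ...) {
  cat(sprintf(
    "landmark_stream: %d frames, %.2f-%.2f s, pupils on %d frames\n",
    length(x$t), min(x$t), max(x$t), sum(is.finite(x$pupil_left[, 1]))
  ))
  invisible(x)
}

#' Score one landmark frame
#'
#' Computes the five per-frame indicators: EAR (arithmetic mean of the two
#' eyes), MAR from the inner-lip ring, gaze score (mean of the per-eye
#' scores when pupil centres are present), and head-pose Euler angles via
#' [estimate_head_pose()]. Degenerate geometry or pose failure is reported
#' through validity flags, never as an error, so one bad frame cannot abort
#' a session.
#'
#' @param frame a [landmark_frame()].
#' @param cam a [camera_model()].
#' @param mar_variant passed to [compute_mar()].
#' @return one-row data.frame with columns `t, ear, mar, gaze, roll, pitch,
#'   yaw, valid_face, valid_gaze, valid_pose, detector`.
#' @export
score_frame <- function(frame, cam = camera_model(), mar_variant = "symmetric") {
  stopifnot(inherits(frame, "landmark_frame"))
  stream <- new_landmark_stream(
    t = frame$t,
    points = array(frame$points, dim = c(1L, 68L, 2L)),
    pupil_left = matrix(if (is.null(frame$pupil_left)) NA_real_ else
      frame$pupil_left, 1L, 2L),
    pupil_right = matrix(if (is.null(frame$pupil_right)) NA_real_ else
      frame$pupil_right, 1L, 2L),
    detector = frame$detector
  )
  score_stream(stream, cam = cam, mar_variant = mar_variant)
}

#' Score every frame of a landmark stream
#'
#' Vectorised version of [score_frame()]. Head pose is solved once per
#' distinct anchor configuration (the six rigid anchor landmarks), so long
#' runs of a static head cost a single perspective-n-point solve.
#'
#' @inheritParams score_frame
#' @param stream a `landmark_stream`.
#' @return data.frame with one row per frame (see [score_frame()]).
#' @export
score_stream <- function(stream, cam = camera_model(),
                         mar_variant = "symmetric") {
  stopifnot(inherits(stream, "landmark_stream"))
  pts <- stream$points
  n <- dim(pts)[1]

  d2 <- function(i, j) {
    sqrt((pts[, i, 1] - pts[, j, 1])^2 + (pts[, i, 2] - pts[, j, 2])^2)
  }
  eye_ratio <- function(e) {  # e: 6 landmark indices in p1..p6 order
    (d2(e[2], e[6]) + d2(e[3], e[5])) / (2 * d2(e[1], e[4]))
  }
  le <- .idx$left_eye; re <- .idx$right_eye; lip <- .idx$inner_lip
  ear_l <- eye_ratio(le)
  ear_r <- eye_ratio(re)
  ear <- (ear_l + ear_r) / 2

  third <- if (mar_variant == "symmetric") d2(lip[4], lip[6]) else
    d2(lip[4], lip[5])
  mar <- (d2(lip[2], lip[8]) + d2(lip[3], lip[7]) + third) /
    (2 * d2(lip[1], lip[5]))

  valid_face <- is.finite(ear) & is.finite(mar) & stream$detector != "none"
  ear[!is.finite(ear)] <- NA_real_
  mar[!is.finite(mar)] <- NA_real_

  gaze_one <- function(e, pup) {
    cx <- (pts[, e[1], 1] + pts[, e[4], 1]) / 2
    cy <- (pts[, e[1], 2] + pts[, e[4], 2]) / 2
    sqrt((cx - pup[, 1])^2 + (cy - pup[, 2])^2) / d2(e[1], e[4])
  }
  gl <- gaze_one(le, stream$pupil_left)
  gr <- gaze_one(re, stream$pupil_right)
  gaze <- (gl + gr) / 2
  valid_gaze <- is.finite(gaze)
  gaze[!valid_gaze] <- NA_real_

  pose <- estimate_pose_batch(pts, cam)

  data.frame(
    t = stream$t, ear = ear, mar = mar, gaze = gaze,
    roll = pose$roll, pitch = pose$pitch, yaw = pose$yaw,
    valid_face = valid_face, valid_gaze = valid_gaze,
    valid_pose = pose$valid & valid_face,
    detector = stream$detector,
    stringsAsFactors = FALSE
  )
}

enorm <- function(v) sqrt(sum(v^2))

check_contour <- function(m, npts, what) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) != npts || ncol(m) != 2L ||
      !all(is.finite(m))) {
    stop_invalid_geometry(sprintf(
      "%s contour must be a finite numeric %d x 2 matrix", what, npts
    ))
  }
  unname(m)
}

stop_invalid_geometry <- function(msg) {
  stop(structure(
    class = c("perclos_invalid_geometry", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
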