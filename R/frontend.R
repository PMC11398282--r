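#' Preprocess a colour frame for face detection
#'
#' Converts to single-channel greyscale with Rec.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B) and applies an edge-preserving bilateral
#' filter: each pixel is replaced by a weighted mean of its neighbourhood,
#' with weights that decay both with spatial distance and with intensity
#' difference, so noise is smoothed while edges stay put.
#'
#' @param frame numeric `h x w x 3` array (RGB, any common intensity scale)
#'   or an already-grey `h x w` matrix.
#' @param d neighbourhood half-width in pixels (window is `2d + 1` square).
#' @param sigma_space spatial Gaussian sigma in pixels.
#' @param sigma_range intensity Gaussian sigma, on the frame's own scale.
#' @return greyscale matrix of the same height and width.
#' @export
preprocess <- function(frame, d = 2L, sigma_space = 2, sigma_range = 0.1) {
  if (length(frame) == 0L) stop("empty frame")
  gray <- if (length(dim(frame)) == 3L) {
    0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  } else {
    as.matrix(frame)
  }
  bilateral_filter(gray, d = d, sigma_space = sigma_space,
                   sigma_range = sigma_range)
}

bilateral_filter <- function(img, d = 2L, sigma_space = 2,
                             sigma_range = 0.1) {
  num <- img * 0
  den <- img * 0
  for (dr in -d:d) {
    for (dc in -d:d) {
      w_sp <- exp(-(dr^2 + dc^2) / (2 * sigma_space^2))
      shifted <- shift_mat(img, dr, dc)  # edge-replicated
      w <- w_sp * exp(-(shifted - img)^2 / (2 * sigma_range^2))
      num <- num + w * shifted
      den <- den + w
    }
  }
  num / den
}

#' Face box
#'
#' Axis-aligned rectangle containing a face, tagged with the detector that
#' produced it. Pixel coordinates, origin top-left, 0-based.
#'
#' @param x,y top-left corner.
#' @param width,height box size (> 0).
#' @param detector `"gradient"` (HOG-style primary) or `"cascade"`
#'   (Haar-style fallback).
#' @return list of class `face_box`.
#' @export
face_box <- function(x, y, width, height, detector = "gradient") {
  stopifnot(width > 0, height > 0)
  detector <- match.arg(detector, c("gradient", "cascade"))
  structure(list(x = x, y = y, width = width, height = height,
                 detector = detector),
            class = "face_box")
}

#' Detect the most prominent face
#'
#' Detector *policy*, with the detectors themselves injected as functions:
#' the gradient-based primary detector runs first and the cascade fallback
#' is consulted only when the primary finds nothing. When several boxes are
#' returned, only the largest by area -- assumed to be the driver -- is
#' kept. The winning box is tagged with its detector; `NULL` means no face,
#' which is a valid outcome. Detection statistics are updated either way.
#'
#' A detector backend is any `function(gray)` returning a list of
#' [face_box()] (or an empty list / `NULL`). Real HOG or Haar-cascade
#' runtimes plug in here; tests use stubs.
#'
#' @param gray preprocessed greyscale matrix.
#' @param primary,fallback detector backends.
#' @param stats a [detection_stats()] to update.
#' @return list with `box` ([face_box()] or `NULL`) and the updated `stats`.
#' @export
detect_face <- function(gray, primary, fallback = NULL,
                        stats = detection_stats()) {
  pick_largest <- function(boxes, tag) {
    boxes <- Filter(Negate(is.null), as.list(boxes))
    if (length(boxes) == 0L) return(NULL)
    areas <- vapply(boxes, function(b) b$width * b$height, numeric(1))
    b <- boxes[[which.max(areas)]]
    b$detector <- tag
    b
  }
  box <- pick_largest(primary(gray), "gradient")
  if (is.null(box) && !is.null(fallback)) {
    box <- pick_largest(fallback(gray), "cascade")
  }
  stats$frames_total <- stats$frames_total + 1L
  if (!is.null(box)) {
    if (box$detector == "gradient") {
      stats$detected_by_gradient <- stats$detected_by_gradient + 1L
    } else {
      stats$detected_by_cascade <- stats$detected_by_cascade + 1L
    }
    stats$frames_detected <- stats$frames_detected + 1L
  }
  list(box = box, stats = stats)
}

#' Predict 68 facial landmarks within a face box
#'
#' Landmark-prediction contract: the predictor backend is injected as a
#' `function(gray, box)` returning a 68 x 2 matrix in the iBUG order. The
#' engine depends only on this contract, so synthetic predictors can be
#' used throughout testing. A failing predictor yields a frame tagged
#' `detector = "none"` with `NA` coordinates rather than an error.
#'
#' @param gray greyscale matrix.
#' @param box a [face_box()] fully inside the image.
#' @param predictor backend `function(gray, box) -> 68 x 2 matrix`.
#' @param t timestamp for the resulting frame.
#' @return a [landmark_frame()].
#' @export
predict_landmarks <- function(gray, box, predictor, t = 0) {
  stopifnot(inherits(box, "face_box"))
  nr <- nrow(gray); nc <- ncol(gray)
  if (box$x < 0 || box$y < 0 || box$x + box$width > nc ||
      box$y + box$height > nr) {
    stop("face box extends outside the image")
  }
  pts <- tryCatch(predictor(gray, box), error = function(e) NULL)
  if (is.null(pts) || !is.matrix(pts) || nrow(pts) != 68L ||
      ncol(pts) != 2L || !all(is.finite(pts))) {
    return(landmark_frame(t, matrix(0, 68, 2), detector = "none"))
  }
  landmark_frame(t, pts, detector = box$detector)
}

#' Read an image directory as a frame source
#'
#' Reads numbered PNG images from a directory (sorted by filename) as a
#' frame sequence, a container-free stand-in for a video file. Requires the
#' `png` package.
#'
#' @param dir directory of `.png` files.
#' @return list of `h x w (x 3)` numeric arrays.
#' @export
read_image_directory <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading image directories requires the 'png' package")
  }
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no .png frames found in ", dir)
  lapply(files, png::readPNG)
}

#' Run the front-end over a sequence of images
#'
#' Applies [preprocess()], [detect_face()] and [predict_landmarks()] per
#' image and assembles a landmark stream plus detection statistics. Frames
#' with no detected face are dropped from the stream but counted in the
#' statistics.
#'
#' @param images list of image arrays/matrices.
#' @param primary,fallback detector backends (see [detect_face()]).
#' @param predictor landmark backend (see [predict_landmarks()]).
#' @param fps frame rate used to timestamp frames.
#' @return list with `stream` (a `landmark_stream` or `NULL` when no face
#'   was ever found) and `stats` (a [detection_stats()]).
#' @export
frontend_stream <- function(images, primary, fallback = NULL, predictor,
                            fps = 4) {
  stats <- detection_stats()
  frames <- list()
  for (i in seq_along(images)) {
    gray <- preprocess(images[[i]])
    det <- detect_face(gray, primary, fallback, stats)
    stats <- det$stats
    if (is.null(det$box)) next
    fr <- predict_landmarks(gray, det$box, predictor, t = (i - 1) / fps)
    if (fr$detector != "none") frames[[length(frames) + 1L]] <- fr
  }
  list(stream = if (length(frames)) landmark_stream(frames), stats = stats)
}
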