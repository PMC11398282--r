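#' Pupil detector parameters
#'
#' Controls for the circular Hough transform used by [detect_pupil()]. The
#' radius bounds are fractions of the smaller patch dimension, so the same
#' configuration serves eye boxes of any size.
#'
#' @param blur_passes number of 3 x 3 box-blur passes applied before
#'   gradient extraction.
#' @param edge_gradient minimum gradient magnitude (intensity units per
#'   pixel, intensities normalised to `[0, 1]`) for a pixel to vote.
#' @param accumulator_frac fraction of the ideal circumference vote count
#'   `2 * pi * r` a candidate circle must collect to be accepted.
#' @param radius_range length-2 fractions of `min(nrow, ncol)` bounding the
#'   candidate pupil radius.
#' @return list of class `pupil_config`.
#' @export
pupil_config <- function(blur_passes = 1L, edge_gradient = 0.05,
                         accumulator_frac = 0.35,
                         radius_range = c(0.10, 0.40)) {
  structure(list(blur_passes = blur_passes, edge_gradient = edge_gradient,
                 accumulator_frac = accumulator_frac,
                 radius_range = radius_range),
            class = "pupil_config")
}

#' Locate the pupil in a greyscale eye patch
#'
#' Finds the strongest dark circular region with a gradient-voting circular
#' Hough transform: edge pixels vote for circle centres one radius inward
#' against the intensity gradient (the pupil is darker than the sclera, so
#' gradients point away from its centre). The winning accumulator cell is
#' refined to sub-pixel precision by a darkness-weighted centroid over the
#' detected disk. Returns `NULL` when no candidate reaches the accumulator
#' threshold (e.g. a featureless patch), which is a valid outcome, not an
#' error.
#'
#' @param patch numeric matrix of intensities (rows = y, cols = x); any
#'   non-negative scale is accepted and normalised internally.
#' @param config a [pupil_config()].
#' @return length-2 numeric `(x, y)` pupil centre in 0-based pixel
#'   coordinates of the patch, or `NULL` when absent.
#' @export
detect_pupil <- function(patch, config = pupil_config()) {
  patch <- as.matrix(patch)
  if (length(patch) == 0L || !is.numeric(patch)) {
    stop("`patch` must be a non-empty numeric matrix")
  }
  rng <- range(patch)
  img <- if (diff(rng) > 0) (patch - rng[1]) / diff(rng) else patch * 0
  for (i in seq_len(config$blur_passes)) img <- box_blur3(img)

  nr <- nrow(img); nc <- ncol(img)
  gx <- shift_mat(img, 0, -1) - shift_mat(img, 0, 1)   # d/dx, central
  gy <- shift_mat(img, -1, 0) - shift_mat(img, 1, 0)   # d/dy
  gmag <- sqrt(gx^2 + gy^2) / 2
  edges <- which(gmag > config$edge_gradient)
  if (length(edges) == 0L) return(NULL)

  erow <- ((edges - 1L) %% nr) + 1L
  ecol <- ((edges - 1L) %/% nr) + 1L
  ux <- gx[edges] / (2 * gmag[edges])
  uy <- gy[edges] / (2 * gmag[edges])

  radii <- seq(max(2, floor(config$radius_range[1] * min(nr, nc))),
               max(3, ceiling(config$radius_range[2] * min(nr, nc))))
  best <- NULL
  for (r in radii) {
    # vote one radius inward, against the gradient (toward the dark side)
    cx <- round(ecol - r * ux)
    cy <- round(erow - r * uy)
    ok <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr
    if (!any(ok)) next
    acc <- matrix(0L, nr, nc)
    idx <- cbind(cy[ok], cx[ok])
    tab <- table((idx[, 2] - 1L) * nr + idx[, 1])
    acc[as.integer(names(tab))] <- as.integer(tab)
    acc <- box_sum3(acc)  # absorb rounding spread of neighbouring votes
    peak <- which.max(acc)
    votes <- acc[peak]
    if (votes >= config$accumulator_frac * 2 * pi * r &&
        (is.null(best) || votes / r > best$score)) {
      best <- list(row = ((peak - 1L) %% nr) + 1L,
                   col = ((peak - 1L) %/% nr) + 1L,
                   r = r, score = votes / r)
    }
  }
  if (is.null(best)) return(NULL)

  # darkness-weighted centroid over the detected disk for sub-pixel accuracy
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  within <- (xs - best$col)^2 + (ys - best$row)^2 <= (best$r + 1)^2
  w <- (1 - img) * within
  if (sum(w) <= 0) {
    return(c(best$col - 1, best$row - 1))
  }
  c(sum(w * xs) / sum(w) - 1, sum(w * ys) / sum(w) - 1)
}

#' Render a synthetic eye patch with a dark pupil disk
#'
#' Fixture generator for the pupil detector: a white elliptical sclera on a
#' mid-grey background with a black disk at a chosen centre. Coordinates are
#' 0-based pixels.
#'
#' @param width,height patch size in pixels.
#' @param centre length-2 `(x, y)` pupil centre; default patch centre.
#' @param radius pupil radius in pixels.
#' @return numeric `height x width` matrix in `[0, 1]`.
#' @export
render_pupil_patch <- function(width = 40, height = 24, centre = NULL,
                               radius = 5) {
  if (is.null(centre)) centre <- c((width - 1) / 2, (height - 1) / 2)
  xs <- matrix(rep(seq_len(width) - 1, each = height), height, width)
  ys <- matrix(rep(seq_len(height) - 1, width), height, width)
  img <- matrix(0.6, height, width)
  ell <- ((xs - (width - 1) / 2) / (width / 2))^2 +
    ((ys - (height - 1) / 2) / (height / 2))^2 <= 1
  img[ell] <- 1
  disk <- (xs - centre[1])^2 + (ys - centre[2])^2 <= radius^2
  img[disk] <- 0
  img
}

box_blur3 <- function(m) box_sum3(m) / box_count3(m)

box_sum3 <- function(m) {
  s <- m * 0
  for (dr in -1:1) for (dc in -1:1) {
    s <- s + shift_mat(m, dr, dc, fill = 0)
  }
  s
}

box_count3 <- function(m) {
  ones <- matrix(1, nrow(m), ncol(m))
  s <- ones * 0
  for (dr in -1:1) for (dc in -1:1) {
    s <- s + shift_mat(ones, dr, dc, fill = 0)
  }
  s
}

# shift a matrix by (dr, dc), padding with `fill` (or edge value if NA fill)
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  src_r <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  src_c <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  out <- m[src_r, src_c, drop = FALSE]
  if (!is.na(fill)) {
    if (dr > 0) out[seq_len(min(dr, nr)), ] <- fill
    if (dr < 0) out[seq(nr + dr + 1, nr), ] <- fill
    if (dc > 0) out[, seq_len(min(dc, nc))] <- fill
    if (dc < 0) out[, seq(nc + dc + 1, nc)] <- fill
  }
  out
}
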