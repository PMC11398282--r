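#' Pinhole camera model
#'
#' Intrinsics used for head-pose recovery. When uncalibrated, the standard
#' approximation is focal length = image width in pixels and principal point
#' = image centre; the defaults encode that for a 640 x 480 frame.
#'
#' @param focal_length focal length in pixels (> 0).
#' @param principal_point length-2 (cx, cy) in pixels.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(focal_length = 640, principal_point = c(320, 240)) {
  stopifnot(is.numeric(focal_length), length(focal_length) == 1L,
            focal_length > 0, length(principal_point) == 2L)
  structure(list(focal_length = focal_length,
                 principal_point = as.numeric(principal_point)),
            class = "camera_model")
}

#' Derive a camera model from an image size
#' @param width,height image dimensions in pixels.
#' @return a [camera_model()].
#' @export
camera_for_image <- function(width, height) {
  camera_model(focal_length = width, principal_point = c(width, height) / 2)
}

#' Generic 3-D head anchor points
#'
#' Six rigid facial points of a generic adult head, in millimetres, used as
#' the 3-D side of the perspective-n-point correspondence: nose tip, chin,
#' the two outer eye corners and the two mouth corners. Axes are
#' image-aligned: x rightward, y downward, z away from the camera (the nose
#' tip, at the origin, is the closest point). The corresponding 1-based
#' landmark indices in the iBUG scheme are 31, 9, 37, 46, 49, 55.
#'
#' @return 6 x 3 numeric matrix with row names.
#' @export
generic_head_model <- function() {
  m <- rbind(
    nose_tip        = c(0, 0, 0),
    chin            = c(0, 110, 25),
    left_eye_outer  = c(-72, -55, 40),
    right_eye_outer = c(72, -55, 40),
    mouth_left      = c(-48, 48, 25),
    mouth_right     = c(48, 48, 25)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' Rotation matrix from head-pose Euler angles
#'
#' Intrinsic rotations applied yaw (about the vertical y axis), then pitch
#' (x), then roll (z), in image-aligned camera axes:
#' `R = Rz(roll) %*% Rx(pitch) %*% Ry(yaw)`.
#'
#' @param yaw,pitch,roll angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
euler_to_rotation <- function(yaw, pitch, roll) {
  y <- yaw * pi / 180; p <- pitch * pi / 180; r <- roll * pi / 180
  Ry <- rbind(c(cos(y), 0, sin(y)), c(0, 1, 0), c(-sin(y), 0, cos(y)))
  Rx <- rbind(c(1, 0, 0), c(0, cos(p), -sin(p)), c(0, sin(p), cos(p)))
  Rz <- rbind(c(cos(r), -sin(r), 0), c(sin(r), cos(r), 0), c(0, 0, 1))
  Rz %*% Rx %*% Ry
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_rotation()]; angles in degrees, each in (-180, 180].
#' Gimbal lock (|pitch| = 90 deg) is outside the working range of head-pose
#' monitoring and resolved by assigning the in-plane rotation to roll.
#'
#' @param R 3 x 3 rotation matrix.
#' @return named numeric vector (yaw, pitch, roll).
#' @export
rotation_to_euler <- function(R) {
  sp <- max(-1, min(1, R[3, 2]))
  pitch <- asin(sp)
  if (abs(sp) < 1 - 1e-9) {
    yaw <- atan2(-R[3, 1], R[3, 3])
    roll <- atan2(-R[1, 2], R[2, 2])
  } else {
    yaw <- 0
    roll <- atan2(R[2, 1], R[1, 1])
  }
  c(yaw = yaw, pitch = pitch, roll = roll) * 180 / pi
}

#' Project 3-D points through a camera
#'
#' Rigid transform followed by perspective division:
#' `u = f * Xc / Zc + cx`, `v = f * Yc / Zc + cy`.
#'
#' @param pts3d n x 3 matrix of model points.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm), z > 0 in front of the
#'   camera.
#' @param cam a [camera_model()].
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(pts3d, rotation, translation, cam) {
  Xc <- t(rotation %*% t(pts3d)) +
    matrix(translation, nrow(pts3d), 3, byrow = TRUE)
  if (any(Xc[, 3] <= 0)) stop("points behind the camera")
  cbind(
    cam$focal_length * Xc[, 1] / Xc[, 3] + cam$principal_point[1],
    cam$focal_length * Xc[, 2] / Xc[, 3] + cam$principal_point[2]
  )
}

# Solve perspective-n-point for the six anchors by Levenberg-Marquardt
# minimisation of reprojection error over (yaw, pitch, roll, tx, ty, tz).
solve_pnp <- function(pts2d, cam, start = NULL) {
  model <- generic_head_model()
  spread <- max(apply(pts2d, 2, function(c) diff(range(c))))
  if (!all(is.finite(pts2d)) || spread < 1e-6) {
    return(list(valid = FALSE, yaw = NA_real_, pitch = NA_real_,
                roll = NA_real_, translation = rep(NA_real_, 3)))
  }
  eye_px <- enorm(pts2d[3, ] - pts2d[4, ])
  tz0 <- cam$focal_length * 144 / max(eye_px, 1e-6)
  centre_px <- colMeans(pts2d)
  cold <- c(0, 0, 0,
            (centre_px[1] - cam$principal_point[1]) * tz0 /
              cam$focal_length,
            (centre_px[2] - cam$principal_point[2]) * tz0 /
              cam$focal_length,
            tz0)
  starts <- list(cold)
  if (!is.null(start)) {
    # snap near-zero angles to exactly zero: MINPACK's relative
    # finite-difference step underflows on tiny nonzero parameters
    start[1:3][abs(start[1:3]) < 1e-4] <- 0
    starts <- c(starts, list(start))
  }
  resid <- function(par) {
    R <- euler_to_rotation(par[1], par[2], par[3])
    proj <- tryCatch(project_points(model, R, par[4:6], cam),
                     error = function(e) NULL)
    if (is.null(proj)) return(rep(1e6, 12))
    as.numeric(proj - pts2d)
  }
  best_par <- NULL
  best_rms <- Inf
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s0, fn = resid,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit) || !all(is.finite(fit$par))) next
    rms_i <- sqrt(mean(resid(fit$par)^2))
    if (rms_i < best_rms) {
      best_rms <- rms_i
      best_par <- fit$par
    }
  }
  if (is.null(best_par)) {
    return(list(valid = FALSE, yaw = NA_real_, pitch = NA_real_,
                roll = NA_real_, translation = rep(NA_real_, 3)))
  }
  fit <- list(par = best_par)
  rms <- best_rms
  ang <- wrap_angle(fit$par[1:3])
  # a fit that cannot place the rigid anchors near the observations is a
  # degenerate configuration, not a pose
  list(valid = rms <= 0.05 * spread,
       yaw = ang[1], pitch = ang[2], roll = ang[3],
       translation = fit$par[4:6], rms = rms, par = fit$par)
}

wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Estimate head pose from a landmark frame
#'
#' Solves a perspective-n-point problem between the six rigid anchors of
#' [generic_head_model()] and the corresponding 2-D landmarks, and reports
#' the rotation as intrinsic yaw-pitch-roll Euler angles in degrees.
#' Degenerate input (collapsed or non-finite anchors, irreducible
#' reprojection error) yields `valid = FALSE` instead of an error.
#'
#' @param frame a [landmark_frame()].
#' @param cam a [camera_model()].
#' @return list with `yaw`, `pitch`, `roll` (degrees), `translation` (mm)
#'   and `valid`.
#' @export
estimate_head_pose <- function(frame, cam = camera_model()) {
  stopifnot(inherits(frame, "landmark_frame"))
  solve_pnp(frame$points[.idx$pose_anchors, , drop = FALSE], cam)
}

# Batch pose over a n x 68 x 2 array; one PnP solve per distinct anchor
# configuration, warm-started from the previous solution.
estimate_pose_batch <- function(pts, cam) {
  n <- dim(pts)[1]
  anchors <- pts[, .idx$pose_anchors, , drop = FALSE]
  key <- apply(round(anchors, 4), 1, paste, collapse = ",")
  out <- data.frame(yaw = rep(NA_real_, n), pitch = NA_real_,
                    roll = NA_real_, valid = FALSE)
  prev_par <- NULL
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    k <- key[i]
    sol <- cache[[k]]
    if (is.null(sol)) {
      sol <- solve_pnp(matrix(anchors[i, , ], 6L, 2L), cam,
                       start = prev_par)
      cache[[k]] <- sol
    }
    if (sol$valid) prev_par <- sol$par
    out$yaw[i] <- sol$yaw; out$pitch[i] <- sol$pitch
    out$roll[i] <- sol$roll; out$valid[i] <- sol$valid
  }
  out
}
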