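# shared fixtures: canonical contours, the neutral template, and helpers

# symmetric eye contour, EAR = 0.5 by hand evaluation
eye_half <- rbind(c(0, 0), c(1, 1), c(3, 1), c(4, 0), c(3, -1), c(1, -1))

# inner-lip contour, symmetric MAR = 0.75 by hand evaluation
mouth_075 <- rbind(c(0, 0), c(1, 1), c(2, 1), c(3, 1),
                   c(4, 0), c(3, -1), c(2, -1), c(1, -1))

# a closed eye: lids touching on the corner axis
eye_closed <- rbind(c(0, 0), c(1, 0), c(3, 0), c(4, 0), c(3, 0), c(1, 0))

the_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- neutral_template()
    tpl
  }
})

# apply a random similarity transform (rotation + uniform scale + shift)
similarity_transform <- function(pts, angle, scale, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * pts %*% t(R), 2, shift, `+`)
}

# indicator scores for a constant-value stream (fps frames per second)
constant_scores <- function(ear, mar, seconds, fps = 4, gaze = 0,
                            roll = 0, pitch = 0, yaw = 0) {
  n <- round(seconds * fps)
  t <- (seq_len(n) - 1) / fps
  data.frame(t = t, ear = ear, mar = mar, gaze = gaze,
             roll = roll, pitch = pitch, yaw = yaw,
             valid_face = TRUE, valid_gaze = TRUE, valid_pose = TRUE,
             detector = "gradient", stringsAsFactors = FALSE)
}

# step trace: `value_on` for t in [on, off), baseline elsewhere
step_scores <- function(field, baseline, value_on, on, off, seconds,
                        fps = 4) {
  sc <- constant_scores(0.3, 0.1, seconds, fps)
  sc$ear <- 0.3; sc$mar <- 0.1
  v <- rep(baseline, nrow(sc))
  v[sc$t >= on & sc$t < off] <- value_on
  sc[[field]] <- v
  sc
}

expect_events_equal <- function(got, expected, frame_period) {
  expect_equal(nrow(got), nrow(expected))
  expect_equal(got$kind, expected$kind)
  expect_true(all(abs(got$onset - expected$onset) <= frame_period + 1e-9))
}

default_calib <- function() compute_thresholds(0.30, NULL)  # EAR 0.225, MAR 0.35
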