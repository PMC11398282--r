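test_that("EAR matches hand-computed values and closed-eye zero", {
  expect_equal(compute_ear(eye_half), 0.5)
  expect_equal(compute_ear(eye_closed), 0)
  expect_equal(compute_ear(eye_half * 3), 0.5)  # similarity invariance
})

test_that("MAR matches hand-computed values in both variants", {
  expect_equal(compute_mar(mouth_075), 0.75)
  closed <- mouth_075
  closed[, 2] <- 0
  expect_equal(compute_mar(closed), 0)
  # printed variant measures the last pair against the mouth corner p5
  expect_equal(compute_mar(mouth_075, "printed"), (2 + 2 + sqrt(2)) / 8)
})

test_that("gaze score is the normalised pupil offset from the corner midpoint", {
  expect_equal(compute_gaze_score(eye_half, c(2, 0)), 0)
  expect_equal(compute_gaze_score(eye_half, c(0, 0)), 0.5)  # at corner p1
  expect_equal(compute_gaze_score(eye_half, c(2, 2)), 0.5)
})

test_that("degenerate contours raise invalid-geometry errors", {
  zero_eye <- eye_half
  zero_eye[4, ] <- zero_eye[1, ]
  expect_error(compute_ear(zero_eye), class = "perclos_invalid_geometry")
  zero_mouth <- mouth_075
  zero_mouth[5, ] <- zero_mouth[1, ]
  expect_error(compute_mar(zero_mouth), class = "perclos_invalid_geometry")
  expect_error(compute_gaze_score(zero_eye, c(0, 0)),
               class = "perclos_invalid_geometry")
  expect_error(compute_gaze_score(eye_half, c(NA, 0)),
               class = "perclos_invalid_geometry")
})

test_that("EAR, MAR and gaze are invariant under similarity transforms", {
  set.seed(11)
  pupil <- c(1.7, 0.4)
  for (i in 1:100) {
    ang <- runif(1, 0, 2 * pi)
    sc <- runif(1, 0.2, 8)
    sh <- runif(2, -50, 50)
    both <- similarity_transform(rbind(eye_half, mouth_075, pupil),
                                 ang, sc, sh)
    expect_equal(compute_ear(both[1:6, ]), 0.5, tolerance = 1e-12)
    expect_equal(compute_mar(both[7:14, ]), 0.75, tolerance = 1e-12)
    expect_equal(compute_gaze_score(both[1:6, ], both[15, ]),
                 compute_gaze_score(eye_half, pupil), tolerance = 1e-12)
  }
})

test_that("EAR and MAR increase strictly with vertical separations", {
  seps <- seq(0.1, 2, by = 0.1)
  ears <- vapply(seps, function(h) {
    e <- eye_half
    e[c(2, 3), 2] <- h
    e[c(5, 6), 2] <- -h
    compute_ear(e)
  }, numeric(1))
  expect_true(all(diff(ears) > 0))
  mars <- vapply(seps, function(h) {
    m <- mouth_075
    m[2:4, 2] <- h
    m[6:8, 2] <- -h
    compute_mar(m)
  }, numeric(1))
  expect_true(all(diff(mars) > 0))
})

test_that("score_frame averages the two eyes and composes zero cases", {
  tpl <- the_template()
  le <- 37:42; re <- 43:48
  scale_eye <- function(pts, idx, f) {
    for (pr in list(idx[c(2, 6)], idx[c(3, 5)])) {
      ctr <- (pts[pr[1], ] + pts[pr[2], ]) / 2
      pts[pr[1], ] <- ctr + f * (pts[pr[1], ] - ctr)
      pts[pr[2], ] <- ctr + f * (pts[pr[2], ] - ctr)
    }
    pts
  }
  # left EAR 0.4, right EAR 0.2 -> mean 0.3
  pts <- scale_eye(tpl$points2d, le, 0.4 / tpl$ear)
  pts <- scale_eye(pts, re, 0.2 / tpl$ear)
  sc <- score_frame(landmark_frame(0, pts), cam = tpl$cam)
  expect_equal(sc$ear, 0.3, tolerance = 1e-9)

  # both eyes and mouth fully closed, frontal pose
  pts0 <- scale_eye(scale_eye(tpl$points2d, le, 0), re, 0)
  for (pr in list(c(62, 68), c(63, 67), c(64, 66))) {
    ctr <- (pts0[pr[1], ] + pts0[pr[2], ]) / 2
    pts0[pr[1], ] <- ctr; pts0[pr[2], ] <- ctr
  }
  sc0 <- score_frame(landmark_frame(0, pts0), cam = tpl$cam)
  expect_equal(sc0$ear, 0)
  expect_equal(sc0$mar, 0)
  expect_true(sc0$valid_pose)
  expect_true(all(abs(c(sc0$roll, sc0$pitch, sc0$yaw)) < 0.5))

  # frame without pupils: gaze invalid, everything else valid
  expect_false(sc0$valid_gaze)
  expect_true(sc0$valid_face)
  with_pupils <- landmark_frame(0, tpl$points2d,
                                pupil_left = (tpl$points2d[37, ] +
                                                tpl$points2d[40, ]) / 2,
                                pupil_right = (tpl$points2d[43, ] +
                                                 tpl$points2d[46, ]) / 2)
  expect_true(score_frame(with_pupils, cam = tpl$cam)$valid_gaze)
})

test_that("landmark frames and streams validate their invariants", {
  expect_error(landmark_frame(0, matrix(0, 67, 2)), "68")
  expect_error(landmark_frame(-1, matrix(0, 68, 2)), "non-negative")
  f1 <- landmark_frame(0, matrix(1, 68, 2))
  f2 <- landmark_frame(0.25, matrix(1, 68, 2))
  expect_error(landmark_stream(list(f2, f1)), "strictly increasing")
  s <- landmark_stream(list(f1, f2))
  expect_equal(length(s), 2L)
  expect_equal(stream_frame(s, 2)$t, 0.25)
})
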