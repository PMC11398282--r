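cfg4 <- function(...) {
  cfg <- scorer_config(capture_fps = 4, ...)
  apply_calibration(cfg, default_calib())
}

run_perclos <- function(ear, t, cfg) {
  st <- perclos_state()
  emitted <- numeric()
  for (i in seq_along(t)) {
    up <- update_perclos(st, ear[i], t[i], cfg)
    st <- up$state
    if (!is.null(up$minute_score)) emitted <- c(emitted, up$minute_score)
  }
  list(state = st, emitted = emitted)
}

# independent oracle: recount sub-threshold frames per fixed 60 s window
brute_perclos <- function(ear, t, cfg) {
  w <- floor(t / cfg$perclos_time_period + 1e-12)
  complete <- seq_len(max(w)) - 1L
  vapply(complete, function(k) {
    sum(ear[w == k] < cfg$ear_thresh, na.rm = TRUE) * cfg$delta_time_frame /
      cfg$perclos_time_period * 100
  }, numeric(1))
}

test_that("PERCLOS windows emit the flowchart arithmetic", {
  cfg <- cfg4()
  t <- (0:243) / 4  # one full minute plus one extra second

  # no closure at all
  r0 <- run_perclos(rep(0.3, length(t)), t, cfg)
  expect_equal(r0$emitted, 0)

  # 48 sub-threshold frames at 4 fps = 12 s -> 20%
  ear <- rep(0.3, length(t))
  ear[10 + seq_len(48)] <- 0.1
  r1 <- run_perclos(ear, t, cfg)
  expect_equal(r1$emitted, 20)

  # closure episodes of 5, 4 and 3 s -> also exactly the 20% drowsy limit
  ear2 <- rep(0.3, length(t))
  for (ep in list(c(5, 5), c(20, 4), c(40, 3))) {
    ear2[t >= ep[1] & t < ep[1] + ep[2]] <- 0.05
  }
  r2 <- run_perclos(ear2, t, cfg)
  expect_equal(r2$emitted, 20)
})

test_that("window scores equal a brute-force recount on random traces", {
  cfg <- cfg4()
  set.seed(42)
  for (i in 1:25) {
    n <- 4 * 60 * sample(2:4, 1) + sample(0:100, 1)
    t <- (seq_len(n) - 1) / 4
    ear <- runif(n, 0, 0.5)
    r <- run_perclos(ear, t, cfg)
    expect_equal(r$state$minute_scores, brute_perclos(ear, t, cfg))
    # conservation: closed + open frames fill the window exactly
    expect_true(all(r$state$minute_scores >= 0 &
                      r$state$minute_scores <= 100))
  }
})

test_that("adding sub-threshold frames never decreases a window's PERCLOS", {
  cfg <- cfg4()
  t <- (0:240) / 4
  set.seed(9)
  ear <- runif(length(t), 0, 0.5)
  base <- run_perclos(ear, t, cfg)$emitted
  worse <- ear
  open_idx <- which(ear >= cfg$ear_thresh & t < 60)
  worse[sample(open_idx, 10)] <- 0.1
  expect_gt(run_perclos(worse, t, cfg)$emitted, base)
})

test_that("global PERCLOS averages completed windows only", {
  st <- perclos_state()
  st$minute_scores <- c(10, 20, 30)
  expect_equal(global_perclos(st), 20)
  st$minute_scores <- 7.5
  expect_equal(global_perclos(st), 7.5)
  expect_error(global_perclos(perclos_state()),
               class = "perclos_undefined_score")
})

test_that("asleep raises exactly at the time threshold on a step trace", {
  cfg <- cfg4()
  sc <- step_scores("ear", 0.3, 0.1, on = 10, off = 40, seconds = 60)
  al <- score_alarms(sc, cfg)
  expect_equal(min(al$flags$t[al$flags$asleep]), 13)

  # a 2.9 s dip never raises the alarm
  sc2 <- step_scores("ear", 0.3, 0.1, on = 10, off = 12.9, seconds = 30)
  expect_false(any(score_alarms(sc2, cfg)$flags$asleep))
})

test_that("yaw above 30 degrees for 6 s raises distracted; pitch is inert", {
  cfg <- cfg4()
  sc <- step_scores("yaw", 0, 35, on = 5, off = 20, seconds = 30)
  fl <- score_alarms(sc, cfg)$flags
  expect_equal(min(fl$t[fl$distracted]), 11)

  # with the default pitch limit of 180 degrees, |pitch| can never exceed
  # it, so pitch alone cannot raise the alarm
  sc2 <- step_scores("pitch", 0, 170, on = 5, off = 29, seconds = 30)
  expect_false(any(score_alarms(sc2, cfg)$flags$distracted))
})

test_that("gaze alarm requires a centred head", {
  cfg <- cfg4()
  sc <- step_scores("gaze", 0, 0.6, on = 5, off = 25, seconds = 30)
  fl <- score_alarms(sc, cfg)$flags
  expect_equal(min(fl$t[fl$gaze_distracted]), 9)

  # same gaze excursion with the head turned: suppressed once the head
  # alarm is active
  sc$yaw <- ifelse(sc$t >= 5 & sc$t < 25, 40, 0)
  fl2 <- score_alarms(sc, cfg)$flags
  expect_true(any(fl2$distracted))
  expect_false(any(fl2$gaze_distracted & fl2$distracted))
  expect_equal(fl2$gaze_distracted, fl2$t >= 9 & fl2$t < 11)
})

test_that("invalid frames break continuity runs", {
  cfg <- cfg4()
  sc <- step_scores("ear", 0.3, 0.1, on = 10, off = 20, seconds = 30)
  sc$valid_face[sc$t == 12] <- FALSE  # one dropout inside the run
  fl <- score_alarms(sc, cfg)$flags
  expect_equal(min(fl$t[fl$asleep]), 12.25 + 3)
})

test_that("flags re-arm only after a fresh continuous run", {
  cfg <- cfg4()
  sc <- constant_scores(0.3, 0.1, seconds = 40)
  sc$ear[sc$t >= 5 & sc$t < 9] <- 0.1    # first closure
  sc$ear[sc$t >= 15 & sc$t < 19] <- 0.1  # second closure
  ev <- alarm_events(score_alarms(sc, cfg)$flags, cfg$delta_time_frame)
  asleep <- ev[ev$kind == "asleep", ]
  expect_equal(nrow(asleep), 2L)
  expect_equal(asleep$onset, c(8, 18))
})

test_that("drowsy follows the most recent completed window", {
  cfg <- cfg4()
  sc <- constant_scores(0.3, 0.1, seconds = 150)
  sc$ear[sc$t < 15] <- 0.1  # 15 s closed in window 1 -> 25% > 20%
  fl <- score_alarms(sc, cfg)$flags
  expect_false(any(fl$drowsy[fl$t < 60]))
  expect_true(all(fl$drowsy[fl$t >= 60 & fl$t < 120]))
  expect_false(any(fl$drowsy[fl$t >= 120]))  # window 2 is clean
})

test_that("session summaries count events and detection rates", {
  cfg <- cfg4()
  empty <- summarize_session(
    alarm_events(score_alarms(constant_scores(0.3, 0.1, 10), cfg)$flags,
                 cfg$delta_time_frame),
    perclos_state(), detection_stats(0, 0, 0), cfg = cfg
  )
  expect_true(all(unlist(empty$alarms$counts) == 0))
  expect_true(is.na(empty$perclos$global))

  stats <- detection_stats(1000, 900, 50)
  rep <- summarize_session(
    data.frame(kind = c("yawning", "yawning", "asleep"),
               onset = c(1, 2, 3), duration = 1),
    perclos_state(), stats, cfg = cfg
  )
  expect_equal(rep$detection$face_rate, 95)
  expect_equal(rep$alarms$counts$yawning, 2L)
  expect_equal(rep$alarms$counts$asleep, 1L)
})
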