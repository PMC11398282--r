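quiet_schedule <- function(len = 70) {
  event_schedule(list(), session_length = len, fps = 4)
}

busy_schedule <- function() {
  event_schedule(list(
    event_spec("closure", 8, 5, 1),
    event_spec("yawn", 20, 6, 0.7),
    event_spec("head_turn", 35, 7, -35, "yaw"),
    event_spec("gaze_shift", 50, 5, 0.6)
  ), session_length = 70, fps = 4)
}

test_that("a quiet session reports zero alarms and zero PERCLOS", {
  s <- run_session(quiet_schedule())
  expect_s3_class(s, "drowsiness_session")
  expect_true(all(unlist(s$report$alarms$counts) == 0))
  expect_equal(s$report$perclos$per_minute, 0)
  expect_equal(s$report$perclos$global, 0)
  expect_equal(s$report$detection$face_rate, 100)
  # calibration on the neutral face: EAR 0.30 -> 0.225, MAR fallback
  expect_equal(s$config$ear_thresh, 0.225, tolerance = 1e-9)
  expect_equal(s$config$mar_thresh, 0.35)
  expect_true(s$calibration$mar_from_default)
})

test_that("session alarms match the generator oracle on a known schedule", {
  sched <- busy_schedule()
  s <- run_session(sched)
  exp <- expected_alarms(sched, s$config)
  expect_events_equal(s$report$alarms$events, exp,
                      s$config$delta_time_frame)
  expect_equal(s$report$alarms$counts$asleep, 1L)
  expect_equal(s$report$alarms$counts$yawning, 1L)
  expect_equal(s$report$alarms$counts$distracted, 1L)
  expect_equal(s$report$alarms$counts$gaze_distracted, 1L)
})

test_that("running twice on the same saved stream is bit-deterministic", {
  stream_path <- tempfile(fileext = ".csv")
  write_landmark_stream(render_stream(busy_schedule()), stream_path)
  log1 <- tempfile(fileext = ".csv")
  log2 <- tempfile(fileext = ".csv")
  run_session(stream_path, log_path = log1)
  run_session(stream_path, log_path = log2)
  expect_identical(readLines(log1), readLines(log2))
  unlink(c(stream_path, log1, log2))
})

test_that("landmark streams round-trip through CSV and JSON lines", {
  str0 <- render_stream(event_schedule(
    list(event_spec("gaze_shift", 1, 1, 0.5)),
    session_length = 3, fps = 4
  ))
  for (ext in c(".csv", ".jsonl")) {
    path <- tempfile(fileext = ext)
    write_landmark_stream(str0, path)
    back <- read_landmark_stream(path)
    expect_equal(back$t, str0$t)
    expect_equal(back$points, str0$points, tolerance = 1e-12)
    expect_equal(back$pupil_left, str0$pupil_left, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(back$detector, str0$detector)
    unlink(path)
  }
})

test_that("replaying a log under the original config reproduces the report", {
  log <- tempfile(fileext = ".csv")
  s <- run_session(busy_schedule(), log_path = log)
  r <- replay_log(log)
  expect_equal(r$report$alarms$counts, s$report$alarms$counts)
  expect_equal(r$report$perclos$per_minute, s$report$perclos$per_minute)
  expect_equal(r$report$alarms$events$onset, s$report$alarms$events$onset)
  expect_equal(r$frame_log$asleep, s$frame_log$asleep)
  unlink(log)
})

test_that("lowering thresholds never decreases alarm counts on a fixed log", {
  log <- tempfile(fileext = ".csv")
  s <- run_session(busy_schedule(), log_path = log)
  meta <- read_frame_log(log)

  softer <- meta$config
  softer$perclos_thresh <- 0.01
  softer$ear_time_thresh <- 1
  softer$gaze_time_thresh <- 2
  r <- replay_log(meta, config = softer)
  for (k in names(s$report$alarms$counts)) {
    expect_gte(r$report$alarms$counts[[k]], s$report$alarms$counts[[k]])
  }
  unlink(log)
})

test_that("a minute containing 12 s of closure flags drowsy on replay only when over the limit", {
  # 12.25 s of cumulative closure -> 20.4% > 20%: drowsy
  sched <- event_schedule(list(event_spec("closure", 6, 6.25, 1),
                               event_spec("closure", 20, 6, 1)),
                          session_length = 70, fps = 4)
  log <- tempfile(fileext = ".csv")
  run_session(sched, log_path = log)
  r <- replay_log(log)
  expect_equal(r$report$alarms$counts$drowsy, 1L)
  expect_equal(r$report$perclos$per_minute[1], 245 / 12)
  unlink(log)
})

test_that("session I/O errors are classified", {
  expect_error(run_session(tempfile(fileext = ".csv")),
               class = "perclos_io_error")
  bad <- tempfile(fileext = ".csv")
  writeLines("t,ear\n0,0.3", bad)
  expect_error(read_frame_log(bad), "malformed|missing")
  unlink(bad)
})

test_that("session report JSON carries calibration, PERCLOS, alarm and detection fields", {
  path <- tempfile(fileext = ".json")
  s <- run_session(busy_schedule(), report_path = path)
  j <- jsonlite::fromJSON(path)
  expect_true(all(c("calibration", "perclos", "alarms", "detection") %in%
                    names(j)))
  expect_equal(j$detection$face_rate, 100)
  expect_equal(j$alarms$counts$asleep, 1L)
  unlink(path)
})
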