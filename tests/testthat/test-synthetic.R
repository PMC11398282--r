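test_that("an empty schedule renders the template verbatim", {
  tpl <- the_template()
  sched <- event_schedule(list(), session_length = 3, fps = 4)
  str <- render_stream(sched, tpl)
  expect_equal(length(str), 12L)
  sc <- score_stream(str, cam = tpl$cam)
  expect_true(all(abs(sc$ear - tpl$ear) < 1e-12))
  expect_true(all(abs(sc$mar - tpl$mar) < 1e-12))
  expect_true(all(abs(sc$gaze) < 1e-12))  # pupils centred by default
})

test_that("closure, yawn and gaze events hit their analytic targets", {
  tpl <- the_template()
  sched <- event_schedule(list(
    event_spec("closure", 1, 2, 1.0),
    event_spec("yawn", 4, 5, 0.8),
    event_spec("gaze_shift", 10, 2, 0.6)
  ), session_length = 13, fps = 4)
  sc <- score_stream(render_stream(sched, tpl), cam = tpl$cam)

  closed <- sc$t >= 1 & sc$t < 3
  expect_true(all(sc$ear[closed] == 0))
  expect_true(all(abs(sc$ear[!closed] - tpl$ear) < 1e-12))

  yawn <- sc$t >= 4 & sc$t < 9
  expect_true(all(abs(sc$mar[yawn] - 0.8) < 1e-6))

  gaze <- sc$t >= 10 & sc$t < 12
  expect_true(all(abs(sc$gaze[gaze] - 0.6) < 1e-9))
  expect_true(all(abs(sc$gaze[!gaze]) < 1e-9))
})

test_that("head turns are recovered by the pose estimator", {
  tpl <- the_template()
  sched <- event_schedule(list(event_spec("head_turn", 1, 2, 25, "roll")),
                          session_length = 4, fps = 4)
  sc <- score_stream(render_stream(sched, tpl), cam = tpl$cam)
  during <- sc$t >= 1 & sc$t < 3
  expect_true(all(abs(sc$roll[during] - 25) < 1))
  expect_true(all(abs(sc$roll[!during]) < 0.5))
})

test_that("identical seeds yield bit-identical streams", {
  sched <- function() {
    event_schedule(list(event_spec("closure", 2, 1, 1)),
                   session_length = 5, fps = 4, seed = 99, jitter_sd = 0.5)
  }
  s1 <- render_stream(sched())
  s2 <- render_stream(sched())
  expect_identical(s1, s2)
  s3 <- render_stream(event_schedule(list(event_spec("closure", 2, 1, 1)),
                                     session_length = 5, fps = 4,
                                     seed = 100, jitter_sd = 0.5))
  expect_false(identical(s1$points, s3$points))
})

test_that("schedule validation rejects conflicts and overruns", {
  expect_error(event_schedule(list(event_spec("closure", 1, 5, 1),
                                   event_spec("closure", 3, 2, 0.9)),
                              session_length = 20), "overlapping")
  expect_error(event_schedule(list(event_spec("closure", 1, 5, 1),
                                   event_spec("blink", 2, 0.5, 1)),
                              session_length = 20), "conflicting")
  expect_error(event_schedule(list(event_spec("yawn", 18, 5, 0.8)),
                              session_length = 20), "beyond")
})

test_that("expected_alarms applies the rules in closed form", {
  cfg <- apply_calibration(scorer_config(), default_calib())

  one <- event_schedule(list(event_spec("closure", 10, 5, 1)),
                        session_length = 30, fps = 4)
  ev <- expected_alarms(one, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "asleep")
  expect_equal(ev$onset, 13)

  short <- event_schedule(list(event_spec("closure", 10, 2, 1)),
                          session_length = 30, fps = 4)
  expect_equal(nrow(expected_alarms(short, cfg)), 0L)

  # 5 + 4 + 3 s of closure within one 60 s window: exactly the 20% limit
  # is NOT above it; one extra frame pushes it over
  at_limit <- event_schedule(list(
    event_spec("closure", 6, 5, 1), event_spec("closure", 20, 4, 1),
    event_spec("closure", 40, 3, 1)
  ), session_length = 70, fps = 4)
  expect_false("drowsy" %in% expected_alarms(at_limit, cfg)$kind)
  over <- event_schedule(list(
    event_spec("closure", 6, 5.25, 1), event_spec("closure", 20, 4, 1),
    event_spec("closure", 40, 3, 1)
  ), session_length = 70, fps = 4)
  drowsy <- expected_alarms(over, cfg)
  drowsy <- drowsy[drowsy$kind == "drowsy", ]
  expect_equal(nrow(drowsy), 1L)
  expect_equal(drowsy$onset, 60)
})

test_that("schedules survive YAML and JSON round trips", {
  sched <- simulate_schedule(12)
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_schedule(sched, path)
    back <- read_schedule(path)
    expect_equal(back$session_length, sched$session_length)
    expect_equal(back$fps, sched$fps)
    expect_equal(length(back$events), length(sched$events))
    for (i in seq_along(sched$events)) {
      expect_equal(back$events[[i]]$kind, sched$events[[i]]$kind)
      expect_equal(back$events[[i]]$magnitude, sched$events[[i]]$magnitude)
      expect_equal(back$events[[i]]$start, sched$events[[i]]$start)
    }
    unlink(path)
  }
})
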