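#' Neutral face template for the synthetic stream generator
#'
#' A fixed, documented 68-point frontal face: a 3-D landmark layout in
#' millimetres (image-aligned axes, nose tip at the origin, consistent with
#' [generic_head_model()] at the six rigid anchors) together with the camera
#' and head translation used to project it. The six eye points share one
#' depth plane and the eight inner-lip points another, so the projected
#' aspect ratios equal their planar values exactly: neutral EAR 0.30 and
#' neutral MAR 0.10 (mouth nearly closed) by construction, chosen inside
#' the ranges typically observed on alert subjects.
#'
#' @param cam a [camera_model()].
#' @param head_distance camera-to-nose distance in millimetres.
#' @return list of class `neutral_template` with `points3d` (68 x 3),
#'   `points2d` (68 x 2, the identity-rotation projection), `cam`,
#'   `translation`, and the neutral `ear` and `mar` values.
#' @export
neutral_template <- function(cam = camera_model(), head_distance = 450) {
  ear0 <- 0.30
  mar0 <- 0.10
  eye_h <- ear0 * 42 / 2          # lid half-separation for a 42 mm eye
  lip_g <- mar0 * 76 / 3          # lip half-separation for a 76 mm mouth

  p <- matrix(NA_real_, 68, 3)
  psi <- (0:16) * pi / 16                                  # jaw 1-17
  p[1:17, ] <- cbind(-75 * cos(psi), -20 + 130 * sin(psi),
                     70 - 45 * sin(psi))
  p[18:22, ] <- cbind(c(-63, -52, -41, -30, -19), -72, 38)  # brows
  p[23:27, ] <- cbind(c(19, 30, 41, 52, 63), -72, 38)
  p[28:31, ] <- cbind(0, c(-45, -30, -15, 0), c(28, 18, 8, 0))  # nose ridge
  p[32:36, ] <- cbind(c(-18, -9, 0, 9, 18), 15, 14)            # nostrils
  p[37:42, ] <- cbind(c(-72, -58, -44, -30, -44, -58),         # left eye
                      -55 + c(0, -eye_h, -eye_h, 0, eye_h, eye_h), 40)
  p[43:48, ] <- cbind(c(30, 44, 58, 72, 58, 44),               # right eye
                      -55 + c(0, -eye_h, -eye_h, 0, eye_h, eye_h), 40)
  p[49:60, ] <- cbind(c(-48, -30, -15, 0, 15, 30, 48, 30, 15, 0, -15, -30),
                      c(48, 39, 39, 39, 39, 39, 48, 57, 57, 57, 57, 57),
                      25)                                      # outer lips
  p[61:68, ] <- cbind(c(-38, -19, 0, 19, 38, 19, 0, -19),
                      48 + c(0, -lip_g, -lip_g, -lip_g, 0,
                             lip_g, lip_g, lip_g),
                      25)                                      # inner lips

  translation <- c(0, 0, head_distance)
  pts2d <- project_points(p, diag(3), translation, cam)
  structure(
    list(points3d = p, points2d = pts2d, cam = cam,
         translation = translation, ear = ear0, mar = mar0),
    class = "neutral_template"
  )
}

#' Behavioural event specification
#'
#' One scheduled behaviour driving the synthetic generator. `magnitude`
#' means: for `blink`/`closure`, the fraction by which the vertical lid
#' separation shrinks (1 = fully closed, EAR 0); for `yawn`, the target MAR;
#' for `head_turn`, the rotation angle in degrees about `axis`; for
#' `gaze_shift`, the pupil offset as a (signed) fraction of the eye width.
#'
#' @param kind one of `"blink"`, `"closure"`, `"yawn"`, `"head_turn"`,
#'   `"gaze_shift"`.
#' @param start onset in seconds.
#' @param duration length in seconds (> 0).
#' @param magnitude see above.
#' @param axis rotation axis for `head_turn`: `"yaw"`, `"pitch"`, `"roll"`.
#' @return list of class `event_spec`.
#' @export
event_spec <- function(kind, start, duration, magnitude,
                       axis = c("yaw", "pitch", "roll")) {
  kind <- match.arg(kind, c("blink", "closure", "yawn", "head_turn",
                            "gaze_shift"))
  axis <- match.arg(axis)
  stopifnot(duration > 0, start >= 0, is.finite(magnitude))
  structure(list(kind = kind, start = start, duration = duration,
                 magnitude = magnitude,
                 axis = if (kind == "head_turn") axis),
            class = "event_spec")
}

#' Assemble and validate an event schedule
#'
#' Events of the same kind must not overlap; overlapping eye events of
#' different kinds (a blink inside a sustained closure) are rejected as
#' conflicting since they would prescribe two lid apertures at once. All
#' events must fit within the session.
#'
#' @param events list of [event_spec()].
#' @param session_length session length in seconds.
#' @param fps frame rate (frames are placed at `t = 0, 1/fps, 2/fps, ...`).
#' @param seed integer seed controlling any stochastic rendering component.
#' @param jitter_sd per-coordinate Gaussian landmark jitter in pixels
#'   (default 0: noiseless).
#' @return list of class `event_schedule`.
#' @export
event_schedule <- function(events, session_length, fps = 4, seed = 1L,
                           jitter_sd = 0) {
  stopifnot(fps > 0, session_length > 0, jitter_sd >= 0)
  events <- lapply(events, function(e) {
    stopifnot(inherits(e, "event_spec"))
    if (e$start + e$duration > session_length + 1e-9) {
      stop("event extends beyond the session: ", e$kind, " at ", e$start)
    }
    e
  })
  overlap <- function(a, b) {
    a$start < b$start + b$duration && b$start < a$start + a$duration
  }
  eye_kinds <- c("blink", "closure")
  for (i in seq_along(events)) {
    for (j in seq_len(i - 1L)) {
      a <- events[[i]]; b <- events[[j]]
      if (a$kind == b$kind && overlap(a, b)) {
        stop("overlapping events of kind ", a$kind)
      }
      if (a$kind %in% eye_kinds && b$kind %in% eye_kinds && overlap(a, b)) {
        stop("conflicting simultaneous eye events (", a$kind, "/", b$kind,
             ")")
      }
    }
  }
  structure(list(events = events, session_length = session_length,
                 fps = fps, seed = as.integer(seed), jitter_sd = jitter_sd),
            class = "event_schedule")
}

active_at <- function(e, t) t >= e$start & t < e$start + e$duration

# scale the separation of point pairs about their midpoints by factor s
scale_pairs <- function(pts, pairs, s) {
  for (pr in pairs) {
    c1 <- (pts[pr[1], ] + pts[pr[2], ]) / 2
    pts[pr[1], ] <- c1 + s * (pts[pr[1], ] - c1)
    pts[pr[2], ] <- c1 + s * (pts[pr[2], ] - c1)
  }
  pts
}

#' Render a synthetic landmark stream from an event schedule
#'
#' Per frame, the template is deformed according to the active events:
#' eye events shrink the projected vertical lid separations by
#' `(1 - magnitude)` (so the frame EAR is exactly
#' `(1 - magnitude) * neutral EAR`); yawns rescale the projected inner-lip
#' separations to reach the target MAR exactly (outer lips follow for
#' visual coherence); head turns rotate the 3-D layout and project; gaze
#' shifts write pupil centres offset by `magnitude * eye width` along the
#' eye axis, otherwise pupils sit at the eye centres. Optional Gaussian
#' landmark jitter is controlled by the schedule's seed, making the stream
#' bit-reproducible.
#'
#' @param schedule an [event_schedule()].
#' @param template a [neutral_template()].
#' @return a `landmark_stream`.
#' @export
render_stream <- function(schedule, template = neutral_template()) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(template, "neutral_template"))
  fps <- schedule$fps
  n <- round(schedule$session_length * fps)
  tvec <- (seq_len(n) - 1L) / fps
  cam <- template$cam

  le <- .idx$left_eye; re <- .idx$right_eye; lip <- .idx$inner_lip
  eye_pairs <- list(le[c(2, 6)], le[c(3, 5)], re[c(2, 6)], re[c(3, 5)])
  lip_pairs <- list(lip[c(2, 8)], lip[c(3, 7)], lip[c(4, 6)])
  outer_pairs <- list(c(50, 60), c(51, 59), c(52, 58), c(53, 57), c(54, 56))

  ev <- schedule$events
  kinds <- vapply(ev, function(e) e$kind, character(1))

  pts_arr <- array(NA_real_, dim = c(n, 68L, 2L))
  pl <- matrix(NA_real_, n, 2L)
  pr <- matrix(NA_real_, n, 2L)

  jitter <- if (schedule$jitter_sd > 0) {
    with_seed(schedule$seed,
              array(stats::rnorm(n * 68 * 2, sd = schedule$jitter_sd),
                    dim = c(n, 68L, 2L)))
  }

  for (i in seq_len(n)) {
    t <- tvec[i]
    act <- vapply(ev, active_at, logical(1), t = t)

    turn <- which(act & kinds == "head_turn")
    pts <- if (length(turn)) {
      e <- ev[[turn[1]]]
      ang <- list(yaw = 0, pitch = 0, roll = 0)
      ang[[e$axis]] <- e$magnitude
      R <- euler_to_rotation(ang$yaw, ang$pitch, ang$roll)
      project_points(template$points3d, R, template$translation, cam)
    } else {
      template$points2d
    }

    eye_ev <- which(act & kinds %in% c("blink", "closure"))
    if (length(eye_ev)) {
      pts <- scale_pairs(pts, eye_pairs, 1 - ev[[eye_ev[1]]]$magnitude)
    }

    yawn <- which(act & kinds == "yawn")
    if (length(yawn)) {
      cur <- compute_mar(pts[lip, , drop = FALSE])
      s <- ev[[yawn[1]]]$magnitude / cur
      pts <- scale_pairs(pts, lip_pairs, s)
      pts <- scale_pairs(pts, outer_pairs, s)
    }

    gaze <- which(act & kinds == "gaze_shift")
    offset_frac <- if (length(gaze)) ev[[gaze[1]]]$magnitude else 0
    eye_centre <- function(e) (pts[e[1], ] + pts[e[4], ]) / 2
    eye_axis <- function(e) {
      v <- pts[e[4], ] - pts[e[1], ]
      v / enorm(v)
    }
    wl <- enorm(pts[le[4], ] - pts[le[1], ])
    wr <- enorm(pts[re[4], ] - pts[re[1], ])
    pl[i, ] <- eye_centre(le) + offset_frac * wl * eye_axis(le)
    pr[i, ] <- eye_centre(re) + offset_frac * wr * eye_axis(re)

    if (!is.null(jitter)) pts <- pts + jitter[i, , ]
    pts_arr[i, , ] <- pts
  }

  new_landmark_stream(tvec, pts_arr, pl, pr, rep("gradient", n))
}

# sustained-run flags: TRUE where `cond` has held for >= thresh seconds
sustained_runs <- function(cond, t, thresh) {
  if (!any(cond)) return(rep(FALSE, length(cond)))
  new_run <- cond & !c(FALSE, cond[-length(cond)])
  grp <- cumsum(new_run)
  run_start <- t[new_run][pmax(grp, 1L)]
  cond & (t - run_start >= thresh - 1e-9)
}

flags_to_events <- function(flag, t, kind, delta) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0L) {
    return(data.frame(kind = character(), onset = numeric(),
                      duration = numeric()))
  }
  data.frame(kind = kind, onset = t[starts[on]],
             duration = t[ends[on]] - t[starts[on]] + delta)
}

#' Closed-form expected alarms for a schedule
#'
#' Derives, directly from the event schedule and without rendering a single
#' landmark, every alarm the scoring engine must produce: per-frame
#' indicator conditions follow analytically from the event definitions
#' (an eye event leaves EAR at `(1 - magnitude) * neutral EAR`, a yawn
#' holds MAR at its target, a head turn holds one Euler angle at its
#' magnitude, a gaze shift holds the gaze score at `|magnitude|`), and the
#' sustained-run, gaze-gating and per-window PERCLOS rules are applied to
#' those boolean series. This is the generator's oracle: on noiseless
#' schedules whose eye events do not overlap head turns, the full engine
#' must reproduce it exactly.
#'
#' @param schedule an [event_schedule()].
#' @param cfg a [scorer_config()] with calibrated thresholds.
#' @param calib optional `drowsiness_calibration`; when supplied its
#'   thresholds override `cfg`'s.
#' @param template the [neutral_template()] the stream is rendered from
#'   (source of the neutral EAR).
#' @return data.frame with columns `kind`, `onset`, `duration`.
#' @export
expected_alarms <- function(schedule, cfg, calib = NULL,
                            template = neutral_template()) {
  stopifnot(inherits(schedule, "event_schedule"))
  if (!is.null(calib)) cfg <- apply_calibration(cfg, calib)
  stopifnot(is.finite(cfg$ear_thresh), is.finite(cfg$mar_thresh))
  fps <- schedule$fps
  delta <- 1 / fps
  n <- round(schedule$session_length * fps)
  t <- (seq_len(n) - 1L) / fps
  ev <- schedule$events

  cond <- list(eye = rep(FALSE, n), mouth = rep(FALSE, n),
               pose = rep(FALSE, n), gaze = rep(FALSE, n))
  for (e in ev) {
    on <- active_at(e, t)
    switch(e$kind,
      blink = ,
      closure = {
        if ((1 - e$magnitude) * template$ear < cfg$ear_thresh) {
          cond$eye <- cond$eye | on
        }
      },
      yawn = {
        if (e$magnitude > cfg$mar_thresh) cond$mouth <- cond$mouth | on
      },
      head_turn = {
        lim <- switch(e$axis, yaw = cfg$yaw_thresh, roll = cfg$roll_thresh,
                      pitch = cfg$pitch_thresh)
        if (abs(e$magnitude) > lim) cond$pose <- cond$pose | on
      },
      gaze_shift = {
        if (abs(e$magnitude) > cfg$gaze_thresh) cond$gaze <- cond$gaze | on
      }
    )
  }

  asleep <- sustained_runs(cond$eye, t, cfg$ear_time_thresh)
  yawning <- sustained_runs(cond$mouth, t, cfg$mar_time_thresh)
  distracted <- sustained_runs(cond$pose, t, cfg$pose_time_thresh)
  gaze_distr <- sustained_runs(cond$gaze, t, cfg$gaze_time_thresh) &
    !distracted

  # per-window PERCLOS: window w covers t in [w*P, (w+1)*P); its score is
  # published at the first frame reaching (w+1)*P and holds until the next
  P <- cfg$perclos_time_period
  w_idx <- floor(t / P + 1e-12)
  n_complete <- max(0L, max(w_idx))
  drowsy <- rep(FALSE, n)
  if (n_complete >= 1L) {
    scores <- vapply(seq_len(n_complete) - 1L, function(w) {
      sum(cond$eye & w_idx == w) * delta / P * 100
    }, numeric(1))
    latest <- ifelse(w_idx >= 1L, w_idx, NA_integer_)
    drowsy <- !is.na(latest) & scores[pmin(latest, n_complete)] >
      cfg$perclos_thresh * 100
  }

  out <- rbind(
    flags_to_events(asleep, t, "asleep", delta),
    flags_to_events(yawning, t, "yawning", delta),
    flags_to_events(distracted, t, "distracted", delta),
    flags_to_events(gaze_distr, t, "gaze_distracted", delta),
    flags_to_events(drowsy, t, "drowsy", delta)
  )
  out[order(out$onset, out$kind), , drop = FALSE]
}

#' Draw a random behavioural schedule
#'
#' Samples a session-length schedule of blinks, sustained closures, yawns,
#' head turns and gaze excursions with realistic timing: blinks of
#' 0.3-0.6 s, closures of 3.5-6.5 s, yawns of 4-7 s (the typical yawn
#' duration range), head turns of 4-8 s and gaze excursions of 3-6.5 s.
#' Magnitudes are drawn clear of the decision thresholds so the schedule's
#' expected alarms are unambiguous, and the first 6 s are kept event-free
#' for calibration. Eye events and head turns never overlap (their
#' deformations would compound).
#'
#' @param seed integer seed.
#' @param session_length session length in seconds.
#' @param fps frame rate.
#' @param jitter_sd landmark jitter passed to the schedule.
#' @return an [event_schedule()].
#' @export
simulate_schedule <- function(seed, session_length = 120, fps = 4,
                              jitter_sd = 0) {
  with_seed(seed, {
    guard <- 6                       # calibration window + margin
    placed_exclusive <- list()       # blink/closure/head_turn intervals
    by_kind <- list()

    try_place <- function(kind, dur, exclusive) {
      for (attempt in 1:40) {
        s <- stats::runif(1, guard, session_length - dur)
        iv <- c(s, s + dur)
        clash <- function(ivs) any(vapply(ivs, function(o) {
          iv[1] < o[2] + 0.5 && o[1] < iv[2] + 0.5  # 0.5 s separation
        }, logical(1)))
        if (clash(by_kind[[kind]] %||% list())) next
        if (exclusive && clash(placed_exclusive)) next
        by_kind[[kind]] <<- c(by_kind[[kind]] %||% list(), list(iv))
        if (exclusive) placed_exclusive[[length(placed_exclusive) + 1L]] <<- iv
        return(s)
      }
      NA_real_
    }

    events <- list()
    add <- function(e) events[[length(events) + 1L]] <<- e

    for (i in seq_len(sample(0:3, 1))) {
      s <- try_place("blink", d <- stats::runif(1, 0.3, 0.6), TRUE)
      if (!is.na(s)) add(event_spec("blink", s, d, stats::runif(1, 0.85, 1)))
    }
    for (i in seq_len(sample(0:2, 1))) {
      s <- try_place("closure", d <- stats::runif(1, 3.5, 6.5), TRUE)
      if (!is.na(s)) add(event_spec("closure", s, d,
                                    stats::runif(1, 0.8, 1)))
    }
    for (i in seq_len(sample(0:2, 1))) {
      s <- try_place("yawn", d <- stats::runif(1, 4, 7), FALSE)
      if (!is.na(s)) add(event_spec("yawn", s, d, stats::runif(1, 0.5, 0.8)))
    }
    for (i in seq_len(sample(0:2, 1))) {
      axis <- sample(c("yaw", "roll", "pitch"), 1, prob = c(.4, .4, .2))
      mag <- switch(axis,
                    yaw = stats::runif(1, 35, 55),
                    roll = stats::runif(1, 25, 40),
                    pitch = stats::runif(1, 5, 20)) *
        sample(c(-1, 1), 1)
      s <- try_place("head_turn", d <- stats::runif(1, 4, 8), TRUE)
      if (!is.na(s)) add(event_spec("head_turn", s, d, mag, axis))
    }
    for (i in seq_len(sample(0:2, 1))) {
      s <- try_place("gaze_shift", d <- stats::runif(1, 3, 6.5), FALSE)
      if (!is.na(s)) add(event_spec("gaze_shift", s, d,
                                    stats::runif(1, 0.5, 0.8) *
                                      sample(c(-1, 1), 1)))
    }
    event_schedule(events, session_length, fps = fps, seed = seed,
                   jitter_sd = jitter_sd)
  })
}

#' Write / read an event schedule (YAML or JSON)
#'
#' @param schedule an [event_schedule()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_schedule` returns an [event_schedule()];
#'   `write_schedule` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  x <- list(
    session_length = schedule$session_length, fps = schedule$fps,
    seed = schedule$seed, jitter_sd = schedule$jitter_sd,
    events = lapply(schedule$events, function(e) {
      ev <- list(kind = e$kind, start = e$start, duration = e$duration,
                 magnitude = e$magnitude)
      if (!is.null(e$axis)) ev$axis <- e$axis
      ev
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_schedule
#' @param path file path.
#' @export
read_schedule <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  events <- lapply(x$events, function(e) {
    event_spec(e$kind, e$start, e$duration, e$magnitude,
               axis = e$axis %||% "yaw")
  })
  event_schedule(events, x$session_length, fps = x$fps,
                 seed = x$seed %||% 1L, jitter_sd = x$jitter_sd %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
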