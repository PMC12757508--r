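test_that("cm-to-pixel conversion reproduces the calibrated zone thresholds", {
  expect_identical(cm_to_px(2, 0.458), 44L)
  expect_identical(cm_to_px(6, 0.458), 132L)
  expect_identical(cm_to_px(0, 0.458), 0L)
  expect_identical(cm_to_px(1, 0.5), 20L)   # exact division stays exact
  expect_error(cm_to_px(2, 0), "mm_per_pixel")
})

test_that("distance from the primary end is a clipped axial projection", {
  tr <- trace_from_distance(c(0, 45.8, 91.6))
  expect_equal(distance_from_primary(tr), c(0, 45.8, 91.6))
  expect_equal(tr$frames$x_px[2], 100)  # 100 px at 0.458 mm/px = 45.8 mm

  # reversed axis, y-aligned tube, positions behind the face clip to 0
  fr <- data.frame(frame = 0:2, time_s = (0:2) / 30, x_px = 0,
                   y_px = c(500, 400, 510))
  tr2 <- tracking_trace(fr, 30, 0.5, primary_reference("y", 500, -1))
  expect_equal(distance_from_primary(tr2), c(0, 50, 0))

  set.seed(1)
  for (dir in c(1, -1)) {
    origin <- runif(1, 0, 200)
    x <- runif(50, 0, 400)
    fr <- data.frame(frame = 0:49, time_s = (0:49) / 30, x_px = x, y_px = 0)
    tr3 <- tracking_trace(fr, 30, 0.458, primary_reference("x", origin, dir))
    manual <- vapply(x, function(xx) max(0, dir * (xx - origin) * 0.458),
                     numeric(1))
    expect_equal(distance_from_primary(tr3), manual)
  }
})

test_that("motion labels classify windowed displacement against the dead band", {
  d_toward <- seq(100, 10, by = -3)
  expect_true(all(motion_labels(d_toward, 8, 2) == "toward"))
  expect_true(all(motion_labels(rep(50, 30), 8, 2) == "stationary"))

  set.seed(2)
  zig <- 50 + cumsum(sample(c(-4, 0, 4), 120, replace = TRUE))
  for (w in c(3, 8)) {
    got <- motion_labels(zig, w, 2)
    manual <- vapply(seq_along(zig), function(i) {
      lo <- max(1, i - floor((w - 1) / 2))
      hi <- min(length(zig), i + ceiling((w - 1) / 2))
      delta <- zig[hi] - zig[lo]
      if (delta < -2) "toward" else if (delta > 2) "away" else "stationary"
    }, character(1))
    expect_equal(got, manual)
  }
  expect_error(motion_labels(c(1, 2), 8, 2), "shorter")
})

test_that("bout detection honors the zone and toward-only rules", {
  rule <- zone_rule()

  # entirely beyond the outer boundary: no bouts
  far <- trace_from_distance(90 + sin(1:200) * 10)
  expect_equal(nrow(detect_bouts(far, rule)), 0L)

  # moving outward from 10 mm to 40 mm enters the zone while "away"
  out <- trace_from_distance(seq(10, 40, length.out = 100))
  expect_equal(nrow(detect_bouts(out, rule)), 0L)

  # approach from 80 mm to 30 mm, then stationary: one bout to the end
  d <- c(seq(80, 30, length.out = 60), rep(30, 60))
  tr <- trace_from_distance(d)
  b <- detect_bouts(tr, rule)
  expect_equal(nrow(b), 1L)
  inv <- oracle_investigating(d, 8, 2, 20, 60)
  expect_equal(b$start_s, (which(inv)[1] - 1) / 30)
  expect_equal(b$end_s, 120 / 30)  # runs to the end of the trace
  expect_equal(b$n_frames, sum(inv))
})

test_that("bout detection matches the brute-force per-frame classifier", {
  set.seed(11)
  rule <- zone_rule()
  for (i in 1:200) {
    d <- random_distance_series(150, start = runif(1, 10, 140),
                                step_sd = runif(1, 1, 10))
    tr <- trace_from_distance(d)
    got <- flags_from_bouts(detect_bouts(tr, rule), tr$frames$time_s)
    want <- oracle_investigating(d, 8, 2, 20, 60)
    expect_equal(got, want)
  }
})

test_that("enlarging the outer boundary never shrinks investigation time", {
  set.seed(12)
  for (i in 1:25) {
    d <- random_distance_series(300)
    tr <- trace_from_distance(d)
    totals <- vapply(c(4, 6, 8, 10), function(oc) {
      b <- detect_bouts(tr, zone_rule(outer_cm = oc))
      sum(b$end_s - b$start_s)
    }, numeric(1))
    expect_true(all(diff(totals) >= -1e-9))
  }
})

test_that("frame counts convert to seconds by the average frame rate", {
  expect_equal(frames_to_seconds(30, 30), 1)
  expect_equal(frames_to_seconds(0, 30), 0)
  expect_equal(frames_to_seconds(45, 29.97), 45 / 29.97)
  expect_error(frames_to_seconds(30, 0), "avg_fps")
})

test_that("trial scores split bouts at window boundaries", {
  win <- data.frame(trial = 1:3, stimulus = c("NSA", "NSA", "NSB"),
                    presentation = c(1L, 2L, 1L),
                    t_start_s = c(0, 120, 240), t_on_end_s = c(60, 180, 300),
                    t_end_s = c(120, 240, 360))

  none <- score_trials(data.frame(start_s = numeric(0), end_s = numeric(0)),
                       win)
  expect_equal(none$duration_s, c(0, 0, 0))

  one <- score_trials(data.frame(start_s = 130, end_s = 140), win)
  expect_equal(one$duration_s, c(0, 10, 0))
  expect_equal(one$stimulus, win$stimulus)

  straddle <- score_trials(data.frame(start_s = 115, end_s = 125), win)
  expect_equal(straddle$duration_s, c(5, 5, 0))

  expect_error(score_trials(data.frame(start_s = c(0, 5), end_s = c(10, 15)),
                            win), "overlapping")
  expect_error(score_trials(data.frame(start_s = 5, end_s = 5), win),
               "end_s <= start_s")
})

test_that("trial scores match the interval-intersection oracle", {
  set.seed(13)
  win <- trial_windows(NULL, schedule = build_ohd_schedule(paradigm_config()))
  for (i in 1:50) {
    n <- sample(0:25, 1)
    if (n == 0) {
      bouts <- data.frame(start_s = numeric(0), end_s = numeric(0))
    } else {
      starts <- sort(runif(n, 0, 1500))
      ends <- starts + runif(n, 0.1, 30)
      keep_s <- numeric(0); keep_e <- numeric(0); last_end <- -Inf
      for (j in seq_len(n)) {
        if (starts[j] >= last_end) {
          keep_s <- c(keep_s, starts[j]); keep_e <- c(keep_e, ends[j])
          last_end <- ends[j]
        }
      }
      bouts <- data.frame(start_s = keep_s, end_s = keep_e)
    }
    sc <- score_trials(bouts, win)
    manual <- vapply(seq_len(nrow(win)), function(j)
      oracle_trial_duration(bouts, win$t_start_s[j], win$t_end_s[j]),
      numeric(1))
    expect_equal(sc$duration_s, manual)
    expect_true(all(sc$duration_s <= win$t_end_s - win$t_start_s + 1e-9))
    expect_lte(sum(sc$duration_s), 1440)
  }
})

test_that("manual annotations are normalized and merged into bouts", {
  expect_equal(nrow(import_manual_bouts(data.frame(start_s = numeric(0),
                                                   end_s = numeric(0)))), 0L)

  two <- import_manual_bouts(data.frame(start_s = c(30, 5), end_s = c(40, 10)))
  expect_equal(two$start_s, c(5, 30))
  expect_equal(two$end_s, c(10, 40))
  expect_equal(two$source, c("manual", "manual"))

  expect_error(import_manual_bouts(data.frame(start_s = 10, end_s = 10)),
               "row 1")

  # overlapping rows merge into their union
  set.seed(14)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    starts <- runif(n, 0, 100)
    rows <- data.frame(start_s = starts, end_s = starts + runif(n, 0.5, 20))
    merged <- import_manual_bouts(rows)
    expect_true(all(diff(merged$start_s) > 0))
    expect_true(all(merged$start_s[-1] > merged$end_s[-nrow(merged)]))
    # union length computed on a fine grid
    grid <- seq(0, 125, by = 0.01)
    covered_rows <- rep(FALSE, length(grid))
    for (j in seq_len(n))
      covered_rows <- covered_rows | (grid >= rows$start_s[j] &
                                        grid < rows$end_s[j])
    covered_merged <- rep(FALSE, length(grid))
    for (j in seq_len(nrow(merged)))
      covered_merged <- covered_merged | (grid >= merged$start_s[j] &
                                            grid < merged$end_s[j])
    expect_equal(covered_merged, covered_rows)
  }
})

test_that("manual bouts flow through the same trial-scoring path", {
  win <- data.frame(trial = 1:2, stimulus = c("NSA", "NSA"),
                    presentation = 1:2, t_start_s = c(0, 120),
                    t_on_end_s = c(60, 180), t_end_s = c(120, 240))
  bouts <- import_manual_bouts(data.frame(start_s = c(10, 115),
                                          end_s = c(20, 130)))
  sc <- score_trials(bouts, win, method = "manual")
  expect_equal(sc$method, c("manual", "manual"))
  expect_equal(sc$duration_s, c(15, 10))
})
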