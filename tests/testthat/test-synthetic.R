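test_that("noiseless VOC kinetics match an independent ODE integration", {
  sched <- small_schedule(2, 2, on_s = 30, off_s = 30)
  vp <- voc_params(noise_sd_ppb = 0)
  rec <- simulate_voc_telemetry(sched, vp, seed = 1)
  # fine-step Euler integration of dC/dt = (target - C) / tau
  dt <- 0.001
  t_grid <- seq(0, sched$total_duration_s, by = dt)
  target <- rep(vp$baseline_ppb, length(t_grid))
  tau <- rep(vp$tau_decay_s, length(t_grid))
  for (i in seq_len(nrow(sched$trials))) {
    on <- t_grid >= sched$trials$t_start_s[i] &
      t_grid < sched$trials$t_on_end_s[i]
    target[on] <- 11500
    tau[on] <- vp$tau_rise_s
  }
  C <- numeric(length(t_grid)); C[1] <- vp$baseline_ppb
  for (k in 2:length(t_grid))
    C[k] <- C[k - 1] + dt * (target[k - 1] - C[k - 1]) / tau[k - 1]
  got <- rec$tvoc_primary_ppb
  want <- C[round(rec$time_ms / 1000 / dt) + 1]
  expect_lt(max(abs(got - want)), 1 + 0.6)  # 1 ppb plus Euler/rounding slack

  # closed-form check around one rise time constant into the first trial:
  # B + (P - B) * (1 - exp(-t / tau)), within rounding
  rise <- rec$time_ms / 1000 < 30
  closed <- 50 + (11500 - 50) * (1 - exp(-(rec$time_ms[rise] / 1000) / 10))
  expect_lt(max(abs(got[rise] - closed)), 1)
  at_tau <- which.min(abs(rec$time_ms / 1000 - vp$tau_rise_s))
  expect_lt(abs(got[at_tau] - (50 + (11500 - 50) * (1 - exp(-1)))),
            1 + 0.13 * (11500 - 50) * exp(-1) / 10)  # half-sample slack
})

test_that("long valve-ON readings approach the plateau and respect the cap", {
  sched <- small_schedule(1, 1, on_s = 120, off_s = 10)
  rec <- simulate_voc_telemetry(sched, voc_params(noise_sd_ppb = 0), seed = 1)
  end_on <- rec$tvoc_primary_ppb[rec$time_ms > 110e3 & rec$time_ms < 120e3]
  expect_true(all(abs(end_on - 11500) < 11500 * exp(-10) + 1))

  capped <- simulate_voc_telemetry(sched, voc_params(plateau_ppb = 32000),
                                   seed = 2)
  expect_lte(max(capped$tvoc_primary_ppb), 29000)
  expect_equal(max(capped$tvoc_primary_ppb), 29000)
  expect_gte(min(capped$tvoc_primary_ppb), 0)
  expect_gte(min(capped$tvoc_secondary_ppb), 0)
})

test_that("telemetry and trace generation are seed-deterministic", {
  sched <- small_schedule(2, 1, on_s = 10, off_s = 10)
  expect_identical(simulate_voc_telemetry(sched, seed = 8),
                   simulate_voc_telemetry(sched, seed = 8))
  a <- simulate_agent_trace(sched, seed = 8)
  b <- simulate_agent_trace(sched, seed = 8)
  expect_identical(a$trace$frames, b$trace$frames)
  expect_identical(a$truth_bouts, b$truth_bouts)
  c2 <- simulate_agent_trace(sched, seed = 9)
  expect_false(identical(a$trace$frames$x_px, c2$trace$frames$x_px))
})

test_that("a zero-salience agent hovers at the rest point with negligible investigation", {
  sched <- small_schedule(2, 2, on_s = 30, off_s = 30)
  pars <- agent_params(salience = c(NSA = 0, NSB = 0))
  totals <- vapply(10:14, function(s) {
    sim <- simulate_agent_trace(sched, pars, seed = s)
    expect_lt(abs(mean(sim$x_mm) - pars$rest_point_mm), 6)
    sum(sim$truth_bouts$end_s - sim$truth_bouts$start_s)
  }, numeric(1))
  expect_lt(mean(totals), 0.005 * sched$total_duration_s)
})

test_that("in-zone investigation increases with stimulus salience", {
  sched <- small_schedule(1, 1, on_s = 60, off_s = 60)
  mean_invest <- function(sal, seeds) {
    pars <- agent_params(salience = c(NSA = sal))
    mean(vapply(seeds, function(s) {
      sim <- simulate_agent_trace(sched, pars, seed = s)
      sum(sim$truth_bouts$end_s - sim$truth_bouts$start_s)
    }, numeric(1)))
  }
  seeds <- 1:15
  totals <- vapply(c(0.2, 1, 2.5), mean_invest, numeric(1), seeds = seeds)
  expect_true(all(diff(totals) > 0))
})

test_that("generated sessions are complete, valid and byte-reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  fx <- generate_session(seed = 21, outdir = dir1)

  expect_equal(nrow(fx$schedule$trials), 12L)
  expect_equal(nrow(fx$trace$frames), 1440L * 30L)
  expect_equal(nrow(fx$telemetry), length(seq(0, 1440e3 - 1, by = 260)))
  expect_equal(nrow(validate_valve_events(fx$events)), 0L)
  expect_true(all(fx$telemetry$tvoc_primary_ppb >= 0 &
                    fx$telemetry$tvoc_primary_ppb <= 32768))

  # every reader accepts its fixture file
  expect_identical(read_telemetry(fx$paths$telemetry), fx$telemetry)
  expect_equal(read_valve_events(fx$paths$events), fx$events)
  back <- read_tracking(fx$paths$trace, mm_per_pixel = 0.458, avg_fps = 30)
  expect_equal(back$frames, fx$trace$frames)

  fx2 <- generate_session(seed = 21, outdir = dir2)
  for (f in c("events.csv", "telemetry.csv", "trace.csv", "truth_bouts.csv",
              "truth_params.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("scoring a generated fixture reproduces the ground truth", {
  fx <- generate_session(seed = 33)
  bouts <- detect_bouts(fx$trace)
  auto <- score_trials(bouts, fx$windows)
  truth <- score_trials(fx$truth_bouts, fx$windows)
  # allow two frames per bout boundary in each trial
  n_bouts <- vapply(seq_len(nrow(fx$windows)), function(i)
    sum(fx$truth_bouts$start_s < fx$windows$t_end_s[i] &
          fx$truth_bouts$end_s > fx$windows$t_start_s[i]), numeric(1))
  tol <- 2 * pmax(1, n_bouts) / 30
  expect_true(all(abs(auto$duration_s - truth$duration_s) <= tol))
})

test_that("the expected-salience table encodes geometric habituation", {
  cfg <- paradigm_config()
  flat <- true_effect_table(agent_params(habituation_ratio = 1), cfg)
  for (st in unique(flat$stimulus))
    expect_equal(length(unique(flat$expected_salience[flat$stimulus == st])),
                 1L)

  tab <- true_effect_table(agent_params(salience = c(NSA = 1),
                                        habituation_ratio = 0.5), cfg)
  expect_equal(tab$expected_salience[tab$stimulus == "NSA"], c(1, 0.5, 0.25))
  # habituation diffs negative iff r < 1; dishabituation into SOC positive
  # iff salience_SOC > salience_NSB * r^2
  def <- true_effect_table(agent_params(), cfg)
  expect_true(all(def$expected_salience[def$presentation == 3] <
                    def$expected_salience[def$presentation == 1]))
  expect_gt(def$expected_salience[def$stimulus == "SOC" &
                                    def$presentation == 1],
            def$expected_salience[def$stimulus == "NSB" &
                                    def$presentation == 3])
})

test_that("the habituation ratio is recoverable from scored cohorts", {
  # calibration-curve estimator: simulate small cohorts at known r values,
  # regress the mean third/first duration ratio (odor stimuli) on r, and
  # invert the fit at a held-out cohort's observed ratio
  cfg <- paradigm_config(
    stimuli = ohd_default_stimuli()[c(2, 4), ],  # NSA + SOC
    presentations_per_stimulus = 3, on_s = 30, off_s = 30)
  obs_ratio <- function(r, seed, n = 6) {
    sc <- simulate_cohort_scores(
      n, cfg, agent_params(habituation_ratio = r), seed = seed)
    first <- sc$duration_s[sc$presentation == 1]
    third <- sc$duration_s[sc$presentation == 3]
    sum(third) / sum(first)
  }
  r_grid <- c(0.4, 0.5, 0.6, 0.7, 0.8)
  ratios <- vapply(seq_along(r_grid),
                   function(i) obs_ratio(r_grid[i], seed = 100 + i),
                   numeric(1))
  fit <- stats::lm(ratios ~ r_grid)
  held_out <- obs_ratio(0.6, seed = 777, n = 24)
  r_hat <- (held_out - stats::coef(fit)[[1]]) / stats::coef(fit)[[2]]
  expect_lt(abs(r_hat - 0.6), 0.1)
})
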