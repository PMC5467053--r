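test_that("trace conditioning sets the 5x RMS-noise threshold", {
  set.seed(1)
  tr <- mua_trace(rnorm(60000, 0, 2), 1000)
  env <- condition_trace(tr)  # default 0.2 Hz cutoff
  expect_identical(env$threshold, 5 * env$rms_noise)
  expect_true(all(env$samples >= 0))
  # independent re-application of the documented estimator (envelope median)
  expect_lt(abs(env$rms_noise - median(env$samples)) / env$rms_noise, 0.20)
  # non-default multiple is honoured
  env3 <- condition_trace(tr, threshold_k = 3)
  expect_identical(env3$threshold, 3 * env3$rms_noise)
  # quiet-window estimator
  envq <- condition_trace(tr, quiet_window_s = c(0, 20))
  expect_gt(envq$rms_noise, 0)

  # constant (pure DC) input: offset removal yields all zeros
  expect_error(condition_trace(mua_trace(rep(3.3, 1000), 1000)),
               "constant trace")
})

test_that("detection rules reproduce hand-traced constructed cases", {
  # rectangular excursion of 1.0 s -> one event of duration 1.0 s
  env1 <- step_envelope(data.frame(level = c(0, 2, 0), dur_s = c(2, 1, 2)))
  ev1 <- detect_upstates(env1)
  expect_identical(nrow(ev1), 1L)
  expect_equal(ev1$duration_s, 1.0, tolerance = 2 / env1$sampling_rate_hz)
  expect_equal(ev1$start_s, 2.0, tolerance = 2 / env1$sampling_rate_hz)

  # everywhere sub-threshold -> no events
  env0 <- step_envelope(data.frame(level = 0.5, dur_s = 5))
  expect_identical(nrow(detect_upstates(env0)), 0L)

  # two 0.3 s excursions, 0.4 s apart -> single merged event spanning both
  env2 <- step_envelope(
    data.frame(level = c(0, 2, 0.2, 2, 0), dur_s = c(1, 0.3, 0.4, 0.3, 1)))
  ev2 <- detect_upstates(env2)
  expect_identical(nrow(ev2), 1L)
  expect_equal(ev2$start_s, 1.0, tolerance = 2 / env2$sampling_rate_hz)
  expect_equal(ev2$end_s, 2.0, tolerance = 2 / env2$sampling_rate_hz)

  # a 0.15 s excursion fails the 200 ms rule
  env3 <- step_envelope(data.frame(level = c(0, 2, 0), dur_s = c(1, 0.15, 1)))
  expect_identical(nrow(detect_upstates(env3)), 0L)

  # a dip longer than 600 ms ends the event: two separate events
  env4 <- step_envelope(
    data.frame(level = c(0, 2, 0.2, 2, 0), dur_s = c(1, 0.5, 0.7, 0.5, 1)))
  expect_identical(nrow(detect_upstates(env4)), 2L)

  # amplitude is normalised to the threshold (threshold 1, level 2)
  expect_equal(ev1$amplitude_norm_peak, 2, tolerance = 1e-12)
  expect_equal(ev1$amplitude_norm_mean, 2, tolerance = 1e-12)
})

test_that("detector matches the brute-force rule oracle on random steps", {
  set.seed(42)
  for (i in 1:200) {
    env <- random_step_envelope()
    ev <- detect_upstates(env)
    ref <- detect_upstates_reference(env)
    expect_identical(nrow(ev), nrow(ref))
    if (nrow(ev)) {
      expect_equal(ev$start_s, ref$start_s, tolerance = 1e-12)
      expect_equal(ev$end_s, ref$end_s, tolerance = 1e-12)
    }
  }
})

test_that("detector output satisfies its structural invariants", {
  set.seed(7)
  for (i in 1:50) {
    env <- random_step_envelope()
    ev <- detect_upstates(env)
    if (nrow(ev)) {
      expect_true(all(ev$duration_s >= 0.2))
      expect_false(is.unsorted(ev$start_s))
      if (nrow(ev) > 1) {
        # merge idempotence: all residual gaps exceed the merge window
        gaps <- ev$start_s[-1] - ev$end_s[-nrow(ev)]
        expect_true(all(gaps > 0.6))
      }
      expect_true(all(ev$amplitude_norm_peak >= 1))
    }
    # monotonicity: a higher threshold never increases time above threshold
    t1 <- sum(env$samples > env$threshold)
    t2 <- sum(env$samples > 1.5 * env$threshold)
    expect_lte(t2, t1)
    # lowering the minimum duration never decreases the event count
    expect_gte(nrow(detect_upstates(env, min_dur_s = 0.1)), nrow(ev))
  }
})

test_that("events are recovered exactly from clean synthetic traces", {
  for (seed in 1:3) {
    cfg <- trace_sim_config(
      total_duration_s = 60, sampling_rate_hz = 8000, event_rate_hz = 0.1,
      duration_mean_s = 1.0, duration_sd_s = 0.25, duration_min_s = 0.5,
      min_gap_s = 1.0, up_gain = 8, seed = seed
    )
    sch <- draw_schedule(cfg)
    sim <- synthesize_trace(sch, cfg)
    env <- condition_trace(sim$trace, cutoff_hz = 2)
    ev <- detect_upstates(env)
    ev <- ev[!ev$truncated, , drop = FALSE]
    expect_identical(nrow(ev), nrow(sch))
    expect_true(all(abs(ev$start_s - sch$start_s) <= env$settling_s))
    expect_true(all(abs(ev$end_s - sch$end_s) <= env$settling_s))
  }
})

test_that("slice summaries aggregate events within the analysis window", {
  empty <- detect_upstates(step_envelope(data.frame(level = 0, dur_s = 2)))
  s0 <- summarize_slice(empty)
  expect_identical(s0$n_events, 0L)
  expect_length(s0$durations_s, 0)
  expect_true(is.na(s0$mean_duration_s))

  env <- step_envelope(data.frame(
    level = c(0, 2, 0, 2, 0, 2, 0), dur_s = c(1, 0.5, 1, 1.0, 1, 1.5, 1)))
  ev <- detect_upstates(env)
  s <- summarize_slice(ev, window_s = 7)
  expect_identical(s$n_events, 3L)
  expect_equal(s$mean_duration_s, 1.0, tolerance = 0.02)
  expect_length(s$amplitudes, 3)

  # events outside the window are rejected
  expect_error(summarize_slice(ev, window_s = 3), "outside")

  # truncated events are excluded from duration statistics by default
  envt <- step_envelope(data.frame(level = c(2, 0, 2, 0), dur_s = c(1, 2, 1, 1)))
  evt <- detect_upstates(envt)
  expect_true(any(evt$truncated))
  st <- summarize_slice(evt, window_s = 5)
  expect_identical(st$n_events, sum(!evt$truncated))
})
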