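test_that("schedule generation respects rate, gaps and the duration floor", {
  cfg <- trace_sim_config(total_duration_s = 300, event_rate_hz = 0.05,
                          duration_mean_s = 1.0, duration_sd_s = 0.3,
                          seed = 11)
  sch <- draw_schedule(cfg)
  # direct count of the emitted schedule, ~ rate * duration (Poisson spread)
  expect_gt(nrow(sch), 6)
  expect_lt(nrow(sch), 26)
  expect_false(is.unsorted(sch$start_s))
  if (nrow(sch) > 1) {
    gaps <- sch$start_s[-1] - sch$end_s[-nrow(sch)]
    expect_true(all(gaps > 0.6))
  }
  expect_true(all(sch$duration_s >= 0.2))
  expect_true(all(sch$end_s <= 300))

  # no events requested
  expect_identical(
    nrow(draw_schedule(trace_sim_config(event_rate_hz = 0, seed = 1))), 0L)

  # duration floor: sub-minimum draws are clamped, not rejected
  cfg2 <- trace_sim_config(event_rate_hz = 0.05, duration_mean_s = 0.1,
                           duration_sd_s = 0, seed = 2)
  sch2 <- draw_schedule(cfg2)
  expect_true(all(sch2$duration_s == 0.2))

  # infeasible regime is rejected up front
  expect_error(
    draw_schedule(trace_sim_config(event_rate_hz = 0.9,
                                   duration_mean_s = 2, seed = 1)),
    "infeasible"
  )
})

test_that("schedule invariants hold over random accepted configs", {
  set.seed(99)
  for (i in 1:25) {
    cfg <- trace_sim_config(
      total_duration_s = runif(1, 30, 120),
      event_rate_hz = runif(1, 0.02, 0.3),
      duration_mean_s = runif(1, 0.3, 2),
      duration_sd_s = runif(1, 0, 0.6),
      min_gap_s = runif(1, 0.61, 1.5),
      seed = i
    )
    if (cfg$event_rate_hz * cfg$duration_mean_s >= 1) next
    sch <- draw_schedule(cfg)
    if (nrow(sch) > 1) {
      gaps <- sch$start_s[-1] - sch$end_s[-nrow(sch)]
      expect_true(all(gaps > 0.6))
      expect_true(all(diff(sch$start_s) > 0))
    }
    expect_true(all(sch$duration_s >= cfg$duration_min_s))
    expect_true(all(sch$start_s >= 0 & sch$end_s <= cfg$total_duration_s))
  }
})

test_that("trace synthesis is deterministic and gain-modulates as scheduled", {
  cfg <- trace_sim_config(total_duration_s = 10, sampling_rate_hz = 8000,
                          event_rate_hz = 0.1, seed = 5)
  s1 <- synthesize_trace(draw_schedule(cfg), cfg)
  s2 <- synthesize_trace(draw_schedule(cfg), cfg)
  expect_identical(s1$trace$samples, s2$trace$samples)
  expect_identical(s1$truth$schedule, s2$truth$schedule)

  # stationarity with no events: RMS of disjoint halves within 10%
  cfg0 <- trace_sim_config(total_duration_s = 10, sampling_rate_hz = 8000,
                           event_rate_hz = 0, seed = 6)
  tr0 <- synthesize_trace(draw_schedule(cfg0), cfg0)$trace
  n <- length(tr0$samples)
  r1 <- sqrt(mean(tr0$samples[1:(n / 2)]^2))
  r2 <- sqrt(mean(tr0$samples[(n / 2 + 1):n]^2))
  expect_lt(abs(r1 - r2) / r1, 0.10)

  # a single 1 s epoch at gain 5 raises the in-epoch RMS ~5x
  cfg1 <- trace_sim_config(total_duration_s = 6, sampling_rate_hz = 8000,
                           event_rate_hz = 0.1, up_gain = 5, seed = 7)
  sch1 <- structure(
    data.frame(start_s = 2.5, duration_s = 1, end_s = 3.5),
    total_duration_s = 6, class = c("upstate_schedule", "data.frame")
  )
  tr1 <- synthesize_trace(sch1, cfg1)$trace
  fs <- tr1$sampling_rate_hz
  inside <- tr1$samples[(2.5 * fs + 1):(3.5 * fs)]
  outside <- tr1$samples[1:(2 * fs)]
  ratio <- sqrt(mean(inside^2)) / sqrt(mean(outside^2))
  expect_gt(ratio, 4)
  expect_lt(ratio, 6)

  # schedule must fit inside the trace
  bad <- structure(
    data.frame(start_s = 5.8, duration_s = 1, end_s = 6.8),
    total_duration_s = 6, class = c("upstate_schedule", "data.frame")
  )
  expect_error(synthesize_trace(bad, cfg1), "fit inside")
})

test_that("cohort simulation honours group sizes, truth and determinism", {
  cfg <- cohort_sim_config(seed = 21)  # 13/13/15/17 default layout
  sim <- simulate_cohort(cfg)
  counts <- table(sim$cohort$group[sim$cohort$measure == "seizure_score"])
  expect_identical(
    as.integer(counts[c("WT:SAL", "WT:Acamp", "KO:SAL", "KO:Acamp")]),
    c(13L, 13L, 15L, 17L)
  )
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$cohort, sim2$cohort)

  # degenerate seizure distribution: all KO animals score 4
  groups <- c("WT:SAL", "KO:SAL")
  probs <- rbind("WT:SAL" = c(1, 0, 0, 0, 0), "KO:SAL" = c(0, 0, 0, 0, 1))
  colnames(probs) <- as.character(0:4)
  cfgd <- cohort_sim_config(
    n_per_group = c("WT:SAL" = 5, "KO:SAL" = 5),
    measures = list(seizure_score = list(type = "ordinal", probs = probs)),
    seed = 3
  )
  simd <- simulate_cohort(cfgd)
  expect_true(all(simd$cohort$value[simd$cohort$genotype == "KO"] == 4))
  expect_true(all(simd$cohort$value[simd$cohort$genotype == "WT"] == 0))

  # invalid probability vector is rejected
  probs_bad <- probs; probs_bad[1, 1] <- 0.5
  expect_error(
    cohort_sim_config(n_per_group = c("WT:SAL" = 5, "KO:SAL" = 5),
                      measures = list(s = list(type = "ordinal",
                                               probs = probs_bad))),
    "sum to 1"
  )
})

test_that("empirical group means converge to configured means at large n", {
  cfg <- cohort_sim_config(
    n_per_group = c("WT:SAL" = 10000, "KO:SAL" = 10000),
    measures = list(m = list(type = "continuous", baseline = 40, sd = 12,
                             gene_effect = 5)),
    seed = 12
  )
  sim <- simulate_cohort(cfg)
  truth <- sim$truth$m$group_means
  se <- 12 / sqrt(10000)
  for (g in names(truth)) {
    emp <- mean(sim$cohort$value[sim$cohort$group == g])
    expect_lt(abs(emp - truth[[g]]), 3 * se)
  }
})
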