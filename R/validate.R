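# Simulation studies: oracle-agreement, recovery, calibration and power
# runs used to validate the toolkit end to end on synthetic ground truth.

random_step_env <- function(max_s = 60, fs = 20, threshold = 1) {
  n_seg <- sample(3:30, 1)
  durs <- stats::runif(n_seg, 0.05, max_s / n_seg)
  levels <- stats::runif(n_seg, 0, 2)
  samples <- unlist(mapply(function(lv, d) rep(lv, round(d * fs)),
                           levels, durs, SIMPLIFY = FALSE))
  mua_envelope(samples, fs, threshold = threshold)
}

#' Detector vs brute-force rule oracle agreement
#'
#' Generates random step-function envelopes on a coarse grid and compares
#' [detect_upstates()] with the literal rule-by-rule reference
#' implementation [detect_upstates_reference()], event by event.
#'
#' @param n_envelopes Number of random envelopes.
#' @param seed RNG seed.
#' @param max_s Maximum envelope duration (s).
#' @param fs Envelope grid rate (Hz).
#' @return List: `n`, `n_agree`, `agreement_pct`.
#' @export
detector_oracle_agreement <- function(n_envelopes = 1000, seed = 1,
                                      max_s = 60, fs = 20) {
  set.seed(as.integer(seed))
  agree <- logical(n_envelopes)
  for (i in seq_len(n_envelopes)) {
    env <- random_step_env(max_s = max_s, fs = fs)
    ev <- detect_upstates(env)
    ref <- detect_upstates_reference(env)
    agree[i] <- nrow(ev) == nrow(ref) &&
      (nrow(ev) == 0 ||
         (max(abs(ev$start_s - ref$start_s)) < 1e-9 &&
          max(abs(ev$end_s - ref$end_s)) < 1e-9))
  }
  list(n = n_envelopes, n_agree = sum(agree),
       agreement_pct = 100 * mean(agree))
}

#' Detector recovery on clean synthetic traces
#'
#' Synthesizes seeded traces whose ground-truth events are long and well
#' separated (durations >= 0.5 s, gaps >= 1 s) with a strong UP gain, runs
#' the full conditioning + detection chain, and scores per-trace event-count
#' exactness and boundary placement against the documented filter settling
#' time.
#'
#' @param n_traces Number of traces.
#' @param seed RNG seed.
#' @param total_duration_s,sampling_rate_hz Trace geometry.
#' @param cutoff_hz Envelope cutoff used for detection (default 2 Hz, which
#'   resolves the simulated ~1 s regime; see the methods vignette).
#' @param up_gain UP-state amplitude gain (>= 5 for clean separation).
#' @return List: `per_trace` data frame (`n_true`, `n_detected`,
#'   `max_boundary_err_s`), `settling_s`, `exact_count_pct`,
#'   `boundary_within_settling_pct`.
#' @export
detector_recovery <- function(n_traces = 50, seed = 1,
                              total_duration_s = 300,
                              sampling_rate_hz = 10000, cutoff_hz = 2,
                              up_gain = 8) {
  set.seed(as.integer(seed))
  res <- data.frame(n_true = integer(n_traces),
                    n_detected = integer(n_traces),
                    max_boundary_err_s = numeric(n_traces))
  settling <- NA_real_
  for (i in seq_len(n_traces)) {
    cfg <- trace_sim_config(
      sampling_rate_hz = sampling_rate_hz,
      total_duration_s = total_duration_s,
      event_rate_hz = 0.1, duration_mean_s = 1.0, duration_sd_s = 0.25,
      duration_min_s = 0.5, min_gap_s = 1.0, up_gain = up_gain,
      seed = NULL
    )
    sch <- draw_schedule(cfg)
    sim <- synthesize_trace(sch, cfg)
    env <- condition_trace(sim$trace, cutoff_hz = cutoff_hz)
    settling <- env$settling_s
    ev <- detect_upstates(env)
    ev <- ev[!ev$truncated, , drop = FALSE]
    res$n_true[i] <- nrow(sch)
    res$n_detected[i] <- nrow(ev)
    res$max_boundary_err_s[i] <- if (nrow(ev) == nrow(sch) && nrow(ev)) {
      max(abs(ev$start_s - sch$start_s), abs(ev$end_s - sch$end_s))
    } else if (nrow(ev) == 0 && nrow(sch) == 0) 0 else Inf
  }
  list(
    per_trace = res, settling_s = settling,
    exact_count_pct = 100 * mean(res$n_true == res$n_detected),
    boundary_within_settling_pct =
      100 * mean(res$max_boundary_err_s <= settling)
  )
}

#' Exact Wilcoxon vs enumeration oracle agreement
#'
#' Random tied-integer datasets over every sample-size pair with
#' `n_x + n_y <= max_n` are scored with both [exact_wilcoxon()] (counting
#' recursion) and [wilcoxon_reference()] (subset enumeration), for all
#' three tail options.
#'
#' @param n_datasets Number of random datasets (cycled over the size pairs).
#' @param seed RNG seed.
#' @param max_n Maximum pooled sample size.
#' @return List: `n`, `max_abs_diff`, `agreement_pct` (p-values equal to
#'   1e-12).
#' @export
wilcoxon_oracle_agreement <- function(n_datasets = 500, seed = 1,
                                      max_n = 10) {
  set.seed(as.integer(seed))
  pairs <- do.call(rbind, lapply(2:max_n, function(N) {
    cbind(nx = 1:(N - 1), ny = N - (1:(N - 1)))
  }))
  max_diff <- 0
  ok <- logical(n_datasets)
  for (i in seq_len(n_datasets)) {
    pr <- pairs[((i - 1) %% nrow(pairs)) + 1L, ]
    x <- sample(0:4, pr["nx"], replace = TRUE)
    y <- sample(0:4, pr["ny"], replace = TRUE)
    diffs <- vapply(c("two", "less", "greater"), function(tl) {
      abs(exact_wilcoxon(x, y, tails = tl)$p.value -
            wilcoxon_reference(x, y, tails = tl))
    }, numeric(1))
    max_diff <- max(max_diff, diffs)
    ok[i] <- all(diffs <= 1e-12)
  }
  list(n = n_datasets, max_abs_diff = max_diff,
       agreement_pct = 100 * mean(ok))
}

#' Null calibration of the factorial ANOVA gene test
#'
#' Simulates replicate null cohorts (two genotypes by three drug arms, all
#' effect sizes zero) and reports the rejection rate of the genotype main
#' effect at `alpha`.
#'
#' @param n_rep Number of replicate cohorts.
#' @param n_per_cell Animals per genotype x drug cell.
#' @param alpha Test level.
#' @param seed RNG seed.
#' @return List: `n_rep`, `rejection_rate_pct`.
#' @export
anova_null_calibration <- function(n_rep = 2000, n_per_cell = 11,
                                   alpha = 0.05, seed = 1) {
  set.seed(as.integer(seed))
  groups <- as.vector(outer(c("WT", "KO"), c("SAL", "CaCl2", "Acamp"),
                            paste, sep = ":"))
  n_per_group <- stats::setNames(rep(n_per_cell, length(groups)), groups)
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- cohort_sim_config(
      n_per_group = n_per_group,
      measures = list(m = list(type = "continuous", baseline = 0, sd = 1)),
      seed = NULL
    )
    mt <- measure_table(simulate_cohort(cfg)$cohort, "m")
    res <- factorial_anova(mt, "value")
    rej[r] <- res$p_raw[res$effect == "genotype"] < alpha
  }
  list(n_rep = n_rep, rejection_rate_pct = 100 * mean(rej))
}

#' Power to recover a genotype effect on UP-state duration
#'
#' End-to-end effect recovery at the UP-state study's slice counts: per
#' replicate, per-slice traces are synthesized (scaled-down geometry, see
#' the methods vignette), conditioned and detected, slice mean durations
#' are compared by factorial ANOVA with an FDR-corrected pairwise family,
#' and the genotype effect counts as detected when the gene main effect is
#' significant and the KO-vs-WT control comparison survives FDR.
#'
#' @param n_rep Number of replicates.
#' @param slice_counts Named slices per group (defaults: WT:VEH 16,
#'   WT:Acamp 14, KO:VEH 27, KO:Acamp 25).
#' @param ko_duration_factor Multiplier on the KO mean UP-state duration
#'   (default 1.5).
#' @param total_duration_s,sampling_rate_hz,band_low_hz,band_high_hz
#'   Scaled-down trace geometry per slice.
#' @param alpha,q Significance and FDR levels.
#' @param seed RNG seed.
#' @return List: `n_rep`, `power_pct`.
#' @export
upstate_effect_power <- function(n_rep = 200,
                                 slice_counts = c("WT:VEH" = 16,
                                                  "WT:Acamp" = 14,
                                                  "KO:VEH" = 27,
                                                  "KO:Acamp" = 25),
                                 ko_duration_factor = 1.5,
                                 total_duration_s = 10,
                                 sampling_rate_hz = 2000,
                                 band_low_hz = 200, band_high_hz = 800,
                                 alpha = 0.05, q = 0.05, seed = 1) {
  set.seed(as.integer(seed))
  grp <- rep(names(slice_counts), slice_counts)
  wt_mean <- 1.0
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    dur <- vapply(grp, function(g) {
      cfg <- trace_sim_config(
        sampling_rate_hz = sampling_rate_hz,
        total_duration_s = total_duration_s,
        event_rate_hz = 0.2,
        duration_mean_s = if (startsWith(g, "KO"))
          wt_mean * ko_duration_factor else wt_mean,
        duration_sd_s = 0.2, duration_min_s = 0.5, min_gap_s = 1.0,
        up_gain = 8, band_low_hz = band_low_hz,
        band_high_hz = band_high_hz, seed = NULL
      )
      sim <- synthesize_trace(draw_schedule(cfg), cfg)
      ev <- detect_upstates(condition_trace(sim$trace, cutoff_hz = 2))
      sm <- summarize_slice(ev, window_s = total_duration_s)
      sm$mean_duration_s
    }, numeric(1))
    d <- data.frame(
      group = grp,
      genotype = geno_of(grp), drug = drug_of(grp),
      value = dur, stringsAsFactors = FALSE
    )
    d <- d[!is.na(d$value), , drop = FALSE]  # slices with no events
    an <- factorial_anova(d, "value")
    pf <- pairwise_family(d, "value", q = q)
    key <- grepl("KO:VEH", pf$effect) & grepl("WT:VEH", pf$effect)
    hits[r] <- an$p_raw[an$effect == "genotype"] < alpha &&
      any(pf$p_adj[key] <= q)
  }
  list(n_rep = n_rep, power_pct = 100 * mean(hits))
}
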