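#' Condition a trace into a detection envelope
#'
#' Reproduces the offline conditioning used for UP-state analysis of
#' extracellular MUA recordings: the trace is offset to zero (mean
#' subtracted), rectified (absolute value), and low-pass filtered. The
#' detection threshold is set at `threshold_k` (default 5) times the RMS
#' noise of the eventless envelope.
#'
#' Because the low-pass cutoff is orders of magnitude below the sampling
#' rate, the rectified signal is first block-averaged down to an internal
#' envelope rate (>= 100 Hz and >= 25x the cutoff) before the zero-phase
#' Butterworth (order 4) filter is applied; this keeps the filter
#' numerically well-conditioned while leaving crossing-time resolution far
#' below the 200/600 ms rule constants.
#'
#' The RMS noise of the baseline envelope is estimated robustly as the
#' median of the conditioned envelope: DOWN states dominate the recording
#' and the quiet-period envelope is nearly constant, so its median equals
#' its RMS to within the envelope ripple, while UP epochs (a minority of
#' samples) cannot drag the median. A user-designated quiet window can be
#' supplied instead, in which case the RMS is computed directly over it.
#'
#' @param trace A [mua_trace()] (or `sim_trace`, whose trace is used).
#' @param cutoff_hz Low-pass cutoff in Hz (default 0.2). Note that a 0.2 Hz
#'   filter smooths over several seconds and cannot resolve events on the
#'   ~1 s scale; use a cutoff of a few Hz to resolve that regime (see the
#'   methods vignette).
#' @param threshold_k Threshold multiple of the RMS noise (default 5).
#' @param quiet_window_s Optional `c(start, end)` in seconds of an eventless
#'   segment over which to compute the RMS noise directly.
#' @param env_fs_hz Optional internal envelope sampling rate override (Hz).
#' @return An object of class `mua_envelope`: nonnegative envelope samples,
#'   `sampling_rate_hz`, `rms_noise`, `threshold` (= `threshold_k *
#'   rms_noise`), `cutoff_hz`, and the documented filter `settling_s`
#'   (`0.5 / cutoff_hz`, a conservative bound on the zero-phase 10-90% step
#'   rise time, measured at ~0.44 / cutoff).
#' @examples
#' tr <- mua_trace(rnorm(20000), 2000)
#' env <- condition_trace(tr, cutoff_hz = 2)
#' env$threshold / env$rms_noise
#' @export
condition_trace <- function(trace, cutoff_hz = 0.2, threshold_k = 5,
                            quiet_window_s = NULL, env_fs_hz = NULL) {
  if (inherits(trace, "sim_trace")) trace <- trace$trace
  stopifnot(inherits(trace, "mua_trace"), cutoff_hz > 0, threshold_k > 0)
  fs <- trace$sampling_rate_hz
  if (cutoff_hz >= fs / 2) stop("cutoff_hz must be below the Nyquist rate")
  x <- trace$samples - mean(trace$samples)
  if (all(x == 0)) {
    stop("constant trace: offset removal yields all zeros, RMS noise is ",
         "undefined")
  }
  rect <- abs(x)
  target_fs <- if (is.null(env_fs_hz)) min(fs, max(100, 25 * cutoff_hz)) else env_fs_hz
  dec <- max(1L, floor(fs / target_fs))
  if (dec > 1L) {
    n_keep <- (length(rect) %/% dec) * dec
    env0 <- colMeans(matrix(rect[seq_len(n_keep)], nrow = dec))
    env_fs <- fs / dec
  } else {
    env0 <- rect
    env_fs <- fs
  }
  if (cutoff_hz >= env_fs / 2) {
    stop("cutoff_hz must be below the internal envelope Nyquist rate; ",
         "raise env_fs_hz")
  }
  lp <- signal::butter(4, cutoff_hz / (env_fs / 2), type = "low")
  env <- as.numeric(signal::filtfilt(lp, env0))
  env[env < 0] <- 0  # zero-phase filtering can undershoot slightly
  if (!is.null(quiet_window_s)) {
    stopifnot(length(quiet_window_s) == 2L,
              quiet_window_s[1] < quiet_window_s[2])
    idx <- which(
      (seq_along(env) - 1L) / env_fs >= quiet_window_s[1] &
      (seq_along(env) - 1L) / env_fs < quiet_window_s[2]
    )
    if (!length(idx)) stop("quiet window contains no envelope samples")
    rms_noise <- sqrt(mean(env[idx]^2))
  } else {
    rms_noise <- stats::median(env)
  }
  if (!is.finite(rms_noise) || rms_noise <= 0) {
    stop("RMS noise estimate is not positive; threshold undefined")
  }
  mua_envelope(env, env_fs, threshold = threshold_k * rms_noise,
               rms_noise = rms_noise, cutoff_hz = cutoff_hz,
               threshold_k = threshold_k)
}

#' Construct a detection envelope directly
#'
#' Mostly useful for testing the detection rules on constructed
#' (step-function) envelopes; [condition_trace()] is the normal entry point.
#'
#' @param samples Nonnegative envelope samples (a.u.).
#' @param sampling_rate_hz Envelope sampling rate (Hz).
#' @param threshold Detection threshold (a.u.).
#' @param rms_noise Baseline RMS noise; defaults to `threshold / 5`.
#' @param cutoff_hz,threshold_k Bookkeeping metadata.
#' @return An object of class `mua_envelope`.
#' @export
mua_envelope <- function(samples, sampling_rate_hz, threshold,
                         rms_noise = threshold / 5, cutoff_hz = NA_real_,
                         threshold_k = threshold / rms_noise) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) > 0, all(is.finite(samples)), all(samples >= 0),
            sampling_rate_hz > 0, threshold > 0, rms_noise > 0)
  structure(
    list(
      samples = samples, sampling_rate_hz = sampling_rate_hz,
      threshold = threshold, rms_noise = rms_noise,
      threshold_k = threshold_k, cutoff_hz = cutoff_hz,
      settling_s = if (is.finite(cutoff_hz)) 0.5 / cutoff_hz else NA_real_,
      duration_s = length(samples) / sampling_rate_hz
    ),
    class = "mua_envelope"
  )
}

#' @export
print.mua_envelope <- function(x, ...) {
  cat(sprintf(
    "<mua_envelope> %d samples @ %g Hz (%.2f s); rms_noise %.4g, threshold %.4g (%.3gx)\n",
    length(x$samples), x$sampling_rate_hz, x$duration_s, x$rms_noise,
    x$threshold, x$threshold_k
  ))
  invisible(x)
}

#' @export
plot.mua_envelope <- function(x, events = NULL, ...) {
  t <- (seq_along(x$samples) - 1L) / x$sampling_rate_hz
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "envelope (a.u.)", ...)
  graphics::abline(h = x$threshold, lty = 2)
  if (!is.null(events) && nrow(events)) {
    graphics::rect(events$start_s, 0, events$end_s, max(x$samples),
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  invisible(x)
}

#' Detect UP states in a conditioned envelope
#'
#' Applies the three detection rules to the threshold-crossed envelope:
#' an event must remain above threshold for at least `min_dur_s` (200 ms);
#' an event ends only when the envelope stays below threshold for more than
#' `end_gap_s` (600 ms), so shorter sub-threshold dips do not terminate it;
#' and two events within `merge_gap_s` (600 ms) of one another are grouped
#' into a single UP state.
#'
#' Concretely: maximal above-threshold runs are extracted at sample
#' resolution (half-open `[start, end)` intervals, 0-based); consecutive
#' runs separated by gaps `<= end_gap_s` are bridged; candidates whose span
#' is shorter than `min_dur_s` are discarded; remaining events with gaps
#' `<= merge_gap_s` are merged. Event duration is the full span
#' `end_s - start_s` (bridged dips included). Amplitude is the envelope
#' within the event divided by the threshold; both the event mean (the
#' headline statistic) and the peak are reported.
#'
#' @param env An `mua_envelope`.
#' @param min_dur_s Minimum event duration in seconds (default 0.2).
#' @param end_gap_s Maximum sub-threshold dip that does not end an event
#'   (default 0.6).
#' @param merge_gap_s Maximum gap between events that are grouped (default
#'   0.6).
#' @return A data frame of class `upstate_events` with columns `start_s`,
#'   `end_s`, `duration_s`, `amplitude_norm_mean`, `amplitude_norm_peak`,
#'   `truncated` (event touches the trace boundary, so its true duration is
#'   unknown). An empty data frame is a valid result.
#' @examples
#' env <- mua_envelope(c(rep(0, 50), rep(2, 100), rep(0, 50)), 100,
#'                     threshold = 1)
#' detect_upstates(env)
#' @export
detect_upstates <- function(env, min_dur_s = 0.2, end_gap_s = 0.6,
                            merge_gap_s = 0.6) {
  stopifnot(inherits(env, "mua_envelope"),
            min_dur_s >= 0, end_gap_s >= 0, merge_gap_s >= 0)
  fs <- env$sampling_rate_hz
  above <- env$samples > env$threshold
  empty <- structure(
    data.frame(start_s = numeric(), end_s = numeric(),
               duration_s = numeric(), amplitude_norm_mean = numeric(),
               amplitude_norm_peak = numeric(), truncated = logical()),
    threshold = env$threshold, sampling_rate_hz = fs,
    class = c("upstate_events", "data.frame")
  )
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values] - 1L  # 0-based half-open sample indices
  run_end <- ends[r$values]
  # bridge sub-threshold dips <= end_gap_s
  b <- bridge_runs(run_start, run_end, end_gap_s * fs)
  # minimum-duration rule on the bridged span
  keep <- (b$end - b$start) / fs >= min_dur_s
  b <- list(start = b$start[keep], end = b$end[keep])
  if (!length(b$start)) return(empty)
  # group events within merge_gap_s
  b <- bridge_runs(b$start, b$end, merge_gap_s * fs)
  start_s <- b$start / fs
  end_s <- b$end / fs
  amp <- vapply(seq_along(b$start), function(i) {
    seg <- env$samples[(b$start[i] + 1L):b$end[i]]
    c(mean(seg), max(seg)) / env$threshold
  }, numeric(2))
  out <- data.frame(
    start_s = start_s, end_s = end_s,
    duration_s = (b$end - b$start) / fs,  # integer span avoids float drift
    amplitude_norm_mean = amp[1L, ], amplitude_norm_peak = amp[2L, ],
    truncated = b$start == 0L | b$end == length(env$samples)
  )
  structure(out, threshold = env$threshold, sampling_rate_hz = fs,
            class = c("upstate_events", "data.frame"))
}

# Merge half-open integer runs whose gap (in samples) is <= max_gap_samples.
bridge_runs <- function(start, end, max_gap_samples) {
  if (length(start) <= 1L) return(list(start = start, end = end))
  out_s <- start[1L]; out_e <- end[1L]
  for (i in 2L:length(start)) {
    if (start[i] - out_e[length(out_e)] <= max_gap_samples) {
      out_e[length(out_e)] <- end[i]
    } else {
      out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
    }
  }
  list(start = out_s, end = out_e)
}

#' @export
print.upstate_events <- function(x, ...) {
  cat(sprintf("<upstate_events> %d event(s), threshold %.4g\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x)) print.data.frame(utils::head(x, 10L), digits = 4)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Summarize detected UP states for one slice
#'
#' Collapses an event list into the per-slice quantities reported for 5-min
#' recordings: number of events, durations, and threshold-normalised
#' amplitudes. Events truncated by the trace boundary have unknown true
#' duration and are excluded by default.
#'
#' @param events An `upstate_events` data frame (see [detect_upstates()]).
#' @param window_s Analysis window in seconds (default 300 = 5 min). Events
#'   outside `[0, window_s]` are an error.
#' @param drop_truncated Exclude boundary-truncated events (default `TRUE`).
#' @return A list of class `slice_summary`: `n_events`, `durations_s`,
#'   `amplitudes` (event-mean normalised amplitude), `mean_duration_s`,
#'   `mean_amplitude`, `window_s`.
#' @examples
#' env <- mua_envelope(c(rep(0, 50), rep(2, 100), rep(0, 50)), 100,
#'                     threshold = 1)
#' summarize_slice(detect_upstates(env), window_s = 2)
#' @export
summarize_slice <- function(events, window_s = 300, drop_truncated = TRUE) {
  stopifnot(inherits(events, "upstate_events"), window_s > 0)
  if (nrow(events)) {
    if (is.unsorted(events$start_s)) stop("events must be sorted by start")
    if (min(events$start_s) < 0 || max(events$end_s) > window_s + 1e-9) {
      stop("events fall outside the [0, window_s] analysis window")
    }
    if (drop_truncated) events <- events[!events$truncated, , drop = FALSE]
  }
  structure(
    list(
      n_events = nrow(events),
      durations_s = events$duration_s,
      amplitudes = events$amplitude_norm_mean,
      mean_duration_s = if (nrow(events)) mean(events$duration_s) else NA_real_,
      mean_amplitude = if (nrow(events)) mean(events$amplitude_norm_mean) else NA_real_,
      window_s = window_s
    ),
    class = "slice_summary"
  )
}

#' @export
print.slice_summary <- function(x, ...) {
  cat(sprintf(
    "<slice_summary> %d events / %g s; mean duration %.3f s, mean amplitude %.3f\n",
    x$n_events, x$window_s,
    if (is.na(x$mean_duration_s)) NA else x$mean_duration_s,
    if (is.na(x$mean_amplitude)) NA else x$mean_amplitude
  ))
  invisible(x)
}

#' Write detected events as delimited text
#'
#' @param events An `upstate_events` data frame.
#' @param path Output CSV path.
#' @param slice_id Identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, slice_id = "slice1") {
  df <- data.frame(slice_id = slice_id,
                   as.data.frame(events, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
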