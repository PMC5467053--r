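#' Reference (brute-force) UP-state detector
#'
#' A deliberately naive sample-by-sample state machine that applies the
#' three detection rules literally: walk the envelope, collect maximal
#' above-threshold runs, bridge sub-threshold dips of at most the end gap,
#' discard candidates whose span is below the minimum duration, then group
#' events within the merge gap by a repeated left-to-right scan until no
#' change. It shares no code with [detect_upstates()] and exists as the
#' validation oracle for the vectorised detector.
#'
#' @inheritParams detect_upstates
#' @return A data frame with columns `start_s`, `end_s`, `duration_s`.
#' @export
detect_upstates_reference <- function(env, min_dur_s = 0.2, end_gap_s = 0.6,
                                      merge_gap_s = 0.6) {
  stopifnot(inherits(env, "mua_envelope"))
  fs <- env$sampling_rate_hz
  n <- length(env$samples)
  runs <- list()
  in_run <- FALSE
  s0 <- NA_integer_
  for (i in seq_len(n)) {
    hi <- env$samples[i] > env$threshold
    if (hi && !in_run) { in_run <- TRUE; s0 <- i - 1L }
    if (!hi && in_run) { in_run <- FALSE; runs[[length(runs) + 1L]] <- c(s0, i - 1L) }
  }
  if (in_run) runs[[length(runs) + 1L]] <- c(s0, n)
  if (!length(runs)) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = numeric()))
  }
  # dips <= end_gap do not terminate an event
  merged <- list(runs[[1L]])
  if (length(runs) > 1L) for (i in 2L:length(runs)) {
    last <- merged[[length(merged)]]
    gap_s <- (runs[[i]][1L] - last[2L]) / fs
    if (gap_s <= end_gap_s) {
      merged[[length(merged)]] <- c(last[1L], runs[[i]][2L])
    } else {
      merged[[length(merged) + 1L]] <- runs[[i]]
    }
  }
  # minimum-duration rule
  events <- Filter(function(r) (r[2L] - r[1L]) / fs >= min_dur_s, merged)
  if (!length(events)) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = numeric()))
  }
  # grouping rule, rescanned to a fixed point
  repeat {
    changed <- FALSE
    out <- list(events[[1L]])
    if (length(events) > 1L) for (i in 2L:length(events)) {
      last <- out[[length(out)]]
      gap_s <- (events[[i]][1L] - last[2L]) / fs
      if (gap_s <= merge_gap_s) {
        out[[length(out)]] <- c(last[1L], events[[i]][2L])
        changed <- TRUE
      } else {
        out[[length(out) + 1L]] <- events[[i]]
      }
    }
    events <- out
    if (!changed) break
  }
  start_s <- vapply(events, `[`, numeric(1), 1L) / fs
  end_s <- vapply(events, `[`, numeric(1), 2L) / fs
  data.frame(start_s = start_s, end_s = end_s, duration_s = end_s - start_s)
}

#' Reference exact Wilcoxon p-value by subset enumeration
#'
#' Enumerates every assignment of the pooled observations to the first
#' group with `utils::combn`, recomputes the mid-rank sum for each
#' assignment from scratch with `base::rank`, and sums the null probability
#' of outcomes at least as extreme as the observed rank sum (distance from
#' the null mean for the two-sided test). This is the validation oracle for
#' [exact_wilcoxon()], which computes the same null distribution by a
#' counting recursion instead.
#'
#' @param x,y Numeric samples (ties allowed).
#' @param tails `"two"`, `"less"` or `"greater"` (direction of `x` relative
#'   to `y`).
#' @return The exact p-value.
#' @export
wilcoxon_reference <- function(x, y, tails = c("two", "less", "greater")) {
  tails <- match.arg(tails)
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  rk <- rank(pooled, ties.method = "average")
  s_obs <- sum(rk[seq_len(nx)])
  idx <- utils::combn(n, nx)
  s_all <- apply(idx, 2L, function(j) sum(rk[j]))
  mu <- nx * (n + 1) / 2
  p <- switch(tails,
    two = mean(abs(s_all - mu) >= abs(s_obs - mu) - 1e-9),
    less = mean(s_all <= s_obs + 1e-9),
    greater = mean(s_all >= s_obs - 1e-9)
  )
  p
}
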