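#' Novel object recognition discrimination index
#'
#' `DI = (novel - familiar) / (novel + familiar)` on object-exploration
#' times; 0 means no preference, +1 exclusive novel-object exploration.
#' Vectorised over trials.
#'
#' @param novel_s,familiar_s Exploration times in seconds (>= 0).
#' @return Discrimination index in `[-1, 1]`.
#' @examples
#' discrimination_index(30, 10)  # 0.5
#' @export
discrimination_index <- function(novel_s, familiar_s) {
  stopifnot(all(novel_s >= 0), all(familiar_s >= 0))
  total <- novel_s + familiar_s
  if (any(total <= 0)) {
    stop("zero total exploration time; such trials are excluded upstream ",
         "(see nor_exclusion)")
  }
  (novel_s - familiar_s) / total
}

#' Novel object recognition attention-time exclusion rule
#'
#' Animals accumulating less than `min_total_s` (default 6 s) of total
#' object attention during the test phase are excluded. The boundary is
#' strict: exactly 6 s is kept.
#'
#' @inheritParams discrimination_index
#' @param min_total_s Exclusion threshold in seconds.
#' @return Logical vector: `TRUE` = keep, `FALSE` = exclude.
#' @examples
#' nor_exclusion(3, 2.9)  # FALSE: 5.9 s total
#' nor_exclusion(3, 3)    # TRUE: exactly 6 s
#' @export
nor_exclusion <- function(novel_s, familiar_s, min_total_s = 6) {
  stopifnot(all(novel_s >= 0), all(familiar_s >= 0), min_total_s >= 0)
  (novel_s + familiar_s) >= min_total_s
}

#' Percent prepulse inhibition from startle V_max readings
#'
#' Computed per animal as `100 * mean(V_max at the prepulse level) /
#' mean(V_max at PPI0)`, i.e. percent of the baseline startle, exactly as
#' conventionally recorded from platform V_max readings (a.u.). Repeats of
#' each trial type (e.g. the four Latin-square repetitions) are aggregated
#' with the mean. Set `as_inhibition = TRUE` to emit the conventional
#' inhibition percentage `100 * (1 - ratio)` instead.
#'
#' @param trials Data frame with columns `trial_type` (e.g. `"PPI0"`,
#'   `"PPI73"`, `"PPI77"`, `"PPI82"`, `"nostim"`) and `vmax` (>= 0), for one
#'   animal.
#' @param level Prepulse level, one of 73, 77, 82 (or the matching
#'   `"PPIxx"` string).
#' @param as_inhibition Emit `100 * (1 - ratio)` instead of `100 * ratio`.
#' @return Percent PPI (scalar).
#' @examples
#' tr <- data.frame(trial_type = c("PPI0", "PPI0", "PPI73", "PPI73"),
#'                  vmax = c(100, 120, 60, 50))
#' percent_ppi(tr, 73)  # 50
#' @export
percent_ppi <- function(trials, level, as_inhibition = FALSE) {
  stopifnot(is.data.frame(trials),
            all(c("trial_type", "vmax") %in% names(trials)),
            all(trials$vmax >= 0))
  lvl <- if (is.numeric(level)) paste0("PPI", level) else as.character(level)
  if (!lvl %in% c("PPI73", "PPI77", "PPI82")) {
    stop("level must be one of 73, 77, 82")
  }
  v0 <- trials$vmax[trials$trial_type == "PPI0"]
  vx <- trials$vmax[trials$trial_type == lvl]
  if (!length(v0)) stop("no PPI0 (startle-only) trials present")
  if (!length(vx)) stop("no trials of type ", lvl)
  if (mean(v0) <= 0) stop("PPI0 mean V_max must be positive")
  ratio <- 100 * mean(vx) / mean(v0)
  if (as_inhibition) 100 - ratio else ratio
}

# Ordinal audiogenic seizure severity codes.
SEIZURE_CODES <- c("wild-running" = 1, "clonic" = 2, "tonic" = 3,
                   "cardiac arrest" = 4)

#' Audiogenic seizure severity score
#'
#' Ordinal 0-4 score: 0 no altered behaviour, 1 wild-running, 2 clonic
#' seizure, 3 tonic seizure, 4 cardiac arrest. The animal's score is its
#' most severe observed response (the maximum code), 0 if none.
#'
#' @param responses Character vector of observed responses, a subset of
#'   `c("wild-running", "clonic", "tonic", "cardiac arrest")`. May be
#'   empty.
#' @return Integer score 0-4.
#' @examples
#' seizure_score(c("wild-running", "clonic"))  # 2
#' seizure_score(character())                  # 0
#' @export
seizure_score <- function(responses) {
  if (length(responses) == 0L) return(0L)
  unknown <- setdiff(responses, names(SEIZURE_CODES))
  if (length(unknown)) {
    stop("unknown seizure response label(s): ",
         paste(unknown, collapse = ", "))
  }
  as.integer(max(SEIZURE_CODES[responses]))
}

#' Bin locomotor beam-break times into 5-min intervals
#'
#' Histograms event times into `n_intervals` half-open intervals of
#' `interval_s` seconds (defaults: 12 intervals of 300 s = a 1-h session)
#' and reports the per-interval counts plus their total.
#'
#' @param event_times_s Event (beam-break) times in seconds; all must lie
#'   in `[0, interval_s * n_intervals)`.
#' @param interval_s Interval width in seconds.
#' @param n_intervals Number of intervals.
#' @return A list with `counts` (integer vector of length `n_intervals`)
#'   and `total`.
#' @examples
#' bin_locomotor(c(0, 3599))$counts[c(1, 12)]
#' @export
bin_locomotor <- function(event_times_s, interval_s = 300, n_intervals = 12) {
  stopifnot(interval_s > 0, n_intervals >= 1)
  if (length(event_times_s) &&
      (min(event_times_s) < 0 ||
       max(event_times_s) >= interval_s * n_intervals)) {
    stop("event times must lie in [0, interval_s * n_intervals)")
  }
  bin <- floor(event_times_s / interval_s) + 1L
  counts <- tabulate(bin, nbins = n_intervals)
  list(counts = counts, total = sum(counts))
}

#' pERK/ERK-total ratio normalised to the reference group
#'
#' Computes the per-sample optical-density ratio `od_phospho / od_total`
#' and divides it by the mean ratio of the reference group (default
#' WT + SAL) within the same brain region, so the reference-group mean of
#' the output is exactly 1.
#'
#' @param samples Data frame with columns `od_phospho`, `od_total` (> 0),
#'   `region`, `genotype`, `drug`.
#' @param ref_genotype,ref_drug Reference group labels (defaults WT, SAL).
#' @return `samples` with an added `ratio_norm` column.
#' @examples
#' df <- data.frame(od_phospho = c(1, 1.2), od_total = 1,
#'                  region = "hippocampus",
#'                  genotype = c("WT", "KO"), drug = "SAL")
#' erk_ratio_normalized(df)$ratio_norm  # 1, 1.2
#' @export
erk_ratio_normalized <- function(samples, ref_genotype = "WT",
                                 ref_drug = "SAL") {
  stopifnot(is.data.frame(samples),
            all(c("od_phospho", "od_total", "region", "genotype",
                  "drug") %in% names(samples)),
            all(samples$od_phospho > 0), all(samples$od_total > 0))
  samples$ratio_norm <- NA_real_
  ratio <- samples$od_phospho / samples$od_total
  for (rg in unique(samples$region)) {
    sel <- samples$region == rg
    ref <- sel & samples$genotype == ref_genotype & samples$drug == ref_drug
    if (!any(ref)) {
      stop("reference group ", ref_genotype, "+", ref_drug,
           " missing in region ", rg)
    }
    samples$ratio_norm[sel] <- ratio[sel] / mean(ratio[ref])
  }
  samples
}

#' Dendritic spine counts per 25-micron segment
#'
#' Bins spine positions along the first 150 microns of apical dendrite into
#' six consecutive 25-micron half-open segments.
#'
#' @param spine_positions_um Spine positions in microns; all in
#'   `[0, segment_um * n_segments)`.
#' @param segment_um Segment length in microns (default 25).
#' @param n_segments Number of segments (default 6).
#' @return Integer vector of length `n_segments` (class `spine_profile`).
#' @examples
#' spine_segment_profile(c(0, 24.9, 25))  # 2 in segment 1, 1 in segment 2
#' @export
spine_segment_profile <- function(spine_positions_um, segment_um = 25,
                                  n_segments = 6) {
  stopifnot(segment_um > 0, n_segments >= 1)
  if (length(spine_positions_um) &&
      (min(spine_positions_um) < 0 ||
       max(spine_positions_um) >= segment_um * n_segments)) {
    stop("spine positions must lie in [0, segment_um * n_segments)")
  }
  counts <- tabulate(floor(spine_positions_um / segment_um) + 1L,
                     nbins = n_segments)
  structure(counts, class = "spine_profile",
            segment_um = segment_um)
}

#' @export
print.spine_profile <- function(x, ...) {
  w <- attr(x, "segment_um")
  cat("<spine_profile> counts per", w, "um segment:",
      paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}
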