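#' Configuration for synthetic MUA trace generation
#'
#' Describes the regime of spontaneous cortical UP states the simulator
#' emulates: band-limited background noise with interleaved epochs of
#' elevated amplitude at a configurable event rate and duration distribution.
#' Slow-oscillation UP/DOWN alternation in slice recordings sits in the
#' ~0.5-1 Hz oscillation regime with events lasting on the order of seconds;
#' the defaults target that regime at the sparse event rates seen over 5-min
#' recordings.
#'
#' @param sampling_rate_hz Sampling rate (Hz). Must exceed `2 * band_high_hz`.
#' @param total_duration_s Trace length in seconds (default 300 = 5 min).
#' @param event_rate_hz Mean UP-state rate (events per second).
#' @param duration_mean_s,duration_sd_s Mean and SD (s) of the normal
#'   duration distribution, truncated below (see `duration_min_s`).
#' @param duration_min_s Lower bound on durations (s); draws below it are
#'   clamped to this value (default 0.2, the detector's minimum-duration
#'   rule, so ground truth is detectable in principle).
#' @param min_gap_s Minimum inter-event gap (s). Must exceed 0.6 s (the
#'   detector's merge window) so ground truth is unambiguous.
#' @param up_gain Amplitude multiplier applied inside UP epochs (> 1).
#' @param noise_sd SD of the white noise before band-pass filtering (a.u.).
#' @param band_low_hz,band_high_hz Pass band of the background noise
#'   (defaults 500 and 3000 Hz, the conventional online MUA acquisition band).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A validated list of class `trace_sim_config`.
#' @examples
#' trace_sim_config(event_rate_hz = 0.05, seed = 1)
#' @export
trace_sim_config <- function(sampling_rate_hz = 10000,
                             total_duration_s = 300,
                             event_rate_hz = 0.05,
                             duration_mean_s = 1.5,
                             duration_sd_s = 0.5,
                             duration_min_s = 0.2,
                             min_gap_s = 0.7,
                             up_gain = 10,
                             noise_sd = 1,
                             band_low_hz = 500,
                             band_high_hz = 3000,
                             seed = NULL) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz, total_duration_s = total_duration_s,
    event_rate_hz = event_rate_hz, duration_mean_s = duration_mean_s,
    duration_sd_s = duration_sd_s, duration_min_s = duration_min_s,
    min_gap_s = min_gap_s, up_gain = up_gain, noise_sd = noise_sd,
    band_low_hz = band_low_hz, band_high_hz = band_high_hz, seed = seed
  )
  with(cfg, {
    stopifnot(
      sampling_rate_hz > 0, total_duration_s > 0, event_rate_hz >= 0,
      duration_mean_s > 0, duration_sd_s >= 0, duration_min_s > 0,
      noise_sd > 0, band_low_hz > 0, band_high_hz > band_low_hz
    )
    if (sampling_rate_hz <= 2 * band_high_hz) {
      stop("sampling_rate_hz must exceed 2 * band_high_hz")
    }
    if (up_gain <= 1) stop("up_gain must be > 1")
    if (min_gap_s <= 0.6) {
      stop("min_gap_s must exceed the 0.6 s merge window for unambiguous ",
           "ground truth")
    }
  })
  structure(cfg, class = "trace_sim_config")
}

#' Draw a ground-truth UP-state schedule
#'
#' Samples candidate event onsets as a Poisson process at `event_rate_hz`,
#' draws durations from a normal distribution clamped at `duration_min_s`,
#' and accepts events greedily left to right subject to the minimum
#' inter-event gap. Events that would overlap the trace boundary are
#' discarded (not clipped) so ground-truth durations stay exact.
#'
#' @param config A [trace_sim_config()].
#' @return A data frame of class `upstate_schedule` with columns `start_s`,
#'   `duration_s`, `end_s`, and attribute `total_duration_s`.
#' @examples
#' sched <- draw_schedule(trace_sim_config(seed = 7))
#' nrow(sched)
#' @export
draw_schedule <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  if (config$event_rate_hz * config$duration_mean_s >= 1) {
    stop("infeasible schedule: event_rate_hz * duration_mean_s >= 1 ",
         "(events would necessarily overlap)")
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  empty <- function() {
    structure(
      data.frame(start_s = numeric(), duration_s = numeric(),
                 end_s = numeric()),
      total_duration_s = config$total_duration_s,
      class = c("upstate_schedule", "data.frame")
    )
  }
  if (config$event_rate_hz == 0) return(empty())
  n_cand <- stats::rpois(1L, config$event_rate_hz * config$total_duration_s)
  if (n_cand == 0L) return(empty())
  starts <- sort(stats::runif(n_cand, 0, config$total_duration_s))
  durs <- pmax(
    stats::rnorm(n_cand, config$duration_mean_s, config$duration_sd_s),
    config$duration_min_s
  )
  keep <- logical(n_cand)
  prev_end <- -Inf
  for (i in seq_len(n_cand)) {
    s <- starts[i]; e <- s + durs[i]
    if (s - prev_end > config$min_gap_s && e <= config$total_duration_s) {
      keep[i] <- TRUE
      prev_end <- e
    }
  }
  out <- data.frame(
    start_s = starts[keep], duration_s = durs[keep],
    end_s = starts[keep] + durs[keep]
  )
  structure(out, total_duration_s = config$total_duration_s,
            class = c("upstate_schedule", "data.frame"))
}

#' Synthesize an MUA trace from a ground-truth schedule
#'
#' The background is Gaussian white noise band-pass filtered to
#' `[band_low_hz, band_high_hz]` (zero-phase Butterworth, order 4); inside
#' each scheduled epoch the instantaneous amplitude is multiplied by
#' `up_gain`. The schedule is carried verbatim in the returned ground truth.
#' The RNG is seeded at `config$seed + 1` (when a seed is set) so the trace
#' is reproducible whether or not [draw_schedule()] was called in the same
#' session.
#'
#' @param schedule An `upstate_schedule` (see [draw_schedule()]); must fit
#'   inside `config$total_duration_s`.
#' @param config A [trace_sim_config()].
#' @return A list of class `sim_trace`: `trace` (a [mua_trace()]) and
#'   `truth` (the schedule plus the generating configuration).
#' @examples
#' cfg <- trace_sim_config(total_duration_s = 5, sampling_rate_hz = 8000,
#'                         event_rate_hz = 0.2, seed = 1)
#' sim <- synthesize_trace(draw_schedule(cfg), cfg)
#' sim$trace
#' @export
synthesize_trace <- function(schedule, config) {
  stopifnot(inherits(schedule, "upstate_schedule"),
            inherits(config, "trace_sim_config"))
  if (nrow(schedule) > 0 &&
      (min(schedule$start_s) < 0 ||
       max(schedule$end_s) > config$total_duration_s)) {
    stop("schedule does not fit inside total_duration_s")
  }
  fs <- config$sampling_rate_hz
  if (fs <= 2 * config$band_high_hz) stop("sampling rate / band violation")
  if (!is.null(config$seed)) set.seed(as.integer(config$seed) + 1L)
  n <- round(config$total_duration_s * fs)
  x <- stats::rnorm(n, 0, config$noise_sd)
  bp <- signal::butter(4, c(config$band_low_hz, config$band_high_hz) /
                         (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bp, x))
  gain <- rep(1, n)
  for (i in seq_len(nrow(schedule))) {
    i0 <- floor(schedule$start_s[i] * fs) + 1L
    i1 <- min(n, ceiling(schedule$end_s[i] * fs))
    gain[i0:i1] <- config$up_gain
  }
  trace <- mua_trace(x * gain, fs)
  structure(list(trace = trace,
                 truth = list(schedule = schedule, config = config)),
            class = "sim_trace")
}

#' Configuration for synthetic behavioural cohorts
#'
#' Describes a two-genotype (WT vs KO) by drug factorial cohort with
#' per-measure effect structure. Continuous measures are built additively on
#' a cell-mean scale (optionally with a within-subject factor), count
#' measures as Poisson rates with multiplicative effects, and ordinal
#' seizure scores (0-4) from per-group probability vectors. Default group
#' sizes follow the juvenile audiogenic-seizure cohort layout
#' (WT+SAL 13, WT+Acamp 13, KO+SAL 15, KO+Acamp 17).
#'
#' @param n_per_group Named integer vector of animals per group; names are
#'   `"<genotype>:<drug>"`. All `n >= 2`.
#' @param measures Named list (default: [default_measures()] for the
#'   configured groups); each element describes one measure:
#'   \describe{
#'     \item{continuous}{`list(type = "continuous", baseline, sd,
#'       gene_effect = 0, drug_effect = c(...), interaction_effect = c(...),
#'       cell_means = NULL, within = NULL)`. `drug_effect` and
#'       `interaction_effect` (the extra KO shift per treated drug, i.e. a
#'       difference-of-differences) are named by drug level; `cell_means`
#'       (named by group) overrides the additive build when supplied.
#'       `within = list(levels, offsets, subject_sd)` adds a complete
#'       within-subject factor with a random intercept per animal.}
#'     \item{count}{`list(type = "count", baseline, gene_mult = 1,
#'       drug_mult = c(...))` -- Poisson with multiplicative rate effects.}
#'     \item{ordinal}{`list(type = "ordinal", probs = <matrix>)`; rows named
#'       by group, columns are scores 0..4, each row summing to 1.}
#'   }
#' @param seed Integer seed or `NULL`.
#' @return A validated list of class `cohort_sim_config`.
#' @examples
#' cfg <- cohort_sim_config(measures = list(
#'   open_time = list(type = "continuous", baseline = 30, sd = 8)))
#' @export
cohort_sim_config <- function(n_per_group = c("WT:SAL" = 13, "WT:Acamp" = 13,
                                              "KO:SAL" = 15, "KO:Acamp" = 17),
                              measures = NULL,
                              seed = NULL) {
  if (is.null(measures)) measures <- default_measures(names(n_per_group))
  stopifnot(length(n_per_group) >= 2, all(n_per_group >= 2),
            !is.null(names(n_per_group)), is.list(measures),
            length(measures) >= 1, !is.null(names(measures)))
  parts <- strsplit(names(n_per_group), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("n_per_group names must be '<genotype>:<drug>'")
  }
  for (m in names(measures)) {
    sp <- measures[[m]]
    if (is.null(sp$type) ||
        !sp$type %in% c("continuous", "count", "ordinal")) {
      stop("measure '", m, "' must declare type continuous/count/ordinal")
    }
    if (sp$type == "continuous" && (is.null(sp$sd) || sp$sd < 0)) {
      stop("measure '", m, "': continuous measures need sd >= 0")
    }
    if (sp$type == "ordinal") {
      pr <- sp$probs
      if (is.null(pr) || !is.matrix(pr) || ncol(pr) != 5L ||
          is.null(rownames(pr))) {
        stop("measure '", m, "': ordinal probs must be a matrix with 5 ",
             "columns (scores 0-4) and group rownames")
      }
      if (any(pr < 0) || any(abs(rowSums(pr) - 1) > 1e-8)) {
        stop("measure '", m, "': each probability row must sum to 1")
      }
      missing_grp <- setdiff(names(n_per_group), rownames(pr))
      if (length(missing_grp)) {
        stop("measure '", m, "': probs missing groups ",
             paste(missing_grp, collapse = ", "))
      }
    }
  }
  structure(
    list(n_per_group = n_per_group, measures = measures, seed = seed,
         genotypes = unique(vapply(parts, `[`, "", 1L)),
         drugs = unique(vapply(parts, `[`, "", 2L))),
    class = "cohort_sim_config"
  )
}

#' Default measure set for cohort simulation
#'
#' A small battery-shaped default: a continuous anxiety-type measure, a
#' Poisson locomotor count, and a null ordinal seizure outcome (all effect
#' sizes zero), for the standard four groups.
#'
#' @param groups Group labels (`"<genotype>:<drug>"`).
#' @return Named list of measure specifications.
#' @export
default_measures <- function(groups = c("WT:SAL", "WT:Acamp",
                                        "KO:SAL", "KO:Acamp")) {
  probs <- matrix(rep(c(0.6, 0.1, 0.1, 0.1, 0.1), length(groups)),
                  ncol = 5, byrow = TRUE,
                  dimnames = list(groups, as.character(0:4)))
  list(
    ezm_open_time_s = list(type = "continuous", baseline = 40, sd = 12),
    beam_breaks = list(type = "count", baseline = 1500),
    seizure_score = list(type = "ordinal", probs = probs)
  )
}

#' Simulate a behavioural cohort with known ground truth
#'
#' @param config A [cohort_sim_config()].
#' @return A list of class `sim_cohort`: `cohort`, a long-format data frame
#'   (one row per animal x measure x within-level) with columns `animal`,
#'   `genotype`, `drug`, `group`, `measure`, `within_level`, `value`; and
#'   `truth`, the configured per-group means (continuous/count) and
#'   probability vectors (ordinal).
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(seed = 3))
#' table(sim$cohort$group[sim$cohort$measure == "seizure_score"])
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  groups <- names(config$n_per_group)
  parts <- strsplit(groups, ":", fixed = TRUE)
  geno <- vapply(parts, `[`, "", 1L)
  drug <- vapply(parts, `[`, "", 2L)
  animals <- data.frame(
    animal = sprintf("a%03d", seq_len(sum(config$n_per_group))),
    genotype = rep(geno, config$n_per_group),
    drug = rep(drug, config$n_per_group),
    group = rep(groups, config$n_per_group),
    stringsAsFactors = FALSE
  )
  ref_drug <- config$drugs[1L]
  ref_geno <- config$genotypes[1L]
  rows <- list()
  truth <- list()
  for (m in names(config$measures)) {
    sp <- config$measures[[m]]
    if (sp$type == "continuous") {
      mu <- cell_means_for(sp, groups, geno = geno_of(groups),
                           drug = drug_of(groups),
                           ref_geno = ref_geno, ref_drug = ref_drug)
      truth[[m]] <- list(type = "continuous", group_means = mu, sd = sp$sd)
      base_mu <- mu[animals$group]
      if (is.null(sp$within)) {
        rows[[m]] <- data.frame(
          animals, measure = m, within_level = NA_character_,
          value = stats::rnorm(nrow(animals), base_mu, sp$sd),
          stringsAsFactors = FALSE
        )
      } else {
        w <- sp$within
        stopifnot(length(w$offsets) == length(w$levels))
        b <- stats::rnorm(nrow(animals), 0,
                          if (is.null(w$subject_sd)) 0 else w$subject_sd)
        sub <- lapply(seq_along(w$levels), function(k) {
          data.frame(
            animals, measure = m, within_level = w$levels[k],
            value = stats::rnorm(nrow(animals),
                                 base_mu + w$offsets[k] + b, sp$sd),
            stringsAsFactors = FALSE
          )
        })
        rows[[m]] <- do.call(rbind, sub)
      }
    } else if (sp$type == "count") {
      gm <- if (is.null(sp$gene_mult)) 1 else sp$gene_mult
      dm <- drug_mult_vec(sp, drug_of(groups), ref_drug)
      lam <- sp$baseline * ifelse(geno_of(groups) == ref_geno, 1, gm) * dm
      names(lam) <- groups
      truth[[m]] <- list(type = "count", group_rates = lam)
      rows[[m]] <- data.frame(
        animals, measure = m, within_level = NA_character_,
        value = stats::rpois(nrow(animals), lam[animals$group]),
        stringsAsFactors = FALSE
      )
    } else {
      pr <- sp$probs[groups, , drop = FALSE]
      truth[[m]] <- list(type = "ordinal", probs = pr)
      val <- vapply(animals$group, function(g) {
        sample(0:4, 1L, prob = pr[g, ])
      }, numeric(1))
      rows[[m]] <- data.frame(
        animals, measure = m, within_level = NA_character_,
        value = as.numeric(val), stringsAsFactors = FALSE
      )
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  structure(list(cohort = cohort, truth = truth, config = config),
            class = "sim_cohort")
}

geno_of <- function(groups) {
  vapply(strsplit(groups, ":", fixed = TRUE), `[`, "", 1L)
}
drug_of <- function(groups) {
  vapply(strsplit(groups, ":", fixed = TRUE), `[`, "", 2L)
}

drug_mult_vec <- function(sp, drugs, ref_drug) {
  dm <- rep(1, length(drugs))
  if (!is.null(sp$drug_mult)) {
    for (d in names(sp$drug_mult)) dm[drugs == d] <- sp$drug_mult[[d]]
  }
  dm
}

# Additive cell-mean construction for continuous measures; an explicit
# cell_means vector (named by group) overrides it.
cell_means_for <- function(sp, groups, geno, drug, ref_geno, ref_drug) {
  if (!is.null(sp$cell_means)) {
    miss <- setdiff(groups, names(sp$cell_means))
    if (length(miss)) stop("cell_means missing groups: ",
                           paste(miss, collapse = ", "))
    return(sp$cell_means[groups])
  }
  ge <- if (is.null(sp$gene_effect)) 0 else sp$gene_effect
  mu <- rep(sp$baseline, length(groups))
  mu <- mu + ifelse(geno == ref_geno, 0, ge)
  if (!is.null(sp$drug_effect)) {
    for (d in names(sp$drug_effect)) {
      mu[drug == d] <- mu[drug == d] + sp$drug_effect[[d]]
    }
  }
  if (!is.null(sp$interaction_effect)) {
    for (d in names(sp$interaction_effect)) {
      sel <- drug == d & geno != ref_geno
      mu[sel] <- mu[sel] + sp$interaction_effect[[d]]
    }
  }
  names(mu) <- groups
  mu
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of a `sim_trace` or `sim_cohort`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
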