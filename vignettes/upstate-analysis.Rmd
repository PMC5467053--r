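---
title: "Methods: UP-state detection and phenotyping battery analysis"
author: "upstatetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UP-state detection and phenotyping battery analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upstatetools)
```

This vignette is the package's account of its science: the detection model
and its numerical choices, what the synthetic-data generators emulate (and
what they do not), the inferential conventions, and the design decisions
taken where the procedure left genuine latitude.

## 1. The UP-state detection model

Cortical slices show a slow (~0.5–1 Hz regime) alternation between
quiescent DOWN states and UP states of persistent, synchronized multiunit
firing. In an extracellular multiunit recording (band-passed 500–3000 Hz at
acquisition) an UP state appears as a sustained elevation of the signal's
instantaneous amplitude. The detector therefore works on an **envelope**:

1. *offset to zero*: subtract the trace mean;
2. *rectify*: take the absolute value;
3. *low-pass filter*: zero-phase (forward–backward) Butterworth of order 4.
   Zero-phase filtering is chosen because it adds no group delay, so event
   boundaries are not biased in time;
4. *threshold*: `threshold = 5 * rms_noise`.

Three rules then define events: an excursion must remain above threshold
for at least 200 ms; the event ends only when the envelope stays below
threshold for more than 600 ms (shorter dips are bridged); and two events
within 600 ms of one another are grouped as one UP state. We apply them in
that order — extract above-threshold runs, bridge dips `<= end_gap`,
discard candidates with span `< min_dur`, merge events with gaps
`<= merge_gap` — and define an event's duration as its full span, bridged
dips included. Crossings are resolved at envelope-sample resolution with
half-open `[start, end)` intervals and 0-based indexing; no sub-sample
interpolation is attempted because the envelope sample interval (10 ms at
the internal 100 Hz rate) is far below the 200/600 ms rule constants.
Events touching the trace boundary have unknown true duration; they are
flagged and excluded from duration statistics by default.

Amplitude is reported in threshold units (envelope ÷ threshold). Which
within-event statistic the original analyses reported is not specified, so
both the event mean (the headline) and the peak are emitted.

### The RMS-noise estimator

The envelope of zero-mean noise is *not* zero-mean: rectification gives it
a positive baseline (≈ 0.8 σ for Gaussian noise), and any low-pass filter
preserves that DC level. A threshold of five times a measure of envelope
*fluctuation* (e.g. a MAD-based spread) would land far below the baseline
and the detector could never cross downward; for the threshold rule to be
meaningful, "RMS noise" must be the RMS *level* of the eventless envelope.
We estimate it robustly as the **median of the conditioned envelope**:
DOWN states dominate the recording, the quiet-period envelope is nearly
constant (so its median ≈ its RMS), and UP epochs — a minority of samples —
cannot drag a median. A user-designated quiet window may be supplied
instead, in which case the RMS is computed directly over it. With this
estimator, `5 * rms_noise ≈ 4 σ` sits cleanly between the DOWN baseline
(≈ 0.8 σ) and UP levels (≈ 0.8 σ × gain), which is what makes threshold
crossing detection work at UP gains of about 5 and above.

### The low-pass cutoff

The conditioning is usually quoted with a 0.2 Hz cutoff, and that is the
package default. A 0.2 Hz filter, however, averages over roughly 5 s and
cannot resolve individual events in the ~1 s regime — it may be a
transcription of 0.2 kHz or 2 Hz. We implement 0.2 Hz as printed, expose
`cutoff_hz` as a first-class parameter, and use **2 Hz** in our own
recovery studies, where events of ≥ 0.5 s separated by ≥ 1 s must be
resolved: filter theory puts the zero-phase 10–90% step rise at
≈ 0.44/f_c (0.22 s at 2 Hz), comfortably inside those gaps. The envelope
object carries the documented, conservative settling bound
`settling_s = 0.5 / cutoff_hz`, and recovery tests require every detected
boundary to sit within it.

Because the cutoff is orders of magnitude below the sampling rate, the
rectified trace is first block-averaged to an internal envelope rate
(≥ 100 Hz and ≥ 25× the cutoff). This keeps the order-4 Butterworth
numerically well conditioned (normalized cutoffs near 1e-5 are not) while
leaving crossing resolution at 10 ms.

```{r detector-demo}
cfg <- trace_sim_config(total_duration_s = 20, sampling_rate_hz = 8000,
                        event_rate_hz = 0.15, duration_mean_s = 1,
                        duration_sd_s = 0.2, duration_min_s = 0.5,
                        min_gap_s = 1, up_gain = 8, seed = 1)
sim <- synthesize_trace(draw_schedule(cfg), cfg)
env <- condition_trace(sim$trace, cutoff_hz = 2)
detect_upstates(env)
```

## 2. What the trace simulator emulates — and what it does not

UP epochs are modelled as **amplitude-gain modulation** of band-limited
Gaussian noise: the detector sees only the rectified envelope, for which a
gain step is the minimal sufficient structure. Defaults: 10 kHz sampling
(unspecified at acquisition; chosen > 2× the 3 kHz band edge), 300 s
traces (the 5-min collection window), a 500–3000 Hz noise band, and
amplitudes in arbitrary units throughout (no physical-unit claim).
Durations are drawn from a normal distribution **clamped** at the 0.2 s
minimum-duration rule (so ground truth is detectable in principle);
clamping rather than resampling slightly inflates mass at the floor, which
is irrelevant because the emitted schedule itself is the ground truth.
Candidate onsets form a Poisson process thinned greedily to enforce
inter-event gaps above the 0.6 s merge window (so truth is unambiguous);
events overlapping the trace boundary are discarded, not clipped, keeping
true durations exact. Configurations with `event_rate * duration_mean >= 1`
are rejected as infeasible.

The simulator does **not** emulate: spiking point-process structure,
slice-to-slice heterogeneity in duration or rate (all slices of a group
share one distribution), baseline drift, line noise, or evoked activity.
Passing recovery tests therefore demonstrates correctness of the detection
*rules* and boundary placement under the stated noise model — not detector
performance on real recordings with inter-UP-state activity, which is why
the threshold multiple, cutoff and rule constants remain user-visible
parameters.

## 3. The cohort generator

Cohorts are two genotypes (WT, KO) crossed with drug arms (SAL, CaCl2,
Acamp), one row per animal × measure (× within-subject level). Group sizes
default to the juvenile seizure cohort layout (13/13/15/17); the adult
battery examples use six groups of ~11. Continuous measures are additive
on the cell-mean scale (`gene_effect`, per-drug `drug_effect`, and an
`interaction_effect` defined as the KO-specific extra drug shift, i.e. a
difference of differences; an explicit `cell_means` vector can override
the build, which the power studies use to specify an effects-coded
interaction where each cell deviates ±1 SD from additivity). Counts are
Poisson with multiplicative effects; the ordinal seizure score is drawn
from per-group probability vectors over {0..4}. Every dataset ships with
its `truth` (configured means, rates, probability vectors), and identical
seed + configuration reproduces outputs bit for bit.

```{r cohort-demo}
sim <- simulate_cohort(cohort_sim_config(seed = 8))
head(sim$cohort, 3)
sim$truth$seizure_score$probs[1, ]
```

## 4. Inferential conventions

**Factorial ANOVA** uses type III sums of squares with sum-to-zero
contrasts (`car::Anova` on a least-squares fit): the convention of
mixed-model ANOVA software for the unbalanced group sizes typical of these
cohorts; on balanced designs it equals the classical decomposition (tested
against a closed-form oracle at 1e-10). A constant response (zero residual
variance) is a documented error, as are empty cells.

**Mixed-factor ANOVA** (between × within) is a linear mixed model with a
random intercept per animal — compound-symmetry covariance — reported as
type III (marginal) F tests via `nlme::lme`. An AR(1) within-subject
structure is deliberately out of scope; with the short, evenly spaced
within factors used here (six dendrite segments, twelve 5-min intervals,
three prepulse levels) compound symmetry is the standard univariate
approximation, and the output carries a `covariance` attribute saying so.
Denominator df follow the containment method, so small df discrepancies
against other software are expected for unbalanced designs. Collapsing a
two-level within factor to differences reproduces the paired-contrast
tests exactly, which is tested. If the response has no within-subject
variability at all, within-factor F ratios are reported as 0 (not NaN)
and between effects are computed from subject means.

**Exact Wilcoxon rank-sum**: mid-ranks for ties; the null is the
distribution of the rank sum over all `choose(n, n_x)` assignments of the
*observed* values, computed by a counting recursion over doubled
mid-ranks (valid under arbitrary ties). The two-sided p-value is
`P(|S − E S| >= |s_obs − E S|)` with `E S = n_x (n+1)/2` — the convention
of exact rank-sum software; on tied data it can differ from doubling a
tail. A seeded permutation Monte-Carlo fallback, flagged in the result,
covers samples above the enumeration cap (default 20, where the support
is 184 756 assignments). An independent `utils::combn` enumeration oracle
ships in the package and the two routes are required to agree to 1e-12 in
the tests.

**FDR**: Benjamini–Hochberg step-up per family, one family per dependent
measure (the pairwise follow-ups to a significant omnibus effect), via
`stats::p.adjust` and checked against a hand step-up loop.

**One-tailed preplanned contrasts**: with the direction declared in
advance, `p_one = p_two / 2` when the observed difference matches the
prediction and `1 − p_two / 2` otherwise (so a zero difference gives 0.5).
The function refuses to run without a declared direction.

**Control pooling**: for each measure, a genotype × drug ANOVA restricted
to the SAL and CaCl2 arms; both arms are relabelled `Controls` only if
neither the drug effect nor the interaction reaches α = 0.05, and every
decision is logged. Note that two α = 0.05 gates imply a ≈ 90% pooling
rate under a true null (not 95%); the calibration test asserts the
two-test rate.

**Descriptives** are LS means ± SEM (`emmeans`), matching the reporting
style of the source analyses.

## 5. Dosing constants

Molar masses ship as overridable constants: N-acetylhomotaurine free base
181.21 g/mol (0.5 Ca per free-base equivalent of the hemicalcium salt),
acamprosate calcium 400.48 g/mol, CaCl2·2H2O 147.01 g/mol. With them,
122.2 mg/kg CaCl2·2H2O and 300 mg/kg acamprosate (free-base basis) both
deliver ≈ 0.83 mmol Ca²⁺/kg/day — the calcium-matched design — and the
333 mg/kg × 3/37 × 70 kg body-surface-area scaling gives 1.89 g/day.
(The 300 vs 333 mg/kg discrepancy in the published worked example is
preserved as printed; both are accepted inputs.)

```{r dosing}
c(cacl2 = calcium_molar_dose(122.2, "cacl2_2h2o"),
  acamp = calcium_molar_dose(300, "acamprosate_free_base"),
  hed_g_day = human_equivalent_dose(333))
```

## 6. Simulation-study problem sizes

The validation studies (`detector_oracle_agreement()`,
`detector_recovery()`, `wilcoxon_oracle_agreement()`,
`anova_null_calibration()`, `upstate_effect_power()`) use, as the
package's own choices: 1000 random step envelopes on a 20 Hz grid (≤ 60 s);
50 full 300-s traces at 10 kHz with durations ≥ 0.5 s, gaps ≥ 1 s and UP
gain 8, detected at a 2 Hz cutoff; 500 tied-integer datasets over all size
pairs with `n_x + n_y <= 10`; 2000 replicate null 2×3 cohorts at 11 per
cell; and 200 replicates of the effect-recovery study at the UP-state
study's slice counts (16/14/27/25) with a 1.5× KO duration effect. The
effect-recovery study runs each slice at a scaled trace geometry (10 s at
2 kHz, 200–800 Hz band) so that the full synthesize–condition–detect chain
is exercised per slice while the study stays desk-sized; detector fidelity
at the full geometry is established separately by the 50-trace recovery
study. Slices with no detected events (~13% at 2 expected events per
slice) are dropped from that replicate's ANOVA, mirroring how empty slices
cannot contribute a duration mean.

## 7. Known limitations

* The envelope noise estimator assumes DOWN states occupy most of the
  recording; at duty cycles approaching 50% the median drifts up and the
  threshold with it (use a quiet window then).
* At the printed 0.2 Hz cutoff the detector cannot resolve sub-5-s
  structure; results at that default are faithful to the description but
  not to the second-scale phenomenology.
* Compound symmetry in place of AR(1) tends to be liberal for long,
  strongly autocorrelated within-series; the locomotor 12-interval case is
  the most exposed.
* Real-data group effect sizes are not reproduced anywhere: the animal
  data are unavailable, and all effect-recovery statements are about
  synthetic ground truth.
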