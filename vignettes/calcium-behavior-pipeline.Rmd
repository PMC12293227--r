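---
title: "Analyzing behavioral-state modulation of astrocytic and neuronal calcium traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing behavioral-state modulation of astrocytic and neuronal calcium traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmod)
```

## The problem

Two-photon calcium imaging of cortical astrocytes and neurons in awake,
head-fixed mice produces, per recording session, a set of ROI
fluorescence time series (astrocytic somata AS, processes AP, gliopil Gp,
perivascular endfeet AE, and neuron somata with a paired neuropil
signal), a wheel-speed trace and a whisker motion-energy trace, all on a
common ~10 Hz clock. The scientific questions calmod addresses are how
calcium activity in each compartment depends on the behavioral state
(stillness, free whisking, locomotion), how reliably ROIs respond at
still-to-locomotion transitions, and how these properties differ between
two animal groups (e.g. wild-type vs IP3R2-knockout mice, whose
astrocytes largely lack IP3-receptor-dependent calcium release) — with
inference that respects the nested structure of the data (ROIs within
mice).

calmod implements the full trace-level pipeline plus a synthetic-session
generator with known ground truth, so every stage can be validated
against analytic expectations before being applied to real recordings.

## Trace processing model

Each raw fluorescence trace is processed as:

1. **Linear detrend.** A first-degree polynomial is fitted by least
   squares and removed, with the fitted line's mean added back; this
   corrects photobleaching drift while keeping the baseline positive.
2. **Neuropil subtraction** (neuron somata only):
   `F <- F - alpha * F_np` with `alpha = 0.7` by default.
3. **dF/F.** The baseline F0 is the 10th percentile of the trace
   smoothed with a first-order Savitzky-Golay filter over an odd window
   of about 5 s (51 samples at 10 Hz); `dff = (F - F0)/F0`. F0 is a
   single scalar per trace: combined with the separate linear detrend
   this matches a two-step baseline procedure, and makes `dff` exactly
   invariant to positive rescaling of F.
4. **Noise floor.** `sigma` is the standard deviation of dF/F inside the
   least noisy 5 s window (sliding, one-sample stride).
5. **Event detection.** A calcium event exists wherever dF/F exceeds
   `k * sigma` (`k = 2` for astrocytic compartments, `2.5` for neurons);
   its extent is the contiguous positive lobe of dF/F around the
   crossing, bounded by zero crossings (trace ends count as crossings).
   One event is emitted per positive lobe containing at least one
   suprathreshold sample, so suprathreshold excursions that share a lobe
   merge. Amplitude is the maximum dF/F in the span; duration the span
   between crossings; onset the first suprathreshold sample.

Degenerate inputs are handled explicitly: a non-positive F0 aborts with
an error (wrong input units), and `sigma = 0` on a non-flat trace (e.g.
noiseless synthetic data) falls back, with a warning, to an absolute
dF/F threshold (`sigma_floor`, default 0.05).

Sigma is computed on dF/F rather than raw fluorescence; the alternative
reading ("fluorescence change" as raw F) differs only by the constant
factor F0 and is available by calling `estimate_sigma()` on any numeric
trace.

## Behavioral segmentation

Sessions are partitioned exhaustively into `Still`, `StillWhisking` and
`Locomotion` (half-open intervals in seconds, sample `i` covering
`[(i-1)/fs, i/fs)`):

* **Locomotion**: wheel speed > 1 cm/s; interruptions shorter than 0.5 s
  are merged; bouts must strictly exceed 0.5 s.
* **Whisking** (assessed only during stillness, since mice whisk
  continuously while running): motion energy smoothed with a 0.33 s
  moving average; baseline W0 = 1st percentile of the smoothed trace;
  threshold `1.5 * W0`. Gaps < 0.3 s are merged, then bouts < 0.4 s
  dropped. Still periods coinciding with whisking become
  `StillWhisking`; overlap with locomotion is always labeled
  `Locomotion`.

Two genuinely open readings are resolved as follows, with both variants
implemented and config-selectable:

* "exceeded this baseline by more than 1.5" is read multiplicatively
  (`W > 1.5 * W0`): W0 is a raw-energy percentile, so the additive
  reading would be unit-dependent. If `W0 <= 0` the multiplicative
  threshold degenerates and the code falls back to `W0 + 1.5 * MAD`
  with a warning.
* Gap-merging is applied before the minimum-bout filter
  (`whisk_order = "merge_first"`): merging last could resurrect
  sub-0.4 s fragments.

All duration and gap comparisons are performed in integer samples, which
keeps thresholds exact on the sample grid and makes the interval
implementation provably equivalent to a per-sample labeler (this
equivalence is asserted on 1000 random traces in the test suite).

## Modulation indices

For each ROI, locomotion and whisking modulation of mean dF/F:

$$\mathrm{LocMI} = \frac{S_{loc} - S_s}{S_{loc} + S_s}, \qquad
  \mathrm{WhiskMI} = \frac{S_w - S_s}{S_w + S_s}$$

* `S_loc`: mean dF/F over locomotion bouts strictly longer than 3 s.
* `S_w`: mean dF/F over Still-Whisking bouts of at least 0.4 s.
* `S_s`: mean dF/F over still time after removing a ±2 s guard around
  every locomotion bout and keeping only residual segments of at least
  2 s. For LocMI, Still-Whisking samples count as still (the contrast is
  locomotion vs non-locomotion); for WhiskMI they are excluded, so whisk
  bouts cannot contaminate their own reference.

Both indices are computed from dF/F directly, not from detected events,
and lie in [-1, 1] whenever both means are non-negative. Because dF/F
can be slightly negative (baseline noise), a denominator with magnitude
below `eps` (default 1e-6) marks the result invalid rather than
producing an unstable value.

## Transition metrics

Still-to-locomotion transitions are onsets of locomotion bouts lasting
at least 3 s, analyzed in a window from 2 s before to 7 s after onset
(windows clipped by session bounds or with under-2 s of pre-onset
context are marked partial). Per transition, an ROI is excluded when an
event overlaps the pre-onset window or ends within 1 s before onset (a
signal still returning to baseline); the exclusion is read at the
event level rather than the signal level, the natural formalization when
events are the unit of analysis. Excluded ROIs are removed from both
numerator and denominator of the activation rate (configurable).

* **Activation rate**: fraction of included ROIs with at least one event
  onset in `(0, 7]` s, per transition.
* **Response reliability**: `RR = RA / n` per ROI, with `RA` the number
  of transitions at which the ROI emitted an event and `n` the number of
  transitions at which it was present; ROIs with `n < 3` are reported
  missing.
* **Onset lag**: first event onset minus transition time, restricted to
  `(0, 7]` s (an onset exactly at the transition is not a response to
  it); the group-level estimate is a hierarchical bootstrap over mice
  then ROIs of per-ROI mean lags.

## Hierarchical bootstrap

Group comparisons resample mice with replacement, then ROI values within
each drawn mouse (same counts as observed at both levels), recording the
overall mean; 10,000 iterations by default. For two groups the paired
iteration means give the exceedance probability
`p_one = P(m_A > m_B)` with ties counted as one half (unbiased under
exchangeability); the reported `p_boot` doubles the smaller tail for a
two-sided test (one-sided reporting available). Identical inputs and
seed reproduce results exactly; the implementation resamples all
occurrences of each mouse in one vectorized draw, so large calibration
experiments remain cheap.

A known limitation, visible in our own calibration experiments: with few
clusters (about five mice) and a large mouse-level variance share, the
mouse-level resampling underestimates between-mouse uncertainty and the
test becomes mildly anticonservative (empirical type-I error near 0.08
at nominal 0.05 when the ROI-level spread is small). At the broad
ROI-level dispersions typical of per-ROI modulation indices the test is
well calibrated, which is the regime the package's calibration check
exercises (6 vs 5 mice, 8–12 ROIs per mouse, mouse-level s.d. 0.1,
ROI-level s.d. 0.35).

## The synthetic-data generator

`simulate_session()` produces complete sessions with known ground truth:

* **Schedule**: alternating Still/Locomotion bouts with exponential
  durations (means 30 s and 8 s; locomotion floored at 1 s, stillness at
  2 s so the segmenter's merge rules are exercised but recoverable), and
  whisk bouts within stillness as a renewal process (6 bouts/min, mean
  1.5 s, floored at 0.5 s with 0.5 s margins and gaps).
* **Behavior traces**: still speed is sub-1 cm/s jitter; locomotion
  speed is Gaussian around 5 cm/s truncated above 1.5 cm/s; whisker
  energy is a baseline level with elevated bouts, and is continuously
  elevated during locomotion.
* **Fluorescence**: per ROI, events arrive as a state-switched Poisson
  process; rates, amplitudes and durations per compartment, state and
  genotype ship as presets patterned on published group statistics for
  wild-type and IP3R2-knockout mice (`genotype_preset()`); neuron event
  amplitude (0.6 dF/F) and duration (1.5 s) are chosen as typical soma
  transients since per-state values are not published. Each event
  contributes a one-sample-rise, single-exponential-decay kernel with
  `tau = duration / 4` (the kernel has decayed to ~2% at its nominal
  duration, making zero-crossing durations comparable to nominal ones);
  the kernel shape is a stand-in — detection only needs threshold
  crossings and zero crossings. Astrocytic ROIs share a field-of-view
  event train (80% of their rate in the wild-type-like regime, 40%
  knockout-like), which couples their activity as in real fields of
  view. Neuron traces receive `alpha_true * F_np` of a shared,
  state-modulated neuropil trace, which is emitted alongside. The
  knockout-like neuron kernel duration during locomotion balances the
  state rate-amplitude-duration products, so event-driven mean neuronal
  dF/F is unmodulated by locomotion in that regime.
* **Noise**: i.i.d. Gaussian per sample (the shot-noise/denoising stage
  of an imaging pipeline is upstream of this package, so synthetic noise
  plays the role of post-denoising residuals).

A second, complementary generator mode produces **state-modulated dF/F
directly** (`simulate_state_modulated_dff()`, and at cohort scale
`simulate_modulated_cohort()` with per-compartment true-LocMI presets in
`modulation_preset()`): the clean trace is a per-state constant plus
noise, so the true modulation index is known analytically and exactly.
This mode drives the modulation-recovery and group-contrast validations;
the event-statistics presets do not by themselves constrain the
modulation of mean dF/F, so the two modes describe complementary aspects
of the data.

### What the generator does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
state-dependent event statistics, shared drive within a field of view,
neuropil contamination, bleaching, and genotype effect sizes. It does
not emulate pixel-level imaging, hemodynamics, non-Gaussian or
time-varying noise, spike-train-level neuronal dynamics, or whisker
video; passing tests therefore validate the analysis logic and its
statistical behavior under the stated model, not performance on raw
microscope output.

One consequence of the noise model deserves emphasis. On i.i.d. Gaussian
noise, a `2 * sigma` threshold (with sigma taken from the least noisy
window) is crossed by noise alone at a rate of tens of small events per
minute regardless of the noise amplitude — threshold and noise scale
together. Denoised recordings do not behave this way (their residual
noise is smooth and effectively bounded), which is why the threshold
works in practice. Validations that compare detected event *frequencies*
between genotypes therefore use noiseless event-based sessions (the
denoised limit, via the detector's absolute-floor fallback), while
amplitude/recovery validations inject transients into noisy traces where
the FP floor is irrelevant. Users applying the detector to data with
appreciable Gaussian-like sample noise should expect a small-amplitude
false-event floor and may wish to set `max_event_duration` or filter on
amplitude downstream.

## Validation problem sizes

The test suite and the acceptance script rerun, from scratch: the
segmentation oracle equivalence on 1000 random traces; the event
detector against a naive scan on constructed and random traces;
transient recovery (40 noisy traces, ~170 injected transients of peak
3–6 sigma); modulation recovery on 100 state-modulated ROIs at noise
s.d. 0.1 over a 600 s session; bootstrap type-I calibration on 200
replicate null experiments at 1000 iterations; and a genotype-contrast
experiment with 6 wild-type-like vs 5 knockout-like mice (the study
design's animal counts), 300 s sessions with six astrocytic-soma ROIs
per mouse for event frequency, and 10 ROIs per mouse in the
state-modulated mode for the LocMI contrasts. These sizes are the
package's chosen validation conditions; all are reproducible from a
single seed.

## Worked example

```{r example, eval = FALSE}
library(calmod)

cfg <- sim_config(seed = 42, genotype = "wildtype", duration = 300,
                  rois_per_compartment = c(AS = 4, AP = 4, Gp = 4,
                                           AE = 1, Neuron = 3))
s <- simulate_session(cfg)
res <- run_pipeline(s, out_dir = "run01")

head(res$segmentation)
subset(res$modulation, index_kind == "LocMI" & compartment == "AS")
res$activation
res$reliability

# group comparison of astrocytic LocMI between two cohorts
wt <- simulate_modulated_cohort("wildtype", 6, 10, seed = 1)
ko <- simulate_modulated_cohort("knockout", 5, 10, seed = 2)
mi <- function(co) {
  out <- do.call(rbind, lapply(co$dff_list, function(d)
    compute_locmi(d, co$segmentations[[d$mouse_id]])))
  out[out$valid, ]
}
mw <- mi(wt); mk <- mi(ko)
compare_groups(mw$value, mw$mouse_id, mk$value, mk$mouse_id,
               n_boot = 10000, seed = 3,
               labels = c("wildtype", "knockout"))
```

## Known limitations

* The scalar-F0 baseline under-corrects slow baseline undulations that a
  rolling baseline would track; with the linear detrend this matches the
  stated procedure, but traces with strong nonlinear drift will bias
  dF/F.
* Zero-crossing durations are ill-defined on traces that never return to
  zero (sustained activity); `max_event_duration` provides a guard, off
  by default because the duration definition is zero-crossing-based.
* Mixed-effects modeling of event amplitude/duration/frequency is out of
  scope; `export_tidy_tables()` writes per-event and per-ROI tables
  shaped for nlme/GLMMadaptive/emmeans-style analysis in dedicated
  tools.
* The hierarchical bootstrap's mild anticonservativeness with few, highly
  distinct clusters (above) applies to any two-level resampling scheme;
  with ~5 mice, significance near the threshold should be read with
  care.
```
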