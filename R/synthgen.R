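# Synthetic-session generator: behavior schedule, wheel-speed and whisker
# motion-energy traces, and multi-ROI fluorescence with known ground truth,
# for wild-type-like and IP3R2-knockout-like parameter regimes.

COMPARTMENTS <- c("AS", "AP", "Gp", "AE", "Neuron")
ASTRO_COMPARTMENTS <- c("AS", "AP", "Gp", "AE")
STATES <- c("Still", "StillWhisking", "Locomotion")

#' Per-compartment event statistics for a genotype preset
#'
#' Returns the event model used by [sim_config()]: expected event rate
#' (events/min), mean peak amplitude (dF/F units) and mean duration (s) for
#' every compartment (astrocytic soma AS, processes AP, gliopil Gp, endfeet
#' AE, and neuron somata) in each behavioral state. The wild-type-like and
#' knockout-like presets are patterned on published group statistics for the
#' two genotypes: knockout-like astrocytic rates are one to two orders of
#' magnitude below wild-type-like rates, while neuronal rates barely differ.
#'
#' @param genotype `"wildtype"` or `"knockout"`.
#' @return A data.frame with columns `compartment`, `state`, `rate_per_min`,
#'   `amp_mean`, `dur_mean`.
#' @export
genotype_preset <- function(genotype = c("wildtype", "knockout")) {
  genotype <- match.arg(genotype)
  grid <- expand.grid(
    state = STATES, compartment = COMPARTMENTS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("compartment", "state")]
  if (genotype == "wildtype") {
    grid$rate_per_min <- c(
      0.69, 1.92, 2.91,   # AS
      0.87, 2.56, 2.66,   # AP
      0.86, 2.28, 2.62,   # Gp
      1.20, 2.68, 3.83,   # AE
      1.19, 0.80, 1.62    # Neuron
    )
    grid$amp_mean <- c(
      0.95, 1.02, 2.12,
      0.72, 0.74, 1.39,
      0.55, 0.56, 1.00,
      0.80, 1.04, 2.65,
      0.60, 0.60, 0.60
    )
    grid$dur_mean <- c(
      10.14, 11.05, 17.28,
      9.63, 10.16, 16.18,
      9.19, 9.72, 15.80,
      7.51, 8.56, 17.12,
      1.50, 1.50, 1.50
    )
  } else {
    grid$rate_per_min <- c(
      0.06, 0.03, 0.34,
      0.01, 0.001, 0.13,
      0.03, 0.014, 0.14,
      0.00, 0.00, 0.23,
      0.95, 1.31, 1.35
    )
    grid$amp_mean <- c(
      0.24, 0.29, 0.29,
      0.34, 0.26, 0.26,
      0.25, 0.26, 0.27,
      0.00, 0.00, 0.36,
      0.60, 0.60, 0.60
    )
    grid$dur_mean <- c(
      7.56, 10.26, 10.59,
      7.80, 9.19, 8.12,
      7.50, 6.44, 7.27,
      0.00, 0.00, 13.05,
      # neuron kernel duration during locomotion balances the state
      # rate x amplitude x duration products so mean neuronal dF/F is
      # unmodulated by locomotion in the knockout-like regime
      1.50, 1.50, 1.50 * 0.95 / 1.35
    )
  }
  grid
}

#' Configuration for a synthetic imaging session
#'
#' Bundles every knob of the generator: acquisition (sampling rate,
#' duration), ROI counts per compartment, the behavioral-state schedule
#' (mean bout durations and whisk-bout rate during stillness), the
#' compartment-by-state event model (rate, amplitude, duration), baseline
#' fluorescence, photobleaching slope, additive noise, neuropil
#' contamination, and the level of shared drive that couples astrocytic
#' ROIs within a field of view.
#'
#' @param seed Integer seed; identical configurations (including seed)
#'   produce bit-identical sessions.
#' @param genotype `"wildtype"` or `"knockout"`; selects the event-model
#'   preset and the default shared-drive fraction.
#' @param sampling_rate Acquisition rate in Hz.
#' @param duration Session length in seconds.
#' @param rois_per_compartment Named integer vector with entries
#'   `AS`, `AP`, `Gp`, `AE`, `Neuron`.
#' @param event_model Data.frame as returned by [genotype_preset()];
#'   override to set custom rates/amplitudes/durations.
#' @param still_bout_mean,loc_bout_mean Mean Still / Locomotion bout
#'   durations (s) of the alternating schedule.
#' @param loc_bout_prob Probability that a locomotion bout follows a still
#'   bout; 0 yields an all-Still session.
#' @param whisk_rate_per_min Whisk-bout rate within Still periods
#'   (bouts/min); 0 disables whisking bouts.
#' @param whisk_bout_mean Mean whisk-bout duration (s).
#' @param baseline_f0 Baseline fluorescence level (a.u.).
#' @param noise_sd Additive Gaussian noise s.d. on raw fluorescence (a.u.).
#' @param bleach_slope Linear photobleaching slope (a.u./s; typically
#'   negative).
#' @param alpha_true True neuropil contamination weight mixed into neuron
#'   traces (0-1).
#' @param shared_frac Fraction of each astrocytic ROI's events drawn from a
#'   field-of-view-shared event train (controls inter-ROI correlation);
#'   default 0.8 for wild-type-like, 0.4 for knockout-like regimes.
#' @param amp_cv,dur_cv Coefficient of variation of per-event amplitude and
#'   duration draws.
#' @param speed_mean,speed_sd Locomotion speed level and spread (cm/s).
#' @param still_jitter_sd S.d. of the residual speed jitter during Still
#'   (cm/s; clipped below 1 cm/s).
#' @param whisk_base,whisk_high Whisker motion-energy level (a.u.) at rest
#'   and during whisking/locomotion.
#' @param whisk_noise_sd Noise s.d. on the motion-energy trace (a.u.).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genotype = c("wildtype", "knockout"),
                       sampling_rate = 10,
                       duration = 600,
                       rois_per_compartment = c(AS = 8L, AP = 16L, Gp = 16L,
                                                AE = 2L, Neuron = 8L),
                       event_model = NULL,
                       still_bout_mean = 30,
                       loc_bout_mean = 8,
                       loc_bout_prob = 1,
                       whisk_rate_per_min = 6,
                       whisk_bout_mean = 1.5,
                       baseline_f0 = 100,
                       noise_sd = 2,
                       bleach_slope = -0.02,
                       alpha_true = 0.7,
                       shared_frac = NULL,
                       amp_cv = 0.25,
                       dur_cv = 0.25,
                       speed_mean = 5,
                       speed_sd = 0.5,
                       still_jitter_sd = 0.1,
                       whisk_base = 1,
                       whisk_high = 5,
                       whisk_noise_sd = 0.05) {
  genotype <- match.arg(genotype)
  assert_scalar_pos(sampling_rate, "sampling_rate")
  assert_scalar_pos(duration, "duration")
  assert_scalar_pos(baseline_f0, "baseline_f0")
  if (is.null(event_model)) event_model <- genotype_preset(genotype)
  req <- c("compartment", "state", "rate_per_min", "amp_mean", "dur_mean")
  if (!all(req %in% names(event_model))) {
    stop("event_model must have columns ", paste(req, collapse = ", "))
  }
  if (any(event_model$rate_per_min < 0) || any(event_model$amp_mean < 0) ||
      any(event_model$dur_mean < 0)) {
    stop("event rates, amplitudes and durations must be non-negative")
  }
  if (alpha_true < 0 || alpha_true > 1) {
    stop("alpha_true must lie in [0, 1]")
  }
  if (still_bout_mean <= 0 || loc_bout_mean < 0 ||
      loc_bout_prob < 0 || loc_bout_prob > 1 ||
      whisk_rate_per_min < 0 || whisk_bout_mean <= 0) {
    stop("invalid state-schedule parameters")
  }
  if (noise_sd < 0 || whisk_noise_sd < 0) stop("noise sd must be >= 0")
  miss <- setdiff(COMPARTMENTS, names(rois_per_compartment))
  if (length(miss)) {
    stop("rois_per_compartment missing entries: ", paste(miss, collapse = ", "))
  }
  if (is.null(shared_frac)) {
    shared_frac <- if (genotype == "wildtype") 0.8 else 0.4
  }
  structure(
    list(
      seed = as.integer(seed), genotype = genotype,
      sampling_rate = sampling_rate, duration = duration,
      rois_per_compartment = rois_per_compartment,
      event_model = event_model,
      still_bout_mean = still_bout_mean, loc_bout_mean = loc_bout_mean,
      loc_bout_prob = loc_bout_prob,
      whisk_rate_per_min = whisk_rate_per_min,
      whisk_bout_mean = whisk_bout_mean,
      baseline_f0 = baseline_f0, noise_sd = noise_sd,
      bleach_slope = bleach_slope, alpha_true = alpha_true,
      shared_frac = shared_frac, amp_cv = amp_cv, dur_cv = dur_cv,
      speed_mean = speed_mean, speed_sd = speed_sd,
      still_jitter_sd = still_jitter_sd,
      whisk_base = whisk_base, whisk_high = whisk_high,
      whisk_noise_sd = whisk_noise_sd
    ),
    class = "sim_config"
  )
}

# sample a bout length in whole samples, exponential with given mean (s),
# truncated below at min_s seconds
draw_bout_samples <- function(mean_s, min_s, fs) {
  len <- max(stats::rexp(1L, rate = 1 / mean_s), min_s)
  max(1L, as.integer(round(len * fs)))
}

#' Generate behavior traces and the true state schedule
#'
#' Produces a wheel-speed trace alternating still periods (residual jitter
#' below 1 cm/s) with locomotion bouts (speed well above 1 cm/s), and a
#' whisker motion-energy trace with discrete whisk bouts during stillness
#' and continuously elevated energy during locomotion, plus the true
#' labeled schedule (an exhaustive partition of the session into Still,
#' Still-Whisking and Locomotion).
#'
#' @param config A [sim_config()].
#' @return A list with `behavior` (data.frame `time_s`, `speed_cmps`,
#'   `whisk_energy` with attribute `sampling_rate`) and `schedule`
#'   (data.frame `start_s`, `end_s`, `label`).
#' @export
generate_behavior <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration * fs))
  if (n < 2L) stop("duration too short for the configured sampling rate")
  with_seed(config$seed, {
    # alternating Still / Locomotion schedule, built in whole samples.
    # bouts are floored (still >= 2 s, locomotion >= 1 s) so that the
    # segmenter's merge/minimum-duration rules recover the truth exactly.
    state <- integer(0) # 1 = Still, 3 = Locomotion
    while (length(state) < n) {
      still_n <- draw_bout_samples(config$still_bout_mean, 2, fs)
      state <- c(state, rep(1L, still_n))
      if (length(state) >= n) break
      if (config$loc_bout_mean > 0 &&
          stats::runif(1L) < config$loc_bout_prob) {
        loc_n <- draw_bout_samples(config$loc_bout_mean, 1, fs)
        state <- c(state, rep(3L, loc_n))
      }
    }
    state <- state[seq_len(n)]

    # whisk bouts inside still periods: renewal process with >= 0.5 s
    # margins and gaps so smoothing cannot fuse adjacent truth bouts
    if (config$whisk_rate_per_min > 0) {
      margin_n <- as.integer(round(0.5 * fs))
      min_gap_n <- as.integer(round(0.5 * fs))
      still_runs <- runs_from_mask(state == 1L)
      rate_per_s <- config$whisk_rate_per_min / 60
      for (i in seq_len(nrow(still_runs))) {
        lo <- still_runs$first[i] + margin_n
        hi <- still_runs$last[i] - margin_n
        pos <- lo + as.integer(round(stats::rexp(1L, rate_per_s) * fs))
        while (pos <= hi) {
          len <- max(1L, as.integer(round(
            max(stats::rexp(1L, 1 / config$whisk_bout_mean), 0.5) * fs
          )))
          stop_at <- min(pos + len - 1L, hi)
          state[pos:stop_at] <- 2L
          pos <- stop_at + min_gap_n +
            as.integer(round(stats::rexp(1L, rate_per_s) * fs)) + 1L
        }
      }
    }

    speed <- numeric(n)
    is_loc <- state == 3L
    speed[!is_loc] <- pmin(abs(stats::rnorm(sum(!is_loc), 0,
                                            config$still_jitter_sd)), 0.9)
    speed[is_loc] <- pmax(stats::rnorm(sum(is_loc), config$speed_mean,
                                       config$speed_sd), 1.5)

    energy <- stats::rnorm(n, config$whisk_base, config$whisk_noise_sd)
    hi_mask <- state != 1L
    energy[hi_mask] <- stats::rnorm(sum(hi_mask), config$whisk_high,
                                    config$whisk_noise_sd)
    energy <- pmax(energy, 0)

    behavior <- data.frame(
      time_s = (seq_len(n) - 1L) / fs,
      speed_cmps = speed,
      whisk_energy = energy
    )
    attr(behavior, "sampling_rate") <- fs

    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    schedule <- data.frame(
      start_s = (starts - 1L) / fs,
      end_s = ends / fs,
      label = STATES[r$values]
    )
    list(behavior = behavior, schedule = schedule)
  })
}

# state index (1 Still, 2 StillWhisking, 3 Locomotion) per sample
schedule_to_state <- function(schedule, n, fs) {
  state <- integer(n)
  runs <- intervals_to_runs(schedule, fs, n)
  lab <- match(schedule$label, STATES)
  for (i in seq_len(nrow(runs))) {
    state[runs$first[i]:runs$last[i]] <- lab[i]
  }
  if (any(state == 0L)) stop("schedule does not cover the session")
  state
}

# draw from a gamma with given mean and coefficient of variation
draw_gamma <- function(k, mean, cv) {
  if (mean <= 0) return(rep(0, k))
  if (cv <= 0) return(rep(mean, k))
  shape <- 1 / cv^2
  stats::rgamma(k, shape = shape, scale = mean / shape)
}

# Poisson event onsets (sample indices) given per-sample rate in events/min
draw_onsets <- function(rate_per_min_by_sample, fs) {
  p <- rate_per_min_by_sample / 60 / fs
  which(stats::runif(length(p)) < p)
}

# add a fast-rise single-exponential-decay kernel to a signal (in place)
add_kernel <- function(sig, onset_idx, amp, dur_s, fs) {
  if (dur_s <= 0 || amp <= 0) return(sig)
  tau <- dur_s / 4
  span <- as.integer(ceiling(1.5 * dur_s * fs))
  idx <- onset_idx:min(length(sig), onset_idx + span)
  t_rel <- (idx - onset_idx) / fs
  sig[idx] <- sig[idx] + amp * exp(-t_rel / tau)
  sig
}

#' Generate ROI fluorescence traces with ground truth
#'
#' For each configured ROI, events arrive as an inhomogeneous Poisson
#' process whose rate switches with the true behavioral state; each event
#' contributes a one-sample-rise, single-exponential-decay kernel whose
#' amplitude and nominal duration are drawn from the compartment-by-state
#' event model. Astrocytic ROIs within the synthetic field of view share a
#' common event train (fraction `shared_frac` of their rate), which couples
#' their activity. Neuron traces receive an additive shared neuropil
#' component with weight `alpha_true`, and the neuropil trace itself is
#' emitted alongside. Raw fluorescence is
#' `F0 * (1 + dff_clean) + bleach_slope * t + noise`.
#'
#' @param config A [sim_config()].
#' @param schedule True state schedule from [generate_behavior()].
#' @return A list with `traces` (list of [roi_trace()]) and `ground_truth`
#'   (list: `events` data.frame with true onsets/amplitudes/durations and
#'   the state at onset, `schedule`, `alpha_true`, `state_means` of the
#'   clean dF/F per ROI and state, `roi_info`).
#' @export
generate_fluorescence <- function(config, schedule) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration * fs))
  state <- schedule_to_state(schedule, n, fs)
  em <- config$event_model
  rate_of <- function(comp) {
    sapply(STATES, function(s) {
      em$rate_per_min[em$compartment == comp & em$state == s]
    })
  }

  with_seed(config$seed + 1L, {
    # FOV-shared astrocytic event train at the envelope (maximum) rate;
    # each ROI keeps a shared event with probability
    # shared_frac * rate_roi(state) / rate_max(state)
    astro_rates <- sapply(ASTRO_COMPARTMENTS, rate_of) # 3 x 4, states x comp
    max_rate <- apply(astro_rates, 1L, max)
    shared_onsets <- draw_onsets(max_rate[state], fs)

    t_sec <- (seq_len(n) - 1L) / fs
    bleach <- config$bleach_slope * t_sec

    # shared neuropil signal: state-modulated slow component plus AR(1)
    np_dff <- ifelse(state == 3L, 0.3, 0.05) +
      as.numeric(stats::filter(stats::rnorm(n, 0, 0.02), 0.95,
                               method = "recursive"))
    f_np <- config$baseline_f0 * 0.5 * (1 + np_dff) + bleach +
      stats::rnorm(n, 0, config$noise_sd)

    traces <- list()
    truth_events <- list()
    state_means <- list()
    roi_rows <- list()

    for (comp in COMPARTMENTS) {
      k_rois <- config$rois_per_compartment[[comp]]
      if (k_rois < 1L) next
      rates <- rate_of(comp)
      amps <- sapply(STATES, function(s) {
        em$amp_mean[em$compartment == comp & em$state == s]
      })
      durs <- sapply(STATES, function(s) {
        em$dur_mean[em$compartment == comp & em$state == s]
      })
      is_astro <- comp %in% ASTRO_COMPARTMENTS
      for (j in seq_len(k_rois)) {
        roi_id <- sprintf("%s_%02d", comp, j)
        onsets <- integer(0)
        if (is_astro && config$shared_frac > 0) {
          p_keep <- ifelse(max_rate[state[shared_onsets]] > 0,
                           config$shared_frac *
                             rates[state[shared_onsets]] /
                             max_rate[state[shared_onsets]],
                           0)
          onsets <- shared_onsets[stats::runif(length(shared_onsets)) < p_keep]
          priv_rate <- (1 - config$shared_frac) * rates[state]
        } else {
          priv_rate <- rates[state]
        }
        onsets <- sort(unique(c(onsets, draw_onsets(priv_rate, fs))))

        k_ev <- length(onsets)
        ev_state <- state[onsets]
        ev_amp <- numeric(k_ev)
        ev_dur <- numeric(k_ev)
        clean <- numeric(n)
        if (k_ev > 0L) {
          for (s_idx in 1:3) {
            sel <- which(ev_state == s_idx)
            if (!length(sel)) next
            ev_amp[sel] <- draw_gamma(length(sel), amps[s_idx], config$amp_cv)
            ev_dur[sel] <- pmax(
              draw_gamma(length(sel), durs[s_idx], config$dur_cv), 0.5
            )
          }
          for (e in seq_len(k_ev)) {
            clean <- add_kernel(clean, onsets[e], ev_amp[e], ev_dur[e], fs)
          }
        }

        f_raw <- config$baseline_f0 * (1 + clean) + bleach +
          stats::rnorm(n, 0, config$noise_sd)
        f_np_roi <- NULL
        if (comp == "Neuron") {
          f_raw <- f_raw + config$alpha_true * f_np
          f_np_roi <- f_np
        }
        traces[[roi_id]] <- roi_trace(
          roi_id = roi_id, compartment = comp, F = f_raw,
          F_np = f_np_roi, sampling_rate = fs
        )
        if (k_ev > 0L) {
          truth_events[[roi_id]] <- data.frame(
            roi_id = roi_id,
            onset_s = (onsets - 1L) / fs,
            amplitude = ev_amp,
            duration_s = ev_dur,
            state = STATES[ev_state]
          )
        }
        sm <- vapply(1:3, function(s_idx) {
          if (any(state == s_idx)) mean(clean[state == s_idx]) else NA_real_
        }, numeric(1))
        state_means[[roi_id]] <- data.frame(
          roi_id = roi_id, state = STATES, mean_dff = sm
        )
        roi_rows[[roi_id]] <- data.frame(
          roi_id = roi_id, compartment = comp
        )
      }
    }

    ground_truth <- list(
      events = if (length(truth_events)) {
        do.call(rbind, c(truth_events, list(make.row.names = FALSE)))
      } else {
        data.frame(roi_id = character(0), onset_s = numeric(0),
                   amplitude = numeric(0), duration_s = numeric(0),
                   state = character(0))
      },
      schedule = schedule,
      alpha_true = config$alpha_true,
      state_means = do.call(rbind, c(state_means,
                                     list(make.row.names = FALSE))),
      roi_info = do.call(rbind, c(roi_rows, list(make.row.names = FALSE)))
    )
    list(traces = traces, ground_truth = ground_truth)
  })
}

#' Simulate a complete synthetic session
#'
#' Runs [generate_behavior()] and [generate_fluorescence()] and assembles a
#' [session()] carrying the ground truth.
#'
#' @param config A [sim_config()].
#' @param session_id,mouse_id,group Identifiers stamped on the session and
#'   all its ROIs; `group` defaults to the configured genotype.
#' @return A `session` object (see [session()]).
#' @export
simulate_session <- function(config, session_id = "sim01",
                             mouse_id = "mouse01", group = NULL) {
  group <- group %||% config$genotype
  beh <- generate_behavior(config)
  fl <- generate_fluorescence(config, beh$schedule)
  for (id in names(fl$traces)) {
    fl$traces[[id]]$session_id <- session_id
    fl$traces[[id]]$mouse_id <- mouse_id
    fl$traces[[id]]$group <- group
  }
  fl$ground_truth$roi_info$mouse_id <- mouse_id
  fl$ground_truth$roi_info$group <- group
  session(
    session_id = session_id, mouse_id = mouse_id, group = group,
    sampling_rate = config$sampling_rate, duration = config$duration,
    traces = fl$traces, behavior = beh$behavior,
    ground_truth = fl$ground_truth
  )
}

#' Simulate a cohort of mice for one genotype
#'
#' One session per mouse, with per-mouse seeds derived from `seed`.
#'
#' @param genotype `"wildtype"` or `"knockout"`.
#' @param n_mice Number of mice.
#' @param seed Base seed.
#' @param ... Passed to [sim_config()] (e.g. `duration`,
#'   `rois_per_compartment`).
#' @return List of `session` objects.
#' @export
simulate_cohort <- function(genotype, n_mice, seed = 1L, ...) {
  lapply(seq_len(n_mice), function(i) {
    cfg <- sim_config(seed = seed + i * 1000L, genotype = genotype, ...)
    simulate_session(
      cfg,
      session_id = sprintf("%s_s%02d", genotype, i),
      mouse_id = sprintf("%s_m%02d", genotype, i)
    )
  })
}

#' Directly state-modulated dF/F trace
#'
#' Generates a dF/F trace whose clean value is a per-state constant plus
#' i.i.d. Gaussian noise. This is the generator mode used to validate the
#' modulation indices against their analytic values: for state means
#' `m_active` and `m_still` the true index is exactly
#' `(m_active - m_still) / (m_active + m_still)` (see [analytic_mi()]).
#'
#' @param schedule State schedule (data.frame `start_s`, `end_s`, `label`).
#' @param state_means Named numeric vector with entries `Still`,
#'   `StillWhisking`, `Locomotion` (clean dF/F level per state).
#' @param noise_sd I.i.d. Gaussian noise s.d. (dF/F units).
#' @param sampling_rate Hz.
#' @param seed Optional seed.
#' @return A `dff_trace` whose `dff` field holds the noisy trace.
#' @export
simulate_state_modulated_dff <- function(schedule, state_means,
                                         noise_sd = 0.1,
                                         sampling_rate = 10,
                                         seed = NULL) {
  stopifnot(all(STATES %in% names(state_means)))
  fs <- sampling_rate
  n <- as.integer(round(max(schedule$end_s) * fs))
  state <- schedule_to_state(schedule, n, fs)
  dff <- with_seed(seed, {
    as.numeric(state_means[STATES][state]) + stats::rnorm(n, 0, noise_sd)
  })
  new_dff_trace(
    dff = dff, F0 = 1, sigma = NULL, roi_id = "state_modulated",
    compartment = "AS", sampling_rate = fs
  )
}

#' Per-compartment locomotion-modulation presets for a genotype
#'
#' True group-level locomotion modulation indices (LocMI) of mean dF/F for
#' each compartment, patterned on published group statistics: strong
#' positive astrocytic modulation and moderate neuronal modulation in the
#' wild-type-like regime; reduced astrocytic and near-zero neuronal
#' modulation in the knockout-like regime. These parameters drive the
#' state-mean generator mode ([simulate_modulated_cohort()]); the
#' event-statistics presets ([genotype_preset()]) do not by themselves
#' constrain the modulation of mean dF/F.
#'
#' @param genotype `"wildtype"` or `"knockout"`.
#' @return Named numeric vector of true LocMI per compartment.
#' @export
modulation_preset <- function(genotype = c("wildtype", "knockout")) {
  genotype <- match.arg(genotype)
  if (genotype == "wildtype") {
    c(AS = 0.787, AP = 0.752, Gp = 0.737, AE = 0.785, Neuron = 0.203)
  } else {
    c(AS = 0.257, AP = 0.328, Gp = 0.281, AE = 0.415, Neuron = -0.02)
  }
}

#' Simulate a cohort of state-modulated dF/F ROIs
#'
#' Generates, for each mouse, a behavior schedule plus a set of ROIs whose
#' dF/F is directly state-modulated: each ROI's true LocMI is drawn around
#' the genotype's [modulation_preset()] value with mouse- and ROI-level
#' spread, converted to still/locomotion state means
#' (`m_loc = m_still (1 + MI) / (1 - MI)`), and realized as a noisy trace
#' via [simulate_state_modulated_dff()]. Whisking bouts share the still
#' mean (whisk modulation is not part of this preset).
#'
#' @param genotype `"wildtype"` or `"knockout"`.
#' @param n_mice Number of mice.
#' @param rois_per_mouse ROIs per mouse.
#' @param compartment Compartment label for the ROIs (default `"AS"`).
#' @param seed Base seed.
#' @param duration Session length (s).
#' @param mouse_sd,roi_sd Between-mouse and between-ROI spread of true
#'   LocMI (defaults 0.1 and 0.3; the reported per-ROI index histograms
#'   are broad).
#' @param m_still True still-state mean dF/F level (default 0.1).
#' @param noise_sd Sample noise on dF/F (default 0.1).
#' @return List with `behavior`/`schedule`/`segmentation` per mouse and a
#'   data.frame `rois` (`roi_id`, `mouse_id`, `group`, `true_mi`, `dff`
#'   list-column omitted; traces in `dff_list`), plus `dff_list` and
#'   `truth` (true LocMI per ROI).
#' @export
simulate_modulated_cohort <- function(genotype, n_mice, rois_per_mouse = 10,
                                      compartment = "AS", seed = 1L,
                                      duration = 300, mouse_sd = 0.1,
                                      roi_sd = 0.3, m_still = 0.1,
                                      noise_sd = 0.1) {
  base_mi <- modulation_preset(genotype)[[compartment]]
  dff_list <- list()
  truth <- list()
  segs <- list()
  for (i in seq_len(n_mice)) {
    mouse_id <- sprintf("%s_m%02d", genotype, i)
    cfg <- sim_config(seed = seed + i * 1000L, genotype = genotype,
                      duration = duration,
                      rois_per_compartment = c(AS = 1, AP = 0, Gp = 0,
                                               AE = 0, Neuron = 0))
    beh <- generate_behavior(cfg)
    segs[[mouse_id]] <- segment_behavior(beh$behavior)
    mi_mouse <- with_seed(seed + i * 1000L + 500L, {
      mu <- base_mi + stats::rnorm(1L, 0, mouse_sd)
      pmin(pmax(stats::rnorm(rois_per_mouse, mu, roi_sd), -0.9), 0.9)
    })
    for (j in seq_len(rois_per_mouse)) {
      roi_id <- sprintf("%s_r%02d", mouse_id, j)
      m_loc <- m_still * (1 + mi_mouse[j]) / (1 - mi_mouse[j])
      d <- simulate_state_modulated_dff(
        beh$schedule,
        c(Still = m_still, StillWhisking = m_still, Locomotion = m_loc),
        noise_sd = noise_sd, sampling_rate = cfg$sampling_rate,
        seed = seed + i * 1000L + j
      )
      d$roi_id <- roi_id
      d$compartment <- compartment
      d$mouse_id <- mouse_id
      d$group <- genotype
      dff_list[[roi_id]] <- d
      truth[[roi_id]] <- data.frame(
        roi_id = roi_id, mouse_id = mouse_id, group = genotype,
        true_mi = mi_mouse[j]
      )
    }
  }
  list(dff_list = dff_list, segmentations = segs,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Analytic modulation index from state means
#'
#' @param m_active,m_still Mean dF/F in the active (locomotion or whisking)
#'   and qualifying still states.
#' @return `(m_active - m_still) / (m_active + m_still)`.
#' @export
analytic_mi <- function(m_active, m_still) {
  (m_active - m_still) / (m_active + m_still)
}
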