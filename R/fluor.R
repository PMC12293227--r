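# dF/F extraction and Ca2+ event detection.
#
# Processing chain: linear detrend (photobleaching) -> neuropil subtraction
# (neurons only) -> dF/F with a percentile baseline on the Savitzky-Golay
# smoothed trace -> noise floor sigma from the least-noisy window -> event
# detection at k * sigma with zero-crossing event extents.

#' Construct an ROI fluorescence trace
#'
#' @param roi_id Identifier, unique within a session.
#' @param compartment One of `"AS"`, `"AP"`, `"Gp"`, `"AE"` (astrocytic
#'   soma, processes, gliopil, endfeet) or `"Neuron"`.
#' @param F Raw fluorescence samples (a.u.).
#' @param F_np Optional paired neuropil samples (a.u.), same length as `F`;
#'   required to neuropil-correct neuron somata.
#' @param sampling_rate Hz.
#' @param session_id,mouse_id,group Optional identifiers carried through
#'   the pipeline into tidy outputs.
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(roi_id, compartment, F, F_np = NULL,
                      sampling_rate = 10, session_id = NA_character_,
                      mouse_id = NA_character_, group = NA_character_) {
  compartment <- as.character(compartment)
  if (!compartment %in% COMPARTMENTS) {
    stop(sprintf("unknown compartment '%s'; allowed: %s", compartment,
                 paste(COMPARTMENTS, collapse = ", ")), call. = FALSE)
  }
  F <- as.numeric(F)
  if (!all(is.finite(F))) stop("F contains non-finite samples")
  if (!is.null(F_np)) {
    F_np <- as.numeric(F_np)
    if (length(F_np) != length(F)) {
      stop(sprintf("F_np length (%d) differs from F length (%d)",
                   length(F_np), length(F)))
    }
    if (!all(is.finite(F_np))) stop("F_np contains non-finite samples")
  }
  assert_scalar_pos(sampling_rate, "sampling_rate")
  structure(
    list(roi_id = as.character(roi_id), compartment = compartment,
         F = F, F_np = F_np, sampling_rate = sampling_rate,
         session_id = session_id, mouse_id = mouse_id, group = group),
    class = "roi_trace"
  )
}

new_dff_trace <- function(dff, F0, sigma, roi_id, compartment,
                          sampling_rate, session_id = NA_character_,
                          mouse_id = NA_character_, group = NA_character_,
                          params = list()) {
  structure(
    list(dff = dff, F0 = F0, sigma = sigma, roi_id = roi_id,
         compartment = compartment, sampling_rate = sampling_rate,
         session_id = session_id, mouse_id = mouse_id, group = group,
         params = params),
    class = "dff_trace"
  )
}

#' Remove the linear trend from a fluorescence trace
#'
#' Fits a first-degree polynomial to the raw trace by least squares and
#' subtracts it, adding the fitted line's mean back so the mean
#' fluorescence level (and hence a positive baseline) is preserved. The
#' paired neuropil trace, when present, is detrended the same way.
#'
#' @param trace A [roi_trace()] of length >= 2.
#' @return The detrended `roi_trace`.
#' @export
detrend_linear <- function(trace) {
  stopifnot(inherits(trace, "roi_trace"))
  n <- length(trace$F)
  if (n < 2L) stop("detrend_linear() needs a trace of length >= 2")
  detrend1 <- function(y) {
    x <- seq_len(length(y))
    fit <- stats::lm.fit(cbind(1, x), y)
    y - fit$fitted.values + mean(fit$fitted.values)
  }
  trace$F <- detrend1(trace$F)
  if (!is.null(trace$F_np)) trace$F_np <- detrend1(trace$F_np)
  trace
}

#' Subtract the scaled neuropil signal from a neuron soma trace
#'
#' Applies `F - alpha * F_np` samplewise for neuron somata; astrocytic
#' traces are passed through unchanged so the operation can be mapped over
#' a whole session.
#'
#' @param trace A [roi_trace()].
#' @param alpha Neuropil contamination ratio (default 0.7).
#' @return The corrected `roi_trace`.
#' @export
subtract_neuropil <- function(trace, alpha = 0.7) {
  stopifnot(inherits(trace, "roi_trace"))
  if (trace$compartment != "Neuron") return(trace)
  if (is.null(trace$F_np)) {
    stop(sprintf("neuron trace '%s' has no paired neuropil trace",
                 trace$roi_id), call. = FALSE)
  }
  trace$F <- trace$F - alpha * trace$F_np
  trace
}

# odd Savitzky-Golay window closest to window_s seconds (ties upward)
sg_window_samples <- function(window_s, fs) {
  n <- as.integer(floor(window_s * fs / 2) * 2 + 1)
  max(n, 3L)
}

#' Compute dF/F with a percentile baseline
#'
#' The baseline F0 is the `percentile`-th percentile of the trace smoothed
#' with a first-order Savitzky-Golay filter over an odd window of
#' approximately `smooth_window` seconds (51 samples at 10 Hz);
#' `dff = (F - F0) / F0` with a single scalar F0 per trace.
#'
#' @param trace A [roi_trace()], typically detrended and
#'   neuropil-corrected.
#' @param smooth_window Smoothing window (s).
#' @param percentile Baseline percentile (default 10).
#' @return A `dff_trace` (fields `dff`, `F0`, `sigma` initially `NULL`).
#' @export
compute_dff <- function(trace, smooth_window = 5, percentile = 10) {
  stopifnot(inherits(trace, "roi_trace"))
  fs <- trace$sampling_rate
  n_w <- sg_window_samples(smooth_window, fs)
  if (length(trace$F) <= n_w) {
    stop("trace must be longer than the smoothing window")
  }
  smoothed <- signal::sgolayfilt(trace$F, p = 1, n = n_w)
  F0 <- as.numeric(stats::quantile(smoothed, percentile / 100, names = FALSE))
  if (!is.finite(F0) || F0 <= 0) {
    stop(sprintf("non-positive baseline F0 = %.4g for ROI '%s': check input units",
                 F0, trace$roi_id), call. = FALSE)
  }
  new_dff_trace(
    dff = (trace$F - F0) / F0, F0 = F0, sigma = NULL,
    roi_id = trace$roi_id, compartment = trace$compartment,
    sampling_rate = fs, session_id = trace$session_id,
    mouse_id = trace$mouse_id, group = trace$group,
    params = list(smooth_window = smooth_window, percentile = percentile,
                  sg_samples = n_w)
  )
}

# rolling sd over w samples, stride 1; mean-centered running sums
rolling_sd <- function(x, w) {
  n <- length(x)
  x <- x - mean(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - w + 1L)
  s <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  v <- (s2 - s^2 / w) / (w - 1)
  sqrt(pmax(v, 0))
}

#' Estimate the baseline noise level sigma
#'
#' Sigma is the sample standard deviation of dF/F within the least noisy
#' window: a sliding window of `window` seconds (stride one sample) is
#' scanned over the trace and the minimum s.d. is returned.
#'
#' @param dff A `dff_trace` (or bare numeric vector with `sampling_rate`).
#' @param window Window length (s), default 5.
#' @param sampling_rate Required only when `dff` is a bare numeric vector.
#' @return Sigma (dF/F units, scalar >= 0).
#' @export
estimate_sigma <- function(dff, window = 5, sampling_rate = NULL) {
  if (inherits(dff, "dff_trace")) {
    x <- dff$dff
    fs <- dff$sampling_rate
  } else {
    x <- as.numeric(dff)
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for a bare numeric trace")
  }
  w <- as.integer(round(window * fs))
  if (w < 2L) stop("sigma window must span at least 2 samples")
  if (length(x) < w) {
    stop(sprintf("trace (%d samples) shorter than the sigma window (%d samples)",
                 length(x), w))
  }
  min(rolling_sd(x, w))
}

default_threshold_k <- function(compartment) {
  if (identical(compartment, "Neuron")) 2.5 else 2.0
}

#' Detect Ca2+ events in a dF/F trace
#'
#' A candidate event exists wherever dF/F exceeds `k * sigma`; its extent
#' is the contiguous positive lobe of dF/F containing it (widened to the
#' nearest zero crossings, with trace ends acting as crossings), so
#' suprathreshold excursions sharing one positive lobe merge into a single
#' event. Amplitude is the maximum dF/F within the span; the onset is the
#' first suprathreshold sample; duration is the span between crossings.
#'
#' @param dff A `dff_trace`.
#' @param k Threshold multiple of sigma; defaults to 2 for astrocytic
#'   compartments and 2.5 for neurons.
#' @param sigma Noise level; computed via [estimate_sigma()] when missing.
#' @param sigma_floor Absolute dF/F threshold used (with a warning) when
#'   sigma is 0 but the trace is not flat.
#' @param max_duration Optional cap (s) on event duration; events in lobes
#'   longer than this are truncated. Default `NULL` (no cap).
#' @return A data.frame with one row per event: `roi_id`, `compartment`,
#'   `mouse_id`, `group`, `start_s`, `onset_s`, `end_s`, `duration_s`,
#'   `amplitude`, sorted by onset; zero rows when nothing crosses
#'   threshold.
#' @export
detect_events <- function(dff, k = NULL, sigma = NULL, sigma_floor = 0.05,
                          max_duration = NULL) {
  stopifnot(inherits(dff, "dff_trace"))
  x <- dff$dff
  fs <- dff$sampling_rate
  if (is.null(k)) k <- default_threshold_k(dff$compartment)
  if (is.null(sigma)) sigma <- dff$sigma %||% estimate_sigma(dff)
  threshold <- k * sigma
  if (sigma == 0 && any(x != 0)) {
    warning("sigma is 0 on a non-flat trace; using the absolute floor ",
            sigma_floor, call. = FALSE)
    threshold <- sigma_floor
  }
  empty <- data.frame(
    roi_id = character(0), compartment = character(0),
    mouse_id = character(0), group = character(0),
    start_s = numeric(0), onset_s = numeric(0), end_s = numeric(0),
    duration_s = numeric(0), amplitude = numeric(0)
  )
  above <- x > threshold
  if (!any(above)) return(empty)
  lobes <- runs_from_mask(x > 0)
  rows <- lapply(seq_len(nrow(lobes)), function(i) {
    span <- lobes$first[i]:lobes$last[i]
    sup <- span[above[span]]
    if (!length(sup)) return(NULL)
    first <- lobes$first[i]
    last <- lobes$last[i]
    if (!is.null(max_duration)) {
      cap <- as.integer(round(max_duration * fs))
      last <- min(last, first + cap - 1L)
      sup <- sup[sup <= last]
      if (!length(sup)) return(NULL)
      span <- first:last
    }
    data.frame(
      roi_id = dff$roi_id, compartment = dff$compartment,
      mouse_id = dff$mouse_id, group = dff$group,
      start_s = (first - 1L) / fs,
      onset_s = (sup[1] - 1L) / fs,
      end_s = last / fs,
      duration_s = (last - first + 1L) / fs,
      amplitude = max(x[span])
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$onset_s), , drop = FALSE]
}

#' Summarize detected events by behavioral state
#'
#' Assigns each event to the state containing its onset and tabulates, per
#' ROI and state: event count, total state time, frequency (events/min),
#' and mean amplitude/duration. States with zero total time yield a
#' missing frequency (not 0); states without events yield frequency 0 with
#' missing amplitude/duration.
#'
#' @param events Event table from [detect_events()] (rows from several
#'   ROIs may be concatenated).
#' @param segmentation A `state_segmentation` (see
#'   [compose_segmentation()]) on the same session clock.
#' @param roi_info Data.frame with one row per ROI: `roi_id`,
#'   `compartment`, and optionally `mouse_id`, `group`; ensures ROIs
#'   without events still appear.
#' @return Tidy data.frame: `roi_id`, `compartment`, `mouse_id`, `group`,
#'   `state`, `n_events`, `state_time_min`, `frequency`, `mean_amplitude`,
#'   `mean_duration`.
#' @export
summarize_events_by_state <- function(events, segmentation, roi_info) {
  stopifnot(is.data.frame(roi_info), "roi_id" %in% names(roi_info))
  seg <- as.data.frame(segmentation)
  state_time_min <- vapply(STATES, function(s) {
    sum(seg$end_s[seg$label == s] - seg$start_s[seg$label == s]) / 60
  }, numeric(1))
  if (nrow(events) > 0) {
    idx <- findInterval(events$onset_s, seg$start_s)
    events$state <- seg$label[idx]
  }
  if (!"mouse_id" %in% names(roi_info)) roi_info$mouse_id <- NA_character_
  if (!"group" %in% names(roi_info)) roi_info$group <- NA_character_
  out <- merge(
    roi_info[, c("roi_id", "compartment", "mouse_id", "group")],
    expand.grid(roi_id = roi_info$roi_id, state = STATES,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    by = "roi_id"
  )
  per <- function(roi, st, col, fun) {
    sel <- nrow(events) > 0 & events$roi_id == roi & events$state == st
    if (nrow(events) == 0 || !any(sel)) return(NA_real_)
    fun(events[[col]][sel])
  }
  out$n_events <- mapply(function(r, s) {
    if (nrow(events) == 0) 0L else sum(events$roi_id == r & events$state == s)
  }, out$roi_id, out$state)
  out$state_time_min <- state_time_min[out$state]
  out$frequency <- ifelse(out$state_time_min > 0,
                          out$n_events / out$state_time_min, NA_real_)
  out$mean_amplitude <- mapply(per, out$roi_id, out$state,
                               MoreArgs = list(col = "amplitude", fun = mean))
  out$mean_duration <- mapply(per, out$roi_id, out$state,
                              MoreArgs = list(col = "duration_s", fun = mean))
  rownames(out) <- NULL
  out[order(out$roi_id, match(out$state, STATES)), , drop = FALSE]
}
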