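# Ca2+ responses around Still -> Locomotion transitions: aligned windows,
# per-ROI inclusion filtering, activation rate per transition, per-ROI
# response reliability (RR = RA / n), and event onset lag with a
# hierarchical (mouse then ROI) bootstrap group estimate.

#' Extract Still-to-Locomotion transition windows
#'
#' One window per onset of a locomotion bout lasting at least `min_loc`
#' seconds, spanning `pre` seconds before to `post` seconds after the
#' onset. Windows clipped by the session bounds, or preceded by less than
#' `pre` seconds of non-locomotion, are marked partial (and kept).
#'
#' @param segmentation A `state_segmentation`.
#' @param pre,post Window extent around the onset (s), defaults 2 and 7.
#' @param min_loc Minimum locomotion bout duration (s, inclusive),
#'   default 3.
#' @return Data.frame: `transition_time`, `bout_duration`, `partial`.
#' @export
extract_transitions <- function(segmentation, pre = 2, post = 7,
                                min_loc = 3) {
  dur <- seg_duration(segmentation)
  loc <- segmentation[segmentation$label == "Locomotion", , drop = FALSE]
  empty <- data.frame(transition_time = numeric(0),
                      bout_duration = numeric(0), partial = logical(0))
  if (nrow(loc) == 0L) return(empty)
  loc <- loc[order(loc$start_s), , drop = FALSE]
  keep <- (loc$end_s - loc$start_s) >= min_loc
  qual <- loc[keep, , drop = FALSE]
  if (nrow(qual) == 0L) return(empty)
  partial <- vapply(seq_len(nrow(qual)), function(i) {
    t0 <- qual$start_s[i]
    if (t0 < pre || t0 + post > dur) return(TRUE)
    prev_end <- loc$end_s[loc$end_s <= t0]
    length(prev_end) > 0 && max(prev_end) > t0 - pre
  }, logical(1))
  data.frame(
    transition_time = qual$start_s,
    bout_duration = qual$end_s - qual$start_s,
    partial = partial
  )
}

#' Per-ROI, per-transition response table
#'
#' The core table behind the transition metrics. For every ROI x
#' transition pair it records whether the ROI passes the inclusion filter
#' (no event overlapping the `pre`-second pre-onset window, and no event
#' ending within `baseline_guard` seconds before the onset - a signal
#' still returning to baseline), whether the ROI responded (at least one
#' event onset in `(0, post]` seconds after the transition), and the lag
#' of the first such onset.
#'
#' @param events Event table ([detect_events()] rows, possibly several
#'   ROIs).
#' @param transitions Output of [extract_transitions()].
#' @param roi_info Data.frame `roi_id`, `compartment`, `mouse_id`, `group`
#'   (one row per ROI; ROIs without events are still scored).
#' @param pre,post Window extent (s), defaults 2 and 7.
#' @param baseline_guard Pre-onset exclusion span for event ends (s),
#'   default 1.
#' @param apply_inclusion If `FALSE`, every ROI counts at every transition
#'   (inclusion flags still reported).
#' @return Data.frame: `roi_id`, `compartment`, `mouse_id`, `group`,
#'   `transition_time`, `included`, `exclusion_reason`, `responded`,
#'   `first_lag`.
#' @export
transition_response_table <- function(events, transitions, roi_info,
                                      pre = 2, post = 7,
                                      baseline_guard = 1,
                                      apply_inclusion = TRUE) {
  stopifnot(is.data.frame(roi_info), "roi_id" %in% names(roi_info))
  if (!"mouse_id" %in% names(roi_info)) roi_info$mouse_id <- NA_character_
  if (!"group" %in% names(roi_info)) roi_info$group <- NA_character_
  if (!"compartment" %in% names(roi_info)) {
    roi_info$compartment <- NA_character_
  }
  rows <- list()
  for (i in seq_len(nrow(roi_info))) {
    roi <- roi_info$roi_id[i]
    ev <- events[nrow(events) > 0 & events$roi_id == roi, , drop = FALSE]
    for (j in seq_len(nrow(transitions))) {
      t0 <- transitions$transition_time[j]
      ongoing <- nrow(ev) > 0 &&
        any(ev$start_s < t0 & ev$end_s > t0 - pre)
      returning <- nrow(ev) > 0 &&
        any(ev$end_s >= t0 - baseline_guard & ev$end_s < t0)
      reason <- if (ongoing) {
        "ongoing_pre_event"
      } else if (returning) {
        "baseline_return"
      } else {
        NA_character_
      }
      included <- !(apply_inclusion && (ongoing || returning))
      lags <- if (nrow(ev) > 0) {
        on <- ev$onset_s - t0
        on[on > 0 & on <= post]
      } else {
        numeric(0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        roi_id = roi, compartment = roi_info$compartment[i],
        mouse_id = roi_info$mouse_id[i], group = roi_info$group[i],
        transition_time = t0, included = included,
        exclusion_reason = reason,
        responded = length(lags) > 0,
        first_lag = if (length(lags)) min(lags) else NA_real_
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      roi_id = character(0), compartment = character(0),
      mouse_id = character(0), group = character(0),
      transition_time = numeric(0), included = logical(0),
      exclusion_reason = character(0), responded = logical(0),
      first_lag = numeric(0)
    ))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Activation rate per transition
#'
#' Fraction of included ROIs with at least one event onset in the
#' post-onset window, per transition. Transitions with no included ROI
#' yield a missing rate.
#'
#' @param response_table Output of [transition_response_table()].
#' @return Data.frame: `transition_time`, `n_included`, `n_responding`,
#'   `activation_rate`.
#' @export
activation_rate <- function(response_table) {
  if (nrow(response_table) == 0L) {
    return(data.frame(transition_time = numeric(0), n_included = integer(0),
                      n_responding = integer(0), activation_rate = numeric(0)))
  }
  sp <- split(response_table, response_table$transition_time)
  out <- do.call(rbind, lapply(sp, function(d) {
    inc <- d$included
    data.frame(
      transition_time = d$transition_time[1],
      n_included = sum(inc),
      n_responding = sum(inc & d$responded),
      activation_rate = if (any(inc)) sum(inc & d$responded) / sum(inc)
                        else NA_real_
    )
  }))
  rownames(out) <- NULL
  out[order(out$transition_time), , drop = FALSE]
}

#' Response reliability per ROI
#'
#' `RR = RA / n` where RA is the number of transitions at which the ROI
#' exhibited a Ca2+ event (onset in the post-onset window) and n the
#' number of transitions at which the ROI was present (included). ROIs
#' with fewer than `min_transitions` transitions are reported with a
#' missing RR.
#'
#' @param response_table Output of [transition_response_table()].
#' @param min_transitions Minimum transition count for a defined RR,
#'   default 3.
#' @return Data.frame: `roi_id`, `compartment`, `mouse_id`, `group`,
#'   `n_transitions`, `n_active`, `rr`.
#' @export
response_reliability <- function(response_table, min_transitions = 3) {
  if (nrow(response_table) == 0L) {
    return(data.frame(roi_id = character(0), compartment = character(0),
                      mouse_id = character(0), group = character(0),
                      n_transitions = integer(0), n_active = integer(0),
                      rr = numeric(0)))
  }
  sp <- split(response_table, response_table$roi_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- sum(d$included)
    ra <- sum(d$included & d$responded)
    data.frame(
      roi_id = d$roi_id[1], compartment = d$compartment[1],
      mouse_id = d$mouse_id[1], group = d$group[1],
      n_transitions = n, n_active = ra,
      rr = if (n >= min_transitions) ra / n else NA_real_
    )
  }))
  rownames(out) <- NULL
  out
}

#' Event onset lag after locomotion onset
#'
#' Per-ROI mean lag of the first event onset after each included
#' transition (restricted to the post-onset window), and a group-level
#' hierarchical bootstrap (mice, then ROIs) of the mean lag.
#'
#' @param response_table Output of [transition_response_table()].
#' @param n_boot Bootstrap iterations, default 10000.
#' @param seed Optional seed for the bootstrap.
#' @return List: `per_roi` (data.frame `roi_id`, `mouse_id`, `mean_lag`,
#'   `n_lags`), `boot` (bootstrap means, length `n_boot`; `NULL` when no
#'   ROI has a lag), `median`, `ci` (2.5/97.5 percentiles).
#' @export
onset_lag <- function(response_table, n_boot = 10000, seed = NULL) {
  d <- response_table[response_table$included & response_table$responded, ,
                      drop = FALSE]
  if (nrow(d) == 0L) {
    return(list(per_roi = data.frame(roi_id = character(0),
                                     mouse_id = character(0),
                                     mean_lag = numeric(0),
                                     n_lags = integer(0)),
                boot = NULL, median = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  sp <- split(d, d$roi_id)
  per_roi <- do.call(rbind, lapply(sp, function(x) {
    data.frame(roi_id = x$roi_id[1], mouse_id = x$mouse_id[1],
               mean_lag = mean(x$first_lag), n_lags = nrow(x))
  }))
  rownames(per_roi) <- NULL
  boot <- hierarchical_bootstrap(per_roi$mean_lag, per_roi$mouse_id,
                                 n_boot = n_boot, seed = seed)
  list(
    per_roi = per_roi, boot = boot,
    median = stats::median(boot),
    ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  )
}
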