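# Locomotion and whisking modulation indices computed from dF/F and the
# behavioral segmentation:
#
#   LocMI   = (S_loc - S_s) / (S_loc + S_s)
#   WhiskMI = (S_w   - S_s) / (S_w   + S_s)
#
# S_loc: mean dF/F over locomotion bouts > 3 s. S_w: mean dF/F over
# still-whisking bouts >= 0.4 s. S_s: mean dF/F over still samples after
# removing a +-2 s guard around every locomotion bout and keeping only
# residual segments of at least 2 s.

#' Qualifying still-sample mask for the modulation indices
#'
#' Marks the samples contributing to the still-state mean S_s: Still (and,
#' by default, Still-Whisking) time minus a guard of `guard` seconds
#' before and after every Locomotion interval, keeping only residual
#' contiguous segments of at least `min_len` seconds.
#'
#' @param segmentation A `state_segmentation`.
#' @param guard Guard zone around locomotion (s), default 2.
#' @param min_len Minimum residual segment length kept (s), default 2.
#' @param include_whisking Count Still-Whisking samples as still (default
#'   `TRUE`, used by LocMI); `FALSE` restricts to pure Still (used for the
#'   WhiskMI denominator, where whisk bouts must not contaminate S_s).
#' @return Logical per-sample mask (length = session samples).
#' @export
qualifying_still_samples <- function(segmentation, guard = 2, min_len = 2,
                                     include_whisking = TRUE) {
  fs <- seg_fs(segmentation)
  n <- as.integer(round(seg_duration(segmentation) * fs))
  labels <- if (include_whisking) c("Still", "StillWhisking") else "Still"
  mask <- mask_from_runs(
    intervals_to_runs(segmentation[segmentation$label %in% labels, ], fs, n),
    n
  )
  guard_n <- as.integer(round(guard * fs))
  loc <- segmentation[segmentation$label == "Locomotion", ]
  loc_runs <- intervals_to_runs(loc, fs, n)
  for (i in seq_len(nrow(loc_runs))) {
    lo <- max(1L, loc_runs$first[i] - guard_n)
    hi <- min(n, loc_runs$last[i] + guard_n)
    mask[lo:hi] <- FALSE
  }
  runs <- filter_run_length(runs_from_mask(mask),
                            as.integer(round(min_len * fs)), strict = FALSE)
  mask_from_runs(runs, n)
}

mi_result <- function(dff, kind, active_mask, still_mask,
                      n_active, n_still, eps) {
  s_active <- if (any(active_mask)) mean(dff$dff[active_mask]) else NA_real_
  s_s <- if (any(still_mask)) mean(dff$dff[still_mask]) else NA_real_
  valid <- is.finite(s_active) && is.finite(s_s) &&
    abs(s_active + s_s) > eps
  data.frame(
    roi_id = dff$roi_id, compartment = dff$compartment,
    mouse_id = dff$mouse_id, group = dff$group,
    index_kind = kind,
    value = if (valid) (s_active - s_s) / (s_active + s_s) else NA_real_,
    S_active = s_active, S_s = s_s,
    n_active_segments = n_active, n_still_segments = n_still,
    valid = valid
  )
}

#' Locomotion modulation index (LocMI) for one ROI
#'
#' `LocMI = (S_loc - S_s) / (S_loc + S_s)` where S_loc is the mean dF/F
#' over locomotion bouts strictly longer than `min_loc` seconds and S_s is
#' the mean over [qualifying_still_samples()]. The result is flagged
#' invalid (value missing) when either sample set is empty or the
#' denominator magnitude falls below `eps`.
#'
#' @param dff A `dff_trace`.
#' @param segmentation A `state_segmentation` on the same clock.
#' @param min_loc Minimum locomotion bout length included in S_loc (s,
#'   strict), default 3.
#' @param guard,min_still Passed to [qualifying_still_samples()].
#' @param include_whisking_in_still Whether Still-Whisking counts toward
#'   S_s (default `TRUE`).
#' @param eps Denominator magnitude below which the index is marked
#'   invalid rather than reported (default 1e-6).
#' @return One-row data.frame (`roi_id`, `compartment`, `mouse_id`,
#'   `group`, `index_kind`, `value`, `S_active`, `S_s`,
#'   `n_active_segments`, `n_still_segments`, `valid`).
#' @export
compute_locmi <- function(dff, segmentation, min_loc = 3, guard = 2,
                          min_still = 2, include_whisking_in_still = TRUE,
                          eps = 1e-6) {
  stopifnot(inherits(dff, "dff_trace"))
  fs <- seg_fs(segmentation)
  n <- length(dff$dff)
  if (as.integer(round(seg_duration(segmentation) * fs)) != n ||
      !isTRUE(all.equal(fs, dff$sampling_rate))) {
    stop("dff trace and segmentation are not on the same clock")
  }
  loc <- segmentation[segmentation$label == "Locomotion", ]
  loc_runs <- intervals_to_runs(loc, fs, n)
  loc_runs <- filter_run_length(loc_runs, as.integer(round(min_loc * fs)),
                                strict = TRUE)
  active_mask <- mask_from_runs(loc_runs, n)
  still_mask <- qualifying_still_samples(
    segmentation, guard, min_still, include_whisking = include_whisking_in_still
  )
  n_still <- nrow(runs_from_mask(still_mask))
  mi_result(dff, "LocMI", active_mask, still_mask,
            nrow(loc_runs), n_still, eps)
}

#' Whisking modulation index (WhiskMI) for one ROI
#'
#' `WhiskMI = (S_w - S_s) / (S_w + S_s)` where S_w is the mean dF/F over
#' Still-Whisking bouts of at least `min_whisk` seconds (whisking during
#' locomotion never contributes, as running and free whisking cannot be
#' separated) and S_s is the qualifying still mean with whisk bouts
#' excluded.
#'
#' @inheritParams compute_locmi
#' @param min_whisk Minimum whisk-bout length included in S_w (s),
#'   default 0.4.
#' @return One-row data.frame as for [compute_locmi()] with
#'   `index_kind = "WhiskMI"`.
#' @export
compute_whiskmi <- function(dff, segmentation, min_whisk = 0.4, guard = 2,
                            min_still = 2, eps = 1e-6) {
  stopifnot(inherits(dff, "dff_trace"))
  fs <- seg_fs(segmentation)
  n <- length(dff$dff)
  if (as.integer(round(seg_duration(segmentation) * fs)) != n ||
      !isTRUE(all.equal(fs, dff$sampling_rate))) {
    stop("dff trace and segmentation are not on the same clock")
  }
  sw <- segmentation[segmentation$label == "StillWhisking", ]
  sw_runs <- intervals_to_runs(sw, fs, n)
  sw_runs <- filter_run_length(sw_runs, as.integer(round(min_whisk * fs)),
                               strict = FALSE)
  active_mask <- mask_from_runs(sw_runs, n)
  still_mask <- qualifying_still_samples(
    segmentation, guard, min_still, include_whisking = FALSE
  )
  n_still <- nrow(runs_from_mask(still_mask))
  mi_result(dff, "WhiskMI", active_mask, still_mask,
            nrow(sw_runs), n_still, eps)
}

#' Both modulation indices for a list of dF/F traces
#'
#' @param dff_list List of `dff_trace` objects.
#' @param segmentation A `state_segmentation`.
#' @param ... Passed to [compute_locmi()] and [compute_whiskmi()]
#'   (shared arguments `guard`, `min_still`, `eps`).
#' @return Data.frame with two rows (LocMI, WhiskMI) per ROI.
#' @export
compute_modulation <- function(dff_list, segmentation, ...) {
  rows <- lapply(dff_list, function(d) {
    rbind(compute_locmi(d, segmentation, ...),
          compute_whiskmi(d, segmentation, ...))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
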