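# Behavioral-state segmentation from wheel speed and whisker motion energy.
#
# Three exhaustive, mutually exclusive states: Still, StillWhisking,
# Locomotion. Locomotion: speed > 1 cm/s with sub-0.5 s interruptions
# merged and bouts of <= 0.5 s discarded. Whisking (assessed within Still
# only): smoothed motion energy above 1.5x its first percentile, gaps
# < 0.3 s merged, bouts < 0.4 s dropped.

#' Construct a behavior trace
#'
#' @param speed_cmps Wheel speed (cm/s), non-negative.
#' @param whisk_energy Whisker motion energy (a.u.; e.g. mean absolute
#'   pixel difference between consecutive video frames).
#' @param sampling_rate Hz.
#' @return Data.frame (`time_s`, `speed_cmps`, `whisk_energy`) of class
#'   `behavior_trace` with a `sampling_rate` attribute.
#' @export
behavior_trace <- function(speed_cmps, whisk_energy, sampling_rate = 10) {
  speed_cmps <- as.numeric(speed_cmps)
  whisk_energy <- as.numeric(whisk_energy)
  if (length(speed_cmps) == 0L) stop("empty behavior trace")
  if (length(speed_cmps) != length(whisk_energy)) {
    stop(sprintf("speed (%d) and whisker-energy (%d) channels differ in length",
                 length(speed_cmps), length(whisk_energy)))
  }
  if (any(speed_cmps < 0)) stop("speed must be non-negative")
  assert_scalar_pos(sampling_rate, "sampling_rate")
  out <- data.frame(
    time_s = (seq_along(speed_cmps) - 1L) / sampling_rate,
    speed_cmps = speed_cmps,
    whisk_energy = whisk_energy
  )
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("behavior_trace", "data.frame")
  out
}

behavior_fs <- function(behavior) {
  fs <- attr(behavior, "sampling_rate")
  if (is.null(fs)) stop("behavior trace lacks a sampling_rate attribute")
  fs
}

#' Locomotion intervals from the wheel-speed trace
#'
#' Thresholds speed at `speed_thresh`, merges interruptions shorter than
#' `merge_gap` into the surrounding locomotion run, and discards resulting
#' bouts not strictly longer than `min_duration`.
#'
#' @param behavior A [behavior_trace()].
#' @param speed_thresh Speed threshold (cm/s), default 1.
#' @param merge_gap Maximum interruption merged (s), default 0.5 (gaps
#'   strictly shorter are merged).
#' @param min_duration Minimum bout duration (s), default 0.5 (bouts must
#'   strictly exceed it).
#' @return Data.frame of half-open intervals `start_s`, `end_s`.
#' @export
segment_locomotion <- function(behavior, speed_thresh = 1,
                               merge_gap = 0.5, min_duration = 0.5) {
  stopifnot(nrow(behavior) > 0L)
  fs <- behavior_fs(behavior)
  runs <- runs_from_mask(behavior$speed_cmps > speed_thresh)
  runs <- merge_run_gaps(runs, as.integer(round(merge_gap * fs)))
  runs <- filter_run_length(runs, as.integer(round(min_duration * fs)),
                            strict = TRUE)
  runs_to_intervals(runs, fs)
}

#' Whisk bouts from the motion-energy trace
#'
#' Smooths the motion energy with a centered moving average
#' (`smooth_window` seconds), sets the resting baseline W0 to the trace's
#' first percentile, and binarizes at `threshold_factor * W0`
#' (multiplicative, the default) or `W0 + threshold_factor` (additive).
#' Gaps shorter than `merge_gap` are merged and bouts shorter than
#' `min_bout` dropped (in that order by default); bouts are then
#' intersected with the supplied Still intervals, since whisking is only
#' assessed during stillness.
#'
#' @param behavior A [behavior_trace()].
#' @param still_intervals Data.frame of Still intervals (`start_s`,
#'   `end_s`), i.e. the complement of the locomotion intervals.
#' @param smooth_window Moving-average window (s), default 0.33.
#' @param threshold_factor Threshold parameter, default 1.5.
#' @param min_bout Minimum bout length kept (s), default 0.4 (bouts of at
#'   least 0.4 s are kept).
#' @param merge_gap Maximum gap merged (s), default 0.3 (gaps strictly
#'   shorter are merged).
#' @param mode `"multiplicative"` (default) or `"additive"` threshold.
#' @param order `"merge_first"` (default: merge gaps, then drop short
#'   bouts) or `"drop_first"`.
#' @return Data.frame of whisk-bout intervals `start_s`, `end_s`.
#' @export
detect_whisking <- function(behavior, still_intervals,
                            smooth_window = 0.33, threshold_factor = 1.5,
                            min_bout = 0.4, merge_gap = 0.3,
                            mode = c("multiplicative", "additive"),
                            order = c("merge_first", "drop_first")) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  fs <- behavior_fs(behavior)
  n <- nrow(behavior)
  w <- max(1L, as.integer(round(smooth_window * fs)))
  smoothed <- zoo::rollapply(behavior$whisk_energy, width = w, FUN = mean,
                             partial = TRUE, align = "center")
  w0 <- as.numeric(stats::quantile(smoothed, 0.01, names = FALSE))
  if (mode == "multiplicative") {
    if (w0 <= 0) {
      warning("whisker baseline W0 <= 0; falling back to the additive ",
              "threshold W0 + 1.5 * MAD", call. = FALSE)
      threshold <- w0 + 1.5 * stats::mad(smoothed)
    } else {
      threshold <- threshold_factor * w0
    }
  } else {
    threshold <- w0 + threshold_factor
  }
  runs <- runs_from_mask(smoothed > threshold)
  gap_n <- as.integer(round(merge_gap * fs))
  min_n <- as.integer(round(min_bout * fs))
  if (order == "merge_first") {
    runs <- merge_run_gaps(runs, gap_n)
    runs <- filter_run_length(runs, min_n, strict = FALSE)
  } else {
    runs <- filter_run_length(runs, min_n, strict = FALSE)
    runs <- merge_run_gaps(runs, gap_n)
  }
  whisk_mask <- mask_from_runs(runs, n)
  still_mask <- mask_from_runs(intervals_to_runs(still_intervals, fs, n), n)
  runs_to_intervals(runs_from_mask(whisk_mask & still_mask), fs)
}

#' Compose the exhaustive state segmentation
#'
#' Assembles locomotion intervals and whisk bouts into a partition of the
#' session with priority Locomotion > Still-Whisking > Still.
#'
#' @param loc_intervals Locomotion intervals from [segment_locomotion()];
#'   must not overlap each other.
#' @param whisk_bouts Whisk bouts from [detect_whisking()].
#' @param duration Session duration (s).
#' @param sampling_rate Hz.
#' @return A `state_segmentation`: data.frame of half-open intervals
#'   (`start_s`, `end_s`, `label`) that are disjoint, sorted, and cover
#'   exactly `[0, duration)`; attributes `sampling_rate` and `duration`.
#' @export
compose_segmentation <- function(loc_intervals, whisk_bouts, duration,
                                 sampling_rate) {
  fs <- sampling_rate
  n <- as.integer(round(duration * fs))
  if (nrow(loc_intervals) > 1L) {
    o <- order(loc_intervals$start_s)
    li <- loc_intervals[o, ]
    if (any(li$start_s[-1] < li$end_s[-nrow(li)])) {
      stop("locomotion intervals overlap")
    }
  }
  label <- rep(1L, n)
  wr <- intervals_to_runs(whisk_bouts, fs, n)
  for (i in seq_len(nrow(wr))) label[wr$first[i]:wr$last[i]] <- 2L
  lr <- intervals_to_runs(loc_intervals, fs, n)
  for (i in seq_len(nrow(lr))) label[lr$first[i]:lr$last[i]] <- 3L
  r <- rle(label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(
    start_s = (starts - 1L) / fs,
    end_s = ends / fs,
    label = STATES[r$values]
  )
  attr(seg, "sampling_rate") <- fs
  attr(seg, "duration") <- n / fs
  class(seg) <- c("state_segmentation", "data.frame")
  seg
}

#' Segment a session's behavior into Still / Still-Whisking / Locomotion
#'
#' Convenience wrapper chaining [segment_locomotion()],
#' [detect_whisking()] (on the complement of locomotion) and
#' [compose_segmentation()].
#'
#' @param behavior A [behavior_trace()].
#' @param speed_thresh,loc_merge_gap,loc_min_duration Locomotion
#'   parameters, see [segment_locomotion()].
#' @param whisk_smooth,whisk_threshold_factor,whisk_min_bout,whisk_merge_gap,whisk_mode,whisk_order
#'   Whisking parameters, see [detect_whisking()].
#' @return A `state_segmentation`.
#' @export
segment_behavior <- function(behavior, speed_thresh = 1,
                             loc_merge_gap = 0.5, loc_min_duration = 0.5,
                             whisk_smooth = 0.33,
                             whisk_threshold_factor = 1.5,
                             whisk_min_bout = 0.4, whisk_merge_gap = 0.3,
                             whisk_mode = "multiplicative",
                             whisk_order = "merge_first") {
  fs <- behavior_fs(behavior)
  n <- nrow(behavior)
  loc <- segment_locomotion(behavior, speed_thresh, loc_merge_gap,
                            loc_min_duration)
  still_runs <- runs_from_mask(!mask_from_runs(
    intervals_to_runs(loc, fs, n), n
  ))
  whisk <- detect_whisking(
    behavior, runs_to_intervals(still_runs, fs),
    smooth_window = whisk_smooth, threshold_factor = whisk_threshold_factor,
    min_bout = whisk_min_bout, merge_gap = whisk_merge_gap,
    mode = whisk_mode, order = whisk_order
  )
  compose_segmentation(loc, whisk, n / fs, fs)
}

#' Promote a labeled schedule to a state segmentation
#'
#' Wraps an interval table (e.g. a synthetic session's ground-truth
#' schedule) as a `state_segmentation`, validating that it is a sorted,
#' disjoint, exhaustive partition starting at 0.
#'
#' @param schedule Data.frame `start_s`, `end_s`, `label`.
#' @param sampling_rate Hz.
#' @return A `state_segmentation`.
#' @export
as_segmentation <- function(schedule, sampling_rate) {
  stopifnot(all(c("start_s", "end_s", "label") %in% names(schedule)))
  schedule <- schedule[order(schedule$start_s), , drop = FALSE]
  if (schedule$start_s[1] != 0 ||
      any(schedule$start_s[-1] != schedule$end_s[-nrow(schedule)])) {
    stop("schedule is not a contiguous partition starting at 0")
  }
  if (!all(schedule$label %in% STATES)) {
    stop("unknown state label; allowed: ", paste(STATES, collapse = ", "))
  }
  seg <- as.data.frame(schedule)
  rownames(seg) <- NULL
  attr(seg, "sampling_rate") <- sampling_rate
  attr(seg, "duration") <- max(seg$end_s)
  class(seg) <- c("state_segmentation", "data.frame")
  seg
}

seg_fs <- function(segmentation) {
  fs <- attr(segmentation, "sampling_rate")
  if (is.null(fs)) stop("segmentation lacks a sampling_rate attribute")
  fs
}

seg_duration <- function(segmentation) {
  attr(segmentation, "duration") %||% max(segmentation$end_s)
}
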