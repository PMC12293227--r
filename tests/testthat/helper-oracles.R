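# Independent brute-force oracles, written per-sample and rule-by-rule,
# against which the interval-based implementations are checked.

# per-sample behavioral labeler: literal application of threshold, merge
# and minimum-duration rules on label arrays
oracle_segment <- function(speed, whisk, fs,
                           speed_thresh = 1, loc_merge = 0.5,
                           loc_min = 0.5, whisk_smooth = 0.33,
                           whisk_factor = 1.5, whisk_min = 0.4,
                           whisk_gap = 0.3) {
  n <- length(speed)
  runs_of <- function(mask) {
    out <- list()
    i <- 1L
    while (i <= n) {
      if (mask[i]) {
        j <- i
        while (j < n && mask[j + 1L]) j <- j + 1L
        out[[length(out) + 1L]] <- c(i, j)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    out
  }
  apply_runs <- function(runs) {
    mask <- rep(FALSE, n)
    for (r in runs) mask[r[1]:r[2]] <- TRUE
    mask
  }
  merge_runs <- function(runs, gap_n) {
    if (length(runs) < 2L) return(runs)
    out <- list(runs[[1]])
    for (k in 2:length(runs)) {
      prev <- out[[length(out)]]
      gap <- runs[[k]][1] - prev[2] - 1L
      if (gap < gap_n) {
        out[[length(out)]] <- c(prev[1], runs[[k]][2])
      } else {
        out[[length(out) + 1L]] <- runs[[k]]
      }
    }
    out
  }

  # locomotion
  loc_runs <- runs_of(speed > speed_thresh)
  loc_runs <- merge_runs(loc_runs, round(loc_merge * fs))
  loc_runs <- Filter(function(r) (r[2] - r[1] + 1L) > round(loc_min * fs),
                     loc_runs)
  loc_mask <- apply_runs(loc_runs)

  # whisking: centered moving average with partial edge windows
  w <- max(1L, round(whisk_smooth * fs))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    mean(whisk[max(1L, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
  w0 <- as.numeric(quantile(sm, 0.01, names = FALSE))
  wk_runs <- runs_of(sm > whisk_factor * w0)
  wk_runs <- merge_runs(wk_runs, round(whisk_gap * fs))
  wk_runs <- Filter(function(r) (r[2] - r[1] + 1L) >= round(whisk_min * fs),
                    wk_runs)
  wk_mask <- apply_runs(wk_runs) & !loc_mask

  label <- rep("Still", n)
  label[wk_mask] <- "StillWhisking"
  label[loc_mask] <- "Locomotion"
  label
}

# segmentation object -> per-sample label vector
seg_to_labels <- function(seg, fs) {
  n <- round(max(seg$end_s) * fs)
  label <- character(n)
  for (i in seq_len(nrow(seg))) {
    a <- round(seg$start_s[i] * fs) + 1L
    b <- round(seg$end_s[i] * fs)
    label[a:b] <- seg$label[i]
  }
  label
}

# naive event scan: expand every suprathreshold sample to the nearest
# zero crossings, deduplicate spans
oracle_detect <- function(dff, threshold, fs) {
  n <- length(dff)
  spans <- list()
  for (i in which(dff > threshold)) {
    a <- i
    while (a > 1L && dff[a - 1L] > 0) a <- a - 1L
    b <- i
    while (b < n && dff[b + 1L] > 0) b <- b + 1L
    spans[[paste(a, b)]] <- c(a, b)
  }
  if (!length(spans)) {
    return(data.frame(start_s = numeric(0), onset_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      amplitude = numeric(0)))
  }
  out <- do.call(rbind, lapply(spans, function(sp) {
    span <- sp[1]:sp[2]
    onset <- span[which(dff[span] > threshold)[1]]
    data.frame(start_s = (sp[1] - 1) / fs, onset_s = (onset - 1) / fs,
               end_s = sp[2] / fs, duration_s = (sp[2] - sp[1] + 1) / fs,
               amplitude = max(dff[span]))
  }))
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random behavior traces for the oracle-equivalence property
random_behavior <- function(n, fs = 10) {
  speed <- pmax(0, rnorm(n, 0, 0.4) + ifelse(runif(n) < 0.3, 2, 0))
  # piecewise-constant blocks to create realistic-length bouts
  blocks <- cumsum(rexp(n, 1 / 8)) # mean 8-sample blocks
  block_id <- findInterval(seq_len(n), c(0, blocks)) + 1L
  base_speed <- ifelse(runif(max(block_id)) < 0.35, 3, 0)
  speed <- pmax(0, base_speed[block_id] + rnorm(n, 0, 0.3))
  whisk <- pmax(0, 1 + ifelse(runif(max(block_id)) < 0.4, 4, 0)[block_id] +
                  rnorm(n, 0, 0.2))
  behavior_trace(speed, whisk, fs)
}

# single-exponential transient added to a trace at a given onset sample
inject_transient <- function(x, onset, amp, dur_s, fs) {
  tau <- dur_s / 4
  idx <- onset:min(length(x), onset + ceiling(1.5 * dur_s * fs))
  x[idx] <- x[idx] + amp * exp(-((idx - onset) / fs) / tau)
  x
}

# minimal dff_trace with exact control over the dff samples
make_dff <- function(dff, fs = 10, sigma = NULL, compartment = "AS",
                     roi_id = "roi", mouse_id = "m1", group = "g") {
  calmod:::new_dff_trace(
    dff = dff, F0 = 100, sigma = sigma, roi_id = roi_id,
    compartment = compartment, sampling_rate = fs,
    mouse_id = mouse_id, group = group
  )
}

# segmentation built directly from labeled intervals (sample-aligned)
make_segmentation <- function(labels_runs, fs = 10) {
  # labels_runs: data.frame(start_s, end_s, label), contiguous from 0
  seg <- labels_runs
  attr(seg, "sampling_rate") <- fs
  attr(seg, "duration") <- max(seg$end_s)
  class(seg) <- c("state_segmentation", "data.frame")
  seg
}
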