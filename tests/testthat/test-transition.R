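# still-to-locomotion transition metrics

trans_seg <- function() {
  # bouts: 20-28 (8 s), 60-62 (2 s, too short), 100-105 (5 s),
  # 150-154 (4 s), all inside a 200 s session
  make_segmentation(data.frame(
    start_s = c(0, 20, 28, 60, 62, 100, 105, 150, 154),
    end_s = c(20, 28, 60, 62, 100, 105, 150, 154, 200),
    label = c("Still", "Locomotion", "Still", "Locomotion", "Still",
              "Locomotion", "Still", "Locomotion", "Still")
  ))
}

mk_events <- function(roi_id, onsets, dur = 1, mouse = "m1") {
  data.frame(
    roi_id = roi_id, compartment = "AS", mouse_id = mouse, group = "g",
    start_s = onsets, onset_s = onsets, end_s = onsets + dur,
    duration_s = dur, amplitude = 0.5
  )
}

test_that("transition extraction applies the >= 3 s bout rule and clipping", {
  seg <- trans_seg()
  tr <- extract_transitions(seg)
  expect_equal(tr$transition_time, c(20, 100, 150))
  expect_false(any(tr$partial))

  # no locomotion at all: empty list
  seg0 <- make_segmentation(data.frame(start_s = 0, end_s = 100,
                                       label = "Still"))
  expect_equal(nrow(extract_transitions(seg0)), 0L)

  # one 5 s bout and one 2 s bout: only the 5 s bout qualifies
  seg1 <- make_segmentation(data.frame(
    start_s = c(0, 30, 35, 60, 62), end_s = c(30, 35, 60, 62, 100),
    label = c("Still", "Locomotion", "Still", "Locomotion", "Still")
  ))
  tr1 <- extract_transitions(seg1)
  expect_equal(tr1$transition_time, 30)

  # bout starting at t = 1 s: partial (only 1 s of pre-context)
  seg2 <- make_segmentation(data.frame(
    start_s = c(0, 1, 10), end_s = c(1, 10, 100),
    label = c("Still", "Locomotion", "Still")
  ))
  expect_true(extract_transitions(seg2)$partial)

  # bout preceded by < 2 s of non-locomotion since the previous bout
  seg3 <- make_segmentation(data.frame(
    start_s = c(0, 20, 25, 26, 40), end_s = c(20, 25, 26, 40, 100),
    label = c("Still", "Locomotion", "Still", "Locomotion", "Still")
  ))
  tr3 <- extract_transitions(seg3)
  expect_equal(tr3$partial, c(FALSE, TRUE))
})

test_that("ROI inclusion excludes ongoing and just-ended events", {
  seg <- trans_seg()
  tr <- extract_transitions(seg)
  roi_info <- data.frame(roi_id = c("clean", "ongoing", "returning"),
                         compartment = "AS", mouse_id = "m1", group = "g")
  ev <- rbind(
    mk_events("clean", c(5, 21, 101, 151)),          # far from pre-windows
    mk_events("ongoing", c(19.5, 99, 149.5), dur = 2), # spans each onset
    mk_events("returning", c(18, 98.7, 148.6), dur = 0.8)
  )
  tbl <- transition_response_table(ev, tr, roi_info)
  clean <- tbl[tbl$roi_id == "clean", ]
  expect_true(all(clean$included))
  expect_true(all(clean$responded))
  ongoing <- tbl[tbl$roi_id == "ongoing", ]
  expect_false(any(ongoing$included))
  expect_equal(unique(ongoing$exclusion_reason), "ongoing_pre_event")
  returning <- tbl[tbl$roi_id == "returning", ]
  # events end 0.8 s after start: ends at 18.8 (within [18,20): excluded),
  # 99.5 and 149.4 (both within 1 s before onset: excluded)
  expect_false(any(returning$included))
})

test_that("activation rate is the included-ROI response fraction", {
  seg <- trans_seg()
  tr <- extract_transitions(seg)
  roi_info <- data.frame(roi_id = sprintf("r%d", 1:4), compartment = "AS",
                         mouse_id = "m1", group = "g")
  # at t=20: r1, r2, r3 respond, r4 silent -> 3/4
  # at t=100: all four respond -> 1.0
  # at t=150: none responds -> 0
  ev <- rbind(
    mk_events("r1", c(21, 101)), mk_events("r2", c(22, 102)),
    mk_events("r3", c(23, 103)), mk_events("r4", 104)
  )
  tbl <- transition_response_table(ev, tr, roi_info)
  ar <- activation_rate(tbl)
  expect_equal(ar$activation_rate, c(0.75, 1, 0))
  expect_equal(ar$n_included, c(4L, 4L, 4L))

  # post-window boundary: onset exactly at t0 does not count (lag must be
  # > 0), onset at t0 + 7 does
  ev2 <- rbind(mk_events("r1", 20), mk_events("r2", 27))
  tbl2 <- transition_response_table(ev2, tr, roi_info[1:2, ])
  expect_equal(tbl2$responded[tbl2$transition_time == 20], c(FALSE, TRUE))
})

test_that("response reliability RR = RA/n with the >= 3 transition rule", {
  seg <- trans_seg()
  tr <- extract_transitions(seg)
  roi_info <- data.frame(roi_id = c("full", "partial", "none"),
                         compartment = "AS", mouse_id = "m1", group = "g")
  ev <- rbind(
    mk_events("full", c(20.5, 100.5, 150.5)),
    mk_events("partial", 20.5)
  )
  tbl <- transition_response_table(ev, tr, roi_info)
  rr <- response_reliability(tbl)
  expect_equal(rr$rr[rr$roi_id == "full"], 1)
  expect_equal(rr$rr[rr$roi_id == "partial"], 1 / 3)
  expect_equal(rr$rr[rr$roi_id == "none"], 0)

  # with only 2 transitions present, RR is missing
  rr2 <- response_reliability(tbl[tbl$transition_time < 150, ])
  expect_true(all(is.na(rr2$rr)))
  expect_equal(rr2$n_transitions, rep(2L, 3))
})

test_that("onset lags are first-onset minus transition time", {
  seg <- trans_seg()
  tr <- extract_transitions(seg)
  roi_info <- data.frame(roi_id = "r1", compartment = "AS",
                         mouse_id = "m1", group = "g")
  ev <- mk_events("r1", c(21.2, 101.2, 151.2))
  tbl <- transition_response_table(ev, tr, roi_info)
  expect_equal(tbl$first_lag, rep(1.2, 3))
  lag <- onset_lag(tbl, n_boot = 200, seed = 1)
  # all lags equal: bootstrap distribution degenerate at 1.2
  expect_equal(unique(lag$boot), 1.2)
  expect_equal(lag$median, 1.2)
})

test_that("transition metrics match a brute-force recomputation", {
  set.seed(77)
  cfg <- sim_config(seed = 55, duration = 300,
                    rois_per_compartment = c(AS = 3, AP = 0, Gp = 0,
                                             AE = 0, Neuron = 0))
  s <- simulate_session(cfg)
  res <- run_pipeline(s)
  tr <- res$transitions
  tbl <- res$response_table
  for (roi in unique(tbl$roi_id)) {
    ev <- res$events[res$events$roi_id == roi, ]
    for (j in seq_len(nrow(tr))) {
      t0 <- tr$transition_time[j]
      row <- tbl[tbl$roi_id == roi & tbl$transition_time == t0, ]
      # brute-force inclusion and response
      excl <- FALSE
      for (i in seq_len(nrow(ev))) {
        if (ev$start_s[i] < t0 && ev$end_s[i] > t0 - 2) excl <- TRUE
        if (ev$end_s[i] >= t0 - 1 && ev$end_s[i] < t0) excl <- TRUE
      }
      lags <- ev$onset_s - t0
      lags <- lags[lags > 0 & lags <= 7]
      expect_identical(row$included, !excl)
      expect_identical(row$responded, length(lags) > 0)
      if (length(lags)) expect_equal(row$first_lag, min(lags))
    }
  }
  # RA and n recomputed per ROI
  rr <- response_reliability(tbl)
  for (roi in rr$roi_id) {
    sub <- tbl[tbl$roi_id == roi, ]
    expect_equal(rr$n_transitions[rr$roi_id == roi], sum(sub$included))
    expect_equal(rr$n_active[rr$roi_id == roi],
                 sum(sub$included & sub$responded))
  }
})

test_that("fixed-lag injected events yield that lag from the bootstrap", {
  cfg <- sim_config(seed = 12, duration = 400,
                    rois_per_compartment = c(AS = 1, AP = 0, Gp = 0,
                                             AE = 0, Neuron = 0))
  beh <- generate_behavior(cfg)
  seg <- segment_behavior(beh$behavior)
  tr <- extract_transitions(seg)
  if (nrow(tr) >= 3) {
    lag_true <- 0.8
    roi_info <- data.frame(roi_id = c("a", "b"), compartment = "AS",
                           mouse_id = c("m1", "m2"), group = "g")
    ev <- rbind(
      mk_events("a", tr$transition_time + lag_true, dur = 0.5),
      mk_events("b", tr$transition_time + lag_true, dur = 0.5,
                mouse = "m2")
    )
    tbl <- transition_response_table(ev, tr, roi_info)
    lag <- onset_lag(tbl, n_boot = 500, seed = 3)
    expect_equal(lag$median, lag_true, tolerance = 0.1)
  } else {
    succeed("too few transitions in this draw")
  }
})
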