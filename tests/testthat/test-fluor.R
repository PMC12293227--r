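# dF/F extraction and event detection

test_that("linear detrend removes a perfect line and preserves the mean", {
  t <- 0:599
  tr <- roi_trace("r1", "AS", F = 100 + 0.5 * t, sampling_rate = 10)
  out <- detrend_linear(tr)
  expect_equal(out$F, rep(mean(tr$F), 600))
  expect_equal(mean(out$F), mean(tr$F))

  # trend-free trace (zero-slope least-squares fit) passes through
  set.seed(1)
  raw <- 100 + sin(2 * pi * t / 50) + rnorm(600, 0, 0.3)
  flat <- as.numeric(resid(lm(raw ~ t))) + 100
  tr2 <- detrend_linear(roi_trace("r2", "AP", F = flat, sampling_rate = 10))
  expect_equal(tr2$F, flat, tolerance = 1e-10)

  # line + oscillation: residual slope is ~0 after detrending
  tr3 <- detrend_linear(roi_trace("r3", "Gp", F = flat + 0.3 * t,
                                  sampling_rate = 10))
  refit <- coef(lm(tr3$F ~ t))[2]
  expect_lt(abs(refit), 1e-10)

  expect_error(detrend_linear(roi_trace("r", "AS", F = 1,
                                        sampling_rate = 10)),
               "length >= 2")
})

test_that("neuropil subtraction follows F - alpha * F_np", {
  f <- rep(1.7, 100)
  np <- rep(1.0, 100)
  tr <- roi_trace("n1", "Neuron", F = f, F_np = np, sampling_rate = 10)
  expect_equal(subtract_neuropil(tr, alpha = 0.7)$F, rep(1.0, 100))
  expect_equal(subtract_neuropil(tr, alpha = 0)$F, f)
  tr0 <- roi_trace("n2", "Neuron", F = f, F_np = rep(0, 100),
                   sampling_rate = 10)
  expect_equal(subtract_neuropil(tr0)$F, f)

  # astrocytic traces pass through, neurons without neuropil error
  astro <- roi_trace("a1", "AS", F = f, sampling_rate = 10)
  expect_identical(subtract_neuropil(astro), astro)
  expect_error(
    subtract_neuropil(roi_trace("n3", "Neuron", F = f, sampling_rate = 10)),
    "neuropil"
  )
})

test_that("dF/F uses the 10th percentile of the smoothed trace", {
  tr <- roi_trace("c", "AS", F = rep(100, 600), sampling_rate = 10)
  d <- compute_dff(tr)
  expect_equal(d$F0, 100)
  expect_equal(d$dff, rep(0, 600))
  expect_equal(d$params$sg_samples, 51)

  # 90% at 100 with a contiguous 10% plateau at 200: F0 ~ 100, plateau ~ 1
  f <- c(rep(100, 540), rep(200, 60))
  d2 <- compute_dff(roi_trace("p", "AS", F = f, sampling_rate = 10))
  expect_equal(d2$F0, 100, tolerance = 0.01)
  expect_equal(max(d2$dff), 1, tolerance = 0.02)

  # scale invariance: dff unchanged under F -> c * F
  set.seed(7)
  f3 <- 100 + abs(rnorm(600, 0, 5))
  d3 <- compute_dff(roi_trace("s", "AS", F = f3, sampling_rate = 10))
  d3c <- compute_dff(roi_trace("s", "AS", F = 3.7 * f3, sampling_rate = 10))
  expect_equal(d3$dff, d3c$dff, tolerance = 1e-12)

  expect_error(
    compute_dff(roi_trace("neg", "AS", F = rnorm(600, 0, 1) - 50,
                          sampling_rate = 10)),
    "non-positive baseline"
  )
})

test_that("sigma is the minimum sliding-window sd of dF/F", {
  d0 <- make_dff(rep(0, 100))
  expect_equal(estimate_sigma(d0), 0)

  # quiet first 5 s, noisy rest: sigma picks the quiet window;
  # brute force over all windows is the oracle
  set.seed(11)
  x <- c(rnorm(50, 0, 0.01), rnorm(550, 0, 0.1))
  d <- make_dff(x)
  sig <- estimate_sigma(d)
  brute <- min(vapply(1:(600 - 49), function(i) sd(x[i:(i + 49)]),
                      numeric(1)))
  expect_equal(sig, brute, tolerance = 1e-12)
  expect_lt(sig, 0.03)

  # shift invariance
  expect_equal(estimate_sigma(make_dff(x + 5)), sig, tolerance = 1e-12)

  expect_error(estimate_sigma(make_dff(rep(0, 10))), "shorter")
})

test_that("event detection matches the naive zero-crossing scan", {
  fs <- 10
  sigma <- 0.02
  # single clean transient, peak 5 sigma, on a zero baseline
  x <- rep(0, 200)
  x <- inject_transient(x, 100, 5 * sigma, 2, fs)
  x[x != 0 & x < 1e-6] <- 0 # keep the tail from lingering above zero
  d <- make_dff(x, sigma = sigma)
  ev <- detect_events(d, k = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude, 5 * sigma)
  expect_equal(ev$onset_s, (100 - 1) / fs)
  orc <- oracle_detect(x, 2 * sigma, fs)
  expect_equal(ev[, c("start_s", "onset_s", "end_s", "amplitude")],
               orc[, c("start_s", "onset_s", "end_s", "amplitude")])

  # two transients separated by a strictly negative dip: two events
  x2 <- c(rep(0, 20), rep(0.3, 10), rep(-0.05, 5), rep(0.3, 10), rep(0, 20))
  ev2 <- detect_events(make_dff(x2, sigma = sigma), k = 2)
  expect_equal(nrow(ev2), 2L)

  # nonnegative subthreshold gap with no zero crossing: one merged event
  x3 <- c(rep(0, 20), rep(0.3, 10), rep(0.01, 5), rep(0.3, 10), rep(0, 20))
  ev3 <- detect_events(make_dff(x3, sigma = sigma), k = 2)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$duration_s, 2.5)

  # pure subthreshold noise: no events
  set.seed(3)
  noise <- rnorm(200, 0, 0.01)
  noise <- noise * 0.019 / max(abs(noise))
  ev4 <- detect_events(make_dff(noise, sigma = 0.02), k = 2)
  expect_equal(nrow(ev4), 0L)

  # degenerate sigma falls back to the absolute floor with a warning
  expect_warning(
    ev5 <- detect_events(make_dff(x2, sigma = 0), k = 2, sigma_floor = 0.05),
    "floor"
  )
  expect_equal(nrow(ev5), 2L)
})

test_that("detected events are disjoint, sorted, and all peaks clear k*sigma", {
  set.seed(21)
  fs <- 10
  for (rep_i in 1:20) {
    x <- rnorm(400, 0, 0.02)
    for (k in 1:5) {
      x <- inject_transient(x, sample(350, 1), runif(1, 0.1, 0.5),
                            runif(1, 0.5, 3), fs)
    }
    d <- make_dff(x, sigma = 0.02)
    ev <- detect_events(d, k = 2)
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$onset_s) >= 0))
      expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
    }
    expect_true(all(ev$amplitude > 2 * 0.02))
    expect_true(all(ev$start_s <= ev$onset_s & ev$onset_s < ev$end_s))
    # amplitude equals the exact span max
    for (i in seq_len(nrow(ev))) {
      span <- (round(ev$start_s[i] * fs) + 1):round(ev$end_s[i] * fs)
      expect_identical(ev$amplitude[i], max(x[span]))
    }
  }
})

test_that("per-state event summaries give frequency in events/min", {
  seg <- make_segmentation(data.frame(
    start_s = c(0, 120), end_s = c(120, 240),
    label = c("Still", "Locomotion")
  ))
  ev <- data.frame(
    roi_id = "r1", compartment = "AS", mouse_id = "m1", group = "g",
    start_s = c(125, 150, 170, 190, 200, 220) - 0.2,
    onset_s = c(125, 150, 170, 190, 200, 220),
    end_s = c(125, 150, 170, 190, 200, 220) + 1,
    duration_s = 1.2, amplitude = 0.5
  )
  roi_info <- data.frame(roi_id = "r1", compartment = "AS",
                         mouse_id = "m1", group = "g")
  sm <- summarize_events_by_state(ev, seg, roi_info)
  loc <- sm[sm$state == "Locomotion", ]
  expect_equal(loc$frequency, 3.0) # 6 events / 2 min
  still <- sm[sm$state == "Still", ]
  expect_equal(still$frequency, 0)
  expect_true(is.na(still$mean_amplitude) && is.na(still$mean_duration))
  # absent state: frequency missing, not zero
  sw <- sm[sm$state == "StillWhisking", ]
  expect_true(is.na(sw$frequency))
})

test_that("detection recovers configured event rates on clean traces", {
  # Poisson recovery: clean short events at a known rate, detected
  # frequency matches the generated count
  fs <- 10
  set.seed(5)
  counts_true <- integer(10)
  counts_det <- integer(10)
  for (i in 1:10) {
    n <- 3000 # 5 min
    x <- rep(0, n)
    onsets <- which(runif(n) < 2 / 60 / fs) # 2 events/min
    onsets <- onsets[c(TRUE, diff(onsets) > 30)] # no overlap: clean lobes
    for (o in onsets) x <- inject_transient(x, o, 0.5, 1, fs)
    x[x < 1e-4] <- 0
    d <- make_dff(x, sigma = NULL)
    suppressWarnings(ev <- detect_events(d, k = 2, sigma_floor = 0.05))
    counts_true[i] <- length(onsets)
    counts_det[i] <- nrow(ev)
  }
  expect_equal(counts_det, counts_true)
})
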