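# synthetic-session generator

small_rois <- c(AS = 2, AP = 0, Gp = 0, AE = 0, Neuron = 1)

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration = -5), "duration")
  expect_error(sim_config(sampling_rate = 0), "sampling_rate")
  expect_error(sim_config(alpha_true = 1.4), "alpha_true")
  expect_error(sim_config(whisk_rate_per_min = -1), "schedule")
  em <- genotype_preset("wildtype")
  em$rate_per_min[1] <- -2
  expect_error(sim_config(event_model = em), "non-negative")
  expect_error(sim_config(rois_per_compartment = c(AS = 1)), "missing")
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(seed = 33, duration = 120,
                    rois_per_compartment = small_rois)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$behavior, s2$behavior)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- simulate_session(sim_config(seed = 34, duration = 120,
                                    rois_per_compartment = small_rois))
  expect_false(identical(s1$traces[[1]]$F, s3$traces[[1]]$F))
})

test_that("degenerate schedules behave as configured", {
  # locomotion probability 0: all speed below 1 cm/s, one still state
  cfg <- sim_config(seed = 2, duration = 120, loc_bout_prob = 0,
                    whisk_rate_per_min = 0,
                    rois_per_compartment = small_rois)
  beh <- generate_behavior(cfg)
  expect_true(all(beh$behavior$speed_cmps < 1))
  expect_equal(beh$schedule$label, "Still")
  expect_equal(nrow(beh$schedule), 1L)

  # whisk rate 0: energy never leaves baseline regime, no whisk truth
  expect_false("StillWhisking" %in% beh$schedule$label)

  # schedule partitions [0, duration)
  cfg2 <- sim_config(seed = 3, duration = 180,
                     rois_per_compartment = small_rois)
  beh2 <- generate_behavior(cfg2)
  expect_equal(beh2$schedule$start_s[1], 0)
  expect_equal(beh2$schedule$end_s[nrow(beh2$schedule)], 180)
  expect_true(all(beh2$schedule$start_s[-1] ==
                    beh2$schedule$end_s[-nrow(beh2$schedule)]))
})

test_that("zero rates, noise and bleaching give flat traces at F0", {
  em <- genotype_preset("wildtype")
  em$rate_per_min <- 0
  cfg <- sim_config(seed = 4, duration = 120, event_model = em,
                    noise_sd = 0, bleach_slope = 0,
                    rois_per_compartment = c(AS = 2, AP = 0, Gp = 0,
                                             AE = 0, Neuron = 0))
  beh <- generate_behavior(cfg)
  fl <- generate_fluorescence(cfg, beh$schedule)
  expect_equal(nrow(fl$ground_truth$events), 0L)
  for (tr in fl$traces) {
    expect_equal(tr$F, rep(cfg$baseline_f0, length(tr$F)))
  }
})

test_that("true event counts calibrate to the configured rates", {
  # single-state sessions so the expected count is rate * duration;
  # aggregate over many seeds and compare within 3 standard errors
  rate <- 2.0 # events/min
  em <- genotype_preset("wildtype")
  em$rate_per_min <- rate
  n_seeds <- 50
  dur <- 120
  counts <- vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = 100 + i, duration = dur, loc_bout_prob = 0,
                      whisk_rate_per_min = 0, event_model = em,
                      shared_frac = 0,
                      rois_per_compartment = c(AS = 1, AP = 0, Gp = 0,
                                               AE = 0, Neuron = 0))
    beh <- generate_behavior(cfg)
    fl <- generate_fluorescence(cfg, beh$schedule)
    nrow(fl$ground_truth$events)
  }, numeric(1))
  expected <- rate * dur / 60
  se <- sqrt(expected / n_seeds) # Poisson
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # knockout-like regime: roughly tenfold fewer astrocytic events
  ko_counts <- vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = 300 + i, genotype = "knockout",
                      duration = dur, loc_bout_prob = 0,
                      whisk_rate_per_min = 0, shared_frac = 0,
                      rois_per_compartment = c(AS = 1, AP = 0, Gp = 0,
                                               AE = 0, Neuron = 0))
    beh <- generate_behavior(cfg)
    fl <- generate_fluorescence(cfg, beh$schedule)
    nrow(fl$ground_truth$events)
  }, numeric(1))
  ko_expected <- 0.06 * dur / 60 # knockout-like AS rate in Still
  expect_lt(abs(mean(ko_counts) - ko_expected),
            3 * sqrt(ko_expected / n_seeds))
})

test_that("stored state means satisfy the analytic modulation identity", {
  cfg <- sim_config(seed = 6, duration = 300,
                    rois_per_compartment = c(AS = 3, AP = 0, Gp = 0,
                                             AE = 0, Neuron = 0))
  s <- simulate_session(cfg)
  sm <- s$ground_truth$state_means
  for (roi in unique(sm$roi_id)) {
    m_loc <- sm$mean_dff[sm$roi_id == roi & sm$state == "Locomotion"]
    m_s <- sm$mean_dff[sm$roi_id == roi & sm$state == "Still"]
    if (is.finite(m_loc) && is.finite(m_s) && (m_loc + m_s) != 0) {
      expect_identical(analytic_mi(m_loc, m_s),
                       (m_loc - m_s) / (m_loc + m_s))
    }
  }
  # every true event lies within the session
  ev <- s$ground_truth$events
  expect_true(all(ev$onset_s >= 0 & ev$onset_s < cfg$duration))
})

test_that("neuropil mixing follows alpha_true and is removable", {
  cfg <- sim_config(seed = 7, duration = 200, noise_sd = 0.5,
                    rois_per_compartment = c(AS = 0, AP = 0, Gp = 0,
                                             AE = 0, Neuron = 2))
  beh <- generate_behavior(cfg)
  fl <- generate_fluorescence(cfg, beh$schedule)
  nrn <- fl$traces[[1]]
  expect_false(is.null(nrn$F_np))
  # with alpha_true = 0 the neuron trace is independent of the emitted
  # neuropil trace
  em0 <- genotype_preset("wildtype")
  em0$rate_per_min <- 0
  cfg0 <- sim_config(seed = 8, duration = 600, alpha_true = 0,
                     event_model = em0, noise_sd = 1, bleach_slope = 0,
                     rois_per_compartment = c(AS = 0, AP = 0, Gp = 0,
                                              AE = 0, Neuron = 1))
  beh0 <- generate_behavior(cfg0)
  fl0 <- generate_fluorescence(cfg0, beh0$schedule)
  n0 <- fl0$traces[[1]]
  expect_lt(abs(cor(n0$F, n0$F_np)), 3 / sqrt(length(n0$F)))

  # subtracting alpha_true * F_np recovers the uncontaminated trace
  clean <- subtract_neuropil(nrn, alpha = cfg$alpha_true)
  recontam <- clean$F + cfg$alpha_true * nrn$F_np
  expect_equal(recontam, nrn$F)
})

test_that("shared drive couples astrocytic ROIs in the wild-type regime", {
  cfg <- sim_config(seed = 15, duration = 600,
                    rois_per_compartment = c(AS = 4, AP = 0, Gp = 0,
                                             AE = 0, Neuron = 0))
  s <- simulate_session(cfg)
  res_dff <- lapply(s$traces, function(tr) {
    d <- compute_dff(detrend_linear(tr))
    d
  })
  tab <- pairwise_roi_correlation(res_dff)
  cfg_uncorr <- sim_config(seed = 15, duration = 600, shared_frac = 0,
                           rois_per_compartment = c(AS = 4, AP = 0,
                                                    Gp = 0, AE = 0,
                                                    Neuron = 0))
  s2 <- simulate_session(cfg_uncorr)
  tab2 <- pairwise_roi_correlation(lapply(s2$traces, function(tr) {
    compute_dff(detrend_linear(tr))
  }))
  expect_gt(mean(tab$r), mean(tab2$r))
  expect_gt(mean(tab$r), 0.3)
})
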