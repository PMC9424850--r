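# Synthetic taps, accelerations and whole-session bundles.

test_that("tap log has 4 ordered events per cycle plus the closing TS1", {
  cfg <- synth_config(seed = 1, n_cycles = 12)
  taps <- generate_taps(cfg, "low")
  ev <- taps$events
  expect_equal(nrow(ev), 4 * 12 + 1)
  expect_equal(n_cycles(taps), 12)
  expect_equal(ev$screen[1:8], rep(paste0("TS", 1:4), 2))
  expect_true(all(diff(ev$t) > 0))
})

test_that("constant configured duration yields exactly that cycle time", {
  cfg <- synth_config(seed = 1, n_cycles = 10,
                      low = synth_height(dur_start = 1.2, dur_end = 1.2))
  ct <- cycle_times(generate_taps(cfg, "low"), bin_cycles = 5)
  expect_equal(ct$durations, rep(1.2, 10))
  expect_equal(ct$bins$value, c(1.2, 1.2))
})

test_that("a decreasing duration trend produces decreasing bin means", {
  cfg <- synth_config(seed = 1, n_cycles = 100)   # low: 1.10 -> 1.00 s
  ct <- cycle_times(generate_taps(cfg, "low"), bin_cycles = 10)
  expect_true(all(diff(ct$bins$value) < 0))
  gt <- ground_truth(cfg, n_bins = 10)
  expect_equal(ct$bins$value, gt$low$dur_bins)
})

test_that("zero dispersion and bias puts every tap at the centre (AS = 100)", {
  cfg <- synth_config(seed = 2, n_cycles = 8,
                      low = synth_height(tap_sigma_mm = 0))
  taps <- generate_taps(cfg, "low")
  as_ <- accuracy_score(taps$events$x, taps$events$y, cfg$circle)
  expect_equal(as_, rep(100, nrow(taps$events)))
})

test_that("mean radial tap distance approaches sigma * sqrt(pi/2)", {
  sig <- 1.5
  cfg <- synth_config(seed = 3, n_cycles = 1000,
                      low = synth_height(tap_sigma_mm = sig))
  ev <- generate_taps(cfg, "low")$events
  d_mm <- sqrt((ev$x - 160)^2 + (ev$y - 120)^2) * cfg$circle$pixel_mm
  # closed form for an isotropic bivariate normal; SE at n = 4001 is ~0.7%
  expect_equal(mean(d_mm), sig * sqrt(pi / 2), tolerance = 0.03)
})

test_that("tap bias shifts the centroid by the configured offset", {
  cfg <- synth_config(seed = 4, n_cycles = 500,
                      low = synth_height(tap_sigma_mm = 0.5,
                                         tap_bias_mm = c(2, -1)))
  ev <- generate_taps(cfg, "low")$events
  px <- cfg$circle$pixel_mm
  expect_equal(mean(ev$x - 160) * px, 2, tolerance = 0.1)
  expect_equal(mean(ev$y - 120) * px, -1, tolerance = 0.1)
})

test_that("noise-free, divergence-free cycles are identical after normalisation", {
  cfg <- synth_config(seed = 5, n_cycles = 6,
                      low = synth_height(kv_noise_sigma = 0, pert_amp = 0,
                                         dur_start = 1.05, dur_end = 1.05))
  taps <- generate_taps(cfg, "low")
  acc <- generate_accel_session(cfg, "low", taps)$accel
  ncs <- time_normalize(segment_cycles(acc, taps), n = 100)
  ref <- ncs$values[1, , ]
  for (i in 2:6) expect_equal(ncs$values[i, , ], ref, tolerance = 1e-10)
})

test_that("doubling the sensor noise doubles the recovered KV", {
  kv_of <- function(sig, seed) {
    cfg <- synth_config(seed = seed, n_cycles = 120,
                        low = synth_height(kv_noise_sigma = sig, pert_amp = 0,
                                           dur_start = 0.99, dur_end = 0.99))
    taps <- generate_taps(cfg, "low")
    acc <- generate_accel_session(cfg, "low", taps)$accel
    ncs <- time_normalize(segment_cycles(acc, taps), n = 100)
    kv <- kinematic_variability(ncs)
    mean(kv$value[kv$axis != "norm"])
  }
  expect_equal(kv_of(0.10, 7) / kv_of(0.05, 7), 2, tolerance = 0.05)
})

test_that("the latent divergence exponent is recovered from a session", {
  cfg <- synth_config_aligned(seed = 6, n_cycles = 150)
  taps <- generate_taps(cfg, "low")
  acc <- generate_accel_session(cfg, "low", taps)
  ncs <- time_normalize(segment_cycles(acc$accel, taps), n = 100)
  sp <- build_state_space(ncs)
  lle <- estimate_lle(divergence_curve(sp, theiler = 100, K = 50))
  # latent-pair oracle: two map trajectories started 1e-9 apart
  a <- exp(0.05); q1 <- 0.312; q2 <- q1 + 1e-9
  ld <- numeric(51)
  for (k in 0:50) {
    ld[k + 1] <- log(abs(q2 - q1)); q1 <- (a * q1) %% 1; q2 <- (a * q2) %% 1
  }
  oracle <- unname(coef(lm(ld ~ I(0:50)))[2])
  expect_equal(oracle, 0.05, tolerance = 1e-6)
  expect_equal(unname(lle[["lambda5"]]), oracle, tolerance = 0.10)
})

test_that("sessions are deterministic in the seed and vary across seeds", {
  s1 <- generate_session(synth_config(seed = 11, n_cycles = 3, mvc_duration = 1))
  s2 <- generate_session(synth_config(seed = 11, n_cycles = 3, mvc_duration = 1))
  s3 <- generate_session(synth_config(seed = 12, n_cycles = 3, mvc_duration = 1))
  expect_identical(s1$low$emg$samples, s2$low$emg$samples)
  expect_identical(s1$low$taps$events, s2$low$taps$events)
  expect_identical(s1$high$accel$samples, s2$high$accel$samples)
  expect_false(identical(s1$low$taps$events$x, s3$low$taps$events$x))
  # same schema regardless of seed
  expect_identical(dim(s1$low$emg$samples), dim(s3$low$emg$samples))
  expect_identical(names(s1), names(s3))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_cycles = 0), "positive")
  expect_error(synth_config(low = synth_height(mf_start = c(ANT = 5, MED = 90, POS = 80))),
               "Nyquist")
  expect_error(synth_height(tap_sigma_mm = -1), ">= 0")
  expect_error(synth_height(dur_start = 0), "> 0")
})
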