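# EMG conditioning: band-pass, moving RMS, %MVC, median frequency, CCI,
# binning.

fs <- 1926

test_that("bandpass removes DC, preserves in-band tones, rejects bad edges", {
  n <- fs * 2
  t <- (0:(n - 1)) / fs
  # constant (DC) input is annihilated by the 10 Hz high-pass (away from
  # the filtfilt edge transients)
  y <- bandpass(rep(2, n), 10, 950, fs = fs)
  expect_lt(max(abs(y[1000:(n - 1000)])), 1e-2)
  # 100 Hz unit sine passes within 1%
  s <- sin(2 * pi * 100 * t)
  y <- bandpass(s, 10, 950, fs = fs)
  mid <- 500:(n - 500)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)
  # in-band idempotence: filtering twice changes little
  y2 <- bandpass(y, 10, 950, fs = fs)
  expect_equal(y2[mid], y[mid], tolerance = 0.01)
  # edge validation
  expect_error(bandpass(s, 10, 970, fs = fs), "Nyquist")
  expect_error(bandpass(s, -1, 950, fs = fs), "low")
})

test_that("moving RMS matches closed forms and scales linearly", {
  # constant c -> |c| everywhere
  r <- moving_rms(rep(-3, fs), fs)
  expect_true(all(abs(r$value - 3) < 1e-12))
  # zeros -> zeros
  expect_true(all(moving_rms(numeric(fs), fs)$value == 0))
  # sine of amplitude A over an integer number of periods -> A / sqrt(2);
  # 240-sample windows at fs = 1926 hold 15 full periods of 120.375 Hz
  w <- 240
  A <- 2.5
  f0 <- 15 * fs / w
  x <- A * sin(2 * pi * f0 * (0:(fs - 1)) / fs)
  r <- moving_rms(x, fs)
  expect_equal(r$value, rep(A / sqrt(2), nrow(r)), tolerance = 1e-6)
  # homogeneity: rms(k x) = k rms(x) for k >= 0
  set.seed(1)
  x <- rnorm(fs)
  expect_equal(moving_rms(3 * x, fs)$value, 3 * moving_rms(x, fs)$value)
  # signal shorter than a window -> empty series with warning
  expect_warning(r0 <- moving_rms(rnorm(100), fs), "shorter")
  expect_equal(nrow(r0), 0)
})

test_that("window centre spacing equals window * (1 - overlap)", {
  r <- moving_rms(rnorm(fs), fs, window = 0.125, overlap = 0.5)
  expect_true(all(abs(diff(r$t) - 240 / 2 / fs) < 1e-12))
})

test_that("percent_mvc rescales against the reference channel", {
  r <- moving_rms(rep(0.5, fs), fs)
  mvc <- mvc_reference(c(ANT = 0.5, MED = 1, POS = 0.25))
  expect_equal(percent_mvc(r, mvc, "ANT")$value, rep(100, nrow(r)))
  expect_equal(percent_mvc(r, mvc, "MED")$value, rep(50, nrow(r)))
  z <- r; z$value <- 0 * z$value
  expect_equal(percent_mvc(z, mvc, "POS")$value, rep(0, nrow(r)))
  expect_error(percent_mvc(r, mvc, "XXX"), "unknown channel")
})

test_that("median frequency finds tones, flat bands, and flags silence", {
  t <- (0:(60 * fs - 1)) / fs
  # pure 50 Hz sine: MF within one periodogram bin (fs / 240 ~ 8 Hz)
  mf <- median_frequency(sin(2 * pi * 50 * t[1:(2 * fs)]), fs)
  expect_true(all(abs(mf$value - 50) < fs / 240))
  # flat-band noise on [10, 190] -> 100 Hz (band midpoint), and [10, 90]
  # -> 50 Hz; the long-run mean estimates are pinned within 2 Hz
  for (spec in list(c(100, 5), c(50, 3))) {
    x <- generate_emg_channel(60, fs, mf_profile = spec[1], rms_profile = 1,
                              seed = 42)
    mf <- median_frequency(x, fs)
    expect_equal(mean(mf$value), spec[1], tolerance = spec[2] / spec[1])
  }
  # amplitude scaling leaves MF untouched
  x <- generate_emg_channel(2, fs, 100, 1, seed = 7)
  expect_equal(median_frequency(5 * x, fs)$value, median_frequency(x, fs)$value)
  # all-zero window -> NA, not zero
  mf <- median_frequency(c(numeric(480), sin(2 * pi * 50 * t[1:480])), fs)
  expect_true(is.na(mf$value[1]))
  expect_false(anyNA(mf$value[4:7]))
})

test_that("MF estimator bias on flat-band noise shrinks with record length", {
  errs <- vapply(c(10, 80), function(dur) {
    x <- generate_emg_channel(dur, fs, 100, 1, seed = 11)
    abs(mean(median_frequency(x, fs)$value) - 100)
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 0.5)  # consistency, allowing sampling noise
  expect_lt(errs[2], 2)
})

test_that("CCI matches constants, is symmetric and bounded", {
  mk <- function(v) windowed_series(seq(0, 1, by = 0.0625), rep(v, 17), 0.125, 0.5)
  # equal constants -> 50
  expect_equal(cci(mk(3), mk(3), c(0, 1)), 50)
  # one silent muscle -> 0
  expect_equal(cci(mk(2), mk(0), c(0, 1)), 0)
  # 2 vs 1 -> 100 / 3
  expect_equal(cci(mk(2), mk(1), c(0, 1)), 100 / 3)
  # symmetry and bounds on random nonnegative series
  set.seed(2)
  a <- mk(0); a$value <- runif(17)
  b <- mk(0); b$value <- runif(17)
  expect_equal(cci(a, b, c(0, 1)), cci(b, a, c(0, 1)))
  expect_gte(cci(a, b, c(0, 1)), 0)
  expect_lte(cci(a, b, c(0, 1)), 50)
  # zero denominator -> NA with warning
  expect_warning(v <- cci(mk(0), mk(0), c(0, 1)), "denominator")
  expect_true(is.na(v))
  # interval with < 2 windows -> NA with warning
  expect_warning(v <- cci(mk(1), mk(1), c(0, 0.01)), "fewer")
  expect_true(is.na(v))
})

test_that("bin_series averages cycles into bins with the stated arithmetic", {
  # 400 identical values -> 10 equal bins
  b <- bin_series(rep(7, 400), cycle = 1:400, bin_cycles = 40)
  expect_equal(b$value, rep(7, 10))
  # values equal to the cycle index -> bin means 20.5, 60.5, ...
  b <- bin_series(1:400, cycle = 1:400, bin_cycles = 40)
  expect_equal(b$value, seq(20.5, by = 40, length.out = 10))
  # 390 cycles with drop-incomplete -> 9 bins; kept when drop = FALSE
  b <- bin_series(1:390, cycle = 1:390, bin_cycles = 40)
  expect_equal(nrow(b), 9)
  b <- bin_series(1:390, cycle = 1:390, bin_cycles = 40, drop_incomplete = FALSE)
  expect_equal(nrow(b), 10)
  expect_false(b$complete[10])
  expect_equal(b$n[10], 30)
  # timestamp-based assignment drops values outside the cycle range
  b <- bin_series(c(5, 1, 2, 9), t = c(-1, 0.5, 1.5, 10), cycle_starts = c(0, 1, 2),
                  bin_cycles = 1)
  expect_equal(b$value, c(1, 2))
})
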