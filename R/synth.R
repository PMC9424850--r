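# Synthetic session generator: EMG with planted median-frequency and RMS
# trajectories, taps with planted dispersion/bias/duration trend, and
# 9-channel accelerations with planted variability and divergence.

#' Synthesise one EMG channel with planted median frequency and RMS
#'
#' Gaussian white noise is passed through a time-varying flat band-pass
#' whose passband `[10, 2 * MF - 10]` has the target median frequency as
#' its midpoint (the median of a flat spectrum is the band midpoint, so the
#' planted MF is exact by construction). Synthesis is overlap-add of
#' Hann-windowed band-limited frames; afterwards the energy of every
#' half-window analysis block is normalised so that the windowed RMS at the
#' matching analysis settings reproduces `rms_profile` almost exactly.
#'
#' @param duration signal length in seconds.
#' @param fs sampling rate in Hz.
#' @param mf_profile target median frequency: a constant or a `function(t)`
#'   in Hz; must stay inside `(10, (fs/2 + 10)/2)` so the band fits below
#'   Nyquist.
#' @param rms_profile target windowed RMS: a constant or a `function(t)`.
#' @param seed RNG seed (same seed, same signal, bit for bit).
#' @param window,overlap analysis window settings the RMS contract is
#'   enforced at.
#' @return numeric signal vector of length `round(duration * fs)`.
#' @export
generate_emg_channel <- function(duration, fs, mf_profile, rms_profile, seed,
                                 window = 0.125, overlap = 0.5) {
  stopifnot(duration > 0)
  mf_fun <- as_profile(mf_profile)
  rms_fun <- as_profile(rms_profile)
  n <- as.integer(round(duration * fs))
  probe <- mf_fun(seq(0, duration, length.out = 101))
  f_lo <- 10
  if (any(probe <= f_lo) || any(2 * probe - f_lo >= fs / 2)) {
    stop(sprintf(paste0("generate_emg_channel: MF profile must stay in (10, %.0f) Hz ",
                        "so that the flat band [10, 2*MF - 10] is Nyquist-safe"),
                 (fs / 2 + f_lo) / 2), call. = FALSE)
  }
  with_seed(seed, {
    L <- 1024L
    if (n < L) L <- 2L^max(4, floor(log2(n)))
    hop <- L %/% 4L
    x <- numeric(n + L)
    dfr <- fs / L
    freqs <- (0:(L - 1)) * dfr
    fsym <- pmin(freqs, fs - freqs)       # two-sided frequency magnitude
    win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
    for (s in seq(1L, n, by = hop)) {
      mf <- mf_fun((s + L / 2) / fs)
      f_hi <- 2 * mf - f_lo
      cov <- pmax(0, pmin(fsym + dfr / 2, f_hi) - pmax(fsym - dfr / 2, f_lo)) / dfr
      X <- fft(rnorm(L)) * sqrt(cov)
      x[s:(s + L - 1)] <- x[s:(s + L - 1)] + Re(fft(X, inverse = TRUE)) / L * win
    }
    x <- x[seq_len(n)]
    # exact windowed-RMS: normalise half-window blocks (one analysis window
    # is exactly two blocks, so its RMS is the quadratic mean of two
    # adjacent block targets)
    w <- window_samples(fs, window)
    blk <- stride_samples(w, overlap)
    nb <- n %/% blk
    bounds <- c(seq(0L, nb * blk, by = blk), if (nb * blk < n) n)
    for (b in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[b] + 1L):bounds[b + 1L]
      e <- sqrt(mean(x[idx]^2))
      x[idx] <- x[idx] * rms_fun(mean(idx - 0.5) / fs) / max(e, 1e-300)
    }
    x
  })
}

as_profile <- function(p) {
  if (is.function(p)) p else {
    v <- as.numeric(p)
    if (length(v) != 1) stop("profiles must be a constant or a function(t)", call. = FALSE)
    function(t) rep(v, length(t))
  }
}

#' Linear time profile
#'
#' Convenience profile for [generate_emg_channel()]: linear interpolation
#' from `from` at `t = 0` to `to` at `t = duration`, constant outside.
#'
#' @param from,to endpoint values.
#' @param duration ramp length in seconds.
#' @return `function(t)`.
#' @export
linear_profile <- function(from, to, duration) {
  function(t) from + (to - from) * pmin(pmax(t / duration, 0), 1)
}

# per-cycle durations of one height: linear trend across cycles
cycle_durations <- function(hc, n_cycles) {
  if (n_cycles == 1) return(hc$dur_start)
  hc$dur_start + (hc$dur_end - hc$dur_start) * (seq_len(n_cycles) - 1) / (n_cycles - 1)
}

#' Generate a tap log with planted dispersion, bias and duration trend
#'
#' Four taps per cycle in TS1..TS4 order at the cycle's quarter points,
#' plus the closing TS1 tap; `n_cycles` complete cycles. Tap coordinates
#' are drawn from an isotropic bivariate normal (SD `tap_sigma_mm`) around
#' the circle centre offset by `tap_bias_mm`, converted to (continuous)
#' pixel coordinates.
#'
#' @param config a [synth_config()].
#' @param height `"low"` or `"high"`.
#' @return a [tap_log()].
#' @export
generate_taps <- function(config, height = c("low", "high")) {
  height <- match.arg(height)
  hc <- config[[height]]
  n <- config$n_cycles
  dur <- cycle_durations(hc, n)
  starts <- c(0, cumsum(dur))
  t <- as.vector(vapply(seq_len(n),
                        function(i) starts[i] + dur[i] * c(0, 0.25, 0.5, 0.75),
                        numeric(4)))
  t <- c(t, starts[n + 1])                 # closing TS1
  screen <- c(rep(paste0("TS", 1:4), n), "TS1")
  m <- length(t)
  with_seed(sub_seed(config$seed, if (height == "low") 101 else 201), {
    px <- config$circle$pixel_mm
    cx <- config$circle$center[1] + hc$tap_bias_mm[1] / px
    cy <- config$circle$center[2] + hc$tap_bias_mm[2] / px
    sig <- hc$tap_sigma_mm / px
    tap_log(data.frame(screen = screen, t = t,
                       x = rnorm(m, cx, sig), y = rnorm(m, cy, sig)))
  })
}

# fixed orthonormal 9x3 mixing matrix
mixing_matrix <- function(mixing_seed) {
  with_seed(mixing_seed, {
    A <- qr.Q(qr(matrix(rnorm(27), 9, 3)))
    if (qr(A)$rank < 3) stop("mixing matrix rank < 3", call. = FALSE)  # unreachable for qr.Q
    A
  })
}

# 3-D cyclic latent template, non-self-intersecting (a circle in the first
# two components plus a weak second harmonic): phase in [0, 1)
latent_template <- function(phase) {
  cbind(2.0 * sin(2 * pi * phase),
        2.0 * cos(2 * pi * phase),
        0.7 * sin(4 * pi * phase))
}

# latent perturbation sequence on the normalised-phase grid (steps of 1% of
# a cycle). gamma >= 0: scalar expanding map q -> exp(gamma) q mod 1, whose
# largest Lyapunov exponent is exactly gamma and whose divergence persists
# across cycle boundaries. gamma < 0: within-cycle exponential contraction
# exp(gamma * k), re-seeded per cycle.
perturbation_grid <- function(gamma, n_cycles, steps_per_cycle, seed) {
  n <- n_cycles * steps_per_cycle + 2L
  with_seed(seed, {
    if (gamma >= 0) {
      a <- exp(gamma)
      q <- numeric(n)
      q[1] <- runif(1)
      for (i in 2:n) q[i] <- (a * q[i - 1]) %% 1
      q - 0.5
    } else {
      v <- runif(n_cycles, -0.5, 0.5)
      as.vector(vapply(seq_len(n_cycles),
                       function(i) v[i] * exp(gamma * (0:(steps_per_cycle - 1))),
                       numeric(steps_per_cycle)))[seq_len(n)] # recycled tail
    }
  })
}

#' Generate the acceleration streams of one height
#'
#' The nine channels are an orthonormal 9 x 3 mixing of a latent signal
#' (3-D cyclic template plus a latent perturbation with planted divergence
#' rate `divergence_gamma` along a fixed direction) plus iid sensor noise,
#' with cycle boundaries aligned to the tap log.
#'
#' @param config a [synth_config()].
#' @param height `"low"` or `"high"`.
#' @param taps the height's [tap_log()] (generated if omitted).
#' @return list with the [accel_recording()] and the latent `pert` sequence
#'   used (for oracle checks).
#' @export
generate_accel_session <- function(config, height = c("low", "high"), taps = NULL) {
  height <- match.arg(height)
  hc <- config[[height]]
  if (is.null(taps)) taps <- generate_taps(config, height)
  t1 <- ts1_times(taps)
  n_cyc <- length(t1) - 1L
  fs <- config$fs_accel
  n <- as.integer(ceiling(t1[n_cyc + 1] * fs)) + 1L
  tt <- (seq_len(n) - 1) / fs
  cyc <- pmin(pmax(findInterval(tt, t1), 1L), n_cyc)
  frac <- (tt - t1[cyc]) / (t1[cyc + 1] - t1[cyc])
  frac <- pmin(pmax(frac, 0), 1)
  latent <- latent_template(frac)
  spc <- 99L  # map steps per cycle: normalised cycles have 100 boundary-inclusive points
  if (hc$pert_amp > 0 && !is.null(hc$divergence_gamma)) {
    q <- perturbation_grid(hc$divergence_gamma, n_cyc, spc,
                           sub_seed(config$seed, if (height == "low") 103 else 203))
    s <- (cyc - 1) * spc + frac * spc      # global phase-grid coordinate
    s[abs(s - round(s)) < 1e-6] <- round(s[abs(s - round(s)) < 1e-6])
    i0 <- pmin(floor(s), length(q) - 2)
    w <- s - i0
    qs <- (1 - w) * q[i0 + 1] + w * q[i0 + 2]
    u <- c(0.5, -0.3, 0.81); u <- u / sqrt(sum(u^2))
    latent <- latent + hc$pert_amp * qs %o% u
  } else {
    q <- NULL
  }
  A <- mixing_matrix(config$mixing_seed)
  x <- latent %*% t(A)
  if (hc$kv_noise_sigma > 0) {
    x <- x + with_seed(sub_seed(config$seed, if (height == "low") 104 else 204),
                       matrix(rnorm(n * 9, 0, hc$kv_noise_sigma), n, 9))
  }
  colnames(x) <- accel_channel_names()
  list(accel = accel_recording(x, fs), pert = q, mixing = A)
}

#' Generate a complete two-height synthetic session
#'
#' Bundles, for each height, the tap log, acceleration streams, three-muscle
#' EMG with planted per-muscle median-frequency trajectories and RMS
#' levels, and a 5 s constant-amplitude MVC reference trial, together with
#' the planted ground truth for every downstream index.
#'
#' @param config a [synth_config()].
#' @param path optional directory; when given, the session is written to
#'   disk via [write_session()].
#' @param n_bins bins used for the ground-truth per-bin tables.
#' @return A `synthetic_session`: list with elements `low`, `high` (each
#'   holding `emg`, `mvc`, `accel`, `taps`), `circle`, `config` and
#'   `ground_truth`.
#' @export
generate_session <- function(config = synth_config(), path = NULL, n_bins = 10) {
  t0 <- Sys.time()
  session <- list(config = config, circle = config$circle)
  muscles <- c("ANT", "MED", "POS")
  for (height in c("low", "high")) {
    hc <- config[[height]]
    taps <- generate_taps(config, height)
    acc <- generate_accel_session(config, height, taps)
    t_end <- max(taps$events$t)
    dur_emg <- t_end + 0.5
    emg <- sapply(seq_along(muscles), function(m) {
      generate_emg_channel(dur_emg, config$fs_emg,
                           linear_profile(hc$mf_start[m], hc$mf_end[m], t_end),
                           hc$rms_level[m] * config$mvc_rms,
                           sub_seed(config$seed,
                                    (if (height == "low") 110 else 210) + m))
    })
    colnames(emg) <- muscles
    mvc <- sapply(seq_along(muscles), function(m) {
      generate_emg_channel(config$mvc_duration, config$fs_emg,
                           mean(c(hc$mf_start[m], hc$mf_end[m])),
                           config$mvc_rms,
                           sub_seed(config$seed,
                                    (if (height == "low") 120 else 220) + m))
    })
    colnames(mvc) <- muscles
    session[[height]] <- list(
      emg = emg_recording(emg, config$fs_emg),
      mvc = emg_recording(mvc, config$fs_emg),
      accel = acc$accel, taps = taps, pert = acc$pert
    )
  }
  session$ground_truth <- ground_truth(config, n_bins)
  class(session) <- "synthetic_session"
  tf_log("generate_session", sprintf("%d cycles x 2 heights", config$n_cycles), t0 = t0)
  if (!is.null(path)) write_session(session, path)
  session
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d cycles x 2 heights, fs_emg %g Hz, fs_accel %g Hz\n",
              x$config$n_cycles, x$config$fs_emg, x$config$fs_accel))
  invisible(x)
}

#' Planted ground truth of a synthetic configuration
#'
#' Closed-form per-bin values every pipeline index should recover: planted
#' median-frequency bin means, %MVC levels, cocontraction index from the
#' constant activation levels, per-axis kinematic variability (valid when
#' the divergence perturbation is off), divergence exponent, tap dispersion
#' and bias, and cycle-duration bin means.
#'
#' @param config a [synth_config()].
#' @param n_bins number of bins.
#' @return nested list, one entry per height.
#' @export
ground_truth <- function(config, n_bins = 10) {
  out <- list()
  for (height in c("low", "high")) {
    hc <- config[[height]]
    n <- config$n_cycles
    dur <- cycle_durations(hc, n)
    starts <- c(0, cumsum(dur))
    t_end <- starts[n + 1]
    bin_cycles <- n %/% n_bins
    bin_of <- pmin((seq_len(n) - 1) %/% bin_cycles + 1, n_bins)
    # bin mean of the linear MF trajectory = profile at the bin's mean time
    mid <- (starts[-(n + 1)] + starts[-1]) / 2
    mf_bins <- sapply(c("ANT", "MED", "POS"), function(m) {
      prof <- linear_profile(hc$mf_start[m], hc$mf_end[m], t_end)
      tapply(prof(mid), bin_of, mean)
    })
    rms_pct <- 100 * hc$rms_level
    ago <- rms_pct["ANT"]; ant <- rms_pct["POS"]
    out[[height]] <- list(
      mf_bins = mf_bins,
      rms_pct = rms_pct,
      cci = unname(100 * min(ago, ant) / (ago + ant)),
      kv_axis_sigma = hc$kv_noise_sigma,
      divergence_gamma = hc$divergence_gamma,
      tap_sigma_mm = hc$tap_sigma_mm,
      tap_bias_mm = hc$tap_bias_mm,
      mean_radial_mm = hc$tap_sigma_mm * sqrt(pi / 2),
      durations = dur,
      dur_bins = as.vector(tapply(dur, bin_of, mean))
    )
  }
  out
}
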