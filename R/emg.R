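# EMG conditioning, activity (RMS, %MVC), fatigue (median frequency) and the
# cocontraction index.

# window geometry shared by moving_rms / median_frequency / the generator:
# window length is rounded to an even sample count so that a 50% stride is
# exact and one window is exactly two strides
window_samples <- function(fs, window) {
  w <- 2L * as.integer(round(window * fs / 2))
  if (w < 2L) stop("window too short for sampling rate", call. = FALSE)
  w
}

stride_samples <- function(w, overlap) {
  s <- as.integer(round(w * (1 - overlap)))
  if (s < 1L) stop("overlap too large: empty stride", call. = FALSE)
  s
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth high-pass and low-pass stages applied
#' forward-backward (zero phase) to every channel. The default 10-950 Hz
#' band at 1926 Hz sampling sits just inside the 963 Hz Nyquist limit.
#'
#' @param rec an [emg_recording()] (or a bare numeric vector/matrix plus
#'   `fs`).
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate, taken from `rec` when it is a recording.
#' @return The filtered input, same class and length.
#' @export
bandpass <- function(rec, low = 10, high = 950, fs = NULL) {
  if (inherits(rec, "emg_recording")) {
    out <- rec
    out$samples <- bandpass(rec$samples, low, high, fs = rec$fs)
    return(out)
  }
  x <- as.matrix(rec)
  if (is.null(fs)) stop("bandpass: `fs` required for plain numeric input", call. = FALSE)
  nyq <- fs / 2
  if (!(low > 0 && low < high)) {
    stop("bandpass: need 0 < low < high", call. = FALSE)
  }
  if (high >= nyq) {
    stop(sprintf(paste0("bandpass: high edge %g Hz is at or above Nyquist ",
                        "(%g Hz at fs = %g); choose high < fs/2"),
                 high, nyq, fs), call. = FALSE)
  }
  hp <- signal::butter(4, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  y <- apply(x, 2, function(ch) {
    ch <- signal::filtfilt(hp, ch)
    signal::filtfilt(lp, ch)
  })
  y <- matrix(y, nrow = nrow(x), dimnames = dimnames(x))
  if (is.vector(rec)) drop(y) else y
}

#' Moving (windowed) RMS
#'
#' Root-mean-square amplitude over unweighted rectangular windows at stride
#' `window * (1 - overlap)`. A trailing partial window is dropped.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param window window length in seconds (default 0.125).
#' @param overlap overlap fraction (default 0.5).
#' @param t0 time of the first sample, seconds.
#' @return A `windowed_series`: data.frame with window centre times `t` and
#'   `value`, plus `window`/`overlap` attributes.
#' @export
moving_rms <- function(x, fs, window = 0.125, overlap = 0.5, t0 = 0) {
  w <- window_samples(fs, window)
  stride <- stride_samples(w, overlap)
  n <- length(x)
  if (n < w) {
    warning("moving_rms: signal shorter than one window; empty series")
    return(windowed_series(numeric(0), numeric(0), window, overlap))
  }
  starts <- seq(1L, n - w + 1L, by = stride)
  cs <- c(0, cumsum(as.numeric(x)^2))
  vals <- sqrt((cs[starts + w] - cs[starts]) / w)
  windowed_series(t0 + (starts + (w - 1) / 2) / fs, vals, window, overlap)
}

windowed_series <- function(t, value, window, overlap) {
  structure(data.frame(t = t, value = value),
            window = window, overlap = overlap,
            class = c("windowed_series", "data.frame"))
}

#' Express a windowed RMS series as percent of MVC
#'
#' @param rms a `windowed_series` of RMS amplitudes.
#' @param mvc an [mvc_reference()].
#' @param channel channel label, one of `"ANT"`, `"MED"`, `"POS"`.
#' @return The series scaled to `100 * rms / mvc`.
#' @export
percent_mvc <- function(rms, mvc, channel) {
  if (!inherits(mvc, "mvc_reference")) stop("percent_mvc: need an mvc_reference")
  if (!channel %in% names(mvc$values)) {
    stop("percent_mvc: unknown channel ", channel, call. = FALSE)
  }
  rms$value <- 100 * rms$value / mvc$values[[channel]]
  rms
}

#' Windowed median frequency
#'
#' Per window, a Hamming-tapered periodogram is computed and the median
#' frequency is the point where cumulative power first reaches half of the
#' total, linearly interpolated within the crossing frequency bin
#' (cumulative power is attributed to bin upper edges, which keeps the
#' estimator unbiased on flat spectra). All-zero windows yield `NA`.
#'
#' @inheritParams moving_rms
#' @return A `windowed_series` of median frequencies in Hz.
#' @export
median_frequency <- function(x, fs, window = 0.125, overlap = 0.5, t0 = 0) {
  w <- window_samples(fs, window)
  if (w < 8) stop("median_frequency: window too short", call. = FALSE)
  stride <- stride_samples(w, overlap)
  n <- length(x)
  if (n < w) {
    warning("median_frequency: signal shorter than one window; empty series")
    return(windowed_series(numeric(0), numeric(0), window, overlap))
  }
  starts <- seq(1L, n - w + 1L, by = stride)
  taper <- 0.54 - 0.46 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  nf <- w %/% 2
  df <- fs / w
  edges <- (0:nf) * df + df / 2  # upper edge of each periodogram bin
  vals <- vapply(starts, function(s) {
    seg <- x[s:(s + w - 1)]
    if (all(seg == 0)) return(NA_real_)
    P <- Mod(fft(seg * taper)[1:(nf + 1)])^2
    cp <- cumsum(P)
    half <- cp[nf + 1] / 2
    i <- which(cp >= half)[1]
    lo_f <- if (i == 1L) 0 else edges[i - 1]
    lo_c <- if (i == 1L) 0 else cp[i - 1]
    lo_f + (half - lo_c) / (cp[i] - lo_c) * (edges[i] - lo_f)
  }, numeric(1))
  windowed_series(t0 + (starts + (w - 1) / 2) / fs, vals, window, overlap)
}

#' Cocontraction index over a time interval
#'
#' `CCI = 100 * integral(min(ago, ant)) / integral(ago + ant)` with
#' trapezoidal integration over the window-centre grid restricted to
#' `interval`. For nonnegative inputs the index lies in `[0, 50]`, reaching
#' 50 only when the two activations coincide. Computed per stage (ST1 =
#' TS1->TS2 interval, ...) and over the full cycle by the pipeline.
#'
#' @param ago,ant `windowed_series` of agonist (anterior deltoid) and
#'   antagonist (posterior deltoid) activation, in %MVC, on a common time
#'   grid.
#' @param interval `c(t0, t1)` in seconds.
#' @return CCI in percent, or `NA` (with a warning) when the denominator
#'   integral vanishes or fewer than two samples fall in the interval.
#' @export
cci <- function(ago, ant, interval) {
  if (nrow(ago) != nrow(ant) || any(abs(ago$t - ant$t) > 1e-9)) {
    stop("cci: series must share one time grid", call. = FALSE)
  }
  keep <- ago$t >= interval[1] & ago$t <= interval[2]
  if (sum(keep) < 2) {
    warning("cci: fewer than two windows in interval; NA")
    return(NA_real_)
  }
  t <- ago$t[keep]
  lo <- pmin(ago$value[keep], ant$value[keep])
  tot <- ago$value[keep] + ant$value[keep]
  den <- pracma::trapz(t, tot)
  if (!is.finite(den) || den == 0) {
    warning("cci: zero denominator integral; NA")
    return(NA_real_)
  }
  100 * pracma::trapz(t, lo) / den
}

#' Aggregate per-cycle or per-window values into cycle bins
#'
#' Assigns each value to a cycle (via its own cycle index, or via a
#' timestamp and the cycle start times) and averages over bins of
#' `bin_cycles` consecutive cycles.
#'
#' @param values numeric vector.
#' @param cycle integer cycle index (1-based) per value. Give either this or
#'   `t` + `cycle_starts`.
#' @param t timestamps per value, seconds.
#' @param cycle_starts cycle boundary times: starts of cycles 1..n plus the
#'   closing boundary (length n + 1). Values outside all cycles are dropped.
#' @param bin_cycles cycles per bin (default 40).
#' @param drop_incomplete drop a trailing bin with fewer than `bin_cycles`
#'   cycles; if `FALSE` it is kept and flagged in column `complete`.
#' @return data.frame with columns `bin`, `value` (bin mean of non-missing
#'   values), `n` (values per bin) and `complete`.
#' @export
bin_series <- function(values, cycle = NULL, t = NULL, cycle_starts = NULL,
                       bin_cycles = 40, drop_incomplete = TRUE) {
  if (is.null(cycle)) {
    if (is.null(t) || is.null(cycle_starts)) {
      stop("bin_series: give `cycle`, or `t` with `cycle_starts`", call. = FALSE)
    }
    cycle <- findInterval(t, cycle_starts)
    keep <- cycle >= 1 & cycle <= length(cycle_starts) - 1
    values <- values[keep]
    cycle <- cycle[keep]
    n_cyc <- length(cycle_starts) - 1L
  } else {
    n_cyc <- max(cycle)
  }
  bin <- (as.integer(cycle) - 1L) %/% as.integer(bin_cycles) + 1L
  n_full <- n_cyc %/% bin_cycles
  bins <- sort(unique(bin))
  out <- data.frame(
    bin = bins,
    value = vapply(bins, function(b) mean(values[bin == b], na.rm = TRUE), 0),
    n = vapply(bins, function(b) sum(bin == b), 0L)
  )
  out$complete <- out$bin <= n_full
  if (drop_incomplete) out <- out[out$complete, , drop = FALSE]
  rownames(out) <- NULL
  out
}
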