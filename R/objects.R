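#' EMG recording
#'
#' Multichannel raw surface EMG from the three deltoid heads. Channels are
#' stored as columns of a numeric matrix with labels `ANT` (anterior), `MED`
#' (medial) and `POS` (posterior deltoid).
#'
#' @param samples numeric matrix, samples x channels; column names must be a
#'   subset of `c("ANT", "MED", "POS")` and unique.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, t0 = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || nrow(samples) < 1) {
    stop("emg_recording: `samples` must be a non-empty numeric matrix", call. = FALSE)
  }
  labs <- colnames(samples)
  if (is.null(labs) || !all(labs %in% c("ANT", "MED", "POS")) || anyDuplicated(labs)) {
    stop("emg_recording: channel labels must be unique and in {ANT, MED, POS}",
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("emg_recording: `fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, t0 = t0), class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels (%s) @ %g Hz, %.1f s\n",
              nrow(x$samples), ncol(x$samples),
              paste(colnames(x$samples), collapse = ","), x$fs,
              nrow(x$samples) / x$fs))
  invisible(x)
}

# sample times of a recording
rec_times <- function(rec) rec$t0 + (seq_len(nrow(rec$samples)) - 1) / rec$fs

#' Maximum voluntary contraction reference
#'
#' Per-channel reference RMS amplitude from an MVC trial, in the same
#' (arbitrary) amplitude units as the task EMG. Task RMS values are expressed
#' as percentages of these references.
#'
#' @param values named numeric vector of strictly positive reference RMS
#'   amplitudes; names in `c("ANT", "MED", "POS")`.
#' @return An object of class `mvc_reference`.
#' @export
mvc_reference <- function(values) {
  if (!is.numeric(values) || is.null(names(values)) ||
      !all(names(values) %in% c("ANT", "MED", "POS")) || anyDuplicated(names(values))) {
    stop("mvc_reference: named numeric values for channels in {ANT, MED, POS}",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("mvc_reference: reference RMS must be strictly positive", call. = FALSE)
  }
  structure(list(values = values), class = "mvc_reference")
}

#' Accelerometer recording
#'
#' Nine gravity-removed acceleration channels: three body segments (`LA`
#' lower arm, `UA` upper arm, `TR` trunk) times three axes (`X`, `Y`, `Z`),
#' stored as columns `LA_X`, ..., `TR_Z` in m/s^2.
#'
#' @param samples numeric matrix, samples x 9, with the column names above.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(samples, fs, t0 = 0) {
  samples <- as.matrix(samples)
  want <- accel_channel_names()
  if (!is.numeric(samples) || ncol(samples) != 9 ||
      !identical(colnames(samples), want)) {
    stop("accel_recording: `samples` must have the 9 columns ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("accel_recording: `fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, t0 = t0), class = "accel_recording")
}

accel_channel_names <- function() {
  as.vector(t(outer(c("LA", "UA", "TR"), c("X", "Y", "Z"), paste, sep = "_")))
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples x 9 channels @ %g Hz, %.1f s\n",
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Tap-event log
#'
#' Ordered touch-screen tap events. One cycle is TS1 -> TS2 -> TS3 -> TS4 ->
#' next TS1 (counterclockwise from the lower-right screen); stage ST1 is the
#' TS1->TS2 interval and so on.
#'
#' @param events data.frame with columns `screen` (character, in
#'   `"TS1"`..`"TS4"`), `t` (seconds, strictly increasing), `x`, `y`
#'   (pixel coordinates, origin top-left, x rightward, y downward).
#' @return An object of class `tap_log`.
#' @export
tap_log <- function(events) {
  need <- c("screen", "t", "x", "y")
  if (!is.data.frame(events) || !all(need %in% names(events))) {
    stop("tap_log: `events` needs columns screen, t, x, y", call. = FALSE)
  }
  events <- as.data.frame(events)[need]
  events$screen <- as.character(events$screen)
  if (nrow(events) < 1) stop("tap_log: empty event table", call. = FALSE)
  bad <- which(!events$screen %in% paste0("TS", 1:4))
  if (length(bad)) {
    stop("tap_log: unknown screen id at row ", bad[1], ": ", events$screen[bad[1]],
         call. = FALSE)
  }
  dt <- diff(events$t)
  if (any(dt <= 0)) {
    stop("tap_log: timestamps must be strictly increasing; violation at row ",
         which(dt <= 0)[1] + 1, call. = FALSE)
  }
  idx <- as.integer(sub("TS", "", events$screen))
  expect <- ((seq_len(nrow(events)) - 1L) %% 4L) + 1L
  if (idx[1] != 1L || any(idx != expect)) {
    stop("tap_log: screens must cycle TS1, TS2, TS3, TS4 starting at TS1; ",
         "violation at row ", which(idx != expect)[1], call. = FALSE)
  }
  structure(list(events = events), class = "tap_log")
}

#' @export
print.tap_log <- function(x, ...) {
  cat(sprintf("<tap_log> %d events, %d complete cycles, %.1f-%.1f s\n",
              nrow(x$events), n_cycles(x), min(x$events$t), max(x$events$t)))
  invisible(x)
}

# times of the TS1 taps (cycle boundaries)
ts1_times <- function(taps) taps$events$t[taps$events$screen == "TS1"]

#' Number of complete tapping cycles in a tap log
#'
#' A cycle runs from one TS1 tap to the next, so `n` TS1 events close
#' `n - 1` cycles.
#'
#' @param taps a [tap_log()].
#' @return integer cycle count.
#' @export
n_cycles <- function(taps) max(0L, length(ts1_times(taps)) - 1L)

#' Target-circle geometry of one touch screen
#'
#' The displayed target is a circle of 110 px diameter (16.83 mm) centred on
#' a 320 x 240 screen whose pixel pitch is 0.153 mm/px.
#'
#' @param center circle centre, pixel coordinates `c(x, y)`.
#' @param diameter_px circle diameter in pixels.
#' @param pixel_mm pixel pitch, mm per pixel.
#' @param resolution screen resolution `c(width, height)` in pixels.
#' @return An object of class `circle_spec` with derived fields `radius_px`,
#'   `radius_mm` and `diameter_mm`.
#' @export
circle_spec <- function(center = c(160, 120), diameter_px = 110,
                        pixel_mm = 0.153, resolution = c(320, 240)) {
  if (diameter_px <= 0 || pixel_mm <= 0) {
    stop("circle_spec: diameter and pixel pitch must be positive", call. = FALSE)
  }
  r <- diameter_px / 2
  if (center[1] - r < 0 || center[1] + r > resolution[1] ||
      center[2] - r < 0 || center[2] + r > resolution[2]) {
    stop("circle_spec: circle must lie fully on the screen", call. = FALSE)
  }
  structure(list(center = center, diameter_px = diameter_px,
                 pixel_mm = pixel_mm, resolution = resolution,
                 radius_px = r, radius_mm = r * pixel_mm,
                 diameter_mm = diameter_px * pixel_mm),
            class = "circle_spec")
}

#' Analysis-pipeline configuration
#'
#' Collects the tunable constants of the measurement chain. Defaults follow
#' the experimental protocol: 0.125 s windows at 50% overlap, a 10-950 Hz
#' EMG band at 1926 Hz sampling, 400 cycles split into 10 bins of 40, and
#' Lyapunov horizons of 5%, 10%, a quarter and half of a (100-sample)
#' normalised cycle.
#'
#' @param window RMS/median-frequency window length, seconds.
#' @param overlap window overlap fraction in (0, 1).
#' @param band EMG band-pass edges in Hz, `c(low, high)`.
#' @param bin_cycles cycles per bin.
#' @param n_bins number of bins per session.
#' @param lle_horizons Lyapunov fit horizons as fractions of a cycle,
#'   ascending.
#' @param theiler Theiler exclusion window for neighbour search, in
#'   normalised samples (one cycle = 100 samples).
#' @param lle_k maximum divergence horizon in normalised samples.
#' @param lle_fit_start first sample of the divergence curve used in the
#'   slope fit.
#' @param n_phase points per time-normalised cycle.
#' @param stage_points points per time-normalised stage.
#' @param alpha significance level.
#' @param n_followups number of follow-up comparisons Bonferroni-corrected
#'   against `alpha`.
#' @param td_reference `"centroid"` for centroid-referenced tapping
#'   deviation (precision), `"center"` for RMS distance about the circle
#'   centre.
#' @param drop_incomplete_bin drop a trailing bin with fewer than
#'   `bin_cycles` cycles (otherwise keep it, flagged).
#' @param delay_embedding optional `c(dim, lag)` to delay-embed the first
#'   principal-component score instead of using the three score series
#'   directly; `NULL` (default) disables it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 0.125, overlap = 0.5,
                            band = c(10, 950), bin_cycles = 40, n_bins = 10,
                            lle_horizons = c(0.05, 0.10, 0.25, 0.50),
                            theiler = 100, lle_k = 50, lle_fit_start = 0,
                            n_phase = 100, stage_points = 25,
                            alpha = 0.05, n_followups = 4,
                            td_reference = c("centroid", "center"),
                            drop_incomplete_bin = TRUE,
                            delay_embedding = NULL) {
  td_reference <- match.arg(td_reference)
  if (overlap <= 0 || overlap >= 1) {
    stop("pipeline_config: overlap must be in (0, 1)", call. = FALSE)
  }
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    stop("pipeline_config: band must be c(low, high) with 0 < low < high",
         call. = FALSE)
  }
  if (is.unsorted(lle_horizons, strictly = TRUE)) {
    stop("pipeline_config: lle_horizons must be ascending", call. = FALSE)
  }
  structure(list(window = window, overlap = overlap, band = band,
                 bin_cycles = bin_cycles, n_bins = n_bins,
                 lle_horizons = lle_horizons, theiler = theiler,
                 lle_k = lle_k, lle_fit_start = lle_fit_start,
                 n_phase = n_phase, stage_points = stage_points,
                 alpha = alpha, n_followups = n_followups,
                 td_reference = td_reference,
                 drop_incomplete_bin = drop_incomplete_bin,
                 delay_embedding = delay_embedding),
            class = "pipeline_config")
}
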