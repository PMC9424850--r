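# Configuration of the synthetic two-height session generator. The defaults
# are the study conditions the pipeline is validated against: 400 cycles per
# height, 1926 Hz EMG, with the HIGH worktable planted to fatigue faster
# (lower final median frequency), work harder (higher %MVC), tap less
# accurately (larger dispersion) and move faster than LOW.

#' Per-height generator settings
#'
#' @param mf_start,mf_end named per-muscle (`ANT`, `MED`, `POS`) median
#'   frequencies in Hz at the start and end of the session; the planted MF
#'   trajectory is linear in time between them.
#' @param rms_level named per-muscle task RMS amplitude as a fraction of the
#'   MVC reference.
#' @param tap_sigma_mm isotropic bivariate-normal tap dispersion around the
#'   aim point, mm.
#' @param tap_bias_mm systematic aim offset from the circle centre,
#'   `c(x, y)` mm.
#' @param dur_start,dur_end cycle duration at the start and end of the
#'   session, seconds (linear trend across cycles).
#' @param kv_noise_sigma iid sensor noise SD per acceleration channel,
#'   m/s^2.
#' @param divergence_gamma planted log-divergence rate of the latent
#'   perturbation, per normalised sample (1% of a cycle). Negative values
#'   give a contracting perturbation.
#' @param pert_amp amplitude of the latent perturbation, m/s^2 (0 disables
#'   it).
#' @return list of settings for one height.
#' @export
synth_height <- function(mf_start = c(ANT = 85, MED = 90, POS = 80),
                         mf_end = c(ANT = 80, MED = 86, POS = 77),
                         rms_level = c(ANT = 0.10, MED = 0.12, POS = 0.06),
                         tap_sigma_mm = 1.2, tap_bias_mm = c(0, 0),
                         dur_start = 1.10, dur_end = 1.00,
                         kv_noise_sigma = 0.05,
                         divergence_gamma = 0.05, pert_amp = 0.3) {
  muscles <- c("ANT", "MED", "POS")
  as_muscle <- function(v) {
    if (length(v) == 1 && is.null(names(v))) v <- stats::setNames(rep(v, 3), muscles)
    if (!all(muscles %in% names(v))) stop("per-muscle values need names ANT, MED, POS",
                                          call. = FALSE)
    v[muscles]
  }
  out <- list(mf_start = as_muscle(mf_start), mf_end = as_muscle(mf_end),
              rms_level = as_muscle(rms_level),
              tap_sigma_mm = tap_sigma_mm, tap_bias_mm = tap_bias_mm,
              dur_start = dur_start, dur_end = dur_end,
              kv_noise_sigma = kv_noise_sigma,
              divergence_gamma = divergence_gamma, pert_amp = pert_amp)
  if (out$tap_sigma_mm < 0) stop("tap_sigma_mm must be >= 0", call. = FALSE)
  if (out$dur_start <= 0 || out$dur_end <= 0) stop("cycle durations must be > 0",
                                                   call. = FALSE)
  if (out$kv_noise_sigma < 0) stop("kv_noise_sigma must be >= 0", call. = FALSE)
  out
}

#' Synthetic-session configuration
#'
#' Bundles the protocol constants and the per-height generator settings,
#' with planted ground truth for every downstream index.
#'
#' @param seed master RNG seed; every sub-stream is derived from it.
#' @param n_cycles tapping cycles per height (default 400).
#' @param fs_emg EMG sampling rate, Hz (default 1926).
#' @param fs_accel accelerometer sampling rate, Hz (default 100; the
#'   hardware rate is not part of the protocol constants, so it is
#'   configurable).
#' @param mvc_rms RMS amplitude of the synthesised 5 s MVC reference trial
#'   (task amplitudes are `rms_level * mvc_rms`).
#' @param mvc_duration MVC trial length, seconds.
#' @param mixing_seed seed of the fixed 9 x 3 orthonormal sensor-mixing
#'   matrix.
#' @param low,high [synth_height()] settings.
#' @param circle a [circle_spec()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_cycles = 400L, fs_emg = 1926,
                         fs_accel = 100, mvc_rms = 1, mvc_duration = 5,
                         mixing_seed = 42L,
                         low = synth_height(),
                         high = synth_height(
                           mf_end = c(ANT = 72, MED = 78, POS = 70),
                           rms_level = c(ANT = 0.15, MED = 0.17, POS = 0.11),
                           tap_sigma_mm = 1.6,
                           dur_start = 1.05, dur_end = 0.95,
                           kv_noise_sigma = 0.065,
                           divergence_gamma = 0.045),
                         circle = circle_spec()) {
  if (n_cycles < 1) stop("n_cycles must be positive", call. = FALSE)
  for (h in list(low, high)) {
    mfs <- c(h$mf_start, h$mf_end)
    if (any(mfs <= 10) || any(2 * mfs - 10 >= fs_emg / 2)) {
      stop(sprintf("planted MF must lie in (10, %.0f) Hz so its flat band fits below Nyquist",
                   (fs_emg / 2 + 10) / 2), call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_cycles = as.integer(n_cycles),
                 fs_emg = fs_emg, fs_accel = fs_accel,
                 mvc_rms = mvc_rms, mvc_duration = mvc_duration,
                 mixing_seed = as.integer(mixing_seed),
                 low = low, high = high, circle = circle),
            class = "synth_config")
}

# derived sub-seed per generator stream, kept inside 32-bit range
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
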