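# Session on-disk layout, configuration files and results tables.
#
# <dir>/session.yml          flat key-value config + ground truth (if any)
# <dir>/<height>/emg.csv     t, ANT, MED, POS
# <dir>/<height>/mvc.csv     t, ANT, MED, POS        (MVC reference trial)
# <dir>/<height>/accel.csv   t, LA_X, ..., TR_Z
# <dir>/<height>/taps.csv    screen, t, x, y
#
# All tables are plain CSV with a one-line header; timestamps in seconds as
# decimals; pixel origin top-left, x rightward, y downward.

read_table_checked <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  dt <- tryCatch(data.table::fread(path, data.table = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0) stop("empty table: ", path, call. = FALSE)
  dt
}

check_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cl in setdiff(cols, "screen")) {
    if (!is.numeric(df[[cl]])) {
      stop("schema error in ", path, ": column ", cl, " is not numeric", call. = FALSE)
    }
  }
  invisible(df)
}

check_uniform_rate <- function(t, path) {
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("schema error in ", path, ": non-increasing timestamp at row ",
         which(dt <= 0)[1] + 1, call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-9) {
    stop("schema error in ", path, ": sampling rate not uniform", call. = FALSE)
  }
  1 / stats::median(dt)
}

read_emg_csv <- function(path) {
  df <- check_columns(read_table_checked(path), c("t", "ANT", "MED", "POS"), path)
  if (nrow(df) < 2) stop("schema error in ", path, ": fewer than 2 samples", call. = FALSE)
  fs <- check_uniform_rate(df$t, path)
  emg_recording(as.matrix(df[c("ANT", "MED", "POS")]), fs = fs, t0 = df$t[1])
}

read_accel_csv <- function(path) {
  cols <- c("t", accel_channel_names())
  df <- check_columns(read_table_checked(path), cols, path)
  if (nrow(df) < 2) stop("schema error in ", path, ": fewer than 2 samples", call. = FALSE)
  fs <- check_uniform_rate(df$t, path)
  accel_recording(as.matrix(df[accel_channel_names()]), fs = fs, t0 = df$t[1])
}

read_taps_csv <- function(path) {
  df <- check_columns(read_table_checked(path), c("screen", "t", "x", "y"), path)
  tryCatch(tap_log(df),
           error = function(e) stop("schema error in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Read one session directory
#'
#' Reads and validates the per-height EMG, MVC trial, acceleration and tap
#' tables plus the session metadata. Malformed input is rejected with an
#' error naming the offending file (and row where known), never silently
#' coerced.
#'
#' @param path session directory.
#' @param heights which height subdirectories to read.
#' @return list with one entry per height (`emg`, `mvc`, `accel`, `taps`),
#'   plus `circle`, `config` (flat key-value list, if stored) and
#'   `ground_truth` (if stored).
#' @export
read_session <- function(path, heights = c("low", "high")) {
  if (!dir.exists(path)) stop("session directory not found: ", path, call. = FALSE)
  out <- list()
  meta_path <- file.path(path, "session.yml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  for (h in heights) {
    hd <- file.path(path, h)
    if (!dir.exists(hd)) stop("missing height directory: ", hd, call. = FALSE)
    out[[h]] <- list(
      emg = read_emg_csv(file.path(hd, "emg.csv")),
      mvc = read_emg_csv(file.path(hd, "mvc.csv")),
      accel = read_accel_csv(file.path(hd, "accel.csv")),
      taps = read_taps_csv(file.path(hd, "taps.csv"))
    )
  }
  out$circle <- if (!is.null(meta$circle)) do.call(circle_spec, meta$circle) else circle_spec()
  out$config <- meta$config
  out$ground_truth <- meta$ground_truth
  out
}

#' Write a session to its on-disk layout
#'
#' @param session a `synthetic_session` (or any list with the same shape).
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (h in intersect(c("low", "high"), names(session))) {
    hd <- file.path(path, h)
    dir.create(hd, showWarnings = FALSE)
    sh <- session[[h]]
    for (nm in c("emg", "mvc")) {
      rec <- sh[[nm]]
      df <- data.frame(t = rec_times(rec), rec$samples, check.names = FALSE)
      data.table::fwrite(df, file.path(hd, paste0(nm, ".csv")))
    }
    df <- data.frame(t = rec_times(sh$accel), sh$accel$samples, check.names = FALSE)
    data.table::fwrite(df, file.path(hd, "accel.csv"))
    data.table::fwrite(sh$taps$events, file.path(hd, "taps.csv"))
  }
  meta <- list(circle = unclass_plain(session$circle)[c("center", "diameter_px",
                                                       "pixel_mm", "resolution")])
  if (!is.null(session$config)) meta$config <- flatten_config(session$config)
  if (!is.null(session$ground_truth)) {
    meta$ground_truth <- rapply(session$ground_truth,
                                function(v) unname(as.vector(v)), how = "replace")
  }
  yaml::write_yaml(meta, file.path(path, "session.yml"))
  invisible(path)
}

unclass_plain <- function(x) { x <- unclass(x); x }

# flat dotted-key representation of a synth_config for the key-value file
flatten_config <- function(config) {
  x <- unclass_plain(config)
  x$circle <- unclass_plain(x$circle)[c("center", "diameter_px", "pixel_mm", "resolution")]
  names(x$circle$center) <- c("x", "y")
  names(x$circle$resolution) <- c("w", "h")
  for (h in c("low", "high")) names(x[[h]]$tap_bias_mm) <- c("x", "y")
  as.list(unlist(x))
}

unflatten <- function(fl) {
  out <- list()
  for (key in names(fl)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    path <- character(0)
    for (p in parts[-length(parts)]) {
      path <- c(path, p)
      if (is.null(out[[path]])) out[[path]] <- list()
    }
    out[[c(path, parts[length(parts)])]] <- fl[[key]]
  }
  out
}

#' Read / write a generator configuration file
#'
#' Flat key-value text (dotted keys, one per line in YAML syntax); every
#' default of [synth_config()] can be overridden.
#'
#' @param path file path.
#' @param config a [synth_config()].
#' @return `read_synth_config` returns a [synth_config()].
#' @export
write_synth_config <- function(config, path) {
  yaml::write_yaml(flatten_config(config), path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  fl <- yaml::read_yaml(path)
  base <- flatten_config(synth_config())
  unknown <- setdiff(names(fl), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  base[names(fl)] <- fl
  nest <- unflatten(base)
  mus <- function(v) unlist(v)[c("ANT", "MED", "POS")]
  xy <- function(v) as.numeric(unlist(v)[c("x", "y")])
  mk_height <- function(h) {
    synth_height(mf_start = mus(h$mf_start), mf_end = mus(h$mf_end),
                 rms_level = mus(h$rms_level),
                 tap_sigma_mm = h$tap_sigma_mm,
                 tap_bias_mm = xy(h$tap_bias_mm),
                 dur_start = h$dur_start, dur_end = h$dur_end,
                 kv_noise_sigma = h$kv_noise_sigma,
                 divergence_gamma = h$divergence_gamma,
                 pert_amp = h$pert_amp)
  }
  synth_config(seed = nest$seed, n_cycles = nest$n_cycles,
               fs_emg = nest$fs_emg, fs_accel = nest$fs_accel,
               mvc_rms = nest$mvc_rms, mvc_duration = nest$mvc_duration,
               mixing_seed = nest$mixing_seed,
               low = mk_height(nest$low), high = mk_height(nest$high),
               circle = circle_spec(center = xy(nest$circle$center),
                                    diameter_px = nest$circle$diameter_px,
                                    pixel_mm = nest$circle$pixel_mm,
                                    resolution = as.numeric(unlist(nest$circle$resolution)[c("w", "h")])))
}

#' MVC reference from an MVC trial recording
#'
#' The per-channel reference is the maximum of the moving RMS series over
#' the trial, at the same window settings as the task analysis.
#'
#' @param rec MVC trial as an [emg_recording()].
#' @param window,overlap analysis window settings.
#' @return an [mvc_reference()].
#' @export
mvc_from_trial <- function(rec, window = 0.125, overlap = 0.5) {
  vals <- vapply(colnames(rec$samples), function(ch) {
    max(moving_rms(rec$samples[, ch], rec$fs, window, overlap)$value)
  }, numeric(1))
  mvc_reference(vals)
}
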