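# End-point task performance: accuracy score, tapping deviation, task time.

#' Accuracy score of taps
#'
#' `AS = 100 * (r - d) / r` where `r` is the target-circle radius and `d`
#' the distance (in mm, via the pixel pitch) between the tap and the circle
#' centre. `AS = 100` for a perfect centre hit, 0 on the circle boundary and
#' negative outside the circle (no clamping).
#'
#' @param x,y tap coordinates in pixels (vectorised).
#' @param circle a [circle_spec()].
#' @return numeric vector of accuracy scores.
#' @export
accuracy_score <- function(x, y, circle) {
  if (!inherits(circle, "circle_spec")) stop("accuracy_score: need a circle_spec")
  d_mm <- sqrt((x - circle$center[1])^2 + (y - circle$center[2])^2) * circle$pixel_mm
  100 * (circle$radius_mm - d_mm) / circle$radius_mm
}

#' Tapping deviation of a group of taps
#'
#' Precision (repeatability) of the taps on one screen: by default the mean
#' Euclidean distance, in mm, of the taps from their own centroid. With
#' `reference = "center"` the RMS distance from the target-circle centre is
#' used instead (an accuracy-type dispersion). Fewer than two taps yield
#' `NA`.
#'
#' @param x,y tap coordinates in pixels.
#' @param circle a [circle_spec()] (supplies the pixel pitch and, for
#'   `reference = "center"`, the centre).
#' @param reference `"centroid"` (default) or `"center"`.
#' @return tapping deviation in mm.
#' @export
tapping_deviation <- function(x, y, circle, reference = c("centroid", "center")) {
  reference <- match.arg(reference)
  if (length(x) < 2) return(NA_real_)
  if (reference == "centroid") {
    d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
    mean(d) * circle$pixel_mm
  } else {
    d <- sqrt((x - circle$center[1])^2 + (y - circle$center[2])^2)
    sqrt(mean(d^2)) * circle$pixel_mm
  }
}

#' Per-cycle task times and bin means
#'
#' Cycle duration is the difference between successive TS1 tap timestamps;
#' bin means pool `bin_cycles` consecutive cycles.
#'
#' @param taps a [tap_log()] with at least two TS1 events.
#' @param bin_cycles cycles per bin.
#' @param drop_incomplete drop a trailing incomplete bin.
#' @return list with `durations` (per cycle, seconds) and `bins` (a
#'   [bin_series()] table of bin mean durations).
#' @export
cycle_times <- function(taps, bin_cycles = 40, drop_incomplete = TRUE) {
  t1 <- ts1_times(taps)
  if (length(t1) < 2) stop("cycle_times: need at least two TS1 events", call. = FALSE)
  dur <- diff(t1)
  list(durations = dur,
       bins = bin_series(dur, cycle = seq_along(dur), bin_cycles = bin_cycles,
                         drop_incomplete = drop_incomplete))
}
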