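# Cycle segmentation of the acceleration streams and kinematic variability.

#' Segment an acceleration recording into tapping cycles
#'
#' Cycle `i` spans TS1 tap `i` to TS1 tap `i + 1`; the intermediate TS2-TS4
#' taps mark the stage boundaries (ST1 = TS1->TS2, ..., ST4 = TS4->next
#' TS1). Cycles with a missing intermediate tap are flagged invalid and
#' excluded.
#'
#' @param accel an [accel_recording()].
#' @param taps a [tap_log()] lying within the recording's time range.
#' @return A `cycle_set`: list with `start`, `end` (cycle boundary times),
#'   `stages` (n x 5 matrix of boundary times TS1..TS4 plus cycle end) and
#'   the `accel` recording itself.
#' @export
segment_cycles <- function(accel, taps) {
  if (!inherits(accel, "accel_recording")) stop("segment_cycles: need an accel_recording")
  if (!inherits(taps, "tap_log")) stop("segment_cycles: need a tap_log")
  tt <- rec_times(accel)
  ev <- taps$events
  out_of_range <- ev$t < tt[1] - 1e-9 | ev$t > tt[length(tt)] + 1e-9
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop(sprintf("segment_cycles: tap %d (%s at %.3f s) outside recording range [%.3f, %.3f] s",
                 i, ev$screen[i], ev$t[i], tt[1], tt[length(tt)]), call. = FALSE)
  }
  t1 <- ts1_times(taps)
  if (length(t1) < 2) stop("segment_cycles: need at least two TS1 events", call. = FALSE)
  n <- length(t1) - 1L
  stages <- matrix(NA_real_, n, 5,
                   dimnames = list(NULL, c("TS1", "TS2", "TS3", "TS4", "end")))
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    inside <- ev$t >= t1[i] & ev$t < t1[i + 1]
    sub <- ev[inside, , drop = FALSE]
    if (!identical(sub$screen, paste0("TS", 1:4))) {
      valid[i] <- FALSE
      tf_log("segment_cycles", sprintf("cycle %d invalid (irregular taps), excluded", i))
      next
    }
    stages[i, ] <- c(sub$t, t1[i + 1])
  }
  structure(list(start = t1[-(n + 1)][valid], end = t1[-1][valid],
                 stages = stages[valid, , drop = FALSE],
                 n_invalid = sum(!valid), accel = accel),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycles (%d excluded), mean duration %.3f s\n",
              length(x$start), x$n_invalid, mean(x$end - x$start)))
  invisible(x)
}

#' Time-normalise cycles to a fixed number of phase points
#'
#' Each channel of each cycle is linearly interpolated onto `n` equally
#' spaced points spanning the cycle (both boundaries included). Degenerate
#' zero-duration cycles are excluded.
#'
#' @param cycles a `cycle_set` from [segment_cycles()].
#' @param n points per cycle (default 100).
#' @param boundaries optional n_cycles x (k + 1) matrix of interval boundary
#'   times to normalise per sub-interval instead of the full cycle (used for
#'   per-stage variability); each interval then gets `n` points.
#' @return A `normalized_cycle_set`: array `cycles x n x channels` (with an
#'   extra `interval` dimension name prefix when `boundaries` has more than
#'   one interval), plus channel labels.
#' @export
time_normalize <- function(cycles, n = 100, boundaries = NULL) {
  acc <- cycles$accel
  tt <- rec_times(acc)
  keep <- which(cycles$end - cycles$start > 0)
  if (length(keep) < length(cycles$start)) {
    tf_log("time_normalize", sprintf("%d zero-duration cycles excluded",
                                     length(cycles$start) - length(keep)))
  }
  nc <- length(keep)
  chan <- colnames(acc$samples)
  if (is.null(boundaries)) {
    boundaries <- cbind(cycles$start, cycles$end)
  }
  n_int <- ncol(boundaries) - 1L
  out <- array(NA_real_, c(nc, n * n_int, length(chan)),
               dimnames = list(NULL, NULL, chan))
  for (ci in seq_len(nc)) {
    i <- keep[ci]
    for (s in seq_len(n_int)) {
      grid <- seq(boundaries[i, s], boundaries[i, s + 1], length.out = n)
      cols <- ((s - 1) * n + 1):(s * n)
      for (ch in seq_along(chan)) {
        out[ci, cols, ch] <- approx(tt, acc$samples[, ch], xout = grid,
                                    rule = 2)$y
      }
    }
  }
  structure(list(values = out, n_phase = n, n_intervals = n_int,
                 channels = chan, start = cycles$start[keep],
                 end = cycles$end[keep]),
            class = "normalized_cycle_set")
}

#' @export
print.normalized_cycle_set <- function(x, ...) {
  cat(sprintf("<normalized_cycle_set> %d cycles x %d points x %d channels\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

#' Kinematic variability per bin
#'
#' Within each bin, the between-cycle standard deviation (sample SD, n - 1)
#' of every channel is taken at each phase point and averaged over phase:
#' the per-axis KV. Per sensor, the Euclidean norm of its three axis KVs
#' gives `KV_LA`, `KV_UA`, `KV_TR`. Bins with fewer than two cycles yield
#' `NA`.
#'
#' @param ncycles a `normalized_cycle_set`.
#' @param bin integer bin index per cycle (e.g. from cycle index and
#'   `bin_cycles`); defaults to one bin holding all cycles.
#' @return data.frame with columns `bin`, `sensor`, `axis` (`"norm"` for the
#'   per-sensor Euclidean norm) and `value` (m/s^2).
#' @export
kinematic_variability <- function(ncycles, bin = NULL) {
  v <- ncycles$values
  nc <- dim(v)[1]
  if (is.null(bin)) bin <- rep(1L, nc)
  stopifnot(length(bin) == nc)
  chan <- ncycles$channels
  sensors <- unique(sub("_[XYZ]$", "", chan))
  res <- list()
  for (b in sort(unique(bin))) {
    sel <- bin == b
    for (sn in sensors) {
      ax_cols <- grep(paste0("^", sn, "_"), chan)
      ax_kv <- rep(NA_real_, length(ax_cols))
      if (sum(sel) >= 2) {
        for (k in seq_along(ax_cols)) {
          sds <- apply(v[sel, , ax_cols[k], drop = FALSE], 2, sd)
          ax_kv[k] <- mean(sds)
        }
      }
      res[[length(res) + 1]] <- data.frame(
        bin = b, sensor = sn,
        axis = c(sub("^.*_", "", chan[ax_cols]), "norm"),
        value = c(ax_kv, sqrt(sum(ax_kv^2)))
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
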