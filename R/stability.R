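# Local dynamic stability: PCA state space over the nine acceleration
# channels and Rosenstein-style largest-Lyapunov-exponent estimation.

#' Build a principal-component state space from normalised cycles
#'
#' Concatenates the cycles in time into a `T x 9` matrix, centres each
#' column (no variance scaling) and projects onto the three dominant
#' principal axes. The three score series form the state space on which
#' neighbour divergence is measured; the variance fractions of all
#' components are reported.
#'
#' Because cycles are normalised with both boundaries included, the last
#' phase point of a cycle and the first point of the next cycle sample the
#' same cycle-boundary instant; the duplicate is dropped when concatenating
#' (`drop_boundary`), so one state-space sample advances the phase
#' everywhere, including across cycle boundaries.
#'
#' @param ncycles a `normalized_cycle_set` (or a plain `T x d` numeric
#'   matrix already in time order).
#' @param delay_embedding optional `c(dim, lag)`: delay-embed the first
#'   score series instead of using three scores directly.
#' @param drop_boundary drop the duplicated cycle-end sample (default).
#' @return A `state_space`: list with `scores` (T x 3), `varfrac` (variance
#'   fraction per component, descending), `cycle` and `phase` index per
#'   sample.
#' @export
build_state_space <- function(ncycles, delay_embedding = NULL,
                              drop_boundary = TRUE) {
  if (inherits(ncycles, "normalized_cycle_set")) {
    v <- ncycles$values
    if (drop_boundary && ncycles$n_intervals == 1L) {
      v <- v[, -dim(v)[2], , drop = FALSE]
    }
    nc <- dim(v)[1]; np <- dim(v)[2]; nchan <- dim(v)[3]
    x <- matrix(aperm(v, c(2, 1, 3)), nc * np, nchan)
    cycle <- rep(seq_len(nc), each = np)
    phase <- rep(seq_len(np) - 1L, nc)
  } else {
    x <- as.matrix(ncycles)
    cycle <- rep(1L, nrow(x))
    phase <- seq_len(nrow(x)) - 1L
  }
  if (nrow(x) < 2 * ncol(x)) stop("build_state_space: too few samples", call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev > ev[1] * 1e-12) < 3) {
    stop("build_state_space: data rank < 3; inspect the input channels",
         call. = FALSE)
  }
  varfrac <- ev / sum(ev)
  scores <- pc$x[, 1:3, drop = FALSE]
  if (!is.null(delay_embedding)) {
    dim_ <- delay_embedding[1]; lag <- delay_embedding[2]
    n <- nrow(scores) - (dim_ - 1) * lag
    scores <- sapply(seq_len(dim_), function(k) pc$x[(1:n) + (k - 1) * lag, 1])
    cycle <- cycle[seq_len(n)]; phase <- phase[seq_len(n)]
  }
  structure(list(scores = scores, varfrac = varfrac,
                 cycle = cycle, phase = phase),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %d samples x %d dims; var fractions %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$varfrac[1:3]), collapse = ", ")))
  invisible(x)
}

#' Mean logarithmic divergence curve of nearest neighbours
#'
#' For every sample `i` the nearest neighbour `j` (Euclidean distance in
#' state space, subject to the Theiler exclusion `|i - j| >= theiler`) is
#' found; `y(k)` is the mean over pairs of `log ||x(i+k) - x(j+k)||` for
#' `k = 0..K`. Pairs running past the record end are excluded from that
#' `k`'s mean; exact duplicate states (zero distance) are excluded from the
#' log mean and counted.
#'
#' @param space a `state_space` (or plain `T x d` matrix).
#' @param theiler Theiler window in samples (default 100 = one normalised
#'   cycle).
#' @param K maximum horizon in samples.
#' @param subset optional integer vector restricting the query samples `i`
#'   (neighbour candidates still span the whole space).
#' @param nn optional precomputed neighbour indices from
#'   [nearest_neighbors()] at the same `theiler`, to share one search
#'   across per-bin curves.
#' @return A `divergence_curve`: data.frame with columns `k` and `y`, plus
#'   attributes `n_pairs` and `n_zero` (excluded duplicate pairs).
#' @export
divergence_curve <- function(space, theiler = 100, K = 50, subset = NULL,
                             nn = NULL) {
  x <- if (inherits(space, "state_space")) space$scores else as.matrix(space)
  n <- nrow(x)
  if (n <= theiler + K) {
    stop("divergence_curve: record too short for theiler + K", call. = FALSE)
  }
  if (is.null(nn)) nn <- nn_theiler(x, as.integer(theiler))
  qi <- if (is.null(subset)) seq_len(n) else as.integer(subset)
  n_zero <- 0L
  y <- rep(NA_real_, K + 1)
  for (k in 0:K) {
    i <- qi[qi + k <= n]
    j <- nn[i]
    ok <- !is.na(j) & (j + k <= n)
    i <- i[ok]; j <- j[ok]
    d2 <- rowSums((x[i + k, , drop = FALSE] - x[j + k, , drop = FALSE])^2)
    pos <- d2 > 0
    if (k == 0L) n_zero <- sum(!pos)
    y[k + 1] <- mean(0.5 * log(d2[pos]))
  }
  if (n_zero > 0) {
    tf_log("divergence_curve", sprintf("%d duplicate-state pairs excluded", n_zero))
  }
  structure(data.frame(k = 0:K, y = y),
            n_pairs = length(qi), n_zero = n_zero,
            class = c("divergence_curve", "data.frame"))
}

#' Largest Lyapunov exponents from a divergence curve
#'
#' `lambda_h` is the ordinary least-squares slope of `y(k)` versus `k` over
#' `k` in `[fit_start, h]`, in units of log-divergence per normalised sample
#' (one sample = 1% of a cycle; per-cycle rates are `100 * lambda`). The
#' default horizons 5, 10, 25 and 50 samples correspond to 5%, 10%, a
#' quarter and half of a cycle.
#'
#' @param curve a `divergence_curve`.
#' @param horizons fit horizons in samples.
#' @param fit_start first `k` included in the fit.
#' @return Named numeric vector (`lambda5`, `lambda10`, `lambdaQ`,
#'   `lambdaH` for the default horizons); `NA` where fewer than 3 curve
#'   points are available.
#' @export
estimate_lle <- function(curve, horizons = c(5, 10, 25, 50), fit_start = 0) {
  if (max(horizons) > max(curve$k)) {
    stop("estimate_lle: curve shorter than the largest horizon", call. = FALSE)
  }
  std <- identical(as.numeric(horizons), c(5, 10, 25, 50))
  nms <- if (std) c("lambda5", "lambda10", "lambdaQ", "lambdaH")
         else paste0("lambda", horizons)
  out <- vapply(horizons, function(h) {
    sel <- curve$k >= fit_start & curve$k <= h & is.finite(curve$y)
    if (sum(sel) < 3) return(NA_real_)
    unname(coef(lm(curve$y[sel] ~ curve$k[sel]))[2])
  }, numeric(1))
  names(out) <- nms
  out
}
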