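# End-to-end per-session analysis: raw recordings -> per-bin index table.

#' Nearest neighbours of a state space under Theiler exclusion
#'
#' Exact scan; exposed so that per-bin divergence curves can share one
#' neighbour search.
#'
#' @param space a `state_space` or `T x d` matrix.
#' @param theiler Theiler window in samples.
#' @return integer vector of 1-based neighbour indices.
#' @export
nearest_neighbors <- function(space, theiler = 100) {
  x <- if (inherits(space, "state_space")) space$scores else as.matrix(space)
  nn_theiler(x, as.integer(theiler))
}

#' Analyse one session into per-bin index tables
#'
#' Runs the full measurement chain per height: EMG band-pass, windowed RMS
#' as %MVC and median frequency binned over cycles; the cocontraction index
#' of anterior (agonist) vs posterior (antagonist) deltoid per stage and
#' full cycle; cycle segmentation, time normalisation, kinematic
#' variability per sensor (full cycle and per stage); the PCA state space
#' with per-bin largest Lyapunov exponents at the four horizons; accuracy
#' score and tapping deviation per screen; and cycle times.
#'
#' @param session a `synthetic_session`, the list returned by
#'   [read_session()], or a session directory path.
#' @param config a [pipeline_config()].
#' @param circle a [circle_spec()]; defaults to the session's.
#' @param stages which analysis stages to run (default all).
#' @return An `analysis`: list with `bins` (long data.frame `height`,
#'   `index`, `bin`, `value`), `varfrac` (PC variance fractions per height)
#'   and `curves` (per-bin divergence curves).
#' @export
analyze_session <- function(session, config = pipeline_config(), circle = NULL,
                            stages = c("emg", "cci", "kv", "lle", "performance")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(session)) session <- read_session(session)
  if (is.null(circle)) circle <- if (!is.null(session$circle)) session$circle else circle_spec()
  rows <- list()
  varfrac <- list()
  curves <- list()
  add <- function(height, index, bins) {
    rows[[length(rows) + 1]] <<- data.frame(height = toupper(height), index = index,
                                            bin = bins$bin, value = bins$value)
  }
  for (height in intersect(c("low", "high"), names(session))) {
    t0 <- Sys.time()
    sh <- session[[height]]
    taps <- sh$taps
    t1 <- ts1_times(taps)
    n_cyc <- length(t1) - 1L
    bin_of_cycle <- (seq_len(n_cyc) - 1L) %/% config$bin_cycles + 1L

    keep_bins <- if (config$drop_incomplete_bin) {
      seq_len(n_cyc %/% config$bin_cycles)
    } else sort(unique(bin_of_cycle))

    ## --- EMG: RMS (%MVC), median frequency ---
    pct <- NULL
    if (any(c("emg", "cci") %in% stages)) {
      emg <- bandpass(sh$emg, config$band[1], config$band[2])
      mvc <- mvc_from_trial(bandpass(sh$mvc, config$band[1], config$band[2]),
                            config$window, config$overlap)
      pct <- list()
      for (m in colnames(emg$samples)) {
        r <- moving_rms(emg$samples[, m], emg$fs, config$window, config$overlap,
                        t0 = emg$t0)
        pct[[m]] <- percent_mvc(r, mvc, m)
        if (!"emg" %in% stages) next
        mf <- median_frequency(emg$samples[, m], emg$fs, config$window,
                               config$overlap, t0 = emg$t0)
        add(height, paste0("RMS_", m),
            bin_series(pct[[m]]$value, t = pct[[m]]$t, cycle_starts = t1,
                       bin_cycles = config$bin_cycles,
                       drop_incomplete = config$drop_incomplete_bin))
        add(height, paste0("MF_", m),
            bin_series(mf$value, t = mf$t, cycle_starts = t1,
                       bin_cycles = config$bin_cycles,
                       drop_incomplete = config$drop_incomplete_bin))
      }
      tf_log("emg", height, t0 = t0)
    }

    cycles <- NULL
    if (any(c("cci", "kv", "lle") %in% stages)) {
      cycles <- segment_cycles(sh$accel, taps)
      cyc_idx <- findInterval(cycles$start, t1)
      bin_of <- bin_of_cycle[cyc_idx]
    }

    ## --- cocontraction: ANT agonist vs POS antagonist ---
    if ("cci" %in% stages) {
      t0 <- Sys.time()
      stg <- cycles$stages
      cci_vals <- matrix(NA_real_, nrow(stg), 5,
                         dimnames = list(NULL, c(paste0("ST", 1:4), "ALL")))
      for (i in seq_len(nrow(stg))) {
        for (s in 1:4) {
          cci_vals[i, s] <- suppressWarnings(
            cci(pct$ANT, pct$POS, c(stg[i, s], stg[i, s + 1])))
        }
        cci_vals[i, 5] <- suppressWarnings(
          cci(pct$ANT, pct$POS, c(stg[i, 1], stg[i, 5])))
      }
      for (cn in colnames(cci_vals)) {
        add(height, paste0("CCI_", cn),
            bin_series(cci_vals[, cn], cycle = cyc_idx,
                       bin_cycles = config$bin_cycles,
                       drop_incomplete = config$drop_incomplete_bin))
      }
      tf_log("cci", height, t0 = t0)
    }

    ncs <- NULL
    if (any(c("kv", "lle") %in% stages)) {
      ncs <- time_normalize(cycles, n = config$n_phase)
    }

    ## --- kinematic variability ---
    if ("kv" %in% stages) {
      t0 <- Sys.time()
      kv <- kinematic_variability(ncs, bin = bin_of)
      kv <- kv[kv$axis == "norm" & kv$bin %in% keep_bins, ]
      for (sn in unique(kv$sensor)) {
        sub <- kv[kv$sensor == sn, ]
        add(height, paste0("KV_", sn),
            data.frame(bin = sub$bin, value = sub$value))
      }
      nstg <- time_normalize(cycles, n = config$stage_points,
                             boundaries = cycles$stages)
      for (s in 1:4) {
        cols <- ((s - 1) * config$stage_points + 1):(s * config$stage_points)
        sub_ncs <- nstg
        sub_ncs$values <- nstg$values[, cols, , drop = FALSE]
        kvs <- kinematic_variability(sub_ncs, bin = bin_of)
        kvs <- kvs[kvs$axis == "norm" & kvs$bin %in% keep_bins, ]
        for (sn in unique(kvs$sensor)) {
          sub <- kvs[kvs$sensor == sn, ]
          add(height, sprintf("KV_%s_ST%d", sn, s),
              data.frame(bin = sub$bin, value = sub$value))
        }
      }
      tf_log("kv", height, t0 = t0)
    }

    ## --- local dynamic stability ---
    if ("lle" %in% stages) {
      t0 <- Sys.time()
      space <- build_state_space(ncs, delay_embedding = config$delay_embedding)
      varfrac[[height]] <- space$varfrac
      nn <- nearest_neighbors(space, config$theiler)
      horizons <- round(config$lle_horizons * config$n_phase)
      lle_bins <- lapply(keep_bins, function(b) {
        qi <- which(bin_of_cycle[space$cycle] == b)
        crv <- divergence_curve(space, theiler = config$theiler, K = config$lle_k,
                                subset = qi, nn = nn)
        curves[[paste(height, b, sep = "_")]] <<- crv
        estimate_lle(crv, horizons = horizons, fit_start = config$lle_fit_start)
      })
      lmat <- do.call(rbind, lle_bins)
      lnames <- c("LLE5", "LLE10", "LLEQ", "LLEH")
      for (k in seq_along(lnames)) {
        add(height, lnames[k], data.frame(bin = keep_bins, value = lmat[, k]))
      }
      tf_log("lle", height, t0 = t0)
    }

    ## --- end-point performance ---
    if (!"performance" %in% stages) next
    t0 <- Sys.time()
    ev <- taps$events
    ev$cycle <- findInterval(ev$t, t1)
    ev <- ev[ev$cycle >= 1 & ev$cycle <= n_cyc, ]
    ev$bin <- bin_of_cycle[ev$cycle]
    ev$as <- accuracy_score(ev$x, ev$y, circle)
    for (sc in paste0("TS", 1:4)) {
      sub <- ev[ev$screen == sc, ]
      add(height, paste0("AS_", sc),
          bin_series(sub$as, cycle = sub$cycle, bin_cycles = config$bin_cycles,
                     drop_incomplete = config$drop_incomplete_bin))
      td <- vapply(keep_bins, function(b) {
        s2 <- sub[sub$bin == b, ]
        tapping_deviation(s2$x, s2$y, circle, reference = config$td_reference)
      }, numeric(1))
      add(height, paste0("TD_", sc), data.frame(bin = keep_bins, value = td))
    }
    add(height, "TIME",
        cycle_times(taps, bin_cycles = config$bin_cycles,
                    drop_incomplete = config$drop_incomplete_bin)$bins)
    tf_log("performance", height, t0 = t0)
  }
  bins <- do.call(rbind, rows)
  rownames(bins) <- NULL
  structure(list(bins = bins, varfrac = varfrac, curves = curves,
                 config = config),
            class = "tap_analysis")
}

#' @export
print.tap_analysis <- function(x, ...) {
  cat(sprintf("<tap_analysis> %d index values (%d indices x %s heights)\n",
              nrow(x$bins), length(unique(x$bins$index)),
              length(unique(x$bins$height))))
  invisible(x)
}

#' Write analysis tables to a directory
#'
#' @param analysis a `tap_analysis`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_analysis <- function(analysis, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(analysis$bins, file.path(path, "bins.csv"))
  vf <- do.call(rbind, lapply(names(analysis$varfrac), function(h) {
    data.frame(height = toupper(h), component = seq_along(analysis$varfrac[[h]]),
               fraction = analysis$varfrac[[h]])
  }))
  data.table::fwrite(vf, file.path(path, "pca.csv"))
  invisible(path)
}

#' Cohort statistics over participants
#'
#' Applies the inference chain to a multi-participant bin table: first-bin
#' ratio normalisation, the paired LOW/HIGH t-test pooling participant x
#' bin pairs, and per height a one-way repeated-measures ANOVA across the
#' five periods gating Bonferroni-corrected follow-ups of P2..P5 against
#' P1.
#'
#' @param bins data.frame with columns `participant`, `height`, `index`,
#'   `bin`, `value` (e.g. stacked `analysis$bins` with a `participant`
#'   column added).
#' @param config a [pipeline_config()].
#' @return data.frame: one row per index x comparison with `statistic`,
#'   `p`, `alpha`, `significant`.
#' @export
cohort_stats <- function(bins, config = pipeline_config()) {
  ratios <- to_ratio(bins)
  out <- list()
  for (ix in unique(ratios$index)) {
    sub <- ratios[ratios$index == ix, ]
    wide <- function(h) {
      s <- sub[sub$height == h, ]
      m <- tapply(s$value, list(s$participant, s$bin), mean)
      m[order(rownames(m)), , drop = FALSE]
    }
    lo <- wide("LOW"); hi <- wide("HIGH")
    ht <- paired_height_test(as.vector(lo), as.vector(hi), alpha = config$alpha)
    out[[length(out) + 1]] <- data.frame(
      index = ix, comparison = "HIGH-LOW", statistic = ht$statistic,
      p = ht$p, alpha = ht$alpha, significant = ht$significant)
    for (h in c("LOW", "HIGH")) {
      pm <- bins_to_periods(if (h == "LOW") lo else hi)
      an <- rm_anova_periods(pm, alpha = config$alpha)
      out[[length(out) + 1]] <- data.frame(
        index = ix, comparison = paste0("periods_", h), statistic = an$F,
        p = an$p, alpha = an$alpha, significant = an$significant)
      fu <- followup_bonferroni(pm, alpha = config$alpha,
                                m = config$n_followups, gate = an$significant)
      out[[length(out) + 1]] <- data.frame(
        index = ix, comparison = paste0(fu$comparison, "_", h),
        statistic = fu$statistic, p = fu$p, alpha = fu$alpha_corrected,
        significant = fu$significant)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render a per-period summary of an analysis
#'
#' Prints, per index and height, the five period means (pairs of bins) of
#' the first-bin-normalised values - the panel structure of the study's
#' results figures, as numbers. With cohort statistics attached,
#' significant period effects are annotated with a dagger and height
#' effects with an asterisk.
#'
#' @param analysis a `tap_analysis`, or a bins data.frame.
#' @param stats optional result of [cohort_stats()].
#' @param file optional path to also write the summary CSV to.
#' @return the summary data.frame, invisibly.
#' @export
report_summary <- function(analysis, stats = NULL, file = NULL) {
  bins <- if (inherits(analysis, "tap_analysis")) analysis$bins else analysis
  if (!"participant" %in% names(bins)) bins$participant <- "S1"
  ratios <- to_ratio(bins)
  agg <- stats::aggregate(value ~ height + index + bin, ratios, mean)
  rows <- list()
  for (ix in unique(agg$index)) {
    for (h in unique(agg$height)) {
      sub <- agg[agg$index == ix & agg$height == h, ]
      sub <- sub[order(sub$bin), ]
      if (nrow(sub) %% 2 != 0) sub <- sub[-nrow(sub), ]
      pm <- colMeans(matrix(sub$value, nrow = 2))
      row <- data.frame(index = ix, height = h)
      for (p in seq_along(pm)) row[[paste0("P", p)]] <- round(pm[p], 4)
      flag <- ""
      if (!is.null(stats)) {
        s1 <- stats[stats$index == ix & stats$comparison == paste0("periods_", h), ]
        if (nrow(s1) && isTRUE(s1$significant[1])) flag <- paste0(flag, "†")
        s2 <- stats[stats$index == ix & stats$comparison == "HIGH-LOW", ]
        if (nrow(s2) && isTRUE(s2$significant[1])) flag <- paste0(flag, "*")
      }
      row$flags <- flag
      rows[[length(rows) + 1]] <- row
    }
  }
  res <- do.call(rbind, rows)
  fmt <- res
  if (!is.null(file)) data.table::fwrite(res, file)
  print(fmt, row.names = FALSE)
  invisible(res)
}
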