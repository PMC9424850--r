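# Ratio normalisation, bins -> periods, paired height tests,
# repeated-measures ANOVA over periods, Bonferroni follow-ups.

#' Normalise per-bin index values to first-bin ratios
#'
#' Every value is divided by the participant's first-bin value of the same
#' index at the LOW height (default policy), so the two heights share one
#' reference and a height effect survives normalisation. Median frequency
#' uses its own-height first bin instead (`own_height_ref`), matching how MF
#' is compared within each height. A zero reference yields `NA` with a
#' warning.
#'
#' @param bins data.frame with columns `participant`, `height` (`"LOW"` /
#'   `"HIGH"`), `index`, `bin`, `value`.
#' @param own_height_ref logical vector (recycled over rows) or a character
#'   vector of index names that reference their own height's first bin;
#'   defaults to indices whose name starts with `"MF"`.
#' @return The input with `value` replaced by ratios.
#' @export
to_ratio <- function(bins, own_height_ref = NULL) {
  need <- c("participant", "height", "index", "bin", "value")
  if (!all(need %in% names(bins))) {
    stop("to_ratio: need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(own_height_ref)) own_height_ref <- grepl("^MF", bins$index)
  if (is.character(own_height_ref)) {
    own_height_ref <- bins$index %in% own_height_ref
  }
  ref_height <- ifelse(own_height_ref, bins$height, "LOW")
  key <- function(p, h, i) paste(p, h, i, sep = "\r")
  first <- bins[bins$bin == min(bins$bin), ]
  ref_map <- first$value
  names(ref_map) <- key(first$participant, first$height, first$index)
  ref <- ref_map[key(bins$participant, ref_height, bins$index)]
  if (any(is.na(ref))) {
    stop("to_ratio: missing first-bin reference for some (participant, index)",
         call. = FALSE)
  }
  zero <- ref == 0
  if (any(zero)) warning("to_ratio: zero reference bin; NA ratios produced")
  bins$value <- ifelse(zero, NA_real_, bins$value / ref)
  bins
}

#' Paired t-test between the two heights
#'
#' Two-sided paired t-test on normalised ratios, pairing participant x bin
#' (18 participants x 10 bins = 180 pairs in the full design).
#'
#' @param low,high equal-length paired numeric vectors.
#' @param alpha significance level.
#' @return list with `statistic`, `df`, `p`, `alpha` and `significant`.
#' @export
paired_height_test <- function(low, high, alpha = 0.05) {
  if (length(low) != length(high)) {
    stop("paired_height_test: vectors must be of equal length", call. = FALSE)
  }
  ht <- t.test(high, low, paired = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, alpha = alpha, significant = ht$p.value < alpha)
}

#' Pool bins into periods
#'
#' Period `p` pools bins `2p - 1` and `2p` (five periods for ten bins); the
#' cell value is the mean of the subject's two bin values.
#'
#' @param mat numeric matrix, subjects x bins (10 columns for the full
#'   design).
#' @return matrix subjects x periods.
#' @export
bins_to_periods <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) %% 2 != 0) stop("bins_to_periods: need an even number of bins", call. = FALSE)
  np <- ncol(mat) / 2
  out <- sapply(seq_len(np), function(p) rowMeans(mat[, c(2 * p - 1, 2 * p), drop = FALSE]))
  colnames(out) <- paste0("P", seq_len(np))
  out
}

#' One-way repeated-measures ANOVA across periods
#'
#' Subjects are the repeated factor: the two-way (subject x period)
#' decomposition gives `F = MS_period / MS_error` with `(p - 1)` and
#' `(p - 1)(s - 1)` degrees of freedom. Subjects with any missing period are
#' dropped (complete-case). An optional Greenhouse-Geisser correction
#' rescales the degrees of freedom by the sphericity estimate epsilon.
#'
#' @param periods numeric matrix, subjects x periods.
#' @param alpha significance level.
#' @param gg apply the Greenhouse-Geisser correction.
#' @return list with `F`, `df1`, `df2`, `p`, `alpha`, `significant`,
#'   `n_subjects` and (when `gg`) `epsilon`.
#' @export
rm_anova_periods <- function(periods, alpha = 0.05, gg = FALSE) {
  m <- as.matrix(periods)
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    tf_log("rm_anova_periods", sprintf("%d incomplete subjects dropped", sum(!complete)))
  }
  m <- m[complete, , drop = FALSE]
  s <- nrow(m); p <- ncol(m)
  if (s < 2 || p < 2) stop("rm_anova_periods: need >= 2 complete subjects and >= 2 periods",
                           call. = FALSE)
  grand <- mean(m)
  ss_subj <- p * sum((rowMeans(m) - grand)^2)
  ss_per <- s * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_per
  df1 <- p - 1
  df2 <- (p - 1) * (s - 1)
  ms_per <- ss_per / df1
  ms_err <- ss_err / df2
  Fv <- if (ms_per <= 0) 0 else if (ms_err <= 0) Inf else ms_per / ms_err
  eps <- 1
  if (gg) {
    # Greenhouse-Geisser epsilon from the double-centred covariance matrix
    S <- stats::cov(m)
    Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
    eps <- sum(diag(Sc))^2 / ((p - 1) * sum(Sc^2))
    eps <- min(1, max(eps, 1 / (p - 1)))
  }
  pv <- pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  out <- list(F = Fv, df1 = df1 * eps, df2 = df2 * eps, p = pv,
              alpha = alpha, significant = pv < alpha, n_subjects = s)
  if (gg) out$epsilon <- eps
  out
}

#' Bonferroni-corrected follow-up tests against the first period
#'
#' Paired t-tests of periods P2..P5 against P1, flagged significant at
#' `alpha / m` (0.0125 for alpha 0.05 and m = 4). Intended to be gated on a
#' significant [rm_anova_periods()] result; the gate decision is recorded in
#' the output but not enforced.
#'
#' @param periods numeric matrix, subjects x periods.
#' @param alpha family significance level.
#' @param m number of comparisons the correction divides `alpha` by
#'   (default: number of follow-ups).
#' @param gate logical: result of the ANOVA gate. When `FALSE`, tests are
#'   still computed but all `significant` flags are `FALSE`.
#' @return data.frame with one row per comparison: `comparison`,
#'   `statistic`, `df`, `p`, `alpha_corrected`, `significant`.
#' @export
followup_bonferroni <- function(periods, alpha = 0.05, m = NULL, gate = TRUE) {
  pm <- as.matrix(periods)
  np <- ncol(pm)
  if (np < 2) stop("followup_bonferroni: need >= 2 periods", call. = FALSE)
  if (is.null(m)) m <- np - 1
  thr <- alpha / m
  rows <- lapply(2:np, function(p) {
    d <- pm[, p] - pm[, 1]
    if (sd(d, na.rm = TRUE) <= .Machine$double.eps * max(1, abs(mean(d)))) {
      # identical periods: no evidence against equality
      st <- 0; dfree <- sum(!is.na(d)) - 1; pv <- 1
    } else {
      ht <- t.test(pm[, p], pm[, 1], paired = TRUE)
      st <- unname(ht$statistic); dfree <- unname(ht$parameter); pv <- ht$p.value
    }
    data.frame(comparison = sprintf("P%d-P1", p),
               statistic = st, df = dfree, p = pv, alpha_corrected = thr,
               significant = gate & pv < thr)
  })
  do.call(rbind, rows)
}
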