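# Ratio normalisation, paired tests, RM-ANOVA, Bonferroni follow-ups.

mk_bins <- function(value_fun, participants = 2, indices = c("MF_ANT", "TIME")) {
  g <- expand.grid(participant = paste0("S", seq_len(participants)),
                   height = c("LOW", "HIGH"), index = indices, bin = 1:10,
                   stringsAsFactors = FALSE)
  g$value <- value_fun(g)
  g
}

test_that("ratio normalisation follows the two reference policies", {
  bins <- mk_bins(function(g) ifelse(g$height == "LOW", 2, 4) * g$bin)
  r <- to_ratio(bins)
  # non-MF indices: everything relative to the LOW first bin (value 2)
  tm <- r[r$index == "TIME", ]
  expect_equal(tm$value[tm$height == "LOW" & tm$bin == 1], c(1, 1))
  expect_equal(tm$value[tm$height == "HIGH" & tm$bin == 1], c(2, 2))
  expect_equal(tm$value[tm$height == "LOW" & tm$bin == 10], c(10, 10))
  # MF: each height relative to its own first bin
  mf <- r[r$index == "MF_ANT", ]
  expect_equal(mf$value[mf$bin == 1], rep(1, 4))
  expect_equal(mf$value[mf$height == "HIGH" & mf$bin == 5], c(5, 5))
  # constant series -> all ratios 1; idempotence under renormalisation
  bins2 <- mk_bins(function(g) rep(3, nrow(g)))
  r2 <- to_ratio(bins2)
  expect_true(all(r2$value == 1))
  expect_equal(to_ratio(r2), r2)
})

test_that("zero references are flagged", {
  bins <- mk_bins(function(g) ifelse(g$bin == 1 & g$height == "LOW", 0, 1),
                  indices = "TIME")
  expect_warning(r <- to_ratio(bins), "zero reference")
  expect_true(all(is.na(r$value)))
})

test_that("paired height test nulls out identical vectors and finds shifts", {
  x <- rnorm(180)
  ht <- paired_height_test(x, x)
  expect_true(is.na(ht$statistic) || abs(ht$statistic) < 1e-8 || ht$p > 0.99)
  # planted shift of 1 within-pair SD at 180 pairs: near-certain rejection
  set.seed(51)
  rej <- vapply(1:200, function(i) {
    lo <- rnorm(180)
    hi <- lo + rnorm(180) + 1      # pair differences ~ N(1, 1)
    paired_height_test(lo, hi)$significant
  }, logical(1))
  expect_gt(mean(rej), 0.99)
  expect_error(paired_height_test(1:3, 1:4), "equal length")
})

test_that("RM-ANOVA matches the two-way decomposition computed by aov", {
  set.seed(52)
  for (rep in 1:5) {
    m <- matrix(rnorm(18 * 5, mean = rep(c(1, 1.1, 1.2, 1.1, 1), each = 18)),
                18, 5)
    got <- rm_anova_periods(m)
    df <- data.frame(y = as.vector(m),
                     subject = factor(rep(1:18, 5)),
                     period = factor(rep(1:5, each = 18)))
    s <- summary(stats::aov(y ~ period + Error(subject / period), data = df))
    tab <- s[["Error: subject:period"]][[1]]
    expect_equal(got$F, tab["period", "F value"], tolerance = 1e-10)
    expect_equal(got$p, tab["period", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(got$df1, 4)
    expect_equal(got$df2, 68)
  }
})

test_that("RM-ANOVA on a 3-subject toy table matches the manual decomposition", {
  m <- rbind(c(1, 2, 3, 4, 5),
             c(2, 2, 4, 4, 6),
             c(0, 1, 2, 5, 5))
  got <- rm_anova_periods(m)
  # hand decomposition: grand mean 3.0667; period / subject / error SS
  grand <- mean(m)
  ss_per <- 3 * sum((colMeans(m) - grand)^2)
  ss_sub <- 5 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_per - ss_sub
  f_manual <- (ss_per / 4) / (ss_err / 8)
  expect_equal(got$F, f_manual)
  df <- data.frame(y = as.vector(m), subject = factor(rep(1:3, 5)),
                   period = factor(rep(1:5, each = 3)))
  s <- summary(stats::aov(y ~ period + Error(subject / period), data = df))
  expect_equal(got$F, s[["Error: subject:period"]][[1]]["period", "F value"])
})

test_that("RM-ANOVA degenerate cases: no period effect and missing subjects", {
  # all periods identical per subject -> F = 0
  m <- matrix(rep(c(1, 5, 3), 5), 3, 5)
  expect_equal(rm_anova_periods(m)$F, 0)
  # subjects with missing periods are dropped (complete-case)
  m2 <- rbind(m + rnorm(15), c(NA, 1, 2, 3, 4))
  expect_equal(rm_anova_periods(m2)$n_subjects, 3)
})

test_that("Bonferroni follow-ups use alpha/m and respect the gate", {
  expect_equal(followup_bonferroni(matrix(rnorm(15), 3), alpha = 0.05,
                                   m = 4)$alpha_corrected,
               rep(0.0125, 4))
  # periods identical to P1 -> no flags
  m <- matrix(rep(rnorm(10), 5), 10, 5)
  fu <- followup_bonferroni(m, m = 4)
  expect_true(all(!fu$significant))
  # a shift planted only in P5 flags only P5 (with high probability)
  set.seed(53)
  hits <- t(vapply(1:100, function(i) {
    m <- matrix(rnorm(18 * 5, 0, 0.3), 18, 5)
    m[, 5] <- m[, 5] + 1
    followup_bonferroni(m, m = 4)$significant
  }, logical(4)))
  expect_gt(mean(hits[, 4]), 0.95)       # P5 flagged
  expect_lt(mean(hits[, 1:3]), 0.05)     # others at most at the corrected level
  # a closed gate suppresses every flag
  m[, 5] <- m[, 5] + 10
  expect_true(all(!followup_bonferroni(m, gate = FALSE)$significant))
})

test_that("bins_to_periods pools bin pairs per subject", {
  m <- matrix(1:20, 2, 10, byrow = TRUE)
  p <- bins_to_periods(m)
  expect_equal(dim(p), c(2, 5))
  expect_equal(p[1, ], c(P1 = 1.5, P2 = 3.5, P3 = 5.5, P4 = 7.5, P5 = 9.5))
  expect_error(bins_to_periods(m[, 1:9]), "even")
})

test_that("ANOVA power: a planted monotone period effect is detected", {
  set.seed(54)
  rej <- vapply(1:100, function(i) {
    m <- matrix(rnorm(18 * 5, mean = rep(seq(1, 1.4, by = 0.1), each = 18),
                      sd = 0.2), 18, 5)
    rm_anova_periods(m)$significant
  }, logical(1))
  expect_gt(mean(rej), 0.95)
})
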