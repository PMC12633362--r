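test_that("paired-site join is an inner join with coverage and zero filters", {
  a <- make_site_table(n_mod = c(12L, 0L, 30L, 30L), n_canon = c(48L, 60L, 30L, 5L),
                       pos0 = c(10L, 20L, 30L, 40L), sample = "a")
  b <- make_site_table(n_mod = c(21L, 0L, 28L), n_canon = c(49L, 70L, 42L),
                       pos0 = c(10L, 20L, 50L), sample = "b")
  pairs <- joinPairedSites(a, b, min_valid_cov = 50)
  # pos 30 and 50 are in one table only; pos 20 is (0, 0); pos 40 under-covered
  expect_equal(pairs$pos0, 10L)
  expect_equal(pairs$delta, 21 / 70 - 12 / 60)
  expect_equal(pairs$log2fc, log2((21 / 70) / (12 / 60)))

  kept0 <- joinPairedSites(a, b, min_valid_cov = 50, drop_zero_both = FALSE)
  expect_equal(kept0$pos0, c(10L, 20L))

  flipped <- joinPairedSites(a, b, min_valid_cov = 50, delta_sign = "A-B")
  expect_equal(flipped$delta, -pairs$delta)

  mismatched <- make_site_table(1L, 1L, tau = 0.95)
  expect_error(joinPairedSites(a, mismatched), "tau")
})

test_that("concordance fit matches cor.test and lm on the same pairs", {
  pairs <- data.frame(f_a = c(0, 1, 2), f_b = c(0, 2, 4))
  fit <- fitConcordance(pairs)
  expect_equal(fit@r, 1)
  expect_equal(fit@slope, 2)
  expect_equal(fit@intercept, 0)

  same <- data.frame(f_a = runif(20), f_b = NA)
  same$f_b <- same$f_a
  fit2 <- fitConcordance(same)
  expect_equal(fit2@r, 1)
  expect_equal(fit2@slope, 1)
  expect_equal(fit2@intercept, 0)

  # closed forms against the stock implementations
  set.seed(101)
  x <- runif(40); y <- 0.8 * x + rnorm(40, sd = 0.1)
  fit3 <- fitConcordance(data.frame(f_a = x, f_b = y))
  ct <- cor.test(x, y)
  lf <- lm(y ~ x)
  expect_equal(fit3@r, unname(ct$estimate))
  expect_equal(fit3@pValue, ct$p.value)
  expect_equal(fit3@slope, unname(coef(lf)[2]))
  expect_equal(fit3@intercept, unname(coef(lf)[1]))

  expect_warning(fitConcordance(data.frame(f_a = c(1, 1, 1),
                                           f_b = c(1, 2, 3))),
                 "constant")
})

test_that("independent pairs show no spurious correlation", {
  set.seed(202)
  pairs <- data.frame(f_a = runif(10000), f_b = runif(10000))
  expect_lt(abs(fitConcordance(pairs)@r), 0.05)
})

test_that("Bland-Altman limits follow mean +/- 1.96 sample SD", {
  ba <- blandAltman(c(-0.1, 0.1))
  expect_equal(ba@meanDiff, 0)
  expect_equal(ba@sdDiff, sqrt(0.02))            # n - 1 denominator
  expect_equal(ba@loaHigh, 0.277186, tolerance = 1e-6)
  expect_equal(ba@loaLow, -0.277186, tolerance = 1e-6)

  zeros <- blandAltman(rep(0, 5))
  expect_equal(zeros@meanDiff, 0)
  expect_equal(c(zeros@loaLow, zeros@loaHigh), c(0, 0))
  expect_equal(zeros@pctWithin, 1)

  expect_error(blandAltman(0.3), "at least 2")

  # reported pct_within equals the directly counted fraction, and the
  # limits bracket the mean, for arbitrary difference sets
  set.seed(9)
  for (i in 1:5) {
    d <- rnorm(200, sd = runif(1, 0.01, 0.2))
    ba <- blandAltman(d)
    expect_true(ba@loaLow <= ba@meanDiff && ba@meanDiff <= ba@loaHigh)
    expect_equal(ba@pctWithin, mean(d >= ba@loaLow & d <= ba@loaHigh))
  }
})

test_that("normal differences land about 95% inside the limits", {
  set.seed(303)
  ba <- blandAltman(rnorm(100000, sd = 0.03))
  expect_gte(ba@pctWithin, 0.94)
  expect_lte(ba@pctWithin, 0.96)
})

test_that("threshold sweep loses sites and tightens limits as T grows", {
  truth <- simulateSiteTruth(800, seed = 21)
  a <- pileupCalls(simulateNanoporeCalls(truth = truth, cov_mean = 80,
                                         seed = 1)$calls, sample = "a")
  b <- pileupCalls(simulateNanoporeCalls(truth = truth, cov_mean = 80,
                                         seed = 2)$calls, sample = "b")
  sweep <- sweepCoverageThresholds(a, b, grid = c(0, 25, 50, 100))
  expect_equal(names(sweep),
               c("T", "n_sites", "r", "R2", "mean_diff", "loa_low", "loa_high"))
  expect_true(all(diff(sweep$n_sites) <= 0))
  expect_equal(sweep$R2, sweep$r^2)

  # two identical tables agree perfectly at every threshold
  self <- sweepCoverageThresholds(a, a, grid = c(0, 50, 100))
  expect_equal(self$R2, rep(1, 3), tolerance = 1e-12)
  expect_equal(self$loa_low, rep(0, 3))
  expect_equal(self$loa_high, rep(0, 3))

  expect_error(sweepCoverageThresholds(a, b, grid = integer()), "grid")
  expect_warning(
    starved <- sweepCoverageThresholds(a, b, grid = c(0, 10000)),
    "< 3")
  expect_true(is.na(starved$R2[2]))
})

test_that("sweep limits match binomial theory at constant truth and coverage", {
  # constant f, fixed coverage n: LoA half-width ~ 1.96 * sqrt(2 f (1-f) / n)
  f <- 0.3; n <- 100
  a <- binomial_site_table(rep(f, 4000), n, seed = 31)
  b <- binomial_site_table(rep(f, 4000), n, seed = 32)
  sweep <- sweepCoverageThresholds(a, b, grid = c(0, 50))
  hw <- (sweep$loa_high - sweep$loa_low) / 2
  expected <- 1.96 * sqrt(2 * f * (1 - f) / n)
  expect_true(all(abs(hw / expected - 1) < 0.10))
})

test_that("threshold suggestion flags the first near-asymptotic half-width", {
  sweep <- data.frame(T = c(0, 25, 50, 100),
                      loa_low = -c(0.30, 0.108, 0.105, 0.10),
                      loa_high = c(0.30, 0.108, 0.105, 0.10))
  expect_equal(suggestCoverageThreshold(sweep), 25)  # 0.108 <= 1.1 * 0.10
  sweep$loa_high[2] <- 0.2; sweep$loa_low[2] <- -0.2
  expect_equal(suggestCoverageThreshold(sweep), 50)
})

test_that("difference distributions give monotone [0, 1] ECDFs", {
  pairs <- data.frame(f_a = c(0.3, 0.2, 0.1, 0.2, 0),
                      f_b = c(0.2, 0.2, 0.2, 0.4, 0.4),
                      cov_a = 100L, cov_b = 100L)
  pairs$delta <- pairs$f_b - pairs$f_a
  pairs$log2fc <- ifelse(pairs$f_a > 0 & pairs$f_b > 0,
                         log2(pairs$f_b / pairs$f_a), NA_real_)
  ds <- deltaDistribution(pairs)
  expect_equal(ds$delta_ecdf(0), 2 / 5)
  expect_equal(ds$n_dropped_nonfinite, 1L)        # the (0, 0.4) pair
  expect_true(1 %in% ds$log2fc)                   # (0.2, 0.4) -> log2fc 1
  # ECDF is a non-decreasing step function from 0 to 1
  grid <- seq(-1.5, 1.5, by = 0.01)
  vals <- ds$delta_ecdf(grid)
  expect_true(all(diff(vals) >= 0))
  expect_equal(range(vals), c(0, 1))

  withps <- deltaDistribution(pairs, pseudocount = 0.01)
  expect_equal(withps$n_dropped_nonfinite, 0L)
  allzero <- pairs; allzero$log2fc <- NA_real_
  expect_warning(ds0 <- deltaDistribution(allzero), "no finite")
  expect_null(ds0$log2fc_ecdf)
})
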