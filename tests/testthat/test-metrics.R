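test_that("ICC(2,1) reproduces canonical agreement patterns", {
  perf <- icc_two_way_single(c(28, 31, 33, 36, 40), c(28, 31, 33, 36, 40))
  expect_equal(perf$icc, 1)
  expect_equal(perf$n, 5L)
  rev <- icc_two_way_single(1:5, 5:1)
  expect_lt(rev$icc, 0)
})

test_that("ICC matches a longhand ANOVA variance-components oracle", {
  for (seed in c(7, 21, 99)) {
    set.seed(seed)
    n <- 20
    subj <- stats::rnorm(n, 30, 4)
    ref <- subj + stats::rnorm(n, 0, 1.2)
    auto <- subj + stats::rnorm(n, 0, 1.2)
    res <- icc_two_way_single(auto, ref)
    expect_equal(res$icc, aov_icc_oracle(auto, ref), tolerance = 1e-10)
    expect_lte(res$ci_low, res$icc)
    expect_gte(res$ci_high, res$icc)
    expect_equal(res$n, n)
  }
})

test_that("ICC is symmetric and invariant to common shift and scale", {
  set.seed(5)
  a <- stats::rnorm(15, 30, 5); b <- a + stats::rnorm(15)
  expect_equal(icc_two_way_single(a, b)$icc, icc_two_way_single(b, a)$icc,
               tolerance = 1e-12)
  expect_equal(icc_two_way_single(a + 7, b + 7)$icc,
               icc_two_way_single(a, b)$icc, tolerance = 1e-12)
  expect_equal(icc_two_way_single(3 * a, 3 * b)$icc,
               icc_two_way_single(a, b)$icc, tolerance = 1e-12)
})

test_that("ICC simulation recovers the true reliability", {
  set.seed(1234)
  sigma_s <- 4; sigma_e <- 2
  true_icc <- sigma_s^2 / (sigma_s^2 + sigma_e^2)
  est <- replicate(400, {
    s <- stats::rnorm(50, 30, sigma_s)
    icc_two_way_single(s + stats::rnorm(50, 0, sigma_e),
                       s + stats::rnorm(50, 0, sigma_e))$icc
  })
  expect_lt(abs(mean(est) - true_icc), 0.02)
})

test_that("degenerate ICC inputs are rejected", {
  expect_error(icc_two_way_single(1, 1), class = "aortrack_degenerate_input")
  expect_error(icc_two_way_single(rep(3, 6), rep(3, 6)),
               class = "aortrack_degenerate_input")
  # pairwise deletion of missing reference measures
  res <- icc_two_way_single(c(1, 2, 3, 4, NA), c(1.1, 2, 2.9, 4.2, 5))
  expect_equal(res$n, 4L)
})

test_that("agreement_table yields one row per site with per-site N", {
  set.seed(8)
  s1 <- stats::rnorm(12, 30, 4); s2 <- stats::rnorm(9, 25, 3)
  df <- data.frame(
    site = c(rep("SOV", 12), rep("DA", 9)),
    auto_mm = c(s1 + stats::rnorm(12, 0, 0.5), s2 + stats::rnorm(9, 0, 0.5)),
    ref_mm = c(s1 + stats::rnorm(12, 0, 0.5), s2 + stats::rnorm(9, 0, 0.5)))
  tab <- agreement_table(df)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$n, c(12, 9))
  expect_true(all(tab$icc > 0.8))

  one <- agreement_table(data.frame(site = "AA", auto_mm = c(30, 32, 35),
                                    ref_mm = c(30, 32, 35)))
  expect_equal(one$icc, 1)

  # degenerate sites become NA rows with a reason, not hard failures
  bad <- rbind(df, data.frame(site = "STJ", auto_mm = 30, ref_mm = 31))
  tab2 <- agreement_table(bad)
  expect_true(is.na(tab2$icc[tab2$site == "STJ"]))
  expect_false(is.na(tab2$reason[tab2$site == "STJ"]))
  expect_error(agreement_table(list()), class = "aortrack_degenerate_input")
})

test_that("spike filter flags isolated diameter spikes only", {
  clean <- synthetic_trace(rep(20, 60) + sin(seq_len(60) / 9))
  expect_false(any(spike_filter(clean)))

  d <- rep(20, 60)
  spikes <- c(12, 30, 47)
  d[spikes] <- 40
  flagged <- which(spike_filter(synthetic_trace(d)))
  expect_equal(flagged, spikes)

  short <- synthetic_trace(c(10, 40, 10, 10, 10))
  expect_false(any(spike_filter(short)))  # shorter than the window
})

test_that("peak diameter ignores spikes and resolves ties to the first step", {
  # aneurysm-like Gaussian bulge on a 20 mm tube, peak 34 mm at s = 60
  s <- 0:119
  d <- 20 + 14 * exp(-((s - 60)^2) / (2 * 36))
  pk <- peak_diameter(synthetic_trace(d))
  expect_equal(pk$step, 61)  # s = 60 at 1 mm steps, 1-based
  expect_equal(pk$diameter_mm, 34, tolerance = 1e-6)

  # spikes above the bulge are excluded from the peak
  d2 <- d; d2[10] <- 50
  pk2 <- peak_diameter(synthetic_trace(d2))
  expect_equal(pk2$step, 61)

  flat <- peak_diameter(synthetic_trace(rep(22, 40)))
  expect_equal(flat$step, 1)  # tie -> first occurrence

  single <- peak_diameter(synthetic_trace(25))
  expect_equal(single$diameter_mm, 25)
  expect_error(peak_diameter(synthetic_trace(numeric(0))),
               class = "aortrack_empty_trace")
})
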