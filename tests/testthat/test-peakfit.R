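test_that("eligibility needs three nonzero fractions with two adjacent", {
  y <- numeric(24)
  y[c(3, 4, 9)] <- 1
  expect_true(eligible_for_fitting(y))
  y <- numeric(24); y[c(2, 5, 9)] <- 1
  expect_false(eligible_for_fitting(y))     # no adjacent pair
  y <- numeric(24); y[c(3, 4)] <- 1
  expect_false(eligible_for_fitting(y))     # only two fractions
})

test_that("a noiseless single Gaussian is recovered", {
  y <- gauss_profile(10, 1.5, 100)
  fit <- fit_elution_peaks(y)
  expect_s3_class(fit, "peakfit")
  expect_equal(fit$method, "gaussian")
  expect_equal(fit$n_peaks, 1L)
  expect_lt(abs(fit$peaks$center - 10), 0.05)
  expect_lt(abs(fit$peaks$sigma - 1.5), 0.05)
  expect_lt(abs(fit$peaks$amplitude - 100), 1)
})

test_that("two well-separated Gaussians are both recovered", {
  y <- gauss_profile(c(6, 14), c(1.5, 1.5), c(100, 50))
  fit <- fit_elution_peaks(y)
  expect_equal(fit$n_peaks, 2L)
  ctr <- sort(fit$peaks$center)
  expect_lt(abs(ctr[1] - 6), 0.1)
  expect_lt(abs(ctr[2] - 14), 0.1)
  # peaks sorted by decreasing amplitude, relative heights in (0, 1]
  expect_true(all(diff(fit$peaks$amplitude) <= 0))
  expect_equal(fit$peaks$relative_height[1], 1)
})

test_that("peaks closer than the separation rule collapse to one", {
  y <- gauss_profile(c(6, 8), c(1.2, 1.2), c(100, 80))
  fit <- fit_elution_peaks(y, min_separation = 4)
  expect_equal(fit$n_peaks, 1L)
})

test_that("secondary peaks below 20% relative height are pruned", {
  y <- gauss_profile(c(6, 14), c(1.5, 1.5), c(100, 10))
  fit <- fit_elution_peaks(y)
  expect_equal(fit$n_peaks, 1L)
  expect_lt(abs(fit$peaks$center - 6), 0.1)
})

test_that("retained peaks always satisfy both acceptance rules", {
  set.seed(42)
  for (case in 1:25) {
    k <- sample(1:3, 1)
    ctr <- sort(runif(k, 4, 21))
    y <- gauss_profile(ctr, runif(k, 1, 2.5), 100 * runif(k, 0.1, 1))
    y <- y * exp(rnorm(24, 0, 0.2))
    fit <- fit_elution_peaks(y)
    if (fit$method != "gaussian") next
    if (fit$n_peaks > 1) {
      expect_gte(min(dist(fit$peaks$center)), 4)
      expect_true(all(fit$peaks$relative_height >= 0.2))
    }
    expect_true(all(fit$peaks$amplitude > 0))
    expect_true(all(fit$peaks$sigma >= 0.5 & fit$peaks$sigma <= 5))
  }
})

test_that("single-peak fits match a dense grid-search oracle", {
  y <- gauss_profile(9.3, 1.8, 55)
  fit <- fit_elution_peaks(y)
  # oracle: exhaustive grid over (center, sigma), closed-form amplitude
  f <- 1:24
  best <- c(rss = Inf, mu = NA, s = NA, A = NA)
  for (mu in seq(8, 11, by = 0.005)) for (s in seq(1.2, 2.4, by = 0.005)) {
    g <- exp(-(f - mu)^2 / (2 * s^2))
    A <- sum(g * y) / sum(g * g)
    rss <- sum((y - A * g)^2)
    if (rss < best["rss"]) best <- c(rss = rss, mu = mu, s = s, A = A)
  }
  expect_lt(abs(fit$peaks$center - best[["mu"]]), 1e-3)
  expect_lt(abs(fit$peaks$sigma - best[["s"]]), 1e-3)
  expect_lt(abs(fit$peaks$amplitude - best[["A"]]) / best[["A"]], 1e-3)
})

test_that("BIC penalizes extra peaks and guards rss = 0", {
  expect_lt(bic_score(24, 10, 1), bic_score(24, 10, 2))
  expect_equal(bic_score(24, 24, 1), 3 * log(24))
  expect_true(is.finite(bic_score(24, 0, 1)))
  expect_error(bic_score(24, -1, 1), "nonnegative")
  expect_error(bic_score(6, 1, 2), "more data points")
})

test_that("global max fallback takes the earliest arg-max fraction", {
  y <- numeric(24); y[7:9] <- c(2, 8, 3)
  gm <- global_max_peak(y)
  expect_equal(gm$method, "global_max")
  expect_equal(gm$peaks$center, 8)
  expect_false(attr(gm$peaks, "tie"))

  y[9] <- 8   # tie between fractions 8 and 9 -> earlier wins, tie recorded
  gm <- global_max_peak(y)
  expect_equal(gm$peaks$center, 8)
  expect_true(attr(gm$peaks, "tie"))

  z <- fit_elution_peaks(numeric(24))
  expect_equal(z$method, "ineligible")
  expect_equal(z$n_peaks, 0L)
})

test_that("void peaks are fitted but flagged unresolved", {
  y <- gauss_profile(c(2, 14), c(1, 1.5), c(100, 60))
  fit <- fit_elution_peaks(y, void_fraction = 2)
  expect_equal(fit$n_peaks, 2L)
  res <- fit$peaks$resolved[order(fit$peaks$center)]
  expect_identical(res, c(FALSE, TRUE))
})

test_that("peakfit methods are coherent", {
  y <- gauss_profile(10, 1.5, 100)
  fit <- fit_elution_peaks(y)
  expect_equal(dim(coef(fit)), c(1L, 3L))
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_lt(max(abs(residuals(fit))), 1e-3)
  expect_equal(predict(fit, fit$peaks$center), fit$peaks$amplitude,
               tolerance = 1e-6)
  expect_output(print(fit), "gaussian")
})
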