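test_that("kernel spike density has the right peak, mass and locality", {
  grid <- seq(-0.05, 0.05, by = 1e-4)
  k <- compute_ksd(0, sigma = 0.002, grid = grid)
  expect_equal(max(k), 1 / (0.002 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(grid[which.max(k)], 0)
  ## integrates to the spike count
  g2 <- seq(-0.5, 1.5, by = 1e-4)
  k2 <- compute_ksd(c(0.2, 0.5, 0.9), 0.002, g2)
  expect_equal(sum(k2) * 1e-4, 3, tolerance = 1e-6)
  ## two spikes 10 sigma apart: equal, non-interacting peaks
  k3 <- compute_ksd(c(0, 0.02), 0.002, grid)
  i0 <- which.min(abs(grid)); i2 <- which.min(abs(grid - 0.02))
  expect_equal(k3[i0], k3[i2], tolerance = 1e-9)
  expect_equal(k3[i0], max(k), tolerance = 1e-3)
  expect_equal(compute_ksd(numeric(0), 0.002, grid), numeric(length(grid)))
})

test_that("CF and MT are recovered from a planted V-shaped tuning curve", {
  unit <- simulate_fra_unit(cf = 16000, mt = 15, evoked_rate = 80,
                            spont_rate = 1, seed = 6)
  res <- extract_cf_mt(unit, fra_grid(), alpha = 0.05, n_perm = 100,
                       seed = 2)
  expect_equal(res$cf, 16000)
  expect_equal(res$mt, 15)
  expect_false(res$flagged)
  ## trial-order invariance (same permutation seed, reordered repetitions)
  ord <- sample(length(unit$spikes))
  shuf <- list(trials = unit$trials[ord, ], spikes = unit$spikes[ord])
  res2 <- extract_cf_mt(shuf, fra_grid(), alpha = 0.05, n_perm = 100,
                        seed = 2)
  expect_equal(res2$cf, res$cf)
  expect_equal(res2$mt, res$mt)
  ## a stricter criterion can only raise the threshold
  res01 <- extract_cf_mt(unit, fra_grid(), alpha = 0.01, n_perm = 100,
                         seed = 2)
  expect_gte(res01$mt, res$mt)
  ## all-silent unit is flagged, not an error
  silent <- unit
  silent$spikes <- lapply(silent$spikes, function(x) numeric(0))
  res0 <- extract_cf_mt(silent, fra_grid(), n_perm = 10)
  expect_true(res0$flagged)
  expect_true(is.na(res0$cf))
})

test_that("family-wise false-positive rate of the tuning test is controlled", {
  g <- fra_grid(freq_low = 2000, freq_high = 32000, freq_step = 0.5,
                level_min = 0, level_max = 60, level_step = 10,
                repetitions = 6)
  hits <- vapply(1:100, function(i) {
    unit <- simulate_fra_unit(grid = g, cf = 8000, mt = 100,  # never responds
                              spont_rate = 5, seed = 1000 + i)
    res <- extract_cf_mt(unit, g, alpha = 0.05, n_perm = 99, seed = i)
    !is.na(res$mt)
  }, logical(1))
  fpr <- mean(hits)
  expect_lte(fpr, 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("the threshold-shift parabola is fitted exactly by least squares", {
  ## points synthesized from a known polynomial are recovered to 1e-6
  cf <- 2 * 2^(seq(0, 5, length.out = 12))        # kHz
  truth <- c(a = -55.66, b = 124.48, c = -44.21)
  dmt <- truth["a"] * log10(cf)^2 + truth["b"] * log10(cf) + truth["c"]
  fit <- fit_mt_parabola(dmt, cf)
  expect_equal(unname(fit$coefficients), unname(truth), tolerance = 1e-6)
  ## constant data: pure intercept
  fit2 <- fit_mt_parabola(c(20, 20, 20), c(4, 8, 16))
  expect_equal(unname(fit2$coefficients), c(0, 0, 20), tolerance = 1e-9)
  ## equals the closed-form normal-equations solution
  set.seed(9)
  y <- dmt + rnorm(length(dmt), 0, 3)
  X <- cbind(log10(cf)^2, log10(cf), 1)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit_mt_parabola(y, cf)$coefficients),
               as.vector(beta), tolerance = 1e-8)
  ## symmetric zero-mean noise leaves the coefficients unbiased
  est <- replicate(200, {
    fit_mt_parabola(dmt + rnorm(length(dmt), 0, 2), cf)$coefficients["a"]
  })
  expect_lt(abs(mean(est) - truth["a"]), 3 * stats::sd(est) / sqrt(200))
  expect_error(fit_mt_parabola(c(1, 2), c(4, 8)), "3 distinct")
})
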