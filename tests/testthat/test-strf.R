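test_that("signal/noise power estimators match hand computation and their identity", {
  pe <- signal_noise_power(rbind(c(0, 2), c(0, 4)))
  expect_identical(pe$signal_power, 2)
  expect_identical(pe$noise_power, 0.5)
  expect_identical(pe$mean_total_power, 2.5)
  ## identical reps: all power is signal
  reps <- matrix(rep(c(1, 3, 0, 2), 4), 4, byrow = TRUE)
  pe2 <- signal_noise_power(reps)
  expect_equal(pe2$noise_power, 0)
  ## exact identity on random instances
  set.seed(4)
  for (i in 1:100) {
    m <- matrix(rpois(5 * 40, 2), 5)
    p <- signal_noise_power(m)
    expect_equal(p$signal_power + p$noise_power, p$mean_total_power,
                 tolerance = 1e-12)
  }
  ## pure noise around a constant: signal power ~ 0 in expectation
  sig <- replicate(1000, signal_noise_power(
    matrix(rnorm(3 * 30, mean = 5), 3))$signal_power)
  expect_lt(abs(mean(sig)), 3 * stats::sd(sig) / sqrt(1000))
  expect_error(signal_noise_power(matrix(1, 1, 5)), "2 repetitions")
})

test_that("inclusion rule is signal >= 2 x noise", {
  mk <- function(s, n) structure(list(signal_power = s, noise_power = n),
                                 class = "power_estimates")
  expect_true(include_unit(mk(2, 0.5)))
  expect_true(include_unit(mk(1, 0.5)))
  expect_false(include_unit(mk(0.9, 0.5)))
})

test_that("ASD recovers a noiseless linear kernel and shrinks noise fits", {
  drc <- small_drc()
  s <- scale_intensity(drc$level_matrix, "amp")
  prf <- fixture_prf()
  y <- context_predict(s, prf, NULL, 0.2)
  fit <- fit_strf_asd(s, y, n_lags = 9)
  expect_gt(stats::cor(as.vector(fit$prf), as.vector(prf)), 0.999)
  expect_equal(fit$c, 0.2, tolerance = 0.05)
  ## white-noise response: posterior weights shrink below plain LS
  set.seed(2)
  yn <- rnorm(length(y))
  fitn <- fit_strf_asd(s, yn, n_lags = 9)
  X <- amcoder:::lagged_design(s, 9)
  wls <- qr.solve(cbind(1, X), yn)[-1]
  expect_lt(sqrt(sum(fitn$prf^2)), sqrt(sum(wls^2)))
})

test_that("ASD posterior collapses to ridge when the length scales vanish", {
  set.seed(8)
  Tn <- 80
  X <- matrix(rnorm(Tn * 10), Tn)            # 10 = 2 lags x 5 freqs
  w0 <- rnorm(10, sd = 0.5)
  y <- as.vector(X %*% w0) + rnorm(Tn, sd = 0.3)
  A <- crossprod(X); b <- crossprod(X, y); yy <- sum(y^2)
  rho2 <- 0.25; sig2 <- 0.09
  post <- amcoder:::asd_neg_evidence(
    c(log(rho2), log(1e-3), log(1e-3), log(sig2)),
    A, b, yy, Tn, n_lags = 2, K = 5, want_posterior = TRUE)
  ridge <- solve(A + diag(sig2 / rho2, 10), b)
  expect_equal(post$w, as.vector(ridge), tolerance = 1e-6)
})

test_that("the context model generalizes the simple model and ALS is monotone", {
  ## CGF = 0 reproduces the simple model's predictions exactly
  drc <- small_drc()
  s <- scale_intensity(drc$level_matrix, "amp")
  prf <- fixture_prf()
  expect_identical(context_predict(s, prf, matrix(0, 5, 13), 0.3),
                   context_predict(s, prf, NULL, 0.3))
  ## penalized ALS objective never increases across half-steps
  fx <- fixture_lnp_counts(with_cgf = TRUE)
  fit0 <- fit_strf_asd(drc, colMeans(fx$counts), scaling = "amp", n_lags = 9)
  ctx <- fit_context_model(drc, colMeans(fx$counts), scaling = "amp",
                           init = fit0, cgf_n_tau = 5, cgf_n_phi = 6,
                           max_iter = 15)
  expect_true(all(diff(ctx$objective) <= 1e-8 * ctx$objective[1]))
  ## the planted suppressive context is recovered with the right sign
  ctr <- 7
  expect_lt(ctx$cgf[1, ctr], 0)
  expect_lt(mean(ctx$cgf[1, (ctr - 2):(ctr + 2)]), 0)
  .fx$ctx_fit <- ctx                          # reused by later tests
})

test_that("a context-free unit shows no more CGF than its permutation null", {
  fx <- fixture_lnp_counts(with_cgf = FALSE)
  drc <- small_drc()
  y <- colMeans(fx$counts)
  fit0 <- fixture_asd_fit()
  ctx <- fit_context_model(drc, y, scaling = "amp", init = fit0,
                           cgf_n_tau = 5, cgf_n_phi = 6, max_iter = 12)
  pn <- cgf_permutation_null(drc, y, ctx, n_perm = 49, seed = 3)
  expect_lt(pn$observed, stats::quantile(pn$null, 0.95))
})

test_that("cross-validated predictive power has its exact reference points", {
  ## noise-free repetitions, prediction = the response itself: pp = 1
  y <- rpois(200, 3)
  psths <- rbind(y, y, y)
  pmu <- signal_noise_power(psths)$signal_power
  expect_equal(normalized_predictive_power(y, y, pmu), 1)
  ## constant prediction: pp = 0 (power is deviation about the mean)
  expect_equal(normalized_predictive_power(y, rep(mean(y), 200), pmu), 0)
  ## invariance to relabeling repetitions
  fx <- fixture_lnp_counts()
  p1 <- cv_predictive_power("simple", small_drc(), fx$counts,
                            scaling = "amp", folds = 5, reps = 1,
                            seed = 2, full_fit = fixture_asd_fit())
  p2 <- cv_predictive_power("simple", small_drc(),
                            fx$counts[sample(nrow(fx$counts)), ],
                            scaling = "amp", folds = 5, reps = 1,
                            seed = 2, full_fit = fixture_asd_fit())
  expect_identical(p1$predictive_power_norm, p2$predictive_power_norm)
  expect_gt(p1$predictive_power_norm, 0.3)
})

test_that("STRF metrics report BF, peak weight and cross-fits", {
  drc <- small_drc()
  s <- scale_intensity(drc$level_matrix, "amp")
  prf <- fixture_prf()
  fit <- fit_strf_asd(s, context_predict(s, prf, NULL, 0.2), n_lags = 9)
  m <- strf_metrics(fit, fit)
  expect_equal(m$correlation, 1)
  expect_equal(m$delta_bf_octaves, 0)
  ## planted BF at the Gabor peak (bin 9), within one 1/12-octave bin
  expect_lte(abs(m$bf_bin - 9), 1)
  expect_equal(m$max_weight, max(fit$prf))
  neg <- fit; neg$prf <- -fit$prf
  expect_equal(strf_metrics(fit, neg)$correlation, -1)
  allneg <- fit; allneg$prf <- -abs(fit$prf)
  expect_true(strf_metrics(allneg)$flagged)
  ## BF-aligned field centers the peak column
  expect_equal(which.max(apply(m$bf_aligned, 2, max)), fit$n_freq)
})
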