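test_that("vector strength matches hand-computed resultants", {
  expect_equal(vector_strength(rep(1.3, 7))$vs, 1)
  expect_equal(vector_strength(c(0, pi / 2, pi, 3 * pi / 2))$vs, 0,
               tolerance = 1e-12)
  v <- vector_strength(c(0, 0, pi / 2))
  expect_equal(v$vs, Mod(2 + 1i) / 3)
  expect_equal(v$mean_phase, atan2(1, 2))
  expect_error(vector_strength(numeric(0)))
})

test_that("phase-projected vector strength projects onto the global phase", {
  ## every trial locked at a common phase: VS_PP = 1
  sp <- lapply(1:5, function(i) seq(1.5, 2 - 1e-9, by = 1 / 16))
  expect_equal(vs_pp(sp, 16, c(1.5, 2))$mean, 1)
  ## an antiphase trial with VS = 1 contributes -1
  anti <- c(sp[1:3], list(seq(1.5, 2 - 1e-9, by = 1 / 16) + 1 / 32))
  v <- vs_pp(anti, 16, c(1.5, 2))
  expect_equal(v$per_trial[4], -1, tolerance = 1e-9)
  ## zero-spike trials contribute 0, empty input is flagged
  v0 <- vs_pp(c(sp[1:2], list(numeric(0))), 16, c(1.5, 2))
  expect_equal(v0$per_trial[3], 0)
  expect_true(vs_pp(list(numeric(0)), 16, c(0, 1))$flagged)
  ## Poisson null: mean VS_PP within 3 SE of 0
  set.seed(11)
  pois <- lapply(1:100, function(i) runif(rpois(1, 100), 1.5, 2))
  vp <- vs_pp(pois, 16, c(1.5, 2))$per_trial
  expect_lt(abs(mean(vp)), 3 * stats::sd(vp) / sqrt(length(vp)))
  ## bounds
  expect_true(all(vp >= -1 & vp <= 1))
})

test_that("ROC area equals the exhaustive pair-counting oracle", {
  sets <- value_multisets(4)
  for (sig in sets) for (nul in sets) {
    expect_equal(roc_auc(sig, nul), roc_auc_oracle(sig, nul))
  }
  ## complementarity with the half-tie convention, exactly
  set.seed(3)
  for (i in 1:50) {
    a <- sample(0:4, sample(1:8, 1), replace = TRUE)
    b <- sample(0:4, sample(1:8, 1), replace = TRUE)
    expect_identical(roc_auc(a, b) + roc_auc(b, a), 1)
  }
  expect_equal(roc_auc(c(1, 2, 3), c(2, 2)), 0.5)
  expect_equal(roc_auc(1:3, 1:3), 0.5)
  expect_equal(roc_auc(4:6, 1:3), 1)
  expect_error(roc_auc(numeric(0), 1))
})

test_that("d-prime conversion follows the equal-variance conventions", {
  expect_equal(dprime_from_auc(0.5), 0)
  expect_equal(dprime_from_auc(pnorm(1 / sqrt(2))), 1, tolerance = 1e-9)
  expect_equal(dprime_from_auc(pnorm(sqrt(2))), 2, tolerance = 1e-9)
  expect_equal(dprime_from_auc(pnorm(0.5), convention = "2"), 1,
               tolerance = 1e-9)
  ## symmetric in auc <-> 1 - auc
  for (a in c(0.1, 0.3, 0.45))
    expect_equal(dprime_from_auc(a), dprime_from_auc(1 - a))
  ## clipping keeps perfect separation finite
  expect_true(is.finite(dprime_from_auc(1, n_pairs = 100)))
  expect_error(dprime_from_auc(1.1))
})

test_that("threshold interpolation and its monotonicity properties hold", {
  expect_equal(modulation_threshold(c(-12.04, -6.02), c(0.5, 1.5)), -9.03)
  expect_true(is.na(modulation_threshold(c(-24, -12, -6), c(0.2, 0.5, 0.9))))
  expect_equal(as.numeric(modulation_threshold(c(-18.06, -12.04), c(1, 2))),
               -18.06)
  cens <- modulation_threshold(c(-12, -6), c(1.5, 2))
  expect_true(isTRUE(attr(cens, "censored")))
  expect_error(modulation_threshold(c(-6, -12), c(0.5, 1.5)), "increasing")
  ## scaling a curve up never raises the threshold (NA = +Inf); adding
  ## depths above an existing crossing leaves it unchanged
  set.seed(7)
  for (i in 1:1000) {
    db <- sort(runif(5, -30, 0))
    dp <- runif(5, 0, 2)
    k <- runif(1, 1, 3)
    t1 <- modulation_threshold(db, dp)
    t2 <- modulation_threshold(db, k * dp)
    expect_lte(ifelse(is.na(t2), Inf, t2), ifelse(is.na(t1), Inf, t1))
    if (!is.na(t1) && db[5] > t1 && dp[5] >= 1) {
      t3 <- modulation_threshold(c(db, db[5] + 3), c(dp, dp[5] + 0.5))
      expect_equal(as.numeric(t3), as.numeric(t1))
    }
  }
})

test_that("sensitivity curves separate lockers from non-lockers", {
  design <- data.frame(fmod = 16, depth = c(0, 0.06, 0.125, 0.25, 0.5, 1),
                       intensity = 60)
  ## non-locking, non-rate-coding unit: d' ~ 0, no threshold
  flat <- simulate_sam_unit(sam_unit_params(r_base = 25, gain_slope = 0,
                                            lock_strength = 0),
                            design, n_trials = 20, seed = 5)
  for (coding in c("temporal", "rate")) {
    sc <- sensitivity_curve(flat, coding)
    expect_true(all(sc$dprime < 0.8))
    expect_true(is.na(sc$threshold_db))
  }
  ## strong locker: d' grows with depth, threshold defined
  strong <- simulate_sam_unit(sam_unit_params(r_base = 30,
                                              lock_strength = 4),
                              design, n_trials = 20, seed = 5)
  sct <- sensitivity_curve(strong, "temporal")
  expect_false(is.na(sct$threshold_db))
  expect_gt(stats::cor(sct$depths_db, sct$dprime, method = "spearman"), 0.5)
  expect_error(sensitivity_curve(
    list(trials = design[design$depth > 0, ],
         spikes = vector("list", 5)), "temporal"), "depth-0")
  ## doubling the lock strength lowers the temporal threshold
  lows <- highs <- numeric(5)
  for (i in 1:5) {
    a <- simulate_sam_unit(sam_unit_params(lock_strength = 1.5),
                           design, n_trials = 20, seed = 100 + i)
    b <- simulate_sam_unit(sam_unit_params(lock_strength = 3),
                           design, n_trials = 20, seed = 100 + i)
    lows[i] <- as.numeric(sensitivity_curve(a, "temporal")$threshold_db)
    highs[i] <- as.numeric(sensitivity_curve(b, "temporal")$threshold_db)
  }
  lows[is.na(lows)] <- Inf
  expect_true(mean(highs < lows) >= 0.8)
})

test_that("sensitivity tables export tidily", {
  design <- data.frame(fmod = 16, depth = c(0, 0.5, 1), intensity = 60)
  tr <- simulate_sam_unit(sam_unit_params(), design, n_trials = 8, seed = 1)
  sc <- sensitivity_curve(tr, "rate")
  tab <- sensitivity_table(list(u1 = sc))
  expect_named(tab, c("unit", "condition", "fmod", "intensity", "coding",
                      "depth_db", "dprime", "threshold_db"))
  expect_equal(nrow(tab), 2)
})
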