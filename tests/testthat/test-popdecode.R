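test_that("the AM-encoding component reflects population symmetry", {
  pop <- fixture_population(seed = 3, n_units = 2, n_trials = 6)
  ## duplicate one unit: equal weights up to sign
  pop$units[[2]] <- pop$units[[1]]
  pa <- population_activity(pop)
  comp <- am_encoding_component(pa)
  expect_equal(abs(as.numeric(comp)), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  ## one unit carries all the AM information: the component concentrates
  silent <- pop
  silent$units[[2]]$spikes <- lapply(silent$units[[2]]$spikes,
                                     function(x) numeric(0))
  pa2 <- population_activity(silent)
  comp2 <- am_encoding_component(pa2)
  expect_gt(abs(comp2[1]), 0.99)
  ## all-silent population: component flagged unreliable
  mute <- pop
  for (u in 1:2) mute$units[[u]]$spikes <-
      lapply(mute$units[[u]]$spikes, function(x) numeric(0))
  pa3 <- population_activity(mute)
  expect_true(attr(am_encoding_component(pa3), "unreliable"))
  expect_error(am_encoding_component(
    structure(list(ksd = array(0, c(1, 2, 3))), class = "population_activity")),
    "2 units")
})

test_that("trial projections are linear in unit rates", {
  pop <- fixture_population(seed = 5, n_units = 3, n_trials = 4)
  pa <- population_activity(pop)
  comp <- am_encoding_component(pa)
  proj <- project_trials(pa, comp)
  ## homogeneity: doubling all rates doubles the projection exactly
  pa2 <- pa; pa2$ksd <- 2 * pa$ksd
  expect_identical(project_trials(pa2, comp), 2 * proj)
  ## additivity across units
  manual <- comp[1] * pa$ksd[1, , ] + comp[2] * pa$ksd[2, , ] +
    comp[3] * pa$ksd[3, , ]
  expect_equal(proj, manual, tolerance = 1e-12)
  expect_error(project_trials(pa, comp[1:2]), "unit set")
})

test_that("threshold-crossing latencies follow the projection geometry", {
  times <- seq_len(400) / 200
  step <- ifelse(times >= 1.05, 2, 0)
  expect_equal(simulate_response_latency(step, times, 1, 0.15, 1),
               0.05 + 0.15)
  ## level below the pre-transition baseline: immediate crossing
  base <- rep(2, length(times))
  expect_equal(simulate_response_latency(base, times, 1, 0.12, 1),
               times[times >= 1][1] - 1 + 0.12)
  ## level above the maximum: no response
  expect_true(is.na(simulate_response_latency(step, times, 5, 0.15, 1)))
  ## lowering the detection level never lengthens the latency
  set.seed(6)
  for (i in 1:50) {
    proj <- cumsum(rnorm(length(times), 0.01))
    l_hi <- simulate_response_latency(proj, times, 1.0, 0.15, 1)
    l_lo <- simulate_response_latency(proj, times, 0.5, 0.15, 1)
    expect_lte(ifelse(is.na(l_lo), Inf, l_lo),
               ifelse(is.na(l_hi), Inf, l_hi))
  }
})

test_that("CDF-RMS goodness is a faithful distance on latency groups", {
  grid <- seq(0, 1, by = 0.01)
  a <- c(0.2, 0.35, 0.5, NA)
  b <- c(0.5, 0.2, NA, 0.35)              # same multiset
  expect_equal(amcoder:::latency_cdf(a, grid), amcoder:::latency_cdf(b, grid))
  d <- sqrt(mean((amcoder:::latency_cdf(a, grid) -
                    amcoder:::latency_cdf(c(0.2, 0.4, 0.5, NA), grid))^2))
  expect_gt(d, 0)
})

test_that("decoder parameters are recovered from self-generated latencies", {
  pop <- fixture_population(seed = 9, n_units = 6, n_trials = 10)
  pa <- population_activity(pop)
  comp <- am_encoding_component(pa)
  proj <- project_trials(pa, comp)
  tt <- pa$trials$transition[1]
  base <- stats::median(apply(proj[, pa$times < tt], 1, max))
  peak <- stats::median(apply(proj[pa$trials$depth == 1, pa$times >= tt],
                              1, max))
  true_dl <- base + 0.5 * (peak - base); true_ndt <- 0.150
  behav <- amcoder:::decoder_latencies(proj, pa$times, true_dl, true_ndt, tt)
  groups <- split(behav, as.character(pa$trials$depth))
  dls <- true_dl * c(0.5, 0.75, 1, 1.5, 2)
  fit <- fit_decoder_params(pa, comp, groups,
                            detection_levels = dls,
                            non_decision_times = c(0.1, 0.15, 0.2))
  expect_equal(fit$best$detection_level, true_dl)
  expect_equal(fit$best$non_decision_time, true_ndt)
  expect_equal(fit$best$rms, 0)
})

test_that("decoder sensitivity degenerates gracefully and responds to gain", {
  ## detection level above every projection: d' ~ 0, no threshold
  lat <- list("0.25" = rep(NA_real_, 20), "1" = rep(NA_real_, 20))
  ds <- decoder_sensitivity(lat, rep(NA_real_, 20))
  expect_true(all(ds$dprime < 0.1))
  expect_true(is.na(ds$threshold_db))
})
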