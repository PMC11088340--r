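test_that("AM start phase matches its closed forms and the power-continuity property", {
  expect_identical(am_phase_offset(0), 0)
  expect_equal(am_phase_offset(1), asin(sqrt(1.5) - 1))
  expect_equal(am_phase_offset(1), 0.22668, tolerance = 1e-4)
  expect_equal(am_phase_offset(0.5), asin(sqrt(1 + 0.125) - 1))
  expect_equal(am_phase_offset(0.5), 0.06070, tolerance = 1e-4)
  expect_equal(am_phase_offset(0.5, "power"),
               asin((sqrt(1 + 0.125) - 1) / 0.5))
  expect_equal(am_phase_offset(0.5, "power"), 0.1216, tolerance = 1e-3)
  expect_error(am_phase_offset(1.2), "0, 1")
  ## only the power variant makes the squared envelope at the transition
  ## equal the AM-segment mean power 1 + m^2/2
  for (m in c(0.25, 0.5, 1))
    expect_equal((1 + m * sin(am_phase_offset(m, "power")))^2, 1 + m^2 / 2,
                 tolerance = 1e-10)
  ## the printed variant misses power continuity wherever it differs (m < 1)
  for (m in c(0.25, 0.5))
    expect_gt(abs((1 + m * sin(am_phase_offset(m)))^2 - (1 + m^2 / 2)), 1e-3)
})

test_that("SAM trials have the expected envelope, power ratio and grid size", {
  p <- sam_params(fmod = 16, m = 1, seed = 3)
  tr <- synthesize_sam_trial(p)
  expect_length(tr$waveform, round((p$um_duration + p$am_duration) *
                                     p$sample_rate))
  ## 16 Hz for 1 s -> exactly 16 modulation cycles in the envelope
  env_am <- tr$envelope[tr$times >= tr$transition_time]
  zero_up <- sum(diff(env_am > 1) == 1)
  expect_equal(zero_up, 16, tolerance = 1)
  ## AM-segment power ~ (1 + m^2/2) x unit carrier power
  am <- tr$waveform[tr$times >= tr$transition_time + 0.05]
  expect_equal(mean(am^2), 1.5, tolerance = 0.05)
  ## m = 0: envelope constant, AM and UM statistically identical
  tr0 <- synthesize_sam_trial(sam_params(fmod = 16, m = 0, seed = 3))
  expect_true(all(tr0$envelope == 1))
  v_um <- mean(tr0$waveform[tr0$times < 1]^2)
  v_am <- mean(tr0$waveform[tr0$times >= 1]^2)
  expect_equal(v_um / v_am, 1, tolerance = 0.05)
  ## full default stimulus grid
  expect_equal(nrow(sam_design()), 48)
})

test_that("matched UM noise preserves the magnitude spectrum but kills the envelope", {
  p <- sam_params(fmod = 16, m = 1, am_duration = 0.5, seed = 5)
  tr <- synthesize_sam_trial(p)
  x <- tr$waveform[tr$times >= tr$transition_time]
  um <- make_matched_um(x, seed = 9)
  mx <- Mod(stats::fft(x)); mu <- Mod(stats::fft(um))
  expect_lt(max(abs(mx - mu)) / max(mx), 1e-9)
  expect_equal(sum(um^2), sum(x^2), tolerance = 1e-9)
  ## Hilbert-envelope spectrum: the fmod component must drop by > 10x
  env_spec_at <- function(w, f, fs) {
    n <- length(w)
    spec <- stats::fft(w)
    spec[(floor(n / 2) + 2):n] <- 0          # analytic signal
    spec[2:(floor(n / 2) + 1)] <- 2 * spec[2:(floor(n / 2) + 1)]
    env <- Mod(stats::fft(spec, inverse = TRUE) / n)
    es <- Mod(stats::fft(env - mean(env)))
    k <- round(f * n / fs) + 1
    max(es[(k - 1):(k + 1)])
  }
  fs <- p$sample_rate
  expect_gt(env_spec_at(x, 16, fs) / env_spec_at(um, 16, fs), 10)
})

test_that("cross-fade conserves power and has the right window length", {
  fs <- 97656.25
  expect_equal(round(20 / 1000 * fs), 1953)
  ## identical inputs: output bounded by sqrt(2) bump, never drops out
  a <- sin(seq(0, 20 * pi, length.out = 4000))
  out <- crossfade_pair(a, a, window_ms = 10, sample_rate = 100000)
  expect_length(out, 2 * length(a) - 1000)
  expect_lte(max(abs(out)), sqrt(2) * max(abs(a)) + 1e-12)
  expect_error(crossfade_pair(a[1:100], a, 10, 100000), "window")
  ## independent unit-power noises: mean power across the window stays 1
  set.seed(1)
  nw <- 200
  pw <- replicate(1000, {
    x <- rnorm(nw); y <- rnorm(nw)
    th <- (seq_len(nw) - 0.5) / nw * pi / 2
    mean((x * cos(th) + y * sin(th))^2)
  })
  se <- stats::sd(pw) / sqrt(length(pw))
  expect_lt(abs(mean(pw) - 1), 3 * se)
})

test_that("DRC generation is deterministic, on-grid, and at the nominal density", {
  d1 <- small_drc()
  d2 <- generate_drc(drc_grid(freq_low = 4000, freq_high = 4000 * 2^1.5,
                              total_duration = 30), seed = 101)
  expect_identical(d1$tones, d2$tones)
  d3 <- generate_drc(drc_grid(freq_low = 4000, freq_high = 4000 * 2^1.5,
                              total_duration = 30), seed = 102)
  expect_false(identical(d1$tones, d3$tones))
  expect_true(all(d1$tones$duration_bins >= 4 & d1$tones$duration_bins <= 40))
  expect_true(all(d1$tones$level_db >= 25 & d1$tones$level_db <= 70))
  expect_true(all(d1$tones$level_db %% 5 == 0))
  ## full-band default grid: 60 frequency bins over 5 octaves, 10 levels
  g <- drc_grid()
  expect_equal(g$n_freq, 60)
  expect_length(g$levels, 10)
  full <- generate_drc(g, seed = 2)
  expect_lt(abs(drc_tones_per_octave(full) - 2), 0.15)
  ## density 0: silent stimulus
  empty <- generate_drc(drc_grid(density = 0), seed = 1)
  expect_equal(nrow(empty$tones), 0)
  expect_true(all(is.na(empty$level_matrix)))
})

test_that("input scalings agree at the endpoints and are monotone", {
  scales <- c("pow", "amp", "dB0", "dB20", "dB40", "binary")
  for (sc in scales) {
    expect_equal(scale_intensity(70, sc), 1)
    expect_equal(scale_intensity(NA, sc), 0)
    lv <- seq(25, 70, by = 5)
    expect_true(all(diff(scale_intensity(lv, sc)) >= 0))
  }
  expect_equal(scale_intensity(50, "amp"), 0.1)
  expect_equal(scale_intensity(50, "pow"), 0.01)
  expect_equal(scale_intensity(30, "dB40"), 0)
  expect_equal(scale_intensity(30, "dB20"), 10 / 50)
  expect_error(scale_intensity(50, "foo"))
})
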