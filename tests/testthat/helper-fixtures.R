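## Shared fixtures, built once per test run and memoized. The STRF test
## fixtures use a 1.5-octave DRC band (18 frequency bins) and a 9-lag
## (45 ms) PRF window so the fits stay small.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

small_drc <- function(duration = 30, seed = 101) {
  memo(sprintf("drc_%g_%d", duration, seed),
       generate_drc(drc_grid(freq_low = 4000, freq_high = 4000 * 2^1.5,
                             total_duration = duration),
                    seed = seed))
}

fixture_prf <- function(amplitude = 3.5) {
  make_gabor_prf(n_lags = 9, n_freq = 18, amplitude = amplitude)
}

## negative context field along the low-tau row and the phi = 0 column,
## the suppressive pattern typical of forward masking
fixture_cgf <- function(strength = 0.5, n_tau = 5, n_phi = 6) {
  cgf <- matrix(0, n_tau, 2 * n_phi + 1)
  ctr <- n_phi + 1
  cgf[1, ] <- -strength * exp(-((seq_len(2 * n_phi + 1) - ctr)^2) / 8)
  cgf[, ctr] <- pmin(cgf[, ctr],
                     -strength * exp(-(seq_len(n_tau) - 1)^2 / 4))
  cgf
}

## LNP unit on the small DRC; returns counts plus generative truth
fixture_lnp_counts <- function(with_cgf = FALSE, n_reps = 20, seed = 7,
                               duration = 30, scaling = "amp") {
  key <- sprintf("lnp_%d_%d_%d_%g_%s", with_cgf, n_reps, seed, duration,
                 scaling)
  memo(key, {
    prf <- fixture_prf()
    cgf <- if (with_cgf) fixture_cgf() else NULL
    up <- lnp_unit_params(true_prf = prf, true_cgf = cgf, c = 0.2,
                          scaling = scaling)
    counts <- simulate_lnp_unit(up, small_drc(duration), n_reps = n_reps,
                                seed = seed)
    list(counts = counts, prf = prf, cgf = cgf, params = up)
  })
}

## simple ASD fit on the linear fixture (reused by several tests)
fixture_asd_fit <- function() {
  memo("asd_fit", {
    fx <- fixture_lnp_counts()
    fit_strf_asd(small_drc(), colMeans(fx$counts), scaling = "amp",
                 n_lags = 9)
  })
}

## two-condition population with salicylate-analogue multipliers
fixture_population <- function(seed = 42, n_units = 8, n_trials = 15,
                               fmod = 16) {
  mult <- list(baseline = c(gain = 1, lock = 1),
               salicylate = c(gain = 1.6, lock = 2))
  design <- do.call(rbind, lapply(names(mult), function(cn)
    data.frame(fmod = fmod, depth = c(0, 0.06, 0.125, 0.25, 0.5, 1),
               intensity = 60, condition = cn)))
  set.seed(substream_seed(seed, "unit_params"))
  ups <- lapply(seq_len(n_units), function(i)
    sam_unit_params(r_base = runif(1, 10, 40),
                    gain_slope = runif(1, 0.3, 0.8),
                    lock_strength = runif(1, 1.5, 4),
                    pref_phase = runif(1, -pi, pi),
                    condition_multipliers = mult))
  simulate_population(ups, design, n_trials = n_trials,
                      seed = substream_seed(seed, "pop"))
}

## brute-force ROC oracle: explicit pair counting with half ties
roc_auc_oracle <- function(sig, nul) {
  tot <- 0
  for (s in sig) for (n in nul)
    tot <- tot + (s > n) + 0.5 * (s == n)
  tot / (length(sig) * length(nul))
}

## all multisets of {0,1,2} with sizes 1..n (order does not affect the AUC)
value_multisets <- function(n) {
  out <- list()
  for (len in seq_len(n))
    out <- c(out, unique(lapply(
      asplit(as.matrix(expand.grid(rep(list(0:2), len))), 1),
      function(x) sort(unname(x)))))
  unique(out)
}
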