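## Synthetic spike trains and behavioral sessions with the statistical
## structure the analyses assume: phase-locked rate-modulated responses to
## SAM noise, linear-nonlinear-Poisson responses to DRCs (with optional
## planted context gain fields), and lick-response sessions with sigmoidal
## psychometric functions and depth-dependent latencies.

#' Parameters of a simulated AM-responsive unit
#'
#' Firing follows an inhomogeneous Poisson process with a von Mises
#' phase-locking profile during the AM segment,
#' \deqn{\lambda(t) = r_{base}\, g(m)\,
#'   e^{\kappa m \cos(2\pi f_{mod}(t-\delta) + \psi - \pi/2)} / I_0(\kappa m)}
#' and constant rate \eqn{r_{base}} before it, where g(m) = 1 +
#' gain_slope * m is the depth-dependent rate gain, \eqn{\kappa} the
#' phase-locking concentration, \eqn{\delta} the response latency and
#' \eqn{\psi} the preferred phase. The normalization by the Bessel function
#' keeps the cycle-averaged rate at \eqn{r_{base} g(m)} for every
#' concentration; at small \eqn{\kappa m} the profile reduces to the
#' sinusoidal modulator \eqn{1 + \kappa m \sin(\cdot)} and as
#' \eqn{\kappa m \to \infty} spikes concentrate at the preferred phase
#' (vector strength \eqn{I_1/I_0 \to 1}). The intensity is non-negative by
#' construction, so no rectification is needed. `condition_multipliers`
#' scale gain and lock strength per condition label, emulating a
#' pharmacological sensitization such as the salicylate effect.
#'
#' @param r_base spontaneous/carrier-driven rate, spikes/s.
#' @param gain_slope slope of the depth-dependent rate gain, per unit depth.
#' @param lock_strength phase-locking concentration, unitless >= 0.
#' @param pref_phase preferred modulation phase, radians.
#' @param latency response latency, s.
#' @param condition_multipliers named list of c(gain =, lock =) per condition.
#' @return object of class `sam_unit_params`.
#' @export
sam_unit_params <- function(r_base = 20, gain_slope = 0.5, lock_strength = 3,
                            pref_phase = 0, latency = 0.005,
                            condition_multipliers = list(
                              baseline = c(gain = 1, lock = 1))) {
  stopifnot(r_base >= 0, is.finite(lock_strength), lock_strength >= 0)
  structure(list(r_base = r_base, gain_slope = gain_slope,
                 lock_strength = lock_strength, pref_phase = pref_phase,
                 latency = latency,
                 condition_multipliers = condition_multipliers),
            class = "sam_unit_params")
}

## inhomogeneous Poisson sampler by thinning on [0, Tdur]
rinhom_poisson <- function(Tdur, lambda_fun, lambda_max) {
  if (lambda_max <= 0) return(numeric(0))
  n <- stats::rpois(1, lambda_max * Tdur)
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, 0, Tdur))
  keep <- stats::runif(n) < lambda_fun(cand) / lambda_max
  cand[keep]
}

#' Simulate spike trains of one unit across a SAM design
#'
#' @param params a [sam_unit_params()].
#' @param design data.frame with columns fmod, depth and optionally
#'   intensity and condition (see [sam_design()]); one row per stimulus
#'   condition.
#' @param n_trials trials per condition.
#' @param um_duration,am_duration segment durations, s (spike times are
#'   relative to trial onset; the UM->AM transition is at `um_duration`).
#' @param seed integer seed.
#' @return object of class `spike_trains`: `trials` (data.frame of trial
#'   metadata incl. `transition` and `duration`) and `spikes` (list of
#'   numeric spike-time vectors, one per trial).
#' @export
simulate_sam_unit <- function(params, design, n_trials = 10,
                              um_duration = 1, am_duration = 1, seed = 1L) {
  set.seed(seed)
  if (is.null(design$condition)) design$condition <- "baseline"
  if (is.null(design$intensity)) design$intensity <- 60
  rows <- design[rep(seq_len(nrow(design)), each = n_trials), ]
  rows$trial <- seq_len(nrow(rows))
  rows$transition <- um_duration
  rows$duration <- um_duration + am_duration
  rownames(rows) <- NULL
  spikes <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    cm <- params$condition_multipliers[[rows$condition[i]]]
    if (is.null(cm)) cm <- c(gain = 1, lock = 1)
    m <- rows$depth[i]; f <- rows$fmod[i]
    g <- 1 + params$gain_slope * cm[["gain"]] * m
    kap <- params$lock_strength * cm[["lock"]] * m
    r_am <- params$r_base * g
    pre <- rinhom_poisson(um_duration, function(t) rep(params$r_base,
                                                       length(t)),
                          params$r_base)
    ## scaled Bessel normalization keeps the mean rate at r_am and avoids
    ## overflow at large concentrations
    i0s <- besselI(kap, 0, expon.scaled = TRUE)
    lam <- function(t) r_am * exp(kap * (cos(2 * pi * f *
                                               (t - params$latency) +
                                               params$pref_phase - pi / 2) -
                                           1)) / i0s
    post <- rinhom_poisson(am_duration, lam, r_am / i0s)
    spikes[[i]] <- c(pre, um_duration + post)
  }
  structure(list(trials = rows, spikes = spikes, params = params),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("spike_trains: %d trials, %d conditions, %.0f spikes total\n",
              nrow(x$trials),
              nrow(unique(x$trials[, intersect(c("fmod", "depth", "intensity",
                                                 "condition"),
                                               names(x$trials))])),
              sum(lengths(x$spikes))))
  invisible(x)
}

#' Parameters of a simulated linear-nonlinear-Poisson DRC unit
#'
#' Ground-truth twin of the context-gain model: the per-bin rate is the
#' context-model prediction (baseline + principal receptive field, optionally
#' gain-modulated by a context gain field), passed through a rectifier and
#' Poisson-sampled per repetition.
#'
#' @param true_prf (J+1) lags x K frequency-bin weight matrix.
#' @param true_cgf (M+1) tau x (2N+1) phi weight matrix, or NULL for a purely
#'   linear unit.
#' @param c baseline rate, spikes/bin.
#' @param scaling input scale id (see [scale_intensity()]).
#' @param nonlinearity "rectify" (half-wave, default) or "exp".
#' @return object of class `lnp_unit_params`.
#' @export
lnp_unit_params <- function(true_prf, true_cgf = NULL, c = 0.1,
                            scaling = "amp",
                            nonlinearity = c("rectify", "exp")) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(is.matrix(true_prf))
  if (!is.null(true_cgf)) stopifnot(is.matrix(true_cgf),
                                    ncol(true_cgf) %% 2 == 1)
  structure(list(true_prf = true_prf, true_cgf = true_cgf, c = c,
                 scaling = scaling, nonlinearity = nonlinearity),
            class = "lnp_unit_params")
}

#' Simulate binned spike counts of an LNP unit driven by a DRC
#'
#' @param params an [lnp_unit_params()].
#' @param drc a `drc_stimulus`.
#' @param n_reps number of stimulus repetitions.
#' @param seed integer seed.
#' @return matrix of spike counts, n_reps x time bins, with the noise-free
#'   rate attached as attribute `"rate"`.
#' @export
simulate_lnp_unit <- function(params, drc, n_reps = 20, seed = 1L) {
  set.seed(seed)
  s <- scale_intensity(drc$level_matrix, params$scaling)
  rate <- context_predict(s, params$true_prf, params$true_cgf, params$c)
  rate <- switch(params$nonlinearity,
                 rectify = pmax(rate, 0),
                 exp = exp(pmin(rate, 10)))
  counts <- matrix(stats::rpois(n_reps * length(rate), rep(rate, each = n_reps)),
                   nrow = n_reps)
  attr(counts, "rate") <- rate
  counts
}

#' A smooth Gabor-like receptive field for simulations
#'
#' Gaussian envelope in lag and frequency with an optional inhibitory
#' sidelobe; peak weight `amplitude` at (`peak_lag`, `peak_freq`).
#'
#' @param n_lags,n_freq field dimensions.
#' @param peak_lag,peak_freq peak position (bins).
#' @param sigma_lag,sigma_freq Gaussian widths (bins).
#' @param amplitude peak weight.
#' @param inhib relative amplitude of a delayed inhibitory lobe.
#' @return (n_lags x n_freq) matrix.
#' @export
make_gabor_prf <- function(n_lags = 9, n_freq = 18, peak_lag = 3,
                           peak_freq = NULL, sigma_lag = 1.2,
                           sigma_freq = 2, amplitude = 1, inhib = 0.4) {
  if (is.null(peak_freq)) peak_freq <- ceiling(n_freq / 2)
  lg <- matrix(seq_len(n_lags), n_lags, n_freq)
  fq <- matrix(seq_len(n_freq), n_lags, n_freq, byrow = TRUE)
  ex <- exp(-((lg - peak_lag)^2 / (2 * sigma_lag^2) +
                (fq - peak_freq)^2 / (2 * sigma_freq^2)))
  inh <- exp(-((lg - peak_lag - 2.5)^2 / (2 * (1.6 * sigma_lag)^2) +
                 (fq - peak_freq)^2 / (2 * (1.4 * sigma_freq)^2)))
  amplitude * (ex - inhib * inh)
}

#' Parameters of a simulated lick-response session
#'
#' Hit probability is a clipped logistic in depth (dB re full modulation):
#' \deqn{p(x) = fa + (1 - fa - lapse) \cdot
#'   \mathrm{logistic}((x - \theta) \beta)}
#' with x = 20 log10(m). Response latency on hits decreases with depth:
#' latency_floor + latency_scale * exp(-(x - theta) beta) * lognormal noise.
#' Catch-trial licks occur at rate `fa_rate` with latencies from the
#' at-threshold (floor + scale) distribution.
#'
#' @param fa_rate false-alarm probability per catch trial.
#' @param lapse lapse probability.
#' @param threshold_db psychometric midpoint, dB re full modulation.
#' @param slope logistic slope, 1/dB.
#' @param latency_floor,latency_scale latency model parameters, s.
#' @param latency_noise lognormal sigma of the latency noise.
#' @return object of class `behavior_model_params`.
#' @export
behavior_model_params <- function(fa_rate = 0.1, lapse = 0.05,
                                  threshold_db = -12, slope = 1,
                                  latency_floor = 0.25, latency_scale = 0.25,
                                  latency_noise = 0.3) {
  stopifnot(fa_rate >= 0, fa_rate <= 1, lapse >= 0, lapse <= 1)
  structure(list(fa_rate = fa_rate, lapse = lapse,
                 threshold_db = threshold_db, slope = slope,
                 latency_floor = latency_floor, latency_scale = latency_scale,
                 latency_noise = latency_noise),
            class = "behavior_model_params")
}

#' Trial grid for a simulated behavioral session
#'
#' @param fmod modulation frequencies, Hz.
#' @param depth nonzero modulation depths.
#' @param intensity dB SPL.
#' @param n_per_cell AM trials per (fmod x depth x intensity) cell.
#' @param n_catch catch (unmodulated) trials per (fmod x intensity).
#' @param condition condition label.
#' @return data.frame of trials with a logical `catch` column.
#' @export
behavior_design <- function(fmod = c(16, 512),
                            depth = c(0.06, 0.125, 0.25, 0.5, 1),
                            intensity = 60, n_per_cell = 25, n_catch = 50,
                            condition = "baseline") {
  am <- expand.grid(fmod = fmod, depth = depth, intensity = intensity,
                    KEEP.OUT.ATTRS = FALSE)
  am <- am[rep(seq_len(nrow(am)), each = n_per_cell), ]
  ct <- expand.grid(fmod = fmod, depth = 0, intensity = intensity,
                    KEEP.OUT.ATTRS = FALSE)
  ct <- ct[rep(seq_len(nrow(ct)), each = n_catch), ]
  out <- rbind(am, ct)
  out$catch <- out$depth == 0
  out$condition <- condition
  rownames(out) <- NULL
  out
}

#' Simulate one behavioral session
#'
#' @param params a [behavior_model_params()].
#' @param design a trial grid from [behavior_design()] (must include catch
#'   trials).
#' @param seed integer seed.
#' @return the design with added columns `responded` (logical) and `latency`
#'   (s from the AM transition; NA when no response).
#' @export
simulate_behavior_session <- function(params, design, seed = 1L) {
  stopifnot(any(design$catch))
  set.seed(seed)
  n <- nrow(design)
  x <- ifelse(design$catch, -Inf, 20 * log10(design$depth))
  p_hit <- ifelse(design$catch, params$fa_rate,
                  params$fa_rate + (1 - params$fa_rate - params$lapse) *
                    stats::plogis((x - params$threshold_db) * params$slope))
  responded <- stats::runif(n) < p_hit
  noise <- exp(stats::rnorm(n, 0, params$latency_noise))
  lat <- ifelse(design$catch,
                params$latency_floor + params$latency_scale * noise,
                params$latency_floor + params$latency_scale *
                  exp(-(x - params$threshold_db) * params$slope) * noise)
  design$responded <- responded
  design$latency <- ifelse(responded, lat, NA_real_)
  design
}

#' Simulate a population of AM-responsive units
#'
#' Runs [simulate_sam_unit()] for each parameter set on a shared design with
#' independent per-unit seed substreams.
#'
#' @param unit_params list of [sam_unit_params()] (>= 2 units).
#' @param design shared stimulus design (see [simulate_sam_unit()]).
#' @param n_trials trials per condition per unit.
#' @param um_duration,am_duration segment durations, s.
#' @param seed integer master seed.
#' @return object of class `population_spikes`: named list `units` of
#'   `spike_trains` plus the shared `design`.
#' @export
simulate_population <- function(unit_params, design, n_trials = 10,
                                um_duration = 1, am_duration = 1, seed = 1L) {
  if (length(unit_params) < 2) stop("a population needs at least 2 units")
  units <- lapply(seq_along(unit_params), function(i)
    simulate_sam_unit(unit_params[[i]], design, n_trials,
                      um_duration, am_duration,
                      seed = substream_seed(seed, paste0("unit", i))))
  tr1 <- units[[1]]$trials
  for (u in units)
    if (!identical(u$trials[, c("fmod", "depth", "intensity", "condition")],
                   tr1[, c("fmod", "depth", "intensity", "condition")]))
      stop("inconsistent designs across units")
  names(units) <- sprintf("unit%02d", seq_along(units))
  structure(list(units = units, design = design,
                 trials = tr1, seed = as.integer(seed)),
            class = "population_spikes")
}

#' Simulate spike-count responses of one pure-tone (FRA) unit
#'
#' V-shaped tuning: the unit responds whenever the tone level exceeds
#' `mt + slope_db_per_oct * |log2(f / cf)|`; evoked spikes are Poisson at
#' `evoked_rate` within the 100-ms tone window on top of spontaneous firing
#' at `spont_rate` throughout the 300-ms trial (tone + intertrial interval).
#'
#' @param grid an [fra_grid()].
#' @param cf characteristic frequency, Hz.
#' @param mt minimum threshold, dB SPL.
#' @param slope_db_per_oct flank slope of the V.
#' @param evoked_rate,spont_rate spikes/s.
#' @param seed integer seed.
#' @return list with `trials` (data.frame freq_hz, level_db, rep) and
#'   `spikes` (list of spike-time vectors on [0, tone_duration + iti)).
#' @export
simulate_fra_unit <- function(grid = fra_grid(), cf = 16000, mt = 15,
                              slope_db_per_oct = 20, evoked_rate = 60,
                              spont_rate = 2, seed = 1L) {
  set.seed(seed)
  trials <- expand.grid(freq_hz = grid$frequencies, level_db = grid$levels,
                        rep = seq_len(grid$repetitions),
                        KEEP.OUT.ATTRS = FALSE)
  tdur <- grid$tone_duration; total <- tdur + grid$iti
  inside <- trials$level_db >= mt + slope_db_per_oct *
    abs(log2(trials$freq_hz / cf))
  spikes <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    sp <- stats::runif(stats::rpois(1, spont_rate * total), 0, total)
    if (inside[i])
      sp <- c(sp, stats::runif(stats::rpois(1, evoked_rate * tdur), 0, tdur))
    spikes[[i]] <- sort(sp)
  }
  list(trials = trials, spikes = spikes, grid = grid,
       truth = list(cf = cf, mt = mt))
}
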