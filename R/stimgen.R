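## Stimulus synthesis: SAM noise with spectrally matched unmodulated noise,
## dynamic random chords (DRCs), and pure-tone FRA grids.

#' Parameters for one SAM-noise trial
#'
#' A trial consists of an unmodulated (UM) pink-noise segment followed by a
#' sinusoidally amplitude-modulated (SAM) segment of the same carrier class,
#' joined by a 20-ms energy-conserving cross-fade. Default parameter grid:
#' modulation frequencies 16/64/128/512 Hz, depths 0-1, intensities 45 and
#' 60 dB SPL, 1 s UM + 1 s AM.
#'
#' @param fmod modulation frequency, Hz.
#' @param m modulation depth in [0, 1] (0 = unmodulated).
#' @param intensity nominal presentation level, dB SPL (metadata only; the
#'   waveform is unit-RMS).
#' @param um_duration,am_duration segment durations, s.
#' @param sample_rate sampling rate, Hz.
#' @param band_low,band_high carrier band edges, Hz.
#' @param crossfade_ms cross-fade window, ms.
#' @param seed integer RNG seed for the carrier noise.
#' @return object of class `sam_params`.
#' @export
sam_params <- function(fmod = 16, m = 1, intensity = 60,
                       um_duration = 1, am_duration = 1,
                       sample_rate = 97656.25,
                       band_low = 2000, band_high = 48000,
                       crossfade_ms = 20, seed = 1L) {
  stopifnot(m >= 0, m <= 1, fmod > 0,
            band_low < band_high, band_high < sample_rate / 2,
            um_duration > crossfade_ms / 1000)
  structure(list(fmod = fmod, m = m, intensity = intensity,
                 um_duration = um_duration, am_duration = am_duration,
                 sample_rate = sample_rate, band_low = band_low,
                 band_high = band_high, crossfade_ms = crossfade_ms,
                 seed = as.integer(seed)),
            class = "sam_params")
}

#' The full default SAM stimulus grid
#'
#' 4 modulation frequencies x 6 depths x 2 intensities = 48 conditions.
#'
#' @return data.frame with columns fmod, depth, intensity.
#' @export
sam_design <- function(fmod = c(16, 64, 128, 512),
                       depth = c(0, 0.06, 0.125, 0.25, 0.5, 1),
                       intensity = c(45, 60)) {
  expand.grid(fmod = fmod, depth = depth, intensity = intensity,
              KEEP.OUT.ATTRS = FALSE)
}

#' Starting phase of the AM modulator
#'
#' The modulation starts at the phase where the instantaneous sine value
#' matches the average power of the preceding unmodulated noise, avoiding a
#' level step at the transition. The default closed form is
#' \eqn{\varphi = \arcsin(\sqrt{1 + m^2/2} - 1)}. Because amplitude modulation
#' raises mean power by the factor \eqn{1 + m^2/2}, exact power continuity
#' actually requires dividing the arcsin argument by \eqn{m}; that variant is
#' available as `mode = "power"` (\eqn{\varphi =
#' \arcsin((\sqrt{1 + m^2/2} - 1)/m)}) and is the only mode for which the
#' squared envelope at the transition equals the AM-segment mean power.
#'
#' @param m modulation depth in [0, 1].
#' @param mode `"printed"` (default) or `"power"`.
#' @return phase offset, radians.
#' @export
am_phase_offset <- function(m, mode = c("printed", "power")) {
  mode <- match.arg(mode)
  if (any(m < 0 | m > 1)) stop("modulation depth must lie in [0, 1]")
  arg <- sqrt(1 + 0.5 * m^2) - 1
  if (mode == "power") arg <- ifelse(m == 0, 0, arg / m)
  ifelse(m == 0, 0, asin(arg))
}

#' Band-limited pink (1/f) noise
#'
#' Frequency-domain construction: magnitude proportional to 1/sqrt(f) inside
#' [band_low, band_high] (power spectral density 1/f), zero outside, random
#' phases, conjugate-symmetric inverse FFT. Output is scaled to unit RMS.
#'
#' @param n number of samples.
#' @param sample_rate Hz.
#' @param band_low,band_high band edges, Hz.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, sample_rate, band_low = 2000, band_high = 48000,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- (seq_len(n) - 1) / n * sample_rate
  half <- 2:(floor(n / 2) + 1)          # positive-frequency bins (excl. DC)
  mag <- numeric(n)
  in_band <- freqs[half] >= band_low & freqs[half] <= band_high
  mag[half][in_band] <- 1 / sqrt(freqs[half][in_band])
  ph <- numeric(n)
  ph[half] <- stats::runif(length(half), 0, 2 * pi)
  spec <- mag * exp(1i * ph)
  ## conjugate symmetry for a real signal
  if (n %% 2 == 0) spec[n / 2 + 1] <- Re(spec[n / 2 + 1])
  idx <- 2:ceiling(n / 2)
  spec[n + 2 - idx] <- Conj(spec[idx])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x / r
  x
}

#' Spectrally matched unmodulated noise
#'
#' Returns a waveform with exactly the magnitude spectrum of the input (hence
#' identical power and spectral envelope, including the AM sidebands' power)
#' but fully randomized phases, which destroys the periodic envelope. This is
#' how the UM segment of each trial is matched to its SAM segment.
#'
#' @param sam_waveform numeric vector.
#' @param seed integer seed for the random phases.
#' @return numeric vector, same length.
#' @export
make_matched_um <- function(sam_waveform, seed = 1L) {
  x <- sam_waveform
  stopifnot(all(is.finite(x)))
  n <- length(x)
  set.seed(seed)
  spec <- stats::fft(x)
  mag <- Mod(spec)
  ph <- numeric(n)
  idx <- 2:ceiling(n / 2)
  ph[idx] <- stats::runif(length(idx), 0, 2 * pi)
  out <- mag * exp(1i * ph)
  out[1] <- spec[1]                              # keep DC as-is (real)
  if (n %% 2 == 0) out[n / 2 + 1] <- mag[n / 2 + 1] * sign(Re(spec[n / 2 + 1]) + (Re(spec[n/2+1]) == 0))
  out[n + 2 - idx] <- Conj(out[idx])
  Re(stats::fft(out, inverse = TRUE)) / n
}

#' Energy-conserving cross-fade of two signals
#'
#' Joins `a` then `b`, overlapping the last part of `a` with the first part of
#' `b` over a window in which `a` is weighted by cos(theta) and `b` by
#' sin(theta), theta running over [0, pi/2]. Since sin^2 + cos^2 = 1 the
#' combined instantaneous power of two uncorrelated noises stays constant
#' through the fade.
#'
#' @param a,b numeric vectors (same sample rate).
#' @param window_ms fade window, ms.
#' @param sample_rate Hz.
#' @return numeric vector of length `length(a) + length(b) - nw` where `nw`
#'   is the window length in samples.
#' @export
crossfade_pair <- function(a, b, window_ms, sample_rate) {
  nw <- round(window_ms / 1000 * sample_rate)
  if (nw > length(a) || nw > length(b))
    stop("cross-fade window longer than a segment")
  theta <- (seq_len(nw) - 0.5) / nw * (pi / 2)
  head_a <- a[seq_len(length(a) - nw)]
  mix <- a[(length(a) - nw + 1):length(a)] * cos(theta) +
    b[seq_len(nw)] * sin(theta)
  c(head_a, mix, b[(nw + 1):length(b)])
}

#' Synthesize one SAM-noise trial
#'
#' The AM segment is band-limited pink noise multiplied by
#' \eqn{1 + m \sin(2\pi f_{mod} t + \varphi)}; the UM segment is produced by
#' sideband phase randomization of an independent SAM instance
#' ([make_matched_um()]), so its intensity and spectral envelope match the AM
#' segment; segments are joined by the 20-ms sine/cosine cross-fade.
#'
#' @param params a [sam_params()] object.
#' @param phase_mode passed to [am_phase_offset()].
#' @return object of class `sam_trial` with fields `waveform`, `envelope`
#'   (the nominal modulator: 1 before the transition), `transition_time` (s),
#'   `times` and `params`.
#' @export
synthesize_sam_trial <- function(params, phase_mode = "printed") {
  p <- params
  fs <- p$sample_rate
  if (p$m > 0 && p$am_duration < 1 / p$fmod)
    warning("AM segment shorter than one modulation period")
  n_um <- round(p$um_duration * fs)
  n_am <- round(p$am_duration * fs)
  nw <- round(p$crossfade_ms / 1000 * fs)
  phi <- am_phase_offset(p$m, phase_mode)

  ## AM segment: fresh carrier times the modulator
  carrier <- pink_noise(n_am, fs, p$band_low, p$band_high,
                        seed = substream_seed(p$seed, "am_carrier"))
  t_am <- (seq_len(n_am) - 1) / fs
  modulator <- 1 + p$m * sin(2 * pi * p$fmod * t_am + phi)
  am <- carrier * modulator

  ## UM segment (extended by the fade window): phase-randomized SAM instance
  src <- pink_noise(n_um + nw, fs, p$band_low, p$band_high,
                    seed = substream_seed(p$seed, "um_src"))
  t_src <- (seq_len(n_um + nw) - 1) / fs
  src <- src * (1 + p$m * sin(2 * pi * p$fmod * t_src + phi))
  um <- make_matched_um(src, seed = substream_seed(p$seed, "um_phase"))
  um <- um / max(sqrt(mean(um^2)), .Machine$double.eps)

  wav <- crossfade_pair(um, am, p$crossfade_ms, fs)
  times <- (seq_along(wav) - 1) / fs
  env <- ifelse(times < p$um_duration, 1,
                1 + p$m * sin(2 * pi * p$fmod * (times - p$um_duration) + phi))
  structure(list(waveform = wav, envelope = env,
                 transition_time = p$um_duration, times = times,
                 params = p),
            class = "sam_trial")
}

#' @export
print.sam_trial <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "SAM-noise trial: fmod %g Hz, depth %g, %g dB SPL, %g s UM + %g s AM @ %g Hz\n",
    p$fmod, p$m, p$intensity, p$um_duration, p$am_duration, p$sample_rate))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Dynamic random chords

#' DRC stimulus grid
#'
#' Time-frequency-level grid for dynamic random chords: 5-ms time bins,
#' 1/12-octave frequency bins covering 2-64 kHz (60 bins), 5-dB level bins
#' covering 25-70 dB SPL, tone durations 20-200 ms (5-ms steps) following a
#' truncated discretized exponential with lambda = 30 ms, average density two
#' simultaneously active tones per octave, 60 s total.
#'
#' @return object of class `drc_grid`.
#' @export
drc_grid <- function(time_bin = 5, freq_low = 2000, freq_high = 64000,
                     freq_step = 1 / 12, level_min = 25, level_max = 70,
                     level_step = 5, duration_min = 20, duration_max = 200,
                     duration_step = 5, duration_lambda = 30, density = 2,
                     total_duration = 60) {
  n_oct <- log2(freq_high / freq_low)
  nf <- round(n_oct / freq_step)
  stopifnot(abs(nf * freq_step - n_oct) < 1e-9)
  structure(list(time_bin = time_bin, freq_low = freq_low,
                 freq_high = freq_high, freq_step = freq_step,
                 level_min = level_min, level_max = level_max,
                 level_step = level_step, duration_min = duration_min,
                 duration_max = duration_max, duration_step = duration_step,
                 duration_lambda = duration_lambda, density = density,
                 total_duration = total_duration,
                 n_freq = nf,
                 frequencies = freq_low * 2^((seq_len(nf) - 1) * freq_step),
                 levels = seq(level_min, level_max, by = level_step),
                 n_time = round(total_duration * 1000 / time_bin)),
            class = "drc_grid")
}

## truncated discretized exponential over tone durations, in time bins
drc_duration_dist <- function(grid) {
  durs_ms <- seq(grid$duration_min, grid$duration_max, by = grid$duration_step)
  w <- exp(-durs_ms / grid$duration_lambda)
  list(bins = durs_ms / grid$time_bin, prob = w / sum(w))
}

#' Generate a dynamic random chord stimulus
#'
#' Tone onsets, frequencies and levels are randomized independently on the
#' grid; durations follow the truncated discretized exponential. A
#' time-frequency bin already occupied by an active tone cannot start a new
#' tone, so the level matrix is single-valued. The per-bin onset probability
#' is solved from the renewal-process occupancy so that the expected number of
#' simultaneously active tones per octave equals `grid$density`: with
#' q = density/12 (bins per octave) and mean duration E[L] bins, occupancy
#' E[L]/(E[L] + 1/p) = q gives p = q / ((1 - q) E[L]).
#'
#' @param grid a [drc_grid()].
#' @param seed integer seed.
#' @return object of class `drc_stimulus`: `tones` (data.frame: onset_bin,
#'   freq_bin, freq_hz, level_db, duration_bins), `level_matrix` (time x freq,
#'   dB SPL with NA = no tone), `grid`, `seed`.
#' @export
generate_drc <- function(grid = drc_grid(), seed = 1L) {
  set.seed(seed)
  nt <- grid$n_time; nf <- grid$n_freq
  dd <- drc_duration_dist(grid)
  lev <- matrix(NA_real_, nt, nf)
  bins_per_oct <- round(1 / grid$freq_step)
  q <- grid$density / bins_per_oct
  if (grid$density == 0) {
    p <- 0
  } else {
    if (q >= 1) stop("tone density unachievable: would require full occupancy")
    p <- q / ((1 - q) * sum(dd$bins * dd$prob))
    if (p > 1) stop("tone density unachievable given the duration distribution")
  }
  busy <- integer(nf)
  onset_bin <- integer(0); freq_bin <- integer(0)
  level_db <- numeric(0); duration_bins <- integer(0)
  if (p > 0) {
    for (t in seq_len(nt)) {
      free <- busy == 0L
      start <- free & (stats::runif(nf) < p)
      ks <- which(start)
      if (length(ks)) {
        di <- sample.int(length(dd$bins), length(ks), replace = TRUE,
                         prob = dd$prob)
        L <- as.integer(dd$bins[di])
        lv <- grid$levels[sample.int(length(grid$levels), length(ks),
                                     replace = TRUE)]
        onset_bin <- c(onset_bin, rep.int(t, length(ks)))
        freq_bin <- c(freq_bin, ks)
        level_db <- c(level_db, lv)
        duration_bins <- c(duration_bins, L)
        for (i in seq_along(ks)) {
          tt <- t:min(nt, t + L[i] - 1L)
          lev[tt, ks[i]] <- lv[i]
        }
        busy[ks] <- L
      }
      busy[busy > 0L] <- busy[busy > 0L] - 1L
    }
  }
  tones <- data.frame(onset_bin = onset_bin, freq_bin = freq_bin,
                      freq_hz = grid$frequencies[freq_bin],
                      level_db = level_db, duration_bins = duration_bins)
  structure(list(grid = grid, tones = tones, level_matrix = lev,
                 seed = as.integer(seed)),
            class = "drc_stimulus")
}

#' @export
print.drc_stimulus <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "DRC stimulus: %d tones over %g s, %d freq bins (%g-%g kHz), density %g/octave (seed %d)\n",
    nrow(x$tones), g$total_duration, g$n_freq, g$freq_low / 1000,
    g$freq_high / 1000, g$density, x$seed))
  invisible(x)
}

#' Mean number of simultaneously active tones per octave
#'
#' Time-averaged concurrency of a DRC instance, for checking the realized
#' tone density against the grid's nominal value.
#'
#' @param drc a `drc_stimulus`.
#' @return numeric scalar.
#' @export
drc_tones_per_octave <- function(drc) {
  bins_per_oct <- round(1 / drc$grid$freq_step)
  mean(rowSums(!is.na(drc$level_matrix))) / (drc$grid$n_freq / bins_per_oct)
}

#' Map tone levels to model input strengths
#'
#' Six lookup scales for the stimulus strength s(t,f) used in receptive-field
#' models, all mapping 70 dB SPL to 1 and silence to 0:
#' \describe{
#'   \item{pow}{10^((x - 70)/10) - proportional to sound power}
#'   \item{amp}{10^((x - 70)/20) - proportional to sound amplitude}
#'   \item{dB0, dB20, dB40}{x/(70 - ref) for x > ref, else 0 - linear in dB
#'     above the reference}
#'   \item{binary}{1 wherever a tone is present}
#' }
#'
#' The dB scales are linear in decibels above their reference and normalized
#' so the top of the level grid maps to 1: s = (x - ref)/(70 - ref) for
#' x > ref, 0 otherwise.
#'
#' @param level dB SPL; `NA` encodes silence. Vector or matrix.
#' @param scale one of "pow", "amp", "dB0", "dB20", "dB40", "binary".
#' @return strengths, same shape as `level`.
#' @export
scale_intensity <- function(level, scale) {
  scale <- match.arg(scale, c("pow", "amp", "dB0", "dB20", "dB40", "binary"))
  x <- level
  s <- switch(scale,
    pow = 10^((x - 70) / 10),
    amp = 10^((x - 70) / 20),
    dB0 = ifelse(x > 0, x / 70, 0),
    dB20 = ifelse(x > 20, (x - 20) / 50, 0),
    dB40 = ifelse(x > 40, (x - 40) / 30, 0),
    binary = (x == x) * 1)                       # 1 where not NA
  s[is.na(level)] <- 0
  if (is.matrix(level)) s <- matrix(s, nrow(level), ncol(level))
  s
}

## ---------------------------------------------------------------------------
## Pure-tone FRA grid

#' Pure-tone frequency-response-area grid
#'
#' 2-64 kHz in 1/4-octave steps (21 frequencies) x 0-60 dB SPL in 5-dB steps
#' (13 levels), 100-ms tones, 200-ms intertrial interval, 20 repetitions.
#'
#' @return object of class `fra_grid`.
#' @export
fra_grid <- function(freq_low = 2000, freq_high = 64000, freq_step = 0.25,
                     level_min = 0, level_max = 60, level_step = 5,
                     tone_duration = 0.1, iti = 0.2, repetitions = 20) {
  n_oct <- log2(freq_high / freq_low)
  freqs <- freq_low * 2^(seq(0, n_oct, by = freq_step))
  structure(list(frequencies = freqs,
                 levels = seq(level_min, level_max, by = level_step),
                 tone_duration = tone_duration, iti = iti,
                 repetitions = repetitions),
            class = "fra_grid")
}

#' Pseudorandom FRA presentation order
#'
#' @param grid an [fra_grid()].
#' @param seed integer seed.
#' @return data.frame with one row per trial: trial, freq_hz, level_db, rep.
#' @export
fra_design <- function(grid = fra_grid(), seed = 1L) {
  set.seed(seed)
  cells <- expand.grid(freq_hz = grid$frequencies, level_db = grid$levels,
                       rep = seq_len(grid$repetitions),
                       KEEP.OUT.ATTRS = FALSE)
  ord <- sample.int(nrow(cells))
  out <- cells[ord, ]
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("trial", "freq_hz", "level_db", "rep")]
}

#' Export a SAM trial as WAV plus JSON metadata sidecar
#'
#' @param trial a `sam_trial`.
#' @param path output WAV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
export_sam_trial <- function(trial, path) {
  write_wav_float32(trial$waveform, trial$params$sample_rate, path)
  meta <- trial$params
  class(meta) <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a DRC tone list as CSV
#'
#' @param drc a `drc_stimulus`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_drc_tones <- function(drc, path) {
  utils::write.csv(drc$tones, path, row.names = FALSE)
  invisible(path)
}
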