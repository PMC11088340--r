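## Signal/noise power decomposition of repeated responses and the derived
## inclusion rule and normalized predictive power.

## averaged squared deviation from the mean over time
resp_power <- function(z) mean((z - mean(z))^2)

#' Signal and noise power of a repeated response
#'
#' Decomposes trial-to-trial response power into a stimulus-locked (signal)
#' and a residual (noise) component. With N repetitions, trial PSTHs r(n) and
#' trial average \eqn{\bar r}, the unbiased signal-power estimator is
#' \deqn{\hat P(\mu) = \frac{1}{N-1}\left(N P(\bar r) -
#'   \overline{P(r(n))}\right)}
#' where P() is the averaged squared deviation from the mean over time; the
#' noise power is \eqn{\overline{P(r(n))} - \hat P(\mu)}, so that signal +
#' noise equals the mean total power exactly.
#'
#' @param psths matrix of binned responses, repetitions x time bins (N >= 2).
#' @return object of class `power_estimates` with `signal_power`,
#'   `noise_power`, `mean_total_power`, `n_reps`.
#' @export
signal_noise_power <- function(psths) {
  psths <- as.matrix(psths)
  N <- nrow(psths)
  if (N < 2) stop("signal/noise power needs at least 2 repetitions")
  p_bar <- resp_power(colMeans(psths))
  p_each <- mean(apply(psths, 1, resp_power))
  signal <- (N * p_bar - p_each) / (N - 1)
  structure(list(signal_power = signal, noise_power = p_each - signal,
                 mean_total_power = p_each, n_reps = N),
            class = "power_estimates")
}

#' @export
print.power_estimates <- function(x, ...) {
  cat(sprintf(
    "Power estimates (N = %d): signal %.4g, noise %.4g (spk/bin)^2; SNR %.2f\n",
    x$n_reps, x$signal_power, x$noise_power,
    x$signal_power / max(x$noise_power, .Machine$double.eps)))
  invisible(x)
}

#' Response-reliability inclusion rule
#'
#' A unit is retained for receptive-field analysis iff its signal power is at
#' least twice its noise power.
#'
#' @param pe a [signal_noise_power()] result.
#' @return logical.
#' @export
include_unit <- function(pe) {
  pe$signal_power >= 2 * pe$noise_power
}

#' Normalized predictive power of a model prediction
#'
#' \deqn{(P(r) - P(r - \rho)) / \hat P(\mu)}: the difference between the
#' power of the observed response and the power of the residual (the "error
#' power"), normalized by the predictable signal power. Equals 1 for a
#' perfect prediction of a noise-free response and 0 for a constant
#' prediction; cross-validated values may be negative.
#'
#' @param r observed response over the evaluation bins.
#' @param rho predicted response, same bins.
#' @param signal_power normalizer \eqn{\hat P(\mu)} (from the full data).
#' @return unitless scalar.
#' @export
normalized_predictive_power <- function(r, rho, signal_power) {
  (resp_power(r) - resp_power(r - rho)) / signal_power
}
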