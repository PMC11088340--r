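## Temporal and rate coding of SAM noise: phase-projected vector strength,
## ROC -> d' conversion, sensitivity curves, interpolated depth thresholds.

#' Vector strength of a set of spike phases
#'
#' Resultant length of the unit phasors, \eqn{|\sum e^{i\theta}|/n}, together
#' with the circular mean phase.
#'
#' @param phases spike phases, radians.
#' @return list with `vs` in [0, 1] and `mean_phase` in (-pi, pi].
#' @export
vector_strength <- function(phases) {
  if (length(phases) == 0) stop("vector_strength needs at least one phase")
  z <- sum(exp(1i * phases))
  list(vs = Mod(z) / length(phases), mean_phase = Arg(z))
}

#' Phase-projected vector strength across trials
#'
#' Classic vector strength is biased upward at low spike counts (a single
#' spike always gives VS = 1). The phase-projected variant computes, per
#' trial, \eqn{VS_{PP,t} = VS_t \cos(\theta_t - \theta_c)}, projecting each
#' trial's resultant onto the global mean phase \eqn{\theta_c} of all spikes
#' pooled across trials; randomly phased low-count trials then average toward
#' zero rather than one. Zero-spike trials contribute 0.
#'
#' @param spikes list of spike-time vectors (s), one per trial.
#' @param fmod modulation frequency, Hz.
#' @param window analysis interval c(t0, t1) in the same time base as the
#'   spikes; only spikes inside it are used (conventionally the last 500 ms
#'   of the AM segment, excluding onset effects).
#' @return list with `per_trial` (VS_PP per trial), `mean`, `mean_phase`
#'   (theta_c) and `n_spikes`.
#' @export
vs_pp <- function(spikes, fmod, window) {
  ph <- lapply(spikes, function(s) {
    s <- s[s >= window[1] & s <= window[2]]
    (2 * pi * fmod * s) %% (2 * pi)
  })
  pooled <- unlist(ph)
  if (length(pooled) == 0)
    return(list(per_trial = rep(0, length(spikes)), mean = 0,
                mean_phase = NA_real_, n_spikes = 0L, flagged = TRUE))
  theta_c <- Arg(sum(exp(1i * pooled)))
  per_trial <- vapply(ph, function(p) {
    if (length(p) == 0) return(0)
    v <- vector_strength(p)
    v$vs * cos(v$mean_phase - theta_c)
  }, numeric(1))
  list(per_trial = per_trial, mean = mean(per_trial), mean_phase = theta_c,
       n_spikes = length(pooled), flagged = FALSE)
}

#' Area under the empirical ROC curve
#'
#' Probability that a randomly drawn signal value exceeds a randomly drawn
#' null value, with ties counted 1/2 (the Mann-Whitney rank-sum
#' formulation). `-Inf` values (e.g. no-response trials coded as worst
#' evidence) are handled by the rank computation.
#'
#' @param signal_values,null_values numeric vectors, both non-empty.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(signal_values, null_values) {
  ns <- length(signal_values); nn <- length(null_values)
  if (ns == 0 || nn == 0) stop("roc_auc needs non-empty inputs")
  r <- rank(c(signal_values, null_values), ties.method = "average")
  (sum(r[seq_len(ns)]) - ns * (ns + 1) / 2) / (ns * nn)
}

#' Convert an ROC area to a sensitivity index d'
#'
#' Equal-variance Gaussian relation \eqn{d' = |\sqrt{2}\,\Phi^{-1}(AUC)|};
#' symmetric in AUC vs 1-AUC, zero at 0.5. `convention = "2"` selects the
#' alternative \eqn{|2\,\Phi^{-1}(AUC)|}. When `n_pairs` is supplied the AUC
#' is first clipped to `[0.5/n_pairs, 1 - 0.5/n_pairs]` so that perfect
#' separation in a finite sample does not map to infinity (the same rule
#' applied to behavioral hit/false-alarm rates).
#'
#' @param auc area under the ROC curve, in [0, 1].
#' @param convention "sqrt2" (default) or "2".
#' @param n_pairs optional number of signal x null comparisons for clipping.
#' @return d' >= 0.
#' @export
dprime_from_auc <- function(auc, convention = c("sqrt2", "2"),
                            n_pairs = NULL) {
  convention <- match.arg(convention)
  if (any(auc < 0 | auc > 1)) stop("AUC must lie in [0, 1]")
  if (!is.null(n_pairs))
    auc <- pmin(pmax(auc, 0.5 / n_pairs), 1 - 0.5 / n_pairs)
  k <- if (convention == "sqrt2") sqrt(2) else 2
  abs(k * stats::qnorm(auc))
}

#' Interpolated modulation-depth threshold at d' = 1
#'
#' Linear interpolation of the d' curve against depth in dB; returns the
#' lowest-depth upward crossing of d' = 1. If the curve never reaches 1 the
#' threshold is undefined (NA). If the curve already starts at or above 1,
#' the lowest tested depth is returned with attribute `censored = TRUE`.
#'
#' @param depths_db depths in dB re full modulation, strictly increasing.
#' @param dprime d' values, same length.
#' @param criterion crossing level (default 1).
#' @return threshold in dB (possibly with attribute `censored`), or NA.
#' @export
modulation_threshold <- function(depths_db, dprime, criterion = 1) {
  stopifnot(length(depths_db) == length(dprime), length(depths_db) >= 2)
  if (any(diff(depths_db) <= 0)) stop("depth grid must be strictly increasing")
  if (dprime[1] >= criterion) {
    th <- depths_db[1]
    if (dprime[1] > criterion) attr(th, "censored") <- TRUE
    return(th)
  }
  for (i in seq_len(length(dprime) - 1)) {
    if (dprime[i] < criterion && dprime[i + 1] >= criterion) {
      frac <- (criterion - dprime[i]) / (dprime[i + 1] - dprime[i])
      return(depths_db[i] + frac * (depths_db[i + 1] - depths_db[i]))
    }
  }
  NA_real_
}

#' Sensitivity curve of one unit for temporal or rate coding
#'
#' For each nonzero modulation depth, the per-trial metric (phase-projected
#' vector strength for temporal coding; firing rate over the analysis window
#' for rate coding) is compared against the depth-0 (unmodulated) trials of
#' the same block via ROC analysis and converted to d'; the threshold is the
#' interpolated depth at which d' crosses 1.
#'
#' @param trains a `spike_trains` object, or a list with `trials` and
#'   `spikes` in the same layout; must contain depth-0 trials.
#' @param coding "temporal" or "rate".
#' @param fmod modulation frequency to select (required if several present).
#' @param window analysis interval, s from trial onset; default the last
#'   500 ms of the AM segment.
#' @param convention d' convention, see [dprime_from_auc()].
#' @return object of class `sensitivity_curve` with fields `depths`,
#'   `depths_db`, `metric_per_trial`, `auc`, `dprime`, `threshold_db`,
#'   `coding`, `stimulus`.
#' @export
sensitivity_curve <- function(trains, coding = c("temporal", "rate"),
                              fmod = NULL, window = NULL,
                              convention = "sqrt2") {
  coding <- match.arg(coding)
  tr <- trains$trials; sp <- trains$spikes
  if (is.null(fmod)) {
    fmods <- unique(tr$fmod)
    if (length(fmods) > 1) stop("several fmod present; specify one")
    fmod <- fmods
  }
  sel <- tr$fmod == fmod
  tr <- tr[sel, , drop = FALSE]; sp <- sp[sel]
  if (is.null(window)) {
    endt <- tr$duration[1] %||% 2
    window <- c(endt - 0.5, endt)
  }
  depths <- sort(unique(tr$depth))
  if (!0 %in% depths) stop("depth-0 (unmodulated) trials required as the ROC null")
  metric_of <- function(idx) {
    if (coding == "temporal") {
      vs_pp(sp[idx], fmod, window)$per_trial
    } else {
      vapply(sp[idx], function(s)
        sum(s >= window[1] & s <= window[2]) / diff(window), numeric(1))
    }
  }
  null_vals <- metric_of(which(tr$depth == 0))
  nz <- depths[depths > 0]
  metric_per_trial <- stats::setNames(vector("list", length(nz)),
                                      as.character(nz))
  auc <- dp <- numeric(length(nz))
  for (i in seq_along(nz)) {
    v <- metric_of(which(tr$depth == nz[i]))
    metric_per_trial[[i]] <- v
    auc[i] <- roc_auc(v, null_vals)
    dp[i] <- dprime_from_auc(auc[i], convention,
                             n_pairs = length(v) * length(null_vals))
  }
  depths_db <- 20 * log10(nz)
  structure(list(depths = nz, depths_db = depths_db,
                 metric_per_trial = metric_per_trial,
                 null_metric = null_vals, auc = auc, dprime = dp,
                 threshold_db = if (length(nz) >= 2)
                   modulation_threshold(depths_db, dp) else NA_real_,
                 coding = coding,
                 stimulus = list(fmod = fmod,
                                 intensity = unique(tr$intensity),
                                 condition = unique(tr$condition))),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  th <- x$threshold_db
  cat(sprintf("Sensitivity curve (%s coding, fmod %g Hz)\n", x$coding,
              x$stimulus$fmod))
  print(data.frame(depth = x$depths, depth_db = round(x$depths_db, 2),
                   auc = round(x$auc, 3), dprime = round(x$dprime, 3)),
        row.names = FALSE)
  if (is.na(th)) cat("threshold: undefined (d' never reaches 1)\n")
  else cat(sprintf("threshold: %.2f dB re full modulation%s\n", th,
                   if (isTRUE(attr(th, "censored"))) " (censored)" else ""))
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  plot(x$depths_db, x$dprime, type = "b", pch = 16,
       xlab = "modulation depth (dB re full)", ylab = "d'",
       main = sprintf("%s coding, fmod %g Hz", x$coding, x$stimulus$fmod), ...)
  graphics::abline(h = 1, lty = 2)
  if (!is.na(x$threshold_db))
    graphics::abline(v = x$threshold_db, col = 2, lty = 3)
  invisible(x)
}

#' Export sensitivity curves as a tidy table
#'
#' @param curves list of `sensitivity_curve` objects (optionally named by
#'   unit).
#' @param path optional CSV path.
#' @return data.frame: unit, condition, fmod, intensity, coding, depth_db,
#'   dprime, threshold_db.
#' @export
sensitivity_table <- function(curves, path = NULL) {
  if (inherits(curves, "sensitivity_curve")) curves <- list(curves)
  nm <- names(curves) %||% as.character(seq_along(curves))
  rows <- do.call(rbind, lapply(seq_along(curves), function(i) {
    x <- curves[[i]]
    data.frame(unit = nm[i],
               condition = paste(x$stimulus$condition, collapse = "+"),
               fmod = x$stimulus$fmod,
               intensity = paste(x$stimulus$intensity, collapse = "+"),
               coding = x$coding, depth_db = x$depths_db,
               dprime = x$dprime,
               threshold_db = as.numeric(x$threshold_db))
  }))
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}
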