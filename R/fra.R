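## Pure-tone analysis: kernel spike density, significance-bounded tuning
## areas, CF/MT extraction, and the CF-dependence parabola of threshold
## shifts.

#' Gaussian kernel spike density
#'
#' Smooths a spike train into an instantaneous rate, in spikes/s, by placing
#' a Gaussian of width `sigma` on each spike. The density integrates to the
#' spike count; an empty spike list yields the zero function.
#'
#' @param spike_times spike times, s.
#' @param sigma kernel SD, s.
#' @param grid evaluation time points, s.
#' @return numeric vector of rates over `grid`, spikes/s.
#' @export
compute_ksd <- function(spike_times, sigma, grid) {
  stopifnot(sigma > 0)
  if (length(spike_times) == 0) return(numeric(length(grid)))
  out <- numeric(length(grid))
  for (s in spike_times) out <- out + stats::dnorm(grid, s, sigma)
  out
}

#' Extract a significance-bounded tuning area, CF and MT from FRA responses
#'
#' For each (frequency x level) cell the evoked response (spike rate in the
#' tone window minus spontaneous rate in the tail of the intertrial interval)
#' is tested against a permutation null built by circularly shifting the
#' spike times within each trial, with family-wise control via the
#' maximum-statistic rule; of the significant cells, only the contiguous
#' region containing the peak response is kept (cluster rule). The
#' characteristic frequency (CF) is the frequency of the significant cell at
#' the lowest significant level (ties broken by the larger response) and the
#' minimum threshold (MT) is that level.
#'
#' @param responses a list with `trials` (data.frame: freq_hz, level_db, rep)
#'   and `spikes` (list of spike-time vectors on one trial's time base), as
#'   produced by [simulate_fra_unit()].
#' @param grid the [fra_grid()] that generated the trials.
#' @param alpha family-wise significance level.
#' @param n_perm number of permutations.
#' @param evoked_window evoked-rate window, s from tone onset.
#' @param spont_window spontaneous window, s from tone onset (default the
#'   final 50 ms of the 200-ms intertrial interval).
#' @param seed integer seed for the permutation draws.
#' @return object of class `fra_result`: `response_matrix` (levels x
#'   frequencies, evoked - spontaneous rate, spikes/s), `significance_mask`,
#'   `cf` (Hz or NA), `mt` (dB SPL or NA), `flagged`.
#' @export
extract_cf_mt <- function(responses, grid, alpha = 0.05, n_perm = 200,
                          evoked_window = c(0, 0.1),
                          spont_window = NULL, seed = 1L) {
  tr <- responses$trials
  if (max(table(paste(tr$freq_hz, tr$level_db))) < 2)
    stop("need at least 2 repetitions per cell")
  total <- grid$tone_duration + grid$iti
  if (is.null(spont_window)) spont_window <- c(total - 0.05, total)
  set.seed(seed)
  freqs <- grid$frequencies; levels <- grid$levels
  fi <- match(tr$freq_hz, freqs); li <- match(tr$level_db, levels)
  cell <- (li - 1L) * length(freqs) + fi
  n_cells <- length(freqs) * length(levels)
  reps_per_cell <- tabulate(cell, n_cells)

  ## flat spike representation so each permutation is a few vector ops
  all_sp <- unlist(responses$spikes)
  sp_trial <- rep(seq_along(responses$spikes), lengths(responses$spikes))
  n_trials <- nrow(tr)
  rate_diff <- function(shift) {
    s <- (all_sp + shift[sp_trial]) %% total
    ev <- tabulate(sp_trial[s >= evoked_window[1] & s < evoked_window[2]],
                   n_trials) / diff(evoked_window)
    sp <- tabulate(sp_trial[s >= spont_window[1] & s < spont_window[2]],
                   n_trials) / diff(spont_window)
    d <- numeric(n_cells)
    agg <- rowsum(ev - sp, cell)
    gi <- as.integer(rownames(agg))
    d[gi] <- agg[, 1] / reps_per_cell[gi]
    d
  }

  obs <- rate_diff(numeric(nrow(tr)))
  if (sum(lengths(responses$spikes)) == 0) {
    mask <- matrix(FALSE, length(levels), length(freqs))
    rm_ <- matrix(0, length(levels), length(freqs),
                  dimnames = list(levels, signif(freqs, 6)))
    return(structure(list(response_matrix = rm_, significance_mask = mask,
                          cf = NA_real_, mt = NA_real_, flagged = TRUE),
                     class = "fra_result"))
  }
  null_max <- vapply(seq_len(n_perm), function(b)
    max(rate_diff(stats::runif(nrow(tr), 0, total))), numeric(1))
  thresh <- stats::quantile(null_max, 1 - alpha, names = FALSE)
  sig <- obs >= thresh

  resp <- matrix(obs, length(levels), length(freqs), byrow = TRUE,
                 dimnames = list(levels, signif(freqs, 6)))
  mask <- matrix(sig, length(levels), length(freqs), byrow = TRUE)

  if (any(mask)) {
    ## cluster rule: keep the 4-connected region containing the peak
    peak <- which(resp == max(resp[mask]) & mask, arr.ind = TRUE)[1, ]
    keep <- matrix(FALSE, nrow(mask), ncol(mask))
    stack <- list(peak)
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask))
        next
      if (!mask[p[1], p[2]] || keep[p[1], p[2]]) next
      keep[p[1], p[2]] <- TRUE
      stack <- c(stack, list(c(p[1] - 1, p[2])), list(c(p[1] + 1, p[2])),
                 list(c(p[1], p[2] - 1)), list(c(p[1], p[2] + 1)))
    }
    mask <- keep
  }

  if (!any(mask)) {
    cf <- NA_real_; mt <- NA_real_; flagged <- TRUE
  } else {
    lvl_i <- which(apply(mask, 1, any))[1]
    cand <- which(mask[lvl_i, ])
    cf <- freqs[cand[which.max(resp[lvl_i, cand])]]
    mt <- levels[lvl_i]
    flagged <- FALSE
  }
  structure(list(response_matrix = resp, significance_mask = mask,
                 cf = cf, mt = mt, flagged = flagged),
            class = "fra_result")
}

#' @export
print.fra_result <- function(x, ...) {
  if (is.na(x$cf)) cat("FRA result: no significant tuning area\n")
  else cat(sprintf("FRA result: CF %.1f kHz, MT %g dB SPL, %d significant cells\n",
                   x$cf / 1000, x$mt, sum(x$significance_mask)))
  invisible(x)
}

#' Export an FRA result as a long-format table
#'
#' @param x an `fra_result`.
#' @param path optional CSV path; CF/MT metadata are written next to it as
#'   `<path>.json`.
#' @return data.frame: frequency_hz, level_db, rate, significant.
#' @export
fra_table <- function(x, path = NULL) {
  freqs <- as.numeric(colnames(x$response_matrix))
  levels <- as.numeric(rownames(x$response_matrix))
  out <- data.frame(frequency_hz = rep(freqs, each = length(levels)),
                    level_db = rep(levels, length(freqs)),
                    rate = as.vector(x$response_matrix),
                    significant = as.vector(x$significance_mask))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    jsonlite::write_json(list(cf_hz = x$cf, mt_db = x$mt),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Parabolic fit of threshold shift against characteristic frequency
#'
#' Ordinary least squares of \eqn{\Delta MT = a (\log_{10} CF)^2 +
#' b \log_{10} CF + c} with CF in kHz.
#'
#' @param delta_mt threshold shifts, dB.
#' @param cf_khz characteristic frequencies, kHz (>= 3 distinct values).
#' @return list with `coefficients` c(a, b, c), `fitted`, and `fun` (the
#'   fitted curve as a function of CF in kHz).
#' @export
fit_mt_parabola <- function(delta_mt, cf_khz) {
  if (length(unique(cf_khz)) < 3)
    stop("parabola fit needs at least 3 distinct CFs")
  lx <- log10(cf_khz)
  X <- cbind(lx^2, lx, 1)
  if (qr(X)$rank < 3) stop("rank-deficient design")
  beta <- qr.solve(X, delta_mt)
  names(beta) <- c("a", "b", "c")
  list(coefficients = beta, fitted = as.vector(X %*% beta),
       fun = function(cf) beta[1] * log10(cf)^2 + beta[2] * log10(cf) +
         beta[3])
}
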