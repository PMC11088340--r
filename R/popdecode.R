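## Population-level AM decoding: the AM-encoding principal component,
## single-trial projections, threshold-crossing latency simulation,
## grid-search fitting to behavioral latency distributions, and derived
## d'/thresholds.

#' Bin a simulated population into PSTHs and single-trial KSD functions
#'
#' Converts a [simulate_population()] result into a common time base:
#' trial-averaged PSTHs (bin width 1/256 s = 3.90625 ms) and single-trial
#' Gaussian kernel spike densities (sigma = 2 ms) per unit.
#'
#' @param pop a `population_spikes` object.
#' @param bin PSTH bin width, s.
#' @param ksd_sigma KSD kernel SD, s.
#' @return object of class `population_activity`: `ksd` (units x trials x
#'   time array, spikes/s), `psth` (units x time, trial-averaged),
#'   `times` (bin centers), `trials` (metadata), `bin`, `ksd_sigma`.
#' @export
population_activity <- function(pop, bin = 1 / 256, ksd_sigma = 0.002) {
  trials <- pop$trials
  dur <- trials$duration[1]
  times <- seq(bin / 2, dur - bin / 2, by = bin)
  nu <- length(pop$units); ntr <- nrow(trials); nt <- length(times)
  ksd <- array(0, c(nu, ntr, nt))
  for (u in seq_len(nu)) {
    sp <- pop$units[[u]]$spikes
    for (i in seq_len(ntr))
      ksd[u, i, ] <- compute_ksd(sp[[i]], ksd_sigma, times)
  }
  psth <- apply(ksd, c(1, 3), mean)
  structure(list(ksd = ksd, psth = psth, times = times, trials = trials,
                 unit_ids = names(pop$units), bin = bin,
                 ksd_sigma = ksd_sigma),
            class = "population_activity")
}

#' The AM-encoding component of a population
#'
#' The difference matrix (units x time) between the PSTH averaged over all
#' fully modulated stimuli and over all unmodulated stimuli in the reference
#' condition is submitted to a principal component analysis over the unit
#' dimension; the largest component is the AM-encoding component. Its sign
#' is chosen so the mean projection of the full-depth difference is
#' positive.
#'
#' @param pop a `population_activity`.
#' @param condition reference condition label.
#' @return unit-norm numeric vector of unit weights, with the difference
#'   matrix attached as attribute `"difference"` and `"unreliable"` set when
#'   the difference is essentially zero.
#' @export
am_encoding_component <- function(pop, condition = "baseline") {
  if (dim(pop$ksd)[1] < 2) stop("population PCA needs at least 2 units")
  tr <- pop$trials
  i_full <- which(tr$depth == 1 & tr$condition == condition)
  i_um <- which(tr$depth == 0 & tr$condition == condition)
  if (!length(i_full) || !length(i_um))
    stop("reference condition must contain full-depth and unmodulated trials")
  D <- apply(pop$ksd[, i_full, , drop = FALSE], c(1, 3), mean) -
    apply(pop$ksd[, i_um, , drop = FALSE], c(1, 3), mean)
  unreliable <- stats::sd(D) < 1e-10
  comp <- if (unreliable) rep(1 / sqrt(nrow(D)), nrow(D))
    else prcomp(t(D), center = TRUE)$rotation[, 1]
  comp <- comp / sqrt(sum(comp^2))
  if (mean(crossprod(comp, D)) < 0) comp <- -comp
  attr(comp, "difference") <- D
  attr(comp, "unreliable") <- unreliable
  comp
}

#' Project single-trial population activity onto a component
#'
#' Weighted sum of the single-trial KSD functions across units; linear in
#' the unit rates. A component estimated in one (e.g. baseline) condition
#' may be applied to trials of any condition of the same units.
#'
#' @param pop a `population_activity`.
#' @param component unit weight vector from [am_encoding_component()].
#' @return matrix trials x time of projection values.
#' @export
project_trials <- function(pop, component) {
  if (length(component) != dim(pop$ksd)[1])
    stop("component does not match the population's unit set")
  ntr <- dim(pop$ksd)[2]; nt <- dim(pop$ksd)[3]
  out <- matrix(0, ntr, nt)
  for (u in seq_along(component))
    out <- out + component[u] * pop$ksd[u, , ]
  out
}

#' Simulated response latency of one trial
#'
#' Time for the projected population signal to first cross the detection
#' level after the AM transition, plus a fixed non-decision time; trials
#' whose projection never crosses yield no response (NA).
#'
#' @param projection projection time series of one trial.
#' @param times bin centers, s.
#' @param detection_level threshold on the projection.
#' @param non_decision_time added fixed latency, s (conventionally
#'   0.100-0.200 s).
#' @param transition_time UM->AM transition, s.
#' @return latency in s from the transition, or NA for no response.
#' @export
simulate_response_latency <- function(projection, times, detection_level,
                                      non_decision_time, transition_time) {
  idx <- which(times >= transition_time & projection >= detection_level)
  if (!length(idx)) return(NA_real_)
  times[idx[1]] - transition_time + non_decision_time
}

## latencies for all trials of a projection matrix
decoder_latencies <- function(proj, times, detection_level,
                              non_decision_time, transition_time) {
  apply(proj, 1, simulate_response_latency, times = times,
        detection_level = detection_level,
        non_decision_time = non_decision_time,
        transition_time = transition_time)
}

## empirical CDF of latencies on a grid; no-response (NA) trials never count
latency_cdf <- function(lat, grid) {
  vapply(grid, function(g) mean(!is.na(lat) & lat <= g), numeric(1))
}

#' Fit decoder parameters to behavioral latency distributions
#'
#' Grid search over (detection level, non-decision time): for each pair the
#' simulated latencies are grouped by stimulus parameters, their empirical
#' CDFs evaluated on a common time grid (10-ms steps from the transition to
#' trial end) and compared to the behavioral CDFs by root-mean-square
#' difference, averaged across groups; the argmin pair wins.
#'
#' @param pop a `population_activity`.
#' @param component unit weights from [am_encoding_component()].
#' @param behav_latencies named list of behavioral latency vectors (s from
#'   transition, NA = no response), one per stimulus group; names must be
#'   the group labels produced by `group_by` applied to the decoder trials.
#' @param group_by function mapping the trials data.frame to group labels
#'   (default: modulation depth).
#' @param detection_levels candidate detection levels; default 12
#'   log-spaced values spanning 0.1x to 3x the median peak projection.
#' @param non_decision_times candidate non-decision times, s.
#' @param cdf_step CDF evaluation step, s.
#' @return list with `best` (detection_level, non_decision_time), `rms_map`
#'   (data.frame over the grid), `latencies` (simulated at the optimum).
#' @export
fit_decoder_params <- function(pop, component, behav_latencies,
                               group_by = function(tr) as.character(tr$depth),
                               detection_levels = NULL,
                               non_decision_times = c(0.100, 0.125, 0.150,
                                                      0.175, 0.200),
                               cdf_step = 0.010) {
  proj <- project_trials(pop, component)
  tr <- pop$trials
  transition <- tr$transition[1]
  grid_t <- seq(0, tr$duration[1] - transition, by = cdf_step)
  if (is.null(detection_levels)) {
    peak <- stats::median(apply(proj[, pop$times >= transition,
                                     drop = FALSE], 1, max))
    detection_levels <- exp(seq(log(0.1 * peak), log(3 * peak),
                                length.out = 12))
  }
  groups <- group_by(tr)
  behav_cdf <- lapply(behav_latencies, latency_cdf, grid = grid_t)
  rows <- list(); best <- NULL
  for (dl in detection_levels) for (ndt in non_decision_times) {
    lat <- decoder_latencies(proj, pop$times, dl, ndt, transition)
    rmss <- c()
    for (g in names(behav_cdf)) {
      idx <- which(groups == g)
      if (!length(idx)) { warning("empty group ", g, "; skipped"); next }
      sim_cdf <- latency_cdf(lat[idx], grid_t)
      rmss <- c(rmss, sqrt(mean((sim_cdf - behav_cdf[[g]])^2)))
    }
    rms <- mean(rmss)
    rows[[length(rows) + 1]] <- data.frame(detection_level = dl,
                                           non_decision_time = ndt,
                                           rms = rms)
    if (is.null(best) || rms < best$rms)
      best <- list(detection_level = dl, non_decision_time = ndt, rms = rms,
                   latencies = lat)
  }
  list(best = best[c("detection_level", "non_decision_time", "rms")],
       rms_map = do.call(rbind, rows), latencies = best$latencies)
}

#' Sensitivity curve of the threshold-crossing decoder
#'
#' Latency-based ROC per depth against the catch (unmodulated) simulations:
#' shorter latency ranks as stronger evidence and no-response trials share
#' the worst rank; the AUC is converted to d' and the threshold interpolated
#' at d' = 1.
#'
#' @param latencies_by_depth named list of simulated latency vectors, names
#'   = nonzero modulation depths.
#' @param catch_latencies simulated latencies of unmodulated trials.
#' @param convention d' convention, see [dprime_from_auc()].
#' @return a `sensitivity_curve` (coding = "decoder").
#' @export
decoder_sensitivity <- function(latencies_by_depth, catch_latencies,
                                convention = "sqrt2") {
  depths <- sort(as.numeric(names(latencies_by_depth)))
  ev_catch <- ifelse(is.na(catch_latencies), -Inf, -catch_latencies)
  auc <- dp <- numeric(length(depths))
  for (i in seq_along(depths)) {
    lat <- latencies_by_depth[[as.character(depths[i])]]
    ev <- ifelse(is.na(lat), -Inf, -lat)
    auc[i] <- roc_auc(ev, ev_catch)
    dp[i] <- dprime_from_auc(auc[i], convention,
                             n_pairs = length(ev) * length(ev_catch))
  }
  depths_db <- 20 * log10(depths)
  structure(list(depths = depths, depths_db = depths_db,
                 metric_per_trial = latencies_by_depth,
                 null_metric = catch_latencies, auc = auc, dprime = dp,
                 threshold_db = if (length(depths) >= 2)
                   modulation_threshold(depths_db, dp) else NA_real_,
                 coding = "decoder",
                 stimulus = list(fmod = NA, intensity = NA, condition = NA)),
            class = "sensitivity_curve")
}
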