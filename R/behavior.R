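## Behavioral psychometrics from lick-response sessions: clipped hit and
## false-alarm rates, latency-based ROC d', and modulation-depth thresholds.

clip_rate <- function(p, n) pmin(pmax(p, 0.5 / n), 1 - 0.5 / n)

#' Hit and false-alarm rates with finite-sample clipping
#'
#' Hit rate per (fmod x depth x intensity x condition) cell and false-alarm
#' rate from the catch trials per (intensity x condition); every rate is
#' clipped to `[0.5/N, 1 - 0.5/N]` (N = trials in the cell) before any d'
#' conversion, so that perfect or empty scores do not map to infinities.
#'
#' @param trials behavioral trial table with columns fmod, depth, intensity,
#'   condition, catch, responded (see [simulate_behavior_session()]).
#' @return list with `hits` (data.frame incl. raw and clipped rates) and
#'   `fa` (data.frame per intensity x condition).
#' @export
compute_rates <- function(trials) {
  am <- trials[!trials$catch, ]
  ct <- trials[trials$catch, ]
  key <- interaction(am$fmod, am$depth, am$intensity, am$condition,
                     drop = TRUE)
  hits <- do.call(rbind, lapply(split(am, key), function(d)
    data.frame(fmod = d$fmod[1], depth = d$depth[1],
               intensity = d$intensity[1], condition = d$condition[1],
               n = nrow(d), hit_rate_raw = mean(d$responded),
               hit_rate = clip_rate(mean(d$responded), nrow(d)))))
  hits <- hits[order(hits$condition, hits$fmod, hits$intensity, hits$depth), ]
  rownames(hits) <- NULL
  fa <- if (nrow(ct)) {
    keyc <- interaction(ct$intensity, ct$condition, drop = TRUE)
    out <- do.call(rbind, lapply(split(ct, keyc), function(d)
      data.frame(intensity = d$intensity[1], condition = d$condition[1],
                 n = nrow(d), fa_rate_raw = mean(d$responded),
                 fa_rate = clip_rate(mean(d$responded), nrow(d)))))
    rownames(out) <- NULL
    out
  } else NULL
  list(hits = hits, fa = fa)
}

#' Latency-based ROC sensitivity per modulation depth
#'
#' For each nonzero depth the latency distribution of the AM trials is
#' compared to that of the catch trials by ROC analysis (shorter latency =
#' stronger evidence; no-response trials share the worst rank) and the AUC
#' converted to d'; the threshold is the interpolated depth at which d'
#' crosses 1.
#'
#' @param am_trials,catch_trials behavioral trial tables (catch required).
#' @param convention d' convention, see [dprime_from_auc()].
#' @return a `sensitivity_curve` (coding = "behavior").
#' @export
latency_roc_dprime <- function(am_trials, catch_trials,
                               convention = "sqrt2") {
  if (is.null(catch_trials) || nrow(catch_trials) == 0)
    stop("catch trials required for the latency ROC")
  depths <- sort(unique(am_trials$depth[am_trials$depth > 0]))
  ev_catch <- ifelse(is.na(catch_trials$latency), -Inf,
                     -catch_trials$latency)
  auc <- dp <- numeric(length(depths))
  metric <- stats::setNames(vector("list", length(depths)),
                            as.character(depths))
  for (i in seq_along(depths)) {
    d <- am_trials[am_trials$depth == depths[i], ]
    ev <- ifelse(is.na(d$latency), -Inf, -d$latency)
    metric[[i]] <- d$latency
    auc[i] <- roc_auc(ev, ev_catch)
    dp[i] <- dprime_from_auc(auc[i], convention,
                             n_pairs = length(ev) * length(ev_catch))
  }
  depths_db <- 20 * log10(depths)
  structure(list(depths = depths, depths_db = depths_db,
                 metric_per_trial = metric,
                 null_metric = catch_trials$latency, auc = auc, dprime = dp,
                 threshold_db = if (length(depths) >= 2)
                   modulation_threshold(depths_db, dp) else NA_real_,
                 coding = "behavior",
                 stimulus = list(fmod = unique(am_trials$fmod),
                                 intensity = unique(am_trials$intensity),
                                 condition = unique(am_trials$condition))),
            class = "sensitivity_curve")
}

#' Full psychometric analysis of a behavioral session
#'
#' Per (fmod x intensity x condition) block: clipped hit and false-alarm
#' rates, median response latency per depth, latency-ROC d' per depth, and
#' the interpolated AM-detection threshold.
#'
#' @param trials behavioral trial table.
#' @param convention d' convention.
#' @return object of class `psychometric_result`: data.frame `summary` (one
#'   row per depth) plus `curves` (list of `sensitivity_curve` per block)
#'   and `rates` (see [compute_rates()]).
#' @export
analyze_behavior <- function(trials, convention = "sqrt2") {
  rates <- compute_rates(trials)
  key <- interaction(trials$fmod, trials$intensity, trials$condition,
                     drop = TRUE)
  curves <- list(); rows <- list()
  for (blk in split(trials, key)) {
    am <- blk[!blk$catch, ]; ct <- blk[blk$catch, ]
    if (!nrow(am) || !nrow(ct)) next
    cv <- latency_roc_dprime(am, ct, convention)
    lbl <- sprintf("fmod%g_int%g_%s", am$fmod[1], am$intensity[1],
                   am$condition[1])
    curves[[lbl]] <- cv
    med <- vapply(cv$depths, function(d)
      stats::median(am$latency[am$depth == d], na.rm = TRUE), numeric(1))
    rows[[lbl]] <- data.frame(fmod = am$fmod[1], intensity = am$intensity[1],
                              condition = am$condition[1],
                              depth = cv$depths, depth_db = cv$depths_db,
                              dprime = cv$dprime, median_latency = med,
                              threshold_db = as.numeric(cv$threshold_db))
  }
  structure(list(summary = do.call(rbind, rows), curves = curves,
                 rates = rates),
            class = "psychometric_result")
}

#' @export
print.psychometric_result <- function(x, ...) {
  cat("Psychometric analysis\n")
  if (!is.null(x$rates$fa)) {
    cat("false-alarm rates:\n")
    print(x$rates$fa, row.names = FALSE)
  }
  th <- unique(x$summary[, c("fmod", "intensity", "condition",
                             "threshold_db")])
  cat("AM-detection thresholds (dB re full modulation):\n")
  print(th, row.names = FALSE)
  invisible(x)
}
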