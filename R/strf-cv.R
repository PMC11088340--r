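## Cross-validated normalized predictive power and the input-scaling
## comparison.

#' Cross-validated normalized predictive power of an STRF model
#'
#' 10-fold cross-validation holding out a randomly distributed disjoint
#' tenth of the time bins per fold, refitting on the remainder and scoring
#' the held-out prediction by [normalized_predictive_power()] against the
#' signal-power estimate from all repetitions; fold sets are redrawn for
#' each repetition. The smoothness hyperparameters are optimized once on
#' the full response and held fixed across folds; each fold re-solves the
#' penalized least-squares weights (simple model) or re-runs warm-started
#' alternating least squares (context model) on the training bins only.
#'
#' @param model "simple" or "context".
#' @param drc a `drc_stimulus` or stimulus strength matrix.
#' @param psths repetitions x time-bin spike-count matrix.
#' @param scaling input scale id.
#' @param folds number of folds (default 10).
#' @param reps number of cross-validation repetitions (default 20).
#' @param seed integer seed for the fold draws.
#' @param n_lags PRF lag window, bins.
#' @param cv_als_iter ALS alternation cap inside each fold refit.
#' @param full_fit optional pre-computed full-data fit of the requested
#'   model (avoids refitting when scoring several models on one unit).
#' @param ... passed to the underlying fitting functions.
#' @return object of class `prediction_score`: `predictive_power_norm`
#'   (mean over folds and repetitions), `per_fold`, `model`, `scaling`,
#'   `cv_folds`, `cv_reps`, `fit` (the full-data model).
#' @export
cv_predictive_power <- function(model = c("simple", "context"), drc, psths,
                                scaling = "amp", folds = 10, reps = 20,
                                seed = 1L, n_lags = 21, cv_als_iter = 8,
                                full_fit = NULL, ...) {
  model <- match.arg(model)
  psths <- as.matrix(psths)
  y <- colMeans(psths)
  pe <- signal_noise_power(psths)
  if (pe$signal_power <= 0)
    stop("non-positive signal power; unit not predictable")
  s <- if (inherits(drc, "drc_stimulus"))
    scale_intensity(drc$level_matrix, scaling) else as.matrix(drc)
  Tn <- length(y)

  if (is.null(full_fit)) {
    full_fit <- if (model == "simple")
      fit_strf_asd(s, y, scaling = scaling, n_lags = n_lags, ...)
    else
      fit_context_model(s, y, scaling = scaling, ...)
  }
  n_lags <- full_fit$n_lags
  h <- full_fit$hyperparams
  if (model == "simple") {
    X <- lagged_design(s, n_lags)
    eg <- asd_prior_eig(n_lags, ncol(s), h$ell_t, h$ell_f)
    pen <- h$sigma2 / (h$rho2 * eg$lam)
  }

  set.seed(seed)
  pp <- matrix(NA_real_, reps, folds)
  for (rp in seq_len(reps)) {
    fold_id <- sample(rep_len(seq_len(folds), Tn))
    for (fd in seq_len(folds)) {
      val <- which(fold_id == fd); trn <- which(fold_id != fd)
      if (length(val) == 0 || length(trn) == 0) stop("empty fold")
      if (model == "simple") {
        Xt <- X[trn, , drop = FALSE]
        xm <- colMeans(Xt); ym <- mean(y[trn]); nt <- length(trn)
        A <- crossprod(Xt) - nt * tcrossprod(xm)
        b <- crossprod(Xt, y[trn]) - nt * xm * ym
        G <- crossprod(eg$U, A %*% eg$U)
        diag(G) <- diag(G) + pen
        w <- eg$U %*% solve(G, crossprod(eg$U, b))
        cc <- ym - sum(xm * w)
        rho <- as.vector(X[val, , drop = FALSE] %*% w) + cc
      } else {
        fit <- fit_context_model(s, y, scaling = scaling, init = full_fit,
                                 cgf_n_tau = nrow(full_fit$cgf),
                                 cgf_n_phi = (ncol(full_fit$cgf) - 1) / 2,
                                 max_iter = cv_als_iter, rows = trn)
        rho <- fit$fitted[val]
      }
      pp[rp, fd] <- normalized_predictive_power(y[val], rho, pe$signal_power)
    }
  }
  structure(list(predictive_power_norm = mean(pp), per_fold = pp,
                 model = model, scaling = scaling, cv_folds = folds,
                 cv_reps = reps, signal_power = pe$signal_power,
                 fit = full_fit),
            class = "prediction_score")
}

#' @export
print.prediction_score <- function(x, ...) {
  cat(sprintf(
    "Normalized predictive power (%s model, scale '%s'): %.3f (%d-fold x %d reps)\n",
    x$model, x$scaling, x$predictive_power_norm, x$cv_folds, x$cv_reps))
  invisible(x)
}

#' Compare input-intensity scalings by cross-validated predictive power
#'
#' Runs [cv_predictive_power()] for each input scale (and each requested
#' model) and records which scale predicts the unit best.
#'
#' @param drc a `drc_stimulus`.
#' @param psths repetitions x time-bin spike-count matrix.
#' @param scales input scales to compare.
#' @param models models to compare ("simple" and/or "context").
#' @param ... passed to [cv_predictive_power()].
#' @return list with `table` (data.frame: model, scale, predictive_power)
#'   and `best` (named character: best scale per model).
#' @export
scaling_comparison <- function(drc, psths,
                               scales = c("pow", "amp", "dB0", "dB20",
                                          "dB40", "binary"),
                               models = "simple", ...) {
  rows <- list()
  for (mdl in models) for (sc in scales) {
    ps <- cv_predictive_power(mdl, drc, psths, scaling = sc, ...)
    rows[[length(rows) + 1]] <- data.frame(model = mdl, scale = sc,
                                           predictive_power =
                                             ps$predictive_power_norm)
  }
  tab <- do.call(rbind, rows)
  best <- vapply(split(tab, tab$model), function(d)
    d$scale[which.max(d$predictive_power)], character(1))
  list(table = tab, best = best)
}
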