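## Evidence-optimized smooth STRF estimation (automatic smoothness
## determination, ASD). The STRF weights are the posterior mean of a linear
## Gaussian model whose prior covariance is a separable squared-exponential
## in time lag and log-frequency; the prior scale, the two smoothness
## lengths and the noise variance are set by maximizing the marginal
## likelihood (evidence).

## squared-exponential correlation matrix over an integer grid
rbf_kernel <- function(n, ell) {
  d <- outer(seq_len(n), seq_len(n), "-")
  exp(-d^2 / (2 * ell^2))
}

## lagged design matrix: X[t, j*K + k] = s[t - j, k], j = 0..n_lags-1
## (zero before stimulus onset); weight vector <-> PRF matrix via
## prf_to_w / w_to_prf below.
lagged_design <- function(s, n_lags) {
  nt <- nrow(s); K <- ncol(s)
  X <- matrix(0, nt, n_lags * K)
  for (j in 0:(n_lags - 1))
    X[(j + 1):nt, j * K + seq_len(K)] <- s[seq_len(nt - j), ]
  X
}

prf_to_w <- function(prf) as.vector(t(prf))
w_to_prf <- function(w, n_lags, K) matrix(w, n_lags, K, byrow = TRUE)

## apply a PRF as a causal filter: out(i) = sum_j s(i-j, ) %*% prf[j+1, ]
apply_prf <- function(s, prf) {
  nt <- nrow(s)
  out <- numeric(nt)
  for (j in 0:(nrow(prf) - 1))
    out[(j + 1):nt] <- out[(j + 1):nt] +
      s[seq_len(nt - j), , drop = FALSE] %*% prf[j + 1, ]
  out
}

## eigen-structure of the separable prior for given lengthscales
asd_prior_eig <- function(n_lags, K, ell_t, ell_f) {
  et <- eigen(rbf_kernel(n_lags, ell_t), symmetric = TRUE)
  ef <- eigen(rbf_kernel(K, ell_f), symmetric = TRUE)
  U <- kronecker(et$vectors, ef$vectors)
  lam <- as.vector(kronecker(pmax(et$values, 1e-12), pmax(ef$values, 1e-12)))
  list(U = U, lam = lam)
}

## negative log evidence and posterior mean for one hyperparameter setting,
## using precomputed sufficient statistics A0 = X'X, b0 = X'y (centered),
## yy = y'y, T = number of samples
asd_neg_evidence <- function(theta, A0, b0, yy, Tn, n_lags, K,
                             want_posterior = FALSE) {
  if (any(abs(theta) > 18)) return(list(nll = 1e10, w = NULL))
  rho2 <- exp(theta[1]); ell_t <- exp(theta[2]); ell_f <- exp(theta[3])
  sig2 <- exp(theta[4])
  eg <- asd_prior_eig(n_lags, K, ell_t, ell_f)
  d <- rho2 * eg$lam
  D <- length(d)
  B <- crossprod(eg$U, A0 %*% eg$U)
  bb <- crossprod(eg$U, b0)
  G <- B + diag(sig2 / d, D)
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch)) return(list(nll = 1e10, w = NULL))
  v <- backsolve(ch, forwardsolve(t(ch), bb))
  quad <- (yy - sum(bb * v)) / sig2
  nll <- 0.5 * (Tn * log(2 * pi) + (Tn - D) * log(sig2) + sum(log(d)) +
                  2 * sum(log(diag(ch))) + quad)
  if (!is.finite(nll)) nll <- 1e10
  out <- list(nll = nll)
  if (want_posterior && nll < 1e10) out$w <- as.vector(eg$U %*% v)
  out
}

#' Fit a smooth STRF by evidence optimization (simple model)
#'
#' Linear model \eqn{\hat r(i) = c + \sum_{j,k} w^{tf}_{j,k}\, s(i-j, k)} of
#' the binned response on the scaled stimulus. The weights are the posterior
#' mean under a zero-mean Gaussian prior with separable squared-exponential
#' covariance over lag and frequency; the prior variance, both length scales
#' and the observation noise variance are optimized by Nelder-Mead ascent of
#' the log marginal likelihood from `n_starts` initializations (evidence
#' surfaces can be multimodal), with the noise variance initialized at the
#' residual variance of a ridge fit. Deterministic for fixed data.
#'
#' @param drc a `drc_stimulus`, or a numeric time x frequency stimulus
#'   matrix already on the model input scale.
#' @param response binned response, one value per stimulus time bin
#'   (spikes/bin; typically the trial-averaged PSTH).
#' @param scaling input scale id, see [scale_intensity()] (ignored when
#'   `drc` is a plain matrix).
#' @param n_lags number of 5-ms time lags (default 21: 0-100 ms).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param n_starts number of optimizer initializations.
#' @return object of class `strf_model` with fields `c`, `prf` (lags x
#'   freq), `cgf` (NULL), `scaling`, `hyperparams`, `evidence`, `fitted`,
#'   `converged`, and grid metadata.
#' @export
fit_strf_asd <- function(drc, response, scaling = "amp", n_lags = 21,
                         maxit = 150, n_starts = 2) {
  s <- if (inherits(drc, "drc_stimulus"))
    scale_intensity(drc$level_matrix, scaling) else as.matrix(drc)
  y <- as.numeric(response)
  stopifnot(length(y) == nrow(s))
  K <- ncol(s); Tn <- length(y)
  X <- lagged_design(s, n_lags)
  xm <- colMeans(X); ym <- mean(y)
  A0 <- crossprod(X) - Tn * tcrossprod(xm)
  b0 <- crossprod(X, y) - Tn * xm * ym
  yy <- sum(y^2) - Tn * ym^2

  ## ridge fit for noise-variance initialization
  D <- ncol(X)
  lam0 <- 0.1 * mean(diag(A0)) + 1e-10
  wr <- solve(A0 + diag(lam0, D), b0)
  sig2_init <- max((yy - 2 * sum(b0 * wr) + sum(wr * (A0 %*% wr))) / Tn,
                   1e-8 * max(yy / Tn, 1e-12), 1e-12)
  ## prior scale so that the prior-predictive variance matches var(y)
  rho2_init <- max(yy, 1e-12) / max(sum(diag(A0)), 1e-12)
  starts <- list(c(log(rho2_init), log(1), log(1), log(sig2_init)),
                 c(log(rho2_init), log(2.5), log(2.5), log(sig2_init)))
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  fn <- function(th) asd_neg_evidence(th, A0, b0, yy, Tn, n_lags, K)$nll
  best <- NULL
  for (st in starts) {
    op <- stats::optim(st, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit))
    if (is.null(best) || op$value < best$value) best <- op
  }
  fin <- asd_neg_evidence(best$par, A0, b0, yy, Tn, n_lags, K,
                          want_posterior = TRUE)
  w <- fin$w
  if (is.null(w)) stop("ASD evidence optimization failed")
  cc <- ym - sum(xm * w)
  prf <- w_to_prf(w, n_lags, K)
  hyper <- list(rho2 = exp(best$par[1]), ell_t = exp(best$par[2]),
                ell_f = exp(best$par[3]), sigma2 = exp(best$par[4]))
  structure(list(c = cc, prf = prf, cgf = NULL, scaling = scaling,
                 hyperparams = hyper, evidence = -best$value,
                 fitted = as.vector(X %*% w) + cc,
                 converged = best$convergence == 0,
                 n_lags = n_lags, n_freq = K,
                 lag_bin_ms = 5, freq_step = 1 / 12,
                 frequencies = if (inherits(drc, "drc_stimulus"))
                   drc$grid$frequencies else NULL),
            class = "strf_model")
}

#' @export
print.strf_model <- function(x, ...) {
  h <- x$hyperparams
  cat(sprintf("STRF %s model: %d lags x %d freq bins, input scale '%s'\n",
              if (is.null(x$cgf)) "simple" else "context",
              x$n_lags, x$n_freq, x$scaling))
  cat(sprintf("  baseline c = %.4g spk/bin; smoothness (ell_t, ell_f) = (%.2f, %.2f) bins\n",
              x$c, h$ell_t, h$ell_f))
  if (!is.null(x$cgf))
    cat(sprintf("  CGF: %d tau x %d phi bins, ||CGF|| = %.3g\n",
                nrow(x$cgf), ncol(x$cgf), sqrt(sum(x$cgf^2))))
  invisible(x)
}

#' @export
coef.strf_model <- function(object, ...) {
  list(c = object$c, prf = object$prf, cgf = object$cgf)
}

#' @export
predict.strf_model <- function(object, drc, ...) {
  s <- if (inherits(drc, "drc_stimulus"))
    scale_intensity(drc$level_matrix, object$scaling) else as.matrix(drc)
  context_predict(s, object$prf, object$cgf, object$c)
}

#' @export
plot.strf_model <- function(x, which = c("prf", "cgf"), ...) {
  which <- match.arg(which)
  if (which == "prf") {
    z <- t(x$prf)
    graphics::image(x = (seq_len(x$n_lags) - 1) * x$lag_bin_ms,
                    y = seq_len(x$n_freq), z = t(z),
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    xlab = "lag (ms)", ylab = "frequency bin",
                    main = "principal receptive field", ...)
  } else {
    if (is.null(x$cgf)) stop("model has no context gain field")
    M <- nrow(x$cgf); Np <- (ncol(x$cgf) - 1) / 2
    graphics::image(x = (seq_len(M) - 1) * x$lag_bin_ms,
                    y = seq(-Np, Np), z = x$cgf,
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    xlab = "tau (ms)", ylab = "phi (freq bins)",
                    main = "context gain field", ...)
  }
  invisible(x)
}
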