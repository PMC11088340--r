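## Descriptive STRF metrics: best frequency, peak weight, cross-condition
## correlation, and BF-aligned fields for population averaging.

#' Descriptive metrics of one or two STRF fits
#'
#' Best frequency (BF) is the frequency bin of the maximum positive PRF
#' weight. When a second model is given (e.g. the same unit in another
#' condition), also returns the Pearson correlation between the flattened
#' PRFs and the BF shift in octaves.
#'
#' @param model_a an `strf_model`.
#' @param model_b optional second `strf_model` on the same bin conventions.
#' @return list with `bf_bin`, `bf_hz` (NA when the stimulus frequencies are
#'   unknown), `max_weight`, `bf_aligned` (PRF with the frequency axis
#'   shifted so BF sits at the center column), and, with `model_b`,
#'   `correlation` and `delta_bf_octaves`.
#' @export
strf_metrics <- function(model_a, model_b = NULL) {
  bf_of <- function(m) {
    if (max(m$prf) <= 0) return(NA_integer_)
    unname(which(m$prf == max(m$prf), arr.ind = TRUE)[1, 2])
  }
  bf <- bf_of(model_a)
  K <- model_a$n_freq
  aligned <- matrix(NA_real_, model_a$n_lags, 2 * K - 1)
  if (!is.na(bf))
    aligned[, (K - bf + 1):(2 * K - bf)] <- model_a$prf
  out <- list(bf_bin = bf,
              bf_hz = if (!is.na(bf) && !is.null(model_a$frequencies))
                model_a$frequencies[bf] else NA_real_,
              max_weight = max(model_a$prf),
              flagged = is.na(bf),
              bf_aligned = aligned)
  if (!is.null(model_b)) {
    stopifnot(identical(dim(model_a$prf), dim(model_b$prf)))
    out$correlation <- stats::cor(as.vector(model_a$prf),
                                  as.vector(model_b$prf))
    bf_b <- bf_of(model_b)
    out$delta_bf_octaves <- if (is.na(bf) || is.na(bf_b)) NA_real_
      else (bf_b - bf) * model_a$freq_step
  }
  out
}
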