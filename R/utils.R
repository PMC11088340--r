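## Internal helpers: seeding, hashing, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' Expands one user-facing seed into independent per-stage streams so that
#' adding or reordering pipeline stages does not perturb the random numbers
#' used by the others. Uses an FNV-1a hash of the label mixed with the master
#' seed, reduced modulo 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param label character stage label, e.g. "stimgen" or "unit3".
#' @return an integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- fnv1a(paste0(label, ":", format(seed, scientific = FALSE)))
  as.integer(h %% (2^31 - 1))
}

## 32-bit FNV-1a over the UTF-8 bytes of a string, done in double arithmetic
## (exact below 2^53) with a final fold into [0, 2^32).
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    ## xor only touches the low byte since b < 256
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

#' Hash a configuration object
#'
#' Stable content hash used for provenance records: the object is serialized
#' to canonical JSON and hashed with FNV-1a.
#'
#' @param config any jsonlite-serializable object.
#' @return hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  h <- fnv1a(as.character(s))
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

## Row-shift a matrix down by dt and its columns by df, zero-padding.
## shift_mat(s, dt, df)[t, k] == s[t - dt, k + df] (0 outside).
shift_mat <- function(s, dt, df) {
  nt <- nrow(s); nf <- ncol(s)
  out <- matrix(0, nt, nf)
  t_dst <- seq_len(nt)[seq_len(nt) - dt >= 1 & seq_len(nt) - dt <= nt]
  f_dst <- seq_len(nf)[seq_len(nf) + df >= 1 & seq_len(nf) + df <= nf]
  if (length(t_dst) && length(f_dst))
    out[t_dst, f_dst] <- s[t_dst - dt, f_dst + df]
  out
}

#' Write a mono float32 WAV file
#'
#' Minimal RIFF/WAVE writer (IEEE float, format code 3) for exporting
#' synthesized stimuli. Samples are written as-is; values outside [-1, 1]
#' are legal in float WAV but may clip on playback.
#'
#' @param samples numeric vector.
#' @param sample_rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav_float32 <- function(samples, sample_rate, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")              # IEEE float
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(round(sample_rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(sample_rate) * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

## format a double so it round-trips bit-exactly through text
fmt_double <- function(x) sprintf("%.17g", x)
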