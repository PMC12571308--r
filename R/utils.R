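# Shared numeric helpers: calibration, ramps, smoothing, seeds.

P_REF_PA <- 20e-6  # 0 dB SPL reference pressure, Pa

#' Convert a sound pressure level to an RMS pressure
#'
#' @param db_spl Level in dB SPL (RMS re 20 uPa).
#' @return RMS pressure in Pascals.
#' @export
db_spl_to_pa <- function(db_spl) P_REF_PA * 10^(db_spl / 20)

#' Convert an RMS pressure to a sound pressure level
#'
#' @param pa RMS pressure in Pascals (> 0).
#' @return Level in dB SPL.
#' @export
pa_to_db_spl <- function(pa) 20 * log10(pa / P_REF_PA)

#' Raised-cosine onset/offset envelope
#'
#' Envelope of ones with 10-ms (by default) raised-cosine flanks, the
#' standard gating used to avoid spectral splatter at sound on/offset.
#'
#' @param n Number of samples.
#' @param fs Sample rate (Hz).
#' @param ramp_dur Ramp duration in seconds (applied at both ends).
#' @return Numeric vector of length `n` in `[0, 1]`.
#' @export
cosine_ramp_envelope <- function(n, fs, ramp_dur = 0.01) {
  env <- rep(1, n)
  nr <- min(round(ramp_dur * fs), floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- ramp
    env[n - nr + seq_len(nr)] <- rev(ramp)
  }
  env
}

apply_ramp <- function(x, fs, ramp_dur = 0.01) x * cosine_ramp_envelope(length(x), fs, ramp_dur)

# Scale x so its RMS equals the pressure of `level_db` dB SPL.
calibrate_rms <- function(x, level_db) {
  r <- sqrt(mean(x^2))
  if (r <= 0) stop("cannot calibrate a silent waveform")
  x * (db_spl_to_pa(level_db) / r)
}

#' Gaussian smoothing of a regularly sampled series
#'
#' Convolution with a Gaussian kernel truncated at +/- 4 sigma, with
#' reflective edge handling (so constants are preserved at the borders).
#'
#' @param x Numeric series.
#' @param sigma Kernel width in seconds.
#' @param dt Sample interval in seconds.
#' @return Smoothed series, same length as `x`.
#' @export
gaussian_smooth <- function(x, sigma, dt) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma / dt))
  if (half >= length(x)) half <- length(x) - 1L
  k <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  k <- k / sum(k)
  # reflective padding
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  stats::filter(xp, k, sides = 2)[half + seq_along(x)]
}

# |log2(f1/f2)|, the field's distance between frequencies.
octave_distance <- function(f1, f2) abs(log2(f1 / f2))

# Snap values to the nearest multiple of `step` (distance binning on
# floating-point frequency grids).
snap_to <- function(x, step = 0.05) round(x / step) * step

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(0)
  stats::sd(x) / sqrt(length(x))
}

# Magnitude of the analytic signal (discrete Hilbert envelope) via FFT.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Deterministic sub-seed from a parent seed and a stage label; keeps every
# stochastic stage on its own stream while staying within 32-bit range.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip1 <- function(x) {
  x[!is.na(x) & x > 1] <- 1
  x[!is.na(x) & x < -1] <- -1
  x
}
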