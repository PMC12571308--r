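# Mouse cochlear periphery: exact tonotopy / innervation / spontaneous-
# rate formulas, and a phenomenological auditory-nerve response simulator
# (gammatone filterbank -> rectify + compress -> envelope low-pass ->
# adaptation -> spontaneous + driven rate -> inhomogeneous Poisson).

#' Basilar-membrane position from characteristic frequency
#'
#' Mouse tonotopic map: `x = -56.5 + 82.5 * log10(CF)`, with `x` in
#' percent of basilar-membrane length from the apex and `CF` in kHz.
#'
#' @param cf_khz Characteristic frequency in kHz (> 0).
#' @return Position in percent from the apex.
#' @export
position_from_cf <- function(cf_khz) {
  if (any(cf_khz <= 0)) stop("characteristic frequency must be positive")
  -56.5 + 82.5 * log10(cf_khz)
}

#' Auditory-nerve fibers per inner hair cell
#'
#' Innervation-density polynomial `N = -0.0038 x^2 + 0.375 x + 7.9`,
#' where `x` is the IHC position in percent from the apex. Returned
#' real-valued; [build_cochlear_map()] rounds to the nearest integer.
#'
#' @param x Position in percent from the apex, in `[0, 100]`.
#' @return Real-valued fiber count per IHC.
#' @export
fibers_per_ihc <- function(x) {
  if (any(x < 0 | x > 100)) stop("position must lie in [0, 100] percent")
  -0.0038 * x^2 + 0.375 * x + 7.9
}

#' Spontaneous rate from the calcium-clearance time constant
#'
#' Power law `SR = 91.1 * tau_Ca^2.66`, `tau_Ca` in ms, `SR` in spikes/s.
#'
#' @param tau_ca Calcium-clearance time constant in ms (> 0).
#' @return Spontaneous rate in spikes/s.
#' @export
sr_from_tau <- function(tau_ca) {
  if (any(tau_ca <= 0)) stop("tau_Ca must be positive")
  91.1 * tau_ca^2.66
}

#' Inverse of the spontaneous-rate power law
#'
#' @param sr Spontaneous rate in spikes/s (> 0).
#' @return tau_Ca in ms such that [sr_from_tau()] returns `sr`.
#' @export
tau_from_sr <- function(sr) {
  if (any(sr <= 0)) stop("spontaneous rate must be positive")
  (sr / 91.1)^(1 / 2.66)
}

#' Build the cochlear map
#'
#' Characteristic frequencies tile the tonotopic axis at 12 IHCs per
#' octave from 5 kHz upward (40 IHCs for the default 5-50 kHz span);
#' positions follow [position_from_cf()], per-IHC fiber counts round
#' [fibers_per_ihc()] to the nearest integer, and per-fiber tau_Ca is
#' drawn log-uniformly over the interval mapping to spontaneous rates in
#' 0.5-95 spikes/s.
#'
#' @param cf_range_khz CF range in kHz (default `c(5, 50)`).
#' @param ihc_per_octave Tonotopic density (default 12).
#' @param sr_range Spontaneous-rate range in spikes/s (default `c(0.5, 95)`).
#' @param seed Integer seed for the tau_Ca draws.
#' @return A `cochlear_map` list: `ihc` data frame (`cf_khz`, `x_percent`,
#'   `n_fibers`) and `fibers` data frame (`fiber_id`, `ihc`, `cf_khz`,
#'   `tau_ca_ms`, `sr`).
#' @export
build_cochlear_map <- function(cf_range_khz = c(5, 50), ihc_per_octave = 12,
                               sr_range = c(0.5, 95), seed = 1L) {
  if (cf_range_khz[2] <= cf_range_khz[1] || any(cf_range_khz <= 0)) {
    stop("invalid CF range")
  }
  n_ihc <- floor(log2(cf_range_khz[2] / cf_range_khz[1]) * ihc_per_octave) + 1L
  cf <- cf_range_khz[1] * 2^((seq_len(n_ihc) - 1) / ihc_per_octave)
  x <- position_from_cf(cf)
  nf <- pmax(1L, as.integer(round(fibers_per_ihc(x))))
  tau_rng <- tau_from_sr(sr_range)
  fibers <- withr::with_seed(as.integer(seed), {
    tau <- exp(stats::runif(sum(nf), log(tau_rng[1]), log(tau_rng[2])))
    data.frame(fiber_id = seq_len(sum(nf)), ihc = rep(seq_len(n_ihc), nf),
               cf_khz = rep(cf, nf), tau_ca_ms = tau, sr = sr_from_tau(tau))
  })
  structure(list(
    ihc = data.frame(cf_khz = cf, x_percent = x, n_fibers = nf),
    fibers = fibers, cascade = "simplified"
  ), class = "cochlear_map")
}

#' @export
print.cochlear_map <- function(x, ...) {
  cat(sprintf("<cochlear_map> %d IHCs (%.3g-%.3g kHz), %d fibers, SR %.2g-%.2g sp/s, cascade = %s\n",
              nrow(x$ihc), min(x$ihc$cf_khz), max(x$ihc$cf_khz),
              nrow(x$fibers), min(x$fibers$sr), max(x$fibers$sr), x$cascade))
  invisible(x)
}

# 4th-order gammatone impulse response at CF (FIR, truncated when the
# envelope has decayed below 1e-4 of its peak).
gammatone_kernel <- function(cf_hz, fs, bw_hz = cf_hz / 8) {
  t_max <- min(0.025, 3 / bw_hz)
  t <- seq(0, t_max, by = 1 / fs)
  k <- t^3 * exp(-2 * pi * bw_hz * t) * cos(2 * pi * cf_hz * t)
  k / sqrt(sum(k^2))
}

#' Simulate auditory-nerve fiber spike trains
#'
#' Phenomenological response chain per fiber: gammatone band-pass at the
#' fiber's CF, half-wave rectification with power-law compression
#' (exponent 0.4), one-pole envelope low-pass (tau 1 ms), divisive
#' exponential adaptation (tau 100 ms), a saturating driven rate added to
#' the fiber's spontaneous rate, and inhomogeneous Poisson spike
#' generation in 1-ms bins. This is a deliberately simplified stand-in
#' for detailed biophysical cascade models; it reproduces tonotopic
#' band-pass selectivity, adaptation and spontaneous activity but not
#' two-tone suppression or middle-ear filtering.
#'
#' @param map A `cochlear_map`.
#' @param waveform Pressure waveform in Pascals with a `sample_rate`
#'   attribute (or pass `fs`).
#' @param seed Integer seed for the Poisson draws.
#' @param fs Sample rate override in Hz.
#' @param max_driven_rate Saturated driven rate in spikes/s (default 250).
#' @param c50_db Input level (dB SPL per-channel envelope) at half
#'   saturation (default 40).
#' @param pad_s Silence appended after the stimulus in seconds (default 0.1).
#' @return Data frame of spikes: `fiber_id`, `spike_time_s`.
#' @export
simulate_anf_responses <- function(map, waveform, seed = 1L,
                                   fs = attr(waveform, "sample_rate"),
                                   max_driven_rate = 250, c50_db = 40,
                                   pad_s = 0.1) {
  stopifnot(inherits(map, "cochlear_map"), !is.null(fs))
  if (max(map$ihc$cf_khz) * 1000 * 2 > fs) {
    stop("waveform sample rate violates Nyquist for the map's highest CF")
  }
  x <- c(as.numeric(waveform), numeric(round(pad_s * fs)))
  bin_w <- 0.001
  n_bins <- floor(length(x) / fs / bin_w)
  dec <- round(bin_w * fs)
  c50 <- db_spl_to_pa(c50_db)^0.4
  rates <- matrix(0, nrow(map$ihc), n_bins)   # driven rate per IHC channel
  for (i in seq_len(nrow(map$ihc))) {
    k <- gammatone_kernel(map$ihc$cf_khz[i] * 1000, fs)
    y <- stats::convolve(x, rev(k), type = "open")[seq_along(x)]
    env <- pmax(y, 0)^0.4
    a1 <- exp(-1 / (fs * 0.001))
    env <- stats::filter(env * (1 - a1), a1, method = "recursive")
    slow <- stats::filter(env * (1 - exp(-1 / (fs * 0.1))),
                          exp(-1 / (fs * 0.1)), method = "recursive")
    env <- env / (1 + as.numeric(slow) / c50)   # adaptation
    env_b <- colMeans(matrix(env[seq_len(n_bins * dec)], dec, n_bins))
    rates[i, ] <- max_driven_rate * env_b / (env_b + c50)
  }
  withr::with_seed(as.integer(seed), {
    out <- vector("list", nrow(map$fibers))
    for (fi in seq_len(nrow(map$fibers))) {
      lam <- (map$fibers$sr[fi] + rates[map$fibers$ihc[fi], ]) * bin_w
      counts <- stats::rpois(n_bins, lam)
      times <- rep((seq_len(n_bins) - 0.5) * bin_w, counts)
      out[[fi]] <- if (length(times)) {
        data.frame(fiber_id = map$fibers$fiber_id[fi], spike_time_s = times)
      } else NULL
    }
    do.call(rbind, out)
  })
}

#' Export a cochlear map as CSV
#'
#' @param map A `cochlear_map`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cochlear_map <- function(map, path) {
  utils::write.csv(map$fibers, path, row.names = FALSE)
  invisible(path)
}
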