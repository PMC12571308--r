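# Waveform synthesis for every catalog category, plus the component
# programs behind the complex-sound surrogates.
#
# Conventions: waveforms are pressure in Pascals; every stimulus carries
# 10-ms raised-cosine on/off ramps; levels are RMS dB SPL re 20 uPa and
# calibration is applied to the final (ramped) waveform so the measured
# RMS matches the target exactly. Intensity-ramped stimuli instead follow
# a linear-in-dB level trajectory and are not globally recalibrated.

khz <- function(f) f * 1000

# Exponential (log-frequency) sweep f0 -> f1 over dur; unit amplitude.
sweep_wave <- function(f0_khz, f1_khz, dur, fs, phase = 0) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  f0 <- khz(f0_khz); f1 <- khz(f1_khz)
  if (abs(f1 - f0) < 1e-9) return(sin(2 * pi * f0 * t + phase))
  k <- log(f1 / f0) / dur
  ph <- 2 * pi * f0 * (exp(k * t) - 1) / k
  sin(ph + phase)
}

tone_wave <- function(f_khz, dur, fs, phase = 0) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  sin(2 * pi * khz(f_khz) * t + phase)
}

# Band-limited Gaussian noise, unit RMS. 8th-order Butterworth band-pass
# realised as order-4 forward-backward filtering (zero phase).
band_noise_wave <- function(f_lo_khz, f_hi_khz, dur, fs, noise_seed) {
  n <- round(dur * fs)
  x <- withr::with_seed(noise_seed, stats::rnorm(n))
  w <- c(khz(f_lo_khz), min(khz(f_hi_khz), fs / 2 * 0.98)) / (fs / 2)
  bf <- signal::butter(4, w, type = "pass")
  y <- signal::filtfilt(bf, x)
  y / sqrt(mean(y^2))
}

# Level trajectory linear in dB between two SPLs; returns pressure envelope.
db_ramp_envelope <- function(level_start, level_end, n) {
  db_spl_to_pa(level_start + (level_end - level_start) * (seq_len(n) - 1) / (n - 1))
}

# --- complex-surrogate component synthesis ------------------------------

# A 2-ms damped-sinusoid click at the band centre.
click_kernel <- function(fc_khz, fs) {
  t <- (seq_len(round(0.002 * fs)) - 1) / fs
  exp(-t / 4e-4) * sin(2 * pi * khz(fc_khz) * t)
}

synth_component <- function(comp, fs) {
  n <- round(comp$dur * fs)
  y <- switch(comp$type,
    chirp = ,
    fm_tone = sweep_wave(comp$f0_khz, comp$f1_khz, comp$dur, fs),
    tone = tone_wave(comp$f_khz, comp$dur, fs),
    band_noise = {
      x <- band_noise_wave(comp$f_lo_khz, comp$f_hi_khz, comp$dur, fs, comp$noise_seed)
      if (!is.null(comp$ramp_db)) {
        x * 10^((comp$ramp_db[1] + diff(comp$ramp_db) *
                   (seq_len(n) - 1) / (n - 1)) / 20)
      } else x
    },
    click_train = {
      fc <- sqrt(comp$f_lo_khz * comp$f_hi_khz)
      kern <- click_kernel(fc, fs)
      y <- numeric(n)
      at <- round(seq(0, comp$dur - 0.002, by = 1 / comp$rate_hz) * fs) + 1
      for (a in at) {
        idx <- a:min(n, a + length(kern) - 1)
        y[idx] <- y[idx] + kern[seq_along(idx)]
      }
      y
    },
    chirp_train = {
      el_dur <- min(0.008, 0.8 / comp$rate_hz)
      kern <- apply_ramp(sweep_wave(comp$f0_khz, comp$f1_khz, el_dur, fs), fs, 0.002)
      y <- numeric(n)
      at <- round(seq(0, comp$dur - el_dur, by = 1 / comp$rate_hz) * fs) + 1
      for (a in at) {
        idx <- a:min(n, a + length(kern) - 1)
        y[idx] <- y[idx] + kern[seq_along(idx)]
      }
      y
    },
    stop("unknown component type: ", comp$type)
  )
  length(y) <- n
  y[is.na(y)] <- 0
  comp$amp * apply_ramp(y, fs, min(0.01, comp$dur / 4))
}

# Sum individually ramped components at their onsets on a fixed grid.
synth_program <- function(components, fs, duration) {
  n <- round(duration * fs)
  y <- numeric(n)
  for (comp in components) {
    w <- synth_component(comp, fs)
    a <- round(comp$onset * fs) + 1
    idx <- a:min(n, a + length(w) - 1)
    y[idx] <- y[idx] + w[seq_along(idx)]
  }
  y
}

component_freqs <- function(comp) {
  switch(comp$type,
    chirp = , fm_tone = sqrt(comp$f0_khz * comp$f1_khz),
    tone = comp$f_khz,
    band_noise = , click_train = sqrt(comp$f_lo_khz * comp$f_hi_khz),
    chirp_train = sqrt(comp$f0_khz * comp$f1_khz)
  )
}

cmp <- function(type, onset, dur, amp = 1, ...) {
  c(list(type = type, onset = onset, dur = dur, amp = amp), list(...))
}

# Fixed component programs for the four decomposable parent identities:
# a ramped-noise "environment" scene, two "bird call" sequences (fast
# chirps, click trains, chirp trains), and a "dolphin call" (chirps,
# clicks, harmonic stack swept down 0.7 octave). Component counts
# 5 / 10 / 13 / 15 so that components + 4 reconstructions total 47.
fixed_programs <- function(seed) {
  ns <- function(tag) derive_seed(seed, paste0("fixedprog_", tag))
  env <- {
    centers <- c(2.5, 4, 6, 8.5, 11)
    lapply(seq_along(centers), function(k) {
      fc <- centers[k]
      cmp("band_noise", onset = (k - 1) * 0.1, dur = 0.1,
          f_lo_khz = fc * 2^(-0.25), f_hi_khz = fc * 2^(0.25),
          ramp_db = c(-20, 0), noise_seed = ns(paste0("env", k)))
    })
  }
  bird1_seq <- list(
    cmp("chirp", 0.00, 0.03, f0_khz = 3, f1_khz = 9),
    cmp("chirp", 0.04, 0.03, f0_khz = 4, f1_khz = 10),
    cmp("click_train", 0.08, 0.06, rate_hz = 120, f_lo_khz = 4, f_hi_khz = 12),
    cmp("click_train", 0.15, 0.06, rate_hz = 90, f_lo_khz = 6, f_hi_khz = 14),
    cmp("chirp_train", 0.21, 0.04, rate_hz = 55, f0_khz = 5, f1_khz = 11)
  )
  bird1 <- c(bird1_seq, lapply(bird1_seq, function(co) { co$onset <- co$onset + 0.25; co }))
  bird2 <- list(
    cmp("chirp", 0.00, 0.025, f0_khz = 2.5, f1_khz = 8),
    cmp("chirp", 0.03, 0.025, f0_khz = 3.5, f1_khz = 9),
    cmp("chirp", 0.06, 0.025, f0_khz = 5, f1_khz = 12),
    cmp("chirp", 0.09, 0.025, f0_khz = 6, f1_khz = 14),
    cmp("click_train", 0.12, 0.05, rate_hz = 110, f_lo_khz = 3, f_hi_khz = 10),
    cmp("chirp_train", 0.18, 0.05, rate_hz = 44, f0_khz = 4, f1_khz = 9),
    cmp("click_train", 0.24, 0.05, rate_hz = 95, f_lo_khz = 5, f_hi_khz = 13),
    cmp("chirp_train", 0.30, 0.05, rate_hz = 44, f0_khz = 5, f1_khz = 11),
    cmp("click_train", 0.36, 0.05, rate_hz = 80, f_lo_khz = 4, f_hi_khz = 12),
    cmp("chirp", 0.42, 0.02, f0_khz = 3, f1_khz = 8),
    cmp("chirp", 0.445, 0.02, f0_khz = 4, f1_khz = 10),
    cmp("click_train", 0.465, 0.02, rate_hz = 150, f_lo_khz = 4, f_hi_khz = 12),
    cmp("chirp_train", 0.475, 0.025, rate_hz = 44, f0_khz = 4.5, f1_khz = 10)
  )
  dolphin_half <- function(t0, with_clicks) {
    out <- list(
      cmp("chirp", t0, 0.015, f0_khz = 6, f1_khz = 20),
      cmp("chirp", t0 + 0.02, 0.015, f0_khz = 8, f1_khz = 24)
    )
    if (with_clicks) {
      out <- c(out, list(cmp("click_train", t0 + 0.04, 0.04, rate_hz = 200,
                             f_lo_khz = 8.1, f_hi_khz = 16)))
    }
    harm <- lapply(1:5, function(h) {
      f <- 11.6 * h
      cmp("fm_tone", t0 + 0.05 + if (with_clicks) 0.0 else 0.0, 0.2,
          amp = 1 / h, f0_khz = f, f1_khz = f * 2^(-0.7))
    })
    c(out, harm)
  }
  dolphin <- c(dolphin_half(0, TRUE), dolphin_half(0.25, FALSE))  # 8 + 7 = 15
  list(env, bird1, bird2, dolphin)
}

#' Generate complex-sound surrogate component programs
#'
#' Builds `n_identities` synthetic "complex sound" programs, each a list of
#' parameterised components (chirps, click trains, chirp trains, band
#' noises, harmonic FM stacks) with stored onset times. The first four
#' identities use fixed decomposable programs whose components also appear
#' individually in the catalog's decomposition category; the rest are
#' seeded random mixtures. Component amplitudes are baked in so that the
#' summed forward program measures exactly 70 dB SPL, making each
#' reconstruction sample-wise identical to the sum of its components.
#'
#' @param n_identities Number of surrogate identities (>= 1).
#' @param seed Integer seed.
#' @param fs Sample rate in Hz used for calibration.
#' @param duration Total duration of each surrogate in seconds.
#' @return List of programs; each has `components` (with absolute `amp`
#'   and per-component `level_db`) and `freq_content_khz`.
#' @export
make_complex_surrogates <- function(n_identities, seed = 1L, fs = 192000,
                                    duration = 0.5) {
  stopifnot(n_identities >= 1)
  fixed <- fixed_programs(seed)
  programs <- vector("list", n_identities)
  for (i in seq_len(n_identities)) {
    comps <- if (i <= 4) fixed[[i]] else {
      withr::with_seed(derive_seed(seed, paste0("cx", i)), {
        nc <- sample(4:8, 1)
        onsets <- sort(stats::runif(nc, 0, duration - 0.08))
        onsets[1] <- 0
        lapply(seq_len(nc), function(k) {
          ty <- sample(c("chirp", "click_train", "band_noise", "tone"), 1)
          d <- stats::runif(1, 0.04, 0.15)
          d <- min(d, duration - onsets[k])
          a <- stats::runif(1, 0.5, 1)
          f1 <- stats::runif(1, 2, 20); f2 <- f1 * 2^stats::runif(1, 0.5, 1.5)
          switch(ty,
            chirp = cmp("chirp", onsets[k], d, a, f0_khz = f1, f1_khz = f2),
            tone = cmp("tone", onsets[k], d, a, f_khz = f1),
            click_train = cmp("click_train", onsets[k], d, a,
                              rate_hz = stats::runif(1, 60, 180),
                              f_lo_khz = f1, f_hi_khz = f2),
            band_noise = cmp("band_noise", onsets[k], d, a, f_lo_khz = f1,
                             f_hi_khz = f2,
                             noise_seed = derive_seed(seed, paste0("cxn", i, "_", k)))
          )
        })
      })
    }
    # calibrate the summed program to 70 dB SPL and bake into amplitudes
    y <- synth_program(comps, fs, duration)
    scale <- db_spl_to_pa(70) / sqrt(mean(y^2))
    comps <- lapply(comps, function(co) {
      co$amp <- co$amp * scale
      w <- synth_component(co, fs)
      co$level_db <- pa_to_db_spl(sqrt(mean(w^2)))
      co
    })
    programs[[i]] <- list(
      components = comps,
      freq_content_khz = sort(unique(round(vapply(comps, component_freqs, 0), 3)))
    )
  }
  programs
}

#' Synthesize a stimulus waveform
#'
#' Renders one catalog entry as a pressure waveform (Pascals) at the
#' stimulus sample rate, with 10-ms raised-cosine gating and RMS
#' calibration to the stimulus level. Chords sum per-component-calibrated
#' tones (each component at the stated level); intensity-ramped stimuli
#' follow a linear-in-dB trajectory between their start and end levels.
#'
#' @param stim A stimulus as returned by [catalog_stimulus()], or a
#'   single-row slice of a `stimulus_catalog`.
#' @param fs Optional sample-rate override in Hz.
#' @return Numeric waveform with attributes `sample_rate` and `sound_id`.
#' @export
synthesize <- function(stim, fs = NULL) {
  if (is.data.frame(stim)) {
    stopifnot(nrow(stim) == 1)
    stim <- list(sound_id = stim$sound_id, category = stim$category,
                 duration = stim$duration, level = stim$level,
                 sample_rate = stim$sample_rate, params = stim$params[[1]])
  }
  fs <- fs %||% stim$sample_rate
  pr <- stim$params
  for (nm in c("freq_khz", "f_lo_khz", "f_hi_khz")) {
    if (!is.null(pr[[nm]]) && !all(is.finite(pr[[nm]]))) {
      stop("non-finite parameter ", nm, " in ", stim$sound_id)
    }
  }
  top_khz <- suppressWarnings(max(unlist(pr[c("freq_khz", "freqs_khz", "f_hi_khz")]),
                                  0, na.rm = TRUE))
  if (top_khz * 1000 * 2 > fs) {
    stop("Nyquist violation: ", top_khz, " kHz content at fs = ", fs, " Hz")
  }
  n <- round(stim$duration * fs)
  y <- switch(stim$category,
    pure_tone = calibrate_rms(apply_ramp(tone_wave(pr$freq_khz, stim$duration, fs), fs),
                              stim$level),
    ramp = {
      x <- tone_wave(pr$freq_khz, stim$duration, fs)
      apply_ramp(x * sqrt(2) * db_ramp_envelope(pr$level_start, pr$level_end, n), fs)
    },
    chord = {
      x <- 0
      for (k in seq_along(pr$freqs_khz)) {
        x <- x + tone_wave(pr$freqs_khz[k], stim$duration, fs, phase = pr$phases[k])
      }
      # each of the k components at the stated level: total is level + 10 log10(k)
      calibrate_rms(apply_ramp(x, fs),
                    stim$level + 10 * log10(length(pr$freqs_khz)))
    },
    chirp = {
      up <- sweep_wave(pr$f_lo_khz, pr$f_hi_khz, stim$duration, fs)
      x <- if (pr$direction == "down") rev(up) else up
      calibrate_rms(apply_ramp(x, fs), stim$level)
    },
    noise = synth_noise(stim, pr, fs, n),
    am = {
      carr <- pr$carrier
      x <- switch(carr$type,
        tone = tone_wave(carr$freqs_khz, stim$duration, fs),
        chord = Reduce(`+`, lapply(seq_along(carr$freqs_khz), function(k)
          tone_wave(carr$freqs_khz[k], stim$duration, fs, phase = k))),
        noise = band_noise_wave(carr$f_lo_khz, carr$f_hi_khz, stim$duration, fs,
                                pr$noise_seed)
      )
      t <- (seq_len(n) - 1) / fs
      m <- (1 - cos(2 * pi * pr$fm_hz * t)) / 2   # 100% depth, zero phase at onset
      calibrate_rms(apply_ramp(x * m, fs), stim$level)
    },
    complex = {
      y <- synth_program(pr$components, fs, stim$duration)
      if (stim$level != pr$ref_level) y <- y * 10^((stim$level - pr$ref_level) / 20)
      if (pr$direction == "reversed") y <- rev(y)
      y
    },
    decomposition = {
      if (identical(pr$role, "component")) synth_component(pr$component, fs)
      else synth_program(pr$components, fs, stim$duration)
    },
    stop("unknown category: ", stim$category)
  )
  structure(y, sample_rate = fs, sound_id = stim$sound_id)
}

synth_noise <- function(stim, pr, fs, n) {
  switch(pr$kind,
    broadband = ,
    band = calibrate_rms(
      apply_ramp(band_noise_wave(pr$f_lo_khz, pr$f_hi_khz, stim$duration, fs,
                                 pr$noise_seed), fs),
      stim$level),
    broadband_ramped = {
      x <- band_noise_wave(pr$f_lo_khz, pr$f_hi_khz, stim$duration, fs, pr$noise_seed)
      apply_ramp(x * db_ramp_envelope(pr$level_start, pr$level_end, n), fs)
    },
    dual_ramped = {
      env <- db_ramp_envelope(pr$level_start, pr$level_end, n)
      x <- 0
      for (k in seq_along(pr$centers_khz)) {
        fc <- pr$centers_khz[k]
        b <- band_noise_wave(fc - pr$band_hw_khz, fc + pr$band_hw_khz,
                             stim$duration, fs, pr$noise_seed + k)
        x <- x + b * env / sqrt(2)   # two bands sum to the trajectory level
      }
      apply_ramp(x, fs)
    },
    stop("unknown noise kind: ", pr$kind)
  )
}

#' Write a waveform as a 32-bit float WAV file
#'
#' Minimal RIFF/WAVE writer (IEEE float, mono) for exporting synthesized
#' stimuli; values are written as-is (Pascals).
#'
#' @param wave Numeric waveform with a `sample_rate` attribute (or pass `fs`).
#' @param path Output path.
#' @param fs Sample rate override in Hz.
#' @return Invisibly, the path.
#' @export
write_wav <- function(wave, path, fs = attr(wave, "sample_rate")) {
  stopifnot(!is.null(fs))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(wave)
  data_bytes <- n * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")              # IEEE float
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(wave), con, size = 4, endian = "little")
  invisible(path)
}
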