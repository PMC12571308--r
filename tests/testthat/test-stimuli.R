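# Catalog structure and waveform synthesis.

test_that("default catalog reproduces the protocol's category counts", {
  cat0 <- catalog_default()
  counts <- catalog_counts(cat0)
  expect_equal(unname(counts[c("pure_tone", "ramp", "chord", "chirp", "noise",
                               "am", "complex", "decomposition")]),
               c(28L, 26L, 48L, 20L, 30L, 48L, 60L, 47L), ignore_attr = TRUE)
  expect_equal(nrow(cat0), 307L)
  expect_false(anyDuplicated(cat0$sound_id) > 0)
  expect_equal(attr(cat0, "trials_per_sound"), 12)
  # AM grid: 8 carriers x 6 modulation frequencies
  am <- cat0[cat0$category == "am", ]
  expect_equal(length(unique(vapply(am$params, `[[`, 0, "carrier_index"))), 8L)
  expect_equal(length(unique(vapply(am$params, `[[`, 0, "fm_hz"))), 6L)
})

test_that("catalog construction is deterministic under a fixed seed", {
  a <- build_catalog(seed = 42L)
  b <- build_catalog(seed = 42L)
  expect_identical(a$sound_id, b$sound_id)
  expect_identical(a$params, b$params)
  # waveforms too (noise realisations are seed-locked)
  id <- "noise_band_bw1.0oct"
  expect_identical(as.numeric(synthesize(catalog_stimulus(a, id))),
                   as.numeric(synthesize(catalog_stimulus(b, id))))
})

test_that("RMS calibration is exact for constant-level stimuli", {
  cat0 <- catalog_default()
  for (id in c("tone_2k_50dB", "tone_60k_70dB", "chirp_6-12k_100ms_up",
               "noise_broad_70dB", "am_c01_fm4Hz", "complex_03_for_50dB")) {
    st <- catalog_stimulus(cat0, id)
    w <- synthesize(st)
    expect_lt(abs(rms_db(w) - st$level), 0.1, label = paste("RMS error for", id))
  }
  # chords: each of k components at the stated level -> total level + 10 log10 k
  ch <- catalog_stimulus(cat0, "chord_low_11")
  w <- synthesize(ch)
  expect_lt(abs(rms_db(w) - (70 + 10 * log10(length(ch$params$freqs_khz)))), 0.1)
})

test_that("waveforms carry 10-ms raised-cosine ramps and correct length", {
  st <- catalog_stimulus(catalog_default(), "tone_9.611k_70dB")
  w <- synthesize(st)
  fs <- attr(w, "sample_rate")
  expect_equal(length(w), round(st$duration * fs))
  env <- cosine_ramp_envelope(length(w), fs)
  nr <- round(0.01 * fs)
  # waveform amplitude tracks the ramp over the onset
  peak_in_ramp <- max(abs(w[1:nr]))
  peak_overall <- max(abs(w))
  expect_lt(peak_in_ramp, peak_overall)
  expect_equal(w[1], 0)
  expect_lt(abs(w[length(w)]), 1e-6 * peak_overall)
})

test_that("intensity ramps follow a linear-in-dB trajectory", {
  st <- catalog_stimulus(catalog_default(), "ramp_2k_up")
  w <- as.numeric(synthesize(st))
  fs <- st$sample_rate
  seg_db <- function(t0, t1) pa_to_db_spl(sqrt(mean(w[round(t0 * fs):round(t1 * fs)]^2)))
  lvl_mid <- seg_db(0.24, 0.26)   # halfway: 60 dB
  expect_lt(abs(lvl_mid - 60), 0.5)
  expect_gt(seg_db(0.4, 0.45), seg_db(0.05, 0.1))   # rising
})

test_that("AM envelope completes fm x duration modulation periods", {
  st <- catalog_stimulus(catalog_default(), "am_c01_fm4Hz")
  w <- as.numeric(synthesize(st))
  fs <- st$sample_rate
  env <- analytic_envelope(w)
  core <- env[round(0.02 * fs):round(0.48 * fs)]     # exclude gating ramps
  peaks <- sum(diff(sign(diff(core))) == -2)
  expect_equal(peaks, 2L)  # 4 Hz x 0.5 s = 2 periods
})

test_that("down-chirps are exact time reversals of their up counterpart", {
  cat0 <- catalog_default()
  wu <- as.numeric(synthesize(catalog_stimulus(cat0, "chirp_4-50k_up")))
  wd <- as.numeric(synthesize(catalog_stimulus(cat0, "chirp_4-50k_down")))
  expect_equal(wd, rev(wu), tolerance = 1e-12)
})

test_that("spectral energy stays inside the stimulus band", {
  st <- catalog_stimulus(catalog_default(), "tone_2k_70dB")
  w <- as.numeric(synthesize(st))
  fs <- st$sample_rate
  sp <- Mod(stats::fft(w))[1:(length(w) / 2)]
  fgrid <- (seq_along(sp) - 1) * fs / length(w)
  inband <- max(sp[fgrid > 1500 & fgrid < 2500])
  above <- max(sp[fgrid > 4000])   # an octave above the tone
  expect_lt(20 * log10(above / inband), -60)
})

test_that("complex surrogates reconstruct exactly from their components", {
  cat0 <- catalog_default()
  for (parent in c(1L, 4L)) {
    recon <- catalog_stimulus(cat0, sprintf("dec_p%d_recon", parent))
    w_recon <- as.numeric(synthesize(recon))
    comps <- cat0[cat0$category == "decomposition" &
                    vapply(cat0$params, function(p) identical(p$parent, parent) &&
                             identical(p$role, "component"), TRUE), ]
    fs <- recon$sample_rate
    acc <- numeric(length(w_recon))
    for (k in seq_len(nrow(comps))) {
      wk <- as.numeric(synthesize(comps[k, ]))
      a <- round(comps$params[[k]]$onset_s * fs) + 1
      idx <- a:min(length(acc), a + length(wk) - 1)
      acc[idx] <- acc[idx] + wk[seq_along(idx)]
    }
    expect_equal(acc, w_recon, tolerance = 1e-12)
    # and the reconstruction is the forward 70-dB complex sound itself
    w_cx <- as.numeric(synthesize(
      catalog_stimulus(cat0, sprintf("complex_%02d_for_70dB", parent))))
    expect_equal(w_recon, w_cx, tolerance = 1e-12)
  }
})

test_that("reversed complex variants are time-reversed waveforms", {
  cat0 <- catalog_default()
  wf <- as.numeric(synthesize(catalog_stimulus(cat0, "complex_07_for_70dB")))
  wr <- as.numeric(synthesize(catalog_stimulus(cat0, "complex_07_rev_70dB")))
  expect_equal(wr, rev(wf), tolerance = 1e-12)
})

test_that("15 identities expand to 60 complex catalog entries", {
  cx <- catalog_subset("complex")
  expect_equal(nrow(cx), 60L)
  expect_equal(length(unique(vapply(cx$params, `[[`, 0, "identity"))), 15L)
})

test_that("Nyquist violations and invalid parameters error", {
  proto <- default_protocol(sample_rate = 44100)
  expect_error(build_catalog(proto), "Nyquist")
  st <- catalog_stimulus(catalog_default(), "tone_2k_50dB")
  st$params$freq_khz <- NaN
  expect_error(synthesize(st), "non-finite")
})

test_that("catalog round-trips through CSV with JSON params", {
  path <- tempfile(fileext = ".csv")
  cat0 <- catalog_default()
  write_catalog(cat0, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 307L)
  p <- jsonlite::fromJSON(df$params[df$sound_id == "tone_2k_50dB"])
  expect_equal(p$freq_khz, 2)
})
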