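# Stimulus catalog: enumeration of the 307-sound battery.
#
# Eight categories: pure tones, intensity ramps, chords, chirps, colored
# noises, amplitude-modulated sounds, complex-sound surrogates, and
# decomposition components/reconstructions. Counts per category are fixed
# by the experimental protocol: 28 / 26 / 48 / 20 / 30 / 48 / 60 / 47 = 307.

#' Default stimulus protocol configuration
#'
#' Returns the parameter map defining the default 307-sound battery:
#' the 14-tone log-spaced frequency grid (2--60 kHz), the two presentation
#' levels (50/70 dB SPL), the chord pools, chirp families, noise bands,
#' AM carrier/modulation grids and the complex-surrogate counts.
#'
#' @param sample_rate Playback rate in Hz (default 192000).
#' @return Named list of protocol parameters.
#' @export
default_protocol <- function(sample_rate = 192000) {
  tone_freqs <- 2 * (60 / 2)^((0:13) / 13)  # kHz, log-spaced incl. endpoints
  list(
    sample_rate = sample_rate,
    trials_per_sound = 12,
    inter_onset = 1.0,
    levels = c(50, 70),
    tone_freqs_khz = tone_freqs,
    tone_dur = 0.2,
    ramp_freqs_khz = tone_freqs[1:13],   # the 13 grid tones between 2 and 50 kHz
    ramp_dur = 0.5,
    chord_dur = 0.2,
    chord_pools = list(
      low = c(2, 4, 5, 8), mid = c(10, 12, 16, 20),
      high = c(25, 32, 40, 50), broad = c(6, 12, 20, 40),
      harmonic = c(4, 8, 12, 16)
    ),
    chirp_durs = c(0.025, 0.05, 0.1, 0.2, 0.4),   # 6-12 kHz family
    chirp_ranges = list(c(4, 8), c(4, 16), c(4, 32), c(8, 50), c(4, 50)),
    chirp_range_dur = 0.5,
    noise_dur = 0.5,
    noise_band_limits = c(2, 80),                  # kHz
    noise_bandwidths_oct = seq(0.5, 4.5, by = 0.5),
    noise_narrow_centers = c(4, 8, 16, 32, 56.57),
    noise_pair_centers = list(c(6, 12), c(6, 20), c(6, 40), c(12, 20), c(12, 40)),
    am_dur = 0.5,
    am_mod_freqs = 4 * (160 / 4)^((0:5) / 5),      # Hz, log-spaced 4-160
    n_complex = 15,
    complex_dur = 0.5
  )
}

chord_subsets <- function(freqs, sizes) {
  out <- list()
  for (k in sizes) {
    cm <- utils::combn(freqs, k, simplify = FALSE)
    out <- c(out, cm)
  }
  out
}

new_stimulus_row <- function(sound_id, category, duration, level, fs, params) {
  data.frame(
    sound_id = sound_id, category = category, duration = duration,
    level = level, sample_rate = fs,
    params = I(list(params)), stringsAsFactors = FALSE
  )
}

fmt_khz <- function(f) as.character(signif(f, 4))

#' Build the default stimulus catalog
#'
#' Enumerates the full sound battery as a data frame with one row per
#' stimulus. The `params` list-column carries the category-specific
#' synthesis parameters (frequencies in kHz, modulation rates in Hz,
#' direction, component programs for complex surrogates) so that
#' [synthesize()] is self-contained.
#'
#' @param protocol Protocol configuration, see [default_protocol()].
#' @param seed Integer seed controlling chord phases, noise realisations
#'   and the complex-surrogate component programs.
#' @return A `stimulus_catalog` data frame (307 rows for the default
#'   protocol) with attributes `trials_per_sound` and `inter_onset`.
#' @export
build_catalog <- function(protocol = default_protocol(), seed = 1L) {
  p <- protocol
  fs <- p$sample_rate
  max_khz <- max(p$noise_band_limits[2], max(p$tone_freqs_khz))
  if (fs < 2 * max_khz * 1000) {
    stop("sample rate ", fs, " Hz violates the Nyquist constraint for ",
         max_khz, " kHz content")
  }
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  ## -- pure tones: 14 freqs x 2 levels = 28 ------------------------------
  for (f in p$tone_freqs_khz) for (lv in p$levels) {
    add(new_stimulus_row(
      sprintf("tone_%sk_%ddB", fmt_khz(f), lv), "pure_tone", p$tone_dur, lv, fs,
      list(freq_khz = f, freq_content_khz = f)
    ))
  }

  ## -- intensity ramps: 13 freqs x {up, down} = 26 -----------------------
  for (f in p$ramp_freqs_khz) for (dir in c("up", "down")) {
    lv <- if (dir == "up") c(50, 70) else c(70, 50)
    add(new_stimulus_row(
      sprintf("ramp_%sk_%s", fmt_khz(f), dir), "ramp", p$ramp_dur, mean(lv), fs,
      list(freq_khz = f, direction = dir, level_start = lv[1], level_end = lv[2],
           freq_content_khz = f)
    ))
  }

  ## -- chords: 11 + 11 + 11 + 10 + 5 = 48 --------------------------------
  pool_sets <- list(
    low = chord_subsets(p$chord_pools$low, 2:4),
    mid = chord_subsets(p$chord_pools$mid, 2:4),
    high = chord_subsets(p$chord_pools$high, 2:4),
    broad = chord_subsets(p$chord_pools$broad, 2:3),
    harmonic = {
      h <- p$chord_pools$harmonic
      list(h[c(1, 2)], h[c(2, 4)], h[1:3], h[2:4], h[1:4])
    }
  )
  phase_rng <- derive_seed(seed, "chord_phases")
  ph_i <- 0L
  for (pool in names(pool_sets)) {
    for (k in seq_along(pool_sets[[pool]])) {
      freqs <- pool_sets[[pool]][[k]]
      ph_i <- ph_i + 1L
      phases <- withr::with_seed(phase_rng + ph_i, stats::runif(length(freqs), 0, 2 * pi))
      add(new_stimulus_row(
        sprintf("chord_%s_%02d", pool, k), "chord", p$chord_dur, 70, fs,
        list(freqs_khz = freqs, phases = phases, pool = pool,
             freq_content_khz = freqs)
      ))
    }
  }

  ## -- chirps: 5 durations x 2 dirs + 5 ranges x 2 dirs = 20 -------------
  for (d in p$chirp_durs) for (dir in c("up", "down")) {
    add(new_stimulus_row(
      sprintf("chirp_6-12k_%dms_%s", round(d * 1000), dir), "chirp", d, 50, fs,
      list(f_lo_khz = 6, f_hi_khz = 12, direction = dir, family = "duration",
           freq_content_khz = 6 * 2^(log2(12 / 6) * (0:4) / 4))
    ))
  }
  for (rg in p$chirp_ranges) for (dir in c("up", "down")) {
    add(new_stimulus_row(
      sprintf("chirp_%s-%sk_%s", fmt_khz(rg[1]), fmt_khz(rg[2]), dir), "chirp",
      p$chirp_range_dur, 50, fs,
      list(f_lo_khz = rg[1], f_hi_khz = rg[2], direction = dir, family = "range",
           freq_content_khz = rg[1] * 2^(log2(rg[2] / rg[1]) * (0:4) / 4))
    ))
  }

  ## -- noises: 6 broadband + 14 band-filtered + 10 dual ramped = 30 ------
  bl <- p$noise_band_limits
  bb_content <- bl[1] * (bl[2] / bl[1])^((0:4) / 4)
  nz_i <- 0L
  nz_seed <- function() { nz_i <<- nz_i + 1L; derive_seed(seed, paste0("noise", nz_i)) }
  for (lv in p$levels) {
    add(new_stimulus_row(
      sprintf("noise_broad_%ddB", lv), "noise", p$noise_dur, lv, fs,
      list(kind = "broadband", f_lo_khz = bl[1], f_hi_khz = bl[2],
           noise_seed = nz_seed(), freq_content_khz = bb_content)
    ))
  }
  for (d in c(0.1, 0.5)) for (dir in c("up", "down")) {
    lv <- if (dir == "up") c(50, 70) else c(70, 50)
    add(new_stimulus_row(
      sprintf("noise_broad_%s_%dms", dir, round(d * 1000)), "noise", d, mean(lv), fs,
      list(kind = "broadband_ramped", f_lo_khz = bl[1], f_hi_khz = bl[2],
           direction = dir, level_start = lv[1], level_end = lv[2],
           noise_seed = nz_seed(), freq_content_khz = bb_content)
    ))
  }
  center <- sqrt(bl[1] * bl[2])  # common geometric centre of the nested bands
  for (bw in p$noise_bandwidths_oct) {
    lo <- center * 2^(-bw / 2); hi <- center * 2^(bw / 2)
    add(new_stimulus_row(
      sprintf("noise_band_bw%.1foct", bw), "noise", p$noise_dur, 70, fs,
      list(kind = "band", f_lo_khz = lo, f_hi_khz = hi, center_khz = center,
           bandwidth_oct = bw, band_family = "nested", noise_seed = nz_seed(),
           freq_content_khz = lo * (hi / lo)^((0:4) / 4))
    ))
  }
  for (fc in p$noise_narrow_centers) {
    lo <- fc * 2^(-0.5); hi <- fc * 2^(0.5)
    add(new_stimulus_row(
      sprintf("noise_band_c%sk", fmt_khz(fc)), "noise", p$noise_dur, 70, fs,
      list(kind = "band", f_lo_khz = lo, f_hi_khz = hi, center_khz = fc,
           bandwidth_oct = 1, band_family = "narrow", noise_seed = nz_seed(),
           freq_content_khz = fc)
    ))
  }
  for (ctrs in p$noise_pair_centers) for (dir in c("up", "down")) {
    lv <- if (dir == "up") c(50, 70) else c(70, 50)
    add(new_stimulus_row(
      sprintf("noise_pair_%s-%sk_%s", fmt_khz(ctrs[1]), fmt_khz(ctrs[2]), dir),
      "noise", p$noise_dur, mean(lv), fs,
      list(kind = "dual_ramped", centers_khz = ctrs, band_hw_khz = 0.5,
           direction = dir, level_start = lv[1], level_end = lv[2],
           noise_seed = nz_seed(), freq_content_khz = ctrs)
    ))
  }

  ## -- AM: 8 carriers x 6 modulation freqs = 48 --------------------------
  tone_carrier_freqs <- p$tone_freqs_khz[c(5, 8)]
  carriers <- c(
    lapply(tone_carrier_freqs, function(f) list(type = "tone", freqs_khz = f)),
    lapply(pool_sets$harmonic, function(fr) list(type = "chord", freqs_khz = fr)),
    list(list(type = "noise", f_lo_khz = bl[1], f_hi_khz = bl[2]))
  )
  for (ci in seq_along(carriers)) for (fm in p$am_mod_freqs) {
    carr <- carriers[[ci]]
    content <- if (carr$type == "noise") bb_content else carr$freqs_khz
    add(new_stimulus_row(
      sprintf("am_c%02d_fm%sHz", ci, signif(fm, 3)),
      "am", p$am_dur, 70, fs,
      list(carrier = carr, carrier_index = ci, fm_hz = fm,
           noise_seed = if (carr$type == "noise") nz_seed() else NULL,
           freq_content_khz = content)
    ))
  }

  ## -- complex surrogates: 15 identities x 2 dirs x 2 levels = 60 --------
  programs <- make_complex_surrogates(p$n_complex, seed, fs,
                                      duration = p$complex_dur)
  for (i in seq_len(p$n_complex)) {
    pr <- programs[[i]]
    for (dir in c("forward", "reversed")) for (lv in p$levels) {
      add(new_stimulus_row(
        sprintf("complex_%02d_%s_%ddB", i, substr(dir, 1, 3), lv), "complex",
        p$complex_dur, lv, fs,
        list(identity = i, direction = dir, components = pr$components,
             calibrated = TRUE, ref_level = 70,
             freq_content_khz = pr$freq_content_khz)
      ))
    }
  }

  ## -- decomposition: components + reconstructions of parents 1-4 = 47 ---
  for (i in 1:4) {
    pr <- programs[[i]]
    for (j in seq_along(pr$components)) {
      comp <- pr$components[[j]]
      add(new_stimulus_row(
        sprintf("dec_p%d_c%02d", i, j), "decomposition", comp$dur, comp$level_db, fs,
        list(parent = i, index = j, role = "component", component = comp,
             onset_s = comp$onset, calibrated = TRUE,
             freq_content_khz = component_freqs(comp))
      ))
    }
    add(new_stimulus_row(
      sprintf("dec_p%d_recon", i), "decomposition", p$complex_dur, 70, fs,
      list(parent = i, role = "reconstruction", components = pr$components,
           calibrated = TRUE, freq_content_khz = pr$freq_content_khz)
    ))
  }

  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  stopifnot(!anyDuplicated(cat$sound_id))
  attr(cat, "trials_per_sound") <- p$trials_per_sound
  attr(cat, "inter_onset") <- p$inter_onset
  attr(cat, "seed") <- seed
  class(cat) <- c("stimulus_catalog", class(cat))
  cat
}

#' Per-category stimulus counts of a catalog
#'
#' @param catalog A `stimulus_catalog`.
#' @return Named integer vector of counts per category.
#' @export
catalog_counts <- function(catalog) {
  table(factor(catalog$category,
               levels = c("pure_tone", "ramp", "chord", "chirp", "noise",
                          "am", "complex", "decomposition")))
}

#' Look up one stimulus of a catalog as a list
#'
#' @param catalog A `stimulus_catalog`.
#' @param sound_id Stimulus identifier.
#' @return List with fields `sound_id`, `category`, `duration`, `level`,
#'   `sample_rate`, `params`.
#' @export
catalog_stimulus <- function(catalog, sound_id) {
  i <- match(sound_id, catalog$sound_id)
  if (is.na(i)) stop("unknown sound_id: ", sound_id)
  list(sound_id = catalog$sound_id[i], category = catalog$category[i],
       duration = catalog$duration[i], level = catalog$level[i],
       sample_rate = catalog$sample_rate[i], params = catalog$params[[i]])
}

#' Write a catalog to CSV (params serialised as JSON)
#'
#' @param catalog A `stimulus_catalog`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_catalog <- function(catalog, path) {
  df <- catalog
  df$params <- vapply(catalog$params, function(x)
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)), "")
  class(df) <- "data.frame"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
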