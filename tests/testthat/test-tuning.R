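# Tuning curves, matched-pair contrasts, linearity tests, salience,
# and region statistics.

# A similarity matrix whose entries follow the closed-form overlap of
# log-Gaussian tuning, for oracle-based curve checks.
tone_truth_matrix <- function(catalog, width) {
  idx <- which(catalog$category == "pure_tone")
  f <- vapply(catalog$params, function(p) p$freq_khz %||% NA_real_, 0)
  n <- nrow(catalog)
  m <- diag(n)
  for (i in idx) for (j in idx) {
    m[i, j] <- exp(-(log2(f[i] / f[j]))^2 / (4 * width^2))
  }
  structure(list(values = m, sound_ids = catalog$sound_id, code = "spatial",
                 n_resamples = 0, seed = 0, combine = "exact"),
            class = "similarity_matrix")
}

test_that("tone tuning-curve pair counts follow the grid combinatorics", {
  cat0 <- catalog_subset("pure_tone")
  tc <- distance_tuning_curve(tone_truth_matrix(cat0, 1), cat0,
                              "tone_octave_distance")
  # 14-tone log grid at 2 levels: adjacent bin has 13 pairs per level, ...
  expect_equal(tc$n_pairs[1:4], c(26L, 24L, 22L, 20L))
  expect_true(all(diff(tc$bin) > 0))
  expect_true(all(diff(tc$n_pairs) <= 0))
})

test_that("fitted tuning-curve decay widens with generative width", {
  cat0 <- catalog_subset("pure_tone")
  curves <- lapply(c(0.3, 0.8, 2), function(w)
    distance_tuning_curve(tone_truth_matrix(cat0, w), cat0, "tone_octave_distance"))
  at_bin3 <- vapply(curves, function(tc) tc$mean[3], 0)
  expect_true(all(diff(at_bin3) > 0))       # broader tuning, higher similarity
  # oracle: closed-form overlap at the exact 3-step grid distance (the
  # bin label is snapped to 0.05 octave; the entries use true distances)
  d <- 3 * log2(60 / 2) / 13
  expect_equal(curves[[2]]$mean[3], exp(-d^2 / (4 * 0.8^2)), tolerance = 1e-6)
})

test_that("a constant matrix yields a flat tuning curve", {
  cat0 <- catalog_subset("pure_tone")
  m <- tone_truth_matrix(cat0, 1)
  m$values[] <- 0.4
  tc <- distance_tuning_curve(m, cat0, "tone_octave_distance")
  expect_true(all(tc$mean == 0.4))
  expect_error(distance_tuning_curve(m, cat0[1, ], "tone_octave_distance"),
               "eligible|identical")
})

test_that("contrast pair counts equal the catalog-implied counts", {
  cat0 <- catalog_default()
  m <- structure(list(values = matrix(1, 307, 307), sound_ids = cat0$sound_id),
                 class = "similarity_matrix")
  expect_equal(nrow(contrast_similarity(m, cat0, "tone_intensity")$pairs), 14L)
  expect_equal(nrow(contrast_similarity(m, cat0, "complex_intensity")$pairs), 15L)
  expect_equal(nrow(contrast_similarity(m, cat0, "complex_direction")$pairs), 15L)
  expect_equal(nrow(contrast_similarity(m, cat0, "sweep_direction")$pairs), 5L)
  expect_equal(nrow(contrast_similarity(m, cat0, "ramp_direction")$pairs), 13L)
  # all-ones matrix -> all contrast values 1
  expect_equal(contrast_similarity(m, cat0, "tone_intensity")$mean, 1)
})

test_that("AM and bandwidth features group pairs within their families", {
  cat0 <- catalog_default()
  am_pairs <- poptune:::feature_pairs(cat0, "am_logfreq_distance")
  # 6 fm per carrier -> 15 pairs per carrier x 8 carriers
  expect_equal(nrow(am_pairs), 15L * 8L)
  bw_pairs <- poptune:::feature_pairs(cat0, "noise_bandwidth_distance")
  expect_equal(nrow(bw_pairs), choose(9, 2))
  # 0.5-octave bandwidth difference: 8 pairs; 3.0: 3 pairs
  expect_equal(sum(bw_pairs$distance == 0.5), 8L)
  expect_equal(sum(bw_pairs$distance == 3.0), 3L)
})

test_that("summed-component similarity is 1 for linear noiseless populations", {
  cat0 <- chord_with_tones_catalog("chord_harmonic_05")   # 4,8,12,16 kHz
  pop <- generate_population(
    synthpop_spec(n_units = 50, regime = "CN", noise = 0, bin_width = 0.05,
                  linear_compound = TRUE, seed = 2), cat0)
  chord_id <- "chord_harmonic_05"
  comp_ids <- cat0$sound_id[cat0$category == "pure_tone"]
  expect_length(comp_ids, 4L)
  s <- summed_component_similarity(pop$tensor, chord_id, comp_ids, seed = 5)
  expect_equal(as.numeric(s), 1, tolerance = 1e-9)
  # scale invariance: doubling component responses leaves it unchanged
  tt2 <- pop$tensor
  ci <- match(comp_ids, tt2$sound_ids)
  tt2$values[, ci, , ] <- 2 * tt2$values[, ci, , ]
  s2 <- summed_component_similarity(tt2, chord_id, comp_ids, seed = 5)
  expect_equal(as.numeric(s2), 1, tolerance = 1e-9)
  expect_error(summed_component_similarity(pop$tensor, chord_id, character(0)),
               "empty")
})

test_that("summed-component similarity is ~0 for unrelated compound patterns", {
  set.seed(31)
  nu <- 200
  vals <- vapply(1:30, function(k) {
    pats <- cbind(rnorm(nu), rnorm(nu), rnorm(nu))  # compound independent of comps
    tt <- pattern_tensor(pats, R = 8)
    as.numeric(summed_component_similarity(tt, 1, c(2, 3), seed = k))
  }, 0)
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("component reconstruction is exact for aligned linear responses and degrades when shifted", {
  nu <- 30; nb <- 12; R <- 8
  set.seed(13)
  c1 <- abs(rnorm(nu)); c2 <- abs(rnorm(nu))
  k1 <- c(1, 1, 0.5, rep(0, 3)); k2 <- c(0.8, 1.2, 0.3, rep(0, 3))
  vals <- array(0, c(nu, 3, R, nb))
  for (ri in seq_len(R)) {
    vals[, 2, ri, 1:6] <- outer(c1, k1)
    vals[, 3, ri, 1:6] <- outer(c2, k2)
    vals[, 1, ri, 1:6] <- outer(c1, k1)              # component 1 at onset 0
    vals[, 1, ri, 7:12] <- outer(c2, k2)             # component 2 at bin 6
  }
  tt <- trial_tensor(vals, 0.05, c(0, 0.6), "imaging")
  comps <- data.frame(index = c(2, 3), onset_s = c(0, 0.3))
  s <- reconstruct_from_components(tt, 1, comps, "spatiotemporal", seed = 3)
  expect_equal(as.numeric(s), 1, tolerance = 1e-9)
  # one-bin misalignment strictly lowers similarity
  comps_shift <- data.frame(index = c(2, 3), onset_s = c(0, 0.35))
  s_sh <- reconstruct_from_components(tt, 1, comps_shift, "spatiotemporal", seed = 3)
  expect_lt(as.numeric(s_sh), as.numeric(s) - 1e-6)
  expect_error(reconstruct_from_components(tt, 1, comps[0, ]), "empty")
})

test_that("salience profile normalizes by unit maximum and reference category", {
  cat0 <- catalog_default()[c(1:4, 255:260), ]   # tones + complex at both levels
  rownames(cat0) <- NULL
  gains <- c(pure_tone = 0.5, complex = 1)
  pop <- generate_population(
    synthpop_spec(n_units = 40, regime = "CN", noise = 0, bin_width = 0.05,
                  category_gains = gains, seed = 8), cat0)
  prof <- salience_profile(pop$tensor, cat0)
  expect_equal(unname(prof["complex"]), 1, tolerance = 1e-9)
  expect_lt(prof["pure_tone"], prof["complex"])
  # per-unit normalization: doubling one unit's responses changes nothing
  tt2 <- pop$tensor
  tt2$values[1, , , ] <- 2 * tt2$values[1, , , ]
  expect_equal(salience_profile(tt2, cat0), prof, tolerance = 1e-9)
})

test_that("region contrast applies a paired signed-rank test", {
  x <- seq(0.1, 1, length.out = 100)
  same <- region_contrast(x, x)
  expect_equal(same$p_value, 1)
  shifted <- region_contrast(x, x - 0.2)
  expect_lt(shifted$p_value, 1e-3)
  expect_equal(shifted$n_pairs, 100L)
  expect_error(region_contrast(x, x[-1]), "mismatched")
  # undefined entries removed pairwise
  y <- x; y[1:3] <- NA
  expect_equal(region_contrast(x, y)$n_pairs, 97L)
})
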