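# Feature-level analyses on similarity matrices: distance-binned tuning
# curves, matched-pair contrasts (intensity, direction, identity),
# summed-component linearity tests, component-based reconstruction,
# category salience, and paired region statistics.

catalog_param <- function(catalog, field) {
  vapply(catalog$params, function(p) p[[field]] %||% NA_real_, 0)
}
catalog_chr_param <- function(catalog, field) {
  vapply(catalog$params, function(p) as.character(p[[field]] %||% NA), "")
}

# Unordered index pairs (i < j) among `idx` with a distance label.
pairs_with_distance <- function(idx, dist_fun) {
  if (length(idx) < 2) return(data.frame(i = integer(), j = integer(), distance = numeric()))
  cb <- utils::combn(idx, 2)
  data.frame(i = cb[1, ], j = cb[2, ],
             distance = mapply(dist_fun, cb[1, ], cb[2, ]))
}

feature_pairs <- function(catalog, feature, snap_step = 0.05) {
  freq <- catalog_param(catalog, "freq_khz")
  switch(feature,
    tone_octave_distance = {
      out <- NULL
      for (lv in unique(catalog$level[catalog$category == "pure_tone"])) {
        idx <- which(catalog$category == "pure_tone" & catalog$level == lv)
        out <- rbind(out, pairs_with_distance(idx, function(i, j)
          snap_to(octave_distance(freq[i], freq[j]), snap_step)))
      }
      out
    },
    am_logfreq_distance = {
      fm <- catalog_param(catalog, "fm_hz")
      ci <- catalog_param(catalog, "carrier_index")
      out <- NULL
      for (c0 in unique(ci[catalog$category == "am"])) {
        idx <- which(catalog$category == "am" & ci == c0)
        out <- rbind(out, pairs_with_distance(idx, function(i, j)
          snap_to(abs(log2(fm[i] / fm[j])), snap_step)))
      }
      out
    },
    noise_bandwidth_distance = {
      fam <- catalog_chr_param(catalog, "band_family")
      bw <- catalog_param(catalog, "bandwidth_oct")
      idx <- which(catalog$category == "noise" & fam == "nested")
      pairs_with_distance(idx, function(i, j) snap_to(abs(bw[i] - bw[j]), snap_step))
    },
    chord_within_pool = {
      pool <- catalog_chr_param(catalog, "pool")
      out <- NULL
      for (p0 in unique(pool[catalog$category == "chord"])) {
        idx <- which(catalog$category == "chord" & pool == p0)
        out <- rbind(out, pairs_with_distance(idx, function(i, j) 0))
      }
      out
    },
    stop("unknown feature: ", feature)
  )
}

#' Population tuning curve over a feature distance
#'
#' Groups eligible sound pairs of a similarity matrix by their absolute
#' feature difference (octaves for tone frequency, AM rate and noise
#' bandwidth) and reports the mean noise-corrected similarity, SEM and
#' contributing pair count per distance bin. Tone pairs are formed within
#' a presentation level; AM pairs within a carrier family. Grid distances
#' are snapped to the nearest 0.05 octave before grouping.
#'
#' @param matrix A `similarity_matrix` from [rsa_matrix()].
#' @param catalog The matching `stimulus_catalog`.
#' @param feature One of `"tone_octave_distance"`, `"am_logfreq_distance"`,
#'   `"noise_bandwidth_distance"`, `"chord_within_pool"`.
#' @param snap_step Distance snap tolerance in octaves (default 0.05).
#' @return A `tuning_curve` data frame: `feature`, `bin`, `mean`, `sem`, `n_pairs`.
#' @export
distance_tuning_curve <- function(matrix, catalog, feature, snap_step = 0.05) {
  stopifnot(identical(matrix$sound_ids, catalog$sound_id))
  pp <- feature_pairs(catalog, feature, snap_step)
  if (is.null(pp) || !nrow(pp)) stop("no eligible pairs for feature ", feature)
  vals <- matrix$values[cbind(pp$i, pp$j)]
  ok <- !is.na(vals)
  pp <- pp[ok, ]; vals <- vals[ok]
  if (!length(vals)) stop("all pairs undefined for feature ", feature)
  bins <- sort(unique(pp$distance))
  out <- do.call(rbind, lapply(bins, function(b) {
    v <- vals[pp$distance == b]
    data.frame(feature = feature, bin = b, mean = mean(v), sem = sem(v),
               n_pairs = length(v))
  }))
  class(out) <- c("tuning_curve", class(out))
  out
}

contrast_pairs <- function(catalog, contrast) {
  freq <- catalog_param(catalog, "freq_khz")
  direction <- catalog_chr_param(catalog, "direction")
  identity <- catalog_param(catalog, "identity")
  family <- catalog_chr_param(catalog, "family")
  f_lo <- catalog_param(catalog, "f_lo_khz")
  f_hi <- catalog_param(catalog, "f_hi_khz")
  match_pairs <- function(idx_a, idx_b, key_a, key_b) {
    m <- match(key_a, key_b)
    ok <- !is.na(m)
    data.frame(i = idx_a[ok], j = idx_b[m[ok]])
  }
  switch(contrast,
    tone_intensity = {
      a <- which(catalog$category == "pure_tone" & catalog$level == 50)
      b <- which(catalog$category == "pure_tone" & catalog$level == 70)
      match_pairs(a, b, freq[a], freq[b])
    },
    complex_intensity = {
      a <- which(catalog$category == "complex" & catalog$level == 50 & direction == "forward")
      b <- which(catalog$category == "complex" & catalog$level == 70 & direction == "forward")
      match_pairs(a, b, identity[a], identity[b])
    },
    complex_direction = {
      a <- which(catalog$category == "complex" & catalog$level == 70 & direction == "forward")
      b <- which(catalog$category == "complex" & catalog$level == 70 & direction == "reversed")
      match_pairs(a, b, identity[a], identity[b])
    },
    sweep_direction = {
      a <- which(catalog$category == "chirp" & family == "range" & direction == "up")
      b <- which(catalog$category == "chirp" & family == "range" & direction == "down")
      match_pairs(a, b, paste(f_lo[a], f_hi[a]), paste(f_lo[b], f_hi[b]))
    },
    ramp_direction = {
      a <- which(catalog$category == "ramp" & direction == "up")
      b <- which(catalog$category == "ramp" & direction == "down")
      match_pairs(a, b, freq[a], freq[b])
    },
    stop("unknown contrast: ", contrast)
  )
}

#' Similarity over matched stimulus pairs
#'
#' Evaluates a matching rule on the catalog (same tone frequency at 50 vs
#' 70 dB SPL; same complex identity at two levels or two playback
#' directions; same sweep range up vs down; same ramp frequency up vs
#' down) and returns the similarity value of each matched pair. Pair
#' counts on the default catalog: tone_intensity 14, complex_intensity
#' 15, complex_direction 15, sweep_direction 5, ramp_direction 13.
#'
#' @param matrix A `similarity_matrix`.
#' @param catalog The matching `stimulus_catalog`.
#' @param contrast One of `"tone_intensity"`, `"complex_intensity"`,
#'   `"complex_direction"`, `"sweep_direction"`, `"ramp_direction"`.
#' @return List with `values` (per matched pair, NA = undefined), `pairs`
#'   (data frame of catalog indices), `mean`, `sem`, `n` (defined pairs).
#' @export
contrast_similarity <- function(matrix, catalog, contrast) {
  stopifnot(identical(matrix$sound_ids, catalog$sound_id))
  pp <- contrast_pairs(catalog, contrast)
  if (!nrow(pp)) stop("matching rule yields zero pairs for contrast ", contrast)
  vals <- matrix$values[cbind(pp$i, pp$j)]
  ok <- !is.na(vals)
  list(values = vals, pairs = pp, contrast = contrast,
       mean = mean(vals[ok]), sem = sem(vals[ok]), n = sum(ok))
}

# Half-average vectors for a set of sounds with halves paired across
# sounds, summed element-wise (the "synthetic sum" construct).
summed_half_vectors <- function(tensor, idx_list, code, bins_list) {
  R <- tensor$trials_per_sound
  acc <- NULL
  for (k in seq_along(idx_list)) {
    h <- split_halves(R)
    hv <- half_vectors(tensor, idx_list[[k]], h, code, bins_list[[k]])
    acc <- if (is.null(acc)) hv else acc + hv
  }
  acc
}

#' Similarity between a compound sound and the sum of its components
#'
#' Tests response linearity: within each resample the compound's trials
#' are half-split as usual while each component's trials are half-split
#' and half-averaged, the component half-vectors summed element-wise
#' (halves paired consistently across components), and the
#' noise-corrected estimator evaluated between the compound half-vectors
#' and the summed half-vectors, including a split-half reliability term
#' for the summed construct.
#'
#' @param tensor A [trial_tensor()].
#' @param compound_sound Compound sound id/index (chord, AM, chirp, noise).
#' @param component_sounds Vector of component sound ids/indices
#'   (e.g. the pure tones composing a chord).
#' @param code `"spatial"` or `"spatiotemporal"`.
#' @param n_resamples Number of split resamples (default 20).
#' @param seed Integer seed.
#' @return Similarity in `[-1, 1]` or `NA` if undefined.
#' @export
summed_component_similarity <- function(tensor, compound_sound, component_sounds,
                                        code = c("spatial", "spatiotemporal"),
                                        n_resamples = 20, seed = 1L) {
  code <- match.arg(code)
  if (!length(component_sounds)) stop("empty component list")
  ic <- sound_index(tensor, compound_sound)
  comps <- lapply(component_sounds, function(s) sound_index(tensor, s))
  missing <- vapply(comps, function(i) is.na(i) || i < 1 || i > n_sounds(tensor), TRUE)
  if (any(missing)) stop("components missing from tensor: ",
                         paste(component_sounds[missing], collapse = ", "))
  R <- tensor$trials_per_sound
  if (R < 4) stop("need at least 4 trials per sound")
  bins_c <- analysis_bins(tensor, ic)
  # common bin count so component and compound vectors align
  bins_list <- lapply(comps, function(i) {
    b <- analysis_bins(tensor, i)
    if (code == "spatiotemporal" && length(b) > length(bins_c)) b[seq_along(bins_c)] else b
  })
  if (code == "spatiotemporal") {
    nb <- min(c(length(bins_c), lengths(bins_list)))
    bins_c <- bins_c[1:nb]
    bins_list <- lapply(bins_list, function(b) b[1:nb])
  }
  acc <- c(cross = 0, rel_a = 0, rel_b = 0); nacc <- c(0L, 0L, 0L)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n_resamples)) {
      hc <- split_halves(R)
      ab <- half_vectors(tensor, ic, hc, code, bins_c)
      cd <- summed_half_vectors(tensor, comps, code, bins_list)
      cross <- c(pearson(ab[, 1], cd[, 1]), pearson(ab[, 1], cd[, 2]),
                 pearson(ab[, 2], cd[, 1]), pearson(ab[, 2], cd[, 2]))
      rel_a <- pearson(ab[, 1], ab[, 2]); rel_b <- pearson(cd[, 1], cd[, 2])
      if (any(fin <- is.finite(cross))) {
        acc["cross"] <- acc["cross"] + sum(cross[fin]) / sum(fin); nacc[1] <- nacc[1] + 1L
      }
      if (is.finite(rel_a)) { acc["rel_a"] <- acc["rel_a"] + rel_a; nacc[2] <- nacc[2] + 1L }
      if (is.finite(rel_b)) { acc["rel_b"] <- acc["rel_b"] + rel_b; nacc[3] <- nacc[3] + 1L }
    }
  })
  if (any(nacc == 0)) return(NA_real_)
  m <- acc / nacc
  if (m["rel_a"] <= 0 || m["rel_b"] <= 0) return(NA_real_)
  clip1(unname(m["cross"] / sqrt(m["rel_a"] * m["rel_b"])))
}

#' Similarity between a complex sound and its component-based reconstruction
#'
#' Builds a synthetic response to the complex sound by shifting each
#' component's half-averaged response time course to its onset offset on
#' the common bin grid and summing (overlaps add); the spatial code
#' time-averages afterwards. The noise-corrected estimator then compares
#' the complex sound's half-vectors with the reconstructed half-vectors.
#'
#' @param tensor A [trial_tensor()].
#' @param complex_sound The compound sound id/index.
#' @param components Data frame with columns `sound_id` (or `index`) and
#'   `onset_s` giving each component's onset within the complex sound.
#' @param code `"spatial"` or `"spatiotemporal"`.
#' @param n_resamples Number of split resamples (default 20).
#' @param seed Integer seed.
#' @return Similarity in `[-1, 1]` or `NA` if undefined.
#' @export
reconstruct_from_components <- function(tensor, complex_sound, components,
                                        code = c("spatial", "spatiotemporal"),
                                        n_resamples = 20, seed = 1L) {
  code <- match.arg(code)
  if (is.null(components) || !nrow(components)) stop("empty component list")
  ic <- sound_index(tensor, complex_sound)
  idx <- if (!is.null(components$index)) as.integer(components$index)
         else vapply(components$sound_id, function(s) sound_index(tensor, s), 0L)
  R <- tensor$trials_per_sound
  bins_c <- analysis_bins(tensor, ic)
  nbc <- length(bins_c)
  offs <- round(components$onset_s / tensor$bin_width)
  nu <- n_units(tensor)
  acc <- c(cross = 0, rel_a = 0, rel_b = 0); nacc <- c(0L, 0L, 0L)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n_resamples)) {
      hc <- split_halves(R)
      ab <- half_vectors(tensor, ic, hc, code, bins_c)
      rec1 <- rec2 <- matrix(0, nu, nbc)
      for (ci in seq_along(idx)) {
        bins_k <- analysis_bins(tensor, idx[ci])
        h <- split_halves(R)
        v <- tensor$values[, idx[ci], , bins_k, drop = FALSE]
        d <- dim(v)
        m1 <- colMeans(aperm(array(v[, 1, h[[1]], , drop = FALSE],
                                   c(d[1], length(h[[1]]), d[4])), c(2, 1, 3)))
        m2 <- colMeans(aperm(array(v[, 1, h[[2]], , drop = FALSE],
                                   c(d[1], length(h[[2]]), d[4])), c(2, 1, 3)))
        dest <- offs[ci] + seq_len(ncol(m1))
        keep <- dest >= 1 & dest <= nbc
        rec1[, dest[keep]] <- rec1[, dest[keep]] + m1[, keep, drop = FALSE]
        rec2[, dest[keep]] <- rec2[, dest[keep]] + m2[, keep, drop = FALSE]
      }
      cd <- if (code == "spatial") cbind(rowMeans(rec1), rowMeans(rec2))
            else cbind(as.numeric(rec1), as.numeric(rec2))
      cross <- c(pearson(ab[, 1], cd[, 1]), pearson(ab[, 1], cd[, 2]),
                 pearson(ab[, 2], cd[, 1]), pearson(ab[, 2], cd[, 2]))
      rel_a <- pearson(ab[, 1], ab[, 2]); rel_b <- pearson(cd[, 1], cd[, 2])
      if (any(fin <- is.finite(cross))) {
        acc["cross"] <- acc["cross"] + sum(cross[fin]) / sum(fin); nacc[1] <- nacc[1] + 1L
      }
      if (is.finite(rel_a)) { acc["rel_a"] <- acc["rel_a"] + rel_a; nacc[2] <- nacc[2] + 1L }
      if (is.finite(rel_b)) { acc["rel_b"] <- acc["rel_b"] + rel_b; nacc[3] <- nacc[3] + 1L }
    }
  })
  if (any(nacc == 0)) return(NA_real_)
  m <- acc / nacc
  if (m["rel_a"] <= 0 || m["rel_b"] <= 0) return(NA_real_)
  clip1(unname(m["cross"] / sqrt(m["rel_a"] * m["rel_b"])))
}

#' Normalized population response per sound category
#'
#' Each unit's trial- and window-averaged response is divided by that
#' unit's maximum across sounds (units with non-positive maxima are
#' excluded with a message), the population mean is taken per category,
#' and the profile is normalized by the mean response to the reference
#' category (complex sounds at 70 dB SPL), which therefore maps to 1.
#'
#' @param tensor A [trial_tensor()].
#' @param catalog The matching `stimulus_catalog`.
#' @param reference_category Reference category (default `"complex"`).
#' @param reference_level Reference level in dB SPL (default 70).
#' @return Named numeric vector of normalized mean responses per category.
#' @export
salience_profile <- function(tensor, catalog, reference_category = "complex",
                             reference_level = 70) {
  stopifnot(identical(tensor$sound_ids, catalog$sound_id))
  ns <- n_sounds(tensor)
  resp <- vapply(seq_len(ns), function(si) {
    bins <- analysis_bins(tensor, si)
    apply(tensor$values[, si, , bins, drop = FALSE], 1, mean)
  }, numeric(n_units(tensor)))
  mx <- apply(resp, 1, max)
  bad <- mx <= 0
  if (any(bad)) message(sum(bad), " unit(s) with non-positive maximum excluded")
  if (all(bad)) stop("no unit with a positive maximum response")
  nr <- resp[!bad, , drop = FALSE] / mx[!bad]
  ref <- catalog$category == reference_category & catalog$level == reference_level
  if (!any(ref)) stop("reference category not present in catalog")
  pop_mean <- colMeans(nr)
  # categories are profiled at the reference level where they have
  # entries at it (level-matched comparison); otherwise over all entries
  cats <- unique(catalog$category)
  out <- vapply(cats, function(cg) {
    at_ref <- catalog$category == cg & catalog$level == reference_level
    mean(pop_mean[if (any(at_ref)) at_ref else catalog$category == cg])
  }, 0)
  names(out) <- cats
  out / mean(pop_mean[ref])
}

#' Paired region contrast of similarity values
#'
#' Compares two regions' similarity values over an identical set of sound
#' pairs with a paired Wilcoxon signed-rank test; undefined entries are
#' removed pairwise.
#'
#' @param values_a,values_b Equal-length numeric vectors of similarity
#'   values over the same pair set.
#' @return A `region_contrast` list: `statistic`, `p_value`, `n_pairs`,
#'   `mean_a`, `mean_b`.
#' @export
region_contrast <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("mismatched pair sets")
  ok <- !is.na(values_a) & !is.na(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) < 2) stop("need at least 2 defined pairs")
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
  p <- if (all(a == b)) 1 else wt$p.value
  structure(list(statistic = unname(wt$statistic), p_value = p,
                 n_pairs = length(a), mean_a = mean(a), mean_b = mean(b)),
            class = "region_contrast")
}
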