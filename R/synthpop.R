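# Synthetic neural populations with known ground-truth representational
# structure. Units carry log-Gaussian frequency tuning of regime-specific
# sharpness, optional AM band-pass tuning, direction selectivity,
# monotonic intensity gain and per-category gains, with an onset temporal
# kernel. Trial noise is Poisson (spike-count-like) or Gaussian
# (deconvolved-imaging-like). The noiseless mean tensor and its exact
# similarity matrices are returned alongside the noisy trial tensor.

#' Specification of a synthetic population
#'
#' @param n_units Number of units.
#' @param modality `"ephys"` (Poisson count noise) or `"imaging"`
#'   (Gaussian noise on deconvolved-trace bins).
#' @param regime Tuning-sharpness regime: `"CN"` (broad, width 1.5
#'   octaves), `"IC"` (intermediate, 0.6), `"AC"` (sharp, 0.25), or a
#'   numeric width in octaves.
#' @param trials_per_sound Trials per sound (default 12).
#' @param bin_width Time-bin width in seconds (default 0.001 for ephys,
#'   0.0435 for imaging).
#' @param noise Noise level: for ephys the Poisson rate scale
#'   (expected driven spikes/s at a unit's best stimulus, default 50);
#'   for imaging the Gaussian SD relative to the peak response
#'   (default 0.5). Set to 0 for noiseless trials.
#' @param am_weight Fraction of units with AM band-pass tuning (default 0.5).
#' @param direction_weight Fraction of direction-selective units (default 0.5).
#' @param category_gains Optional named vector of per-category response
#'   gains (defaults to 1 for all categories).
#' @param linear_compound If `TRUE`, responses are exactly linear in the
#'   stimulus frequency components (AM/direction/category modulation and
#'   response thresholding disabled), so compound responses equal the sum
#'   of their components' responses.
#' @param seed Integer seed.
#' @return A `synthpop_spec` list.
#' @export
synthpop_spec <- function(n_units = 100, modality = c("ephys", "imaging"),
                          regime = "IC", trials_per_sound = 12,
                          bin_width = NULL, noise = NULL,
                          am_weight = 0.5, direction_weight = 0.5,
                          category_gains = NULL, linear_compound = FALSE,
                          seed = 1L) {
  modality <- match.arg(modality)
  width <- if (is.numeric(regime)) regime else
    switch(regime, CN = 1.5, IC = 0.6, AC = 0.25,
           stop("unknown regime: ", regime))
  stopifnot(n_units >= 2, trials_per_sound >= 4, width > 0)
  structure(list(
    n_units = n_units, modality = modality, regime = regime,
    tuning_width_oct = width, trials_per_sound = trials_per_sound,
    bin_width = bin_width %||% if (modality == "ephys") 0.001 else 0.0435,
    noise = noise %||% if (modality == "ephys") 50 else 0.5,
    am_weight = am_weight, direction_weight = direction_weight,
    category_gains = category_gains, linear_compound = linear_compound,
    seed = as.integer(seed)
  ), class = "synthpop_spec")
}

# Scalar noiseless amplitude of one unit for one stimulus.
unit_amplitude <- function(unit, st, linear) {
  pr <- st$params
  freqs <- pr$freq_content_khz
  w <- unit$width
  fresp <- sum(exp(-(log2(freqs / unit$cf))^2 / (2 * w^2)))
  lv <- st$level
  gain <- (lv / 70)^unit$level_gamma
  # additive over components when linear; sublinear normalisation otherwise
  if (linear) return(fresp * gain)
  fresp <- fresp / sqrt(length(freqs))
  if (st$category == "am" && unit$am_pref > 0) {
    fresp <- fresp * (1 + unit$am_depth *
                        exp(-(log2(pr$fm_hz / unit$am_pref))^2 / (2 * 0.5^2)))
  }
  dirn <- pr$direction %||% NA
  if (!is.na(dirn) && dirn %in% c("up", "down")) {
    fresp <- fresp * (1 + unit$dir_sel * ifelse(dirn == "up", 0.5, -0.5))
  }
  if (!is.null(unit$cat_gain)) {
    g <- unname(unit$cat_gain[st$category])
    if (!is.na(g)) fresp <- fresp * g
  }
  fresp * gain
}

#' Generate a synthetic population and its ground truth
#'
#' Computes each unit's noiseless response to every catalog stimulus from
#' its tuning parameters and an onset temporal kernel, draws noisy trials
#' around the noiseless means, and returns both the [trial_tensor()] and
#' a `ground_truth` object holding the noiseless tensor and its exact
#' spatial/spatio-temporal similarity matrices.
#'
#' @param spec A [synthpop_spec()].
#' @param catalog A `stimulus_catalog` (possibly a subset of rows).
#' @return List with elements `tensor` (noisy [trial_tensor()]) and
#'   `truth` (list: `tensor` noiseless unit x sound x bin array,
#'   `spatial`, `spatiotemporal` similarity matrices).
#' @export
generate_population <- function(spec, catalog) {
  stopifnot(inherits(spec, "synthpop_spec"))
  ns <- nrow(catalog)
  nu <- spec$n_units
  R <- spec$trials_per_sound
  bw <- spec$bin_width
  win_end <- max(catalog$duration) + 0.1
  nb <- max(1L, round(win_end / bw))
  tcent <- (seq_len(nb) - 0.5) * bw
  units <- withr::with_seed(spec$seed, {
    lapply(seq_len(nu), function(i) {
      list(
        cf = 2 * 2^(stats::runif(1, 0, log2(30))),     # log-uniform 2-60 kHz
        width = spec$tuning_width_oct * exp(stats::rnorm(1, 0, 0.2)),
        level_gamma = stats::runif(1, 0.5, 1.5),
        am_pref = if (stats::runif(1) < spec$am_weight)
          4 * (160 / 4)^stats::runif(1) else 0,
        am_depth = stats::runif(1, 0.3, 1),
        dir_sel = if (stats::runif(1) < spec$direction_weight)
          stats::runif(1, -1, 1) else 0,
        cat_gain = spec$category_gains,
        latency = stats::runif(1, 0.01, 0.05),
        tau_resp = stats::runif(1, 0.03, 0.1)
      )
    })
  })
  # noiseless tensor: amplitude x normalized onset kernel
  G <- array(0, c(nu, ns, nb))
  stims <- lapply(seq_len(ns), function(si) catalog_stimulus(catalog, catalog$sound_id[si]))
  for (ui in seq_len(nu)) {
    un <- units[[ui]]
    tk <- pmax(0, tcent - un$latency) / un$tau_resp *
      exp(1 - pmax(0, tcent - un$latency) / un$tau_resp)   # alpha kernel, peak 1
    for (si in seq_len(ns)) {
      # kernel gated to the stimulus duration + decay
      gate <- as.numeric(tcent <= stims[[si]]$duration + 0.1)
      G[ui, si, ] <- unit_amplitude(un, stims[[si]], spec$linear_compound) * tk * gate
    }
  }
  vals <- array(0, c(nu, ns, R, nb))
  withr::with_seed(derive_seed(spec$seed, "trials"), {
    if (spec$modality == "ephys") {
      lam <- spec$noise * G * bw          # expected counts per bin
      if (spec$noise > 0) {
        for (ri in seq_len(R)) {
          vals[, , ri, ] <- array(stats::rpois(length(lam), lam), dim(lam))
        }
        vals <- vals / (spec$noise * bw)  # back to the ground-truth scale
      } else {
        for (ri in seq_len(R)) vals[, , ri, ] <- G
      }
    } else {
      peak <- max(G)
      for (ri in seq_len(R)) {
        vals[, , ri, ] <- G + if (spec$noise > 0)
          array(stats::rnorm(length(G), 0, spec$noise * peak), dim(G)) else 0
      }
    }
  })
  tensor <- trial_tensor(vals, bw, c(0, win_end), spec$modality,
                         sound_ids = catalog$sound_id,
                         durations = catalog$duration)
  truth <- ground_truth_from_tensor(G, tensor)
  list(tensor = tensor, truth = truth)
}

# Exact similarity matrices of a noiseless unit x sound x bin array,
# using the same per-sound analysis windows as the estimator.
ground_truth_from_tensor <- function(G, tensor) {
  ns <- dim(G)[2]
  spat <- vapply(seq_len(ns), function(si) {
    rowMeans(G[, si, analysis_bins(tensor, si), drop = FALSE])
  }, numeric(dim(G)[1]))
  spatial <- suppressWarnings(stats::cor(spat))
  nb_min <- min(vapply(seq_len(ns), function(si) length(analysis_bins(tensor, si)), 0L))
  st <- vapply(seq_len(ns), function(si) {
    as.numeric(G[, si, analysis_bins(tensor, si)[1:nb_min]])
  }, numeric(dim(G)[1] * nb_min))
  spatiotemporal <- suppressWarnings(stats::cor(st))
  structure(list(tensor = G, spatial = spatial, spatiotemporal = spatiotemporal),
            class = "ground_truth")
}

#' Matched pattern pair with controlled correlation and noise
#'
#' Generates a minimal two-sound population: Gaussian spatial patterns
#' with expected correlation `rho` across `n_units` units, and
#' `trials_per_sound` noisy trials per sound with independent Gaussian
#' noise of SD `noise_sd` (patterns have unit variance). The single-bin
#' tensor feeds the estimator-validation analyses.
#'
#' @param n_units Number of units.
#' @param rho Target pattern correlation.
#' @param noise_sd Trial noise SD (pattern SD = 1).
#' @param trials_per_sound Trials per sound (default 12).
#' @param seed Integer seed.
#' @return List: `tensor` ([trial_tensor()], 1 time bin), `true_rho` (the
#'   realised pattern correlation), `naive` (Pearson correlation of the
#'   trial-averaged patterns).
#' @export
generate_pattern_pair <- function(n_units = 500, rho = 0.5, noise_sd = 2.83,
                                  trials_per_sound = 12, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    z1 <- stats::rnorm(n_units)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_units)
    vals <- array(0, c(n_units, 2, trials_per_sound, 1))
    for (ri in seq_len(trials_per_sound)) {
      vals[, 1, ri, 1] <- z1 + stats::rnorm(n_units, 0, noise_sd)
      vals[, 2, ri, 1] <- z2 + stats::rnorm(n_units, 0, noise_sd)
    }
  })
  tensor <- trial_tensor(vals, bin_width = 1, window = c(0, 1),
                         modality = "imaging", sound_ids = c("a", "b"))
  naive <- stats::cor(rowMeans(vals[, 1, , 1]), rowMeans(vals[, 2, , 1]))
  list(tensor = tensor, true_rho = stats::cor(z1, z2), naive = naive)
}

#' Validate the noise-corrected estimator against ground truth
#'
#' For each condition (units, trials, noise SD, true correlation) and
#' seed, generates a matched pattern pair, computes the noise-corrected
#' and the naive trial-averaged estimates, and summarises bias and RMSE
#' of both against the realised ground-truth correlation.
#'
#' @param conditions Data frame with columns `n_units`, `trials_per_sound`,
#'   `noise_sd`, `rho` (one row per condition).
#' @param n_seeds Seeds per condition (default 20).
#' @param n_resamples Split resamples for the corrected estimator (default 20).
#' @param seed Base seed.
#' @return Data frame per condition: mean bias and RMSE of the corrected
#'   and naive estimators, and `small_n` flag (n_units < 50, where the
#'   corrected estimator's variance grows markedly).
#' @export
estimator_validation_suite <- function(conditions, n_seeds = 20,
                                       n_resamples = 20, seed = 1L) {
  out <- lapply(seq_len(nrow(conditions)), function(ci) {
    cd <- conditions[ci, ]
    res <- vapply(seq_len(n_seeds), function(k) {
      pp <- generate_pattern_pair(cd$n_units, cd$rho, cd$noise_sd,
                                  cd$trials_per_sound,
                                  seed = derive_seed(seed, paste0("val", ci, "_", k)))
      est <- noise_corrected_similarity(pp$tensor, 1, 2, "spatial",
                                        n_resamples = n_resamples,
                                        seed = derive_seed(seed, paste0("split", ci, "_", k)))
      c(corrected = as.numeric(est) - pp$true_rho, naive = pp$naive - pp$true_rho)
    }, c(corrected = 0, naive = 0))
    data.frame(
      n_units = cd$n_units, trials_per_sound = cd$trials_per_sound,
      noise_sd = cd$noise_sd, rho = cd$rho,
      bias_corrected = mean(res["corrected", ], na.rm = TRUE),
      bias_naive = mean(res["naive", ]),
      rmse_corrected = sqrt(mean(res["corrected", ]^2, na.rm = TRUE)),
      rmse_naive = sqrt(mean(res["naive", ]^2)),
      n_undefined = sum(is.na(res["corrected", ])),
      small_n = cd$n_units < 50
    )
  })
  do.call(rbind, out)
}
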