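# Preprocessing: fluorescence -> dF/F -> deconvolved rate proxy, spike
# times -> PSTHs, trial extraction with baseline subtraction, reliability
# screening, and virtual-population pooling.

#' Construct a trial tensor
#'
#' The central response container: baseline-subtracted responses indexed
#' `(unit, sound, trial, time bin)` with the bin width and extraction
#' window needed to form population vectors downstream.
#'
#' @param values 4-d numeric array `(unit, sound, trial, bin)`.
#' @param bin_width Bin width in seconds.
#' @param window Length-2 window (start, end) in seconds relative to onset.
#' @param modality `"ephys"` or `"imaging"`.
#' @param sound_ids Character vector of sound identifiers.
#' @param unit_ids Character vector of unit identifiers.
#' @param durations Optional per-sound stimulus durations in seconds,
#'   used for the onset-to-offset+100 ms analysis window.
#' @param unit_meta Optional data frame of per-unit labels (region, session).
#' @return A `trial_tensor` object.
#' @export
trial_tensor <- function(values, bin_width, window, modality,
                         sound_ids = NULL, unit_ids = NULL,
                         durations = NULL, unit_meta = NULL) {
  stopifnot(length(dim(values)) == 4, modality %in% c("ephys", "imaging"))
  if (!all(is.finite(values))) stop("trial tensor contains non-finite values")
  d <- dim(values)
  structure(list(
    values = values, bin_width = bin_width, window = window,
    modality = modality,
    sound_ids = sound_ids %||% paste0("sound_", seq_len(d[2])),
    unit_ids = unit_ids %||% paste0("unit_", seq_len(d[1])),
    durations = durations, unit_meta = unit_meta,
    trials_per_sound = d[3]
  ), class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trial_tensor> %d units x %d sounds x %d trials x %d bins (%s, %.4g s bins, window %.2f..%.2f s)\n",
              d[1], d[2], d[3], d[4], x$modality, x$bin_width,
              x$window[1], x$window[2]))
  invisible(x)
}

n_units <- function(tensor) dim(tensor$values)[1]
n_sounds <- function(tensor) dim(tensor$values)[2]

#' Compute dF/F from raw fluorescence
#'
#' Subtracts a fixed fraction of the local neuropil signal, estimates the
#' baseline F0 as a sliding low percentile of the Gaussian-filtered
#' corrected trace, and returns f = (F - F0) / F0.
#'
#' @param F Raw ROI fluorescence series.
#' @param F_np Local neuropil series (same length).
#' @param frame_rate Acquisition rate in Hz (default 22.9).
#' @param neuropil_fraction Fraction of neuropil subtracted (default 0.7).
#' @param percentile Baseline percentile (default 3).
#' @param baseline_filter_sigma Gaussian pre-filter width in seconds
#'   applied before the percentile (default 2).
#' @param baseline_window Sliding-percentile window length in seconds
#'   (default 60).
#' @param tau_decay Indicator decay constant in seconds (default 2),
#'   stored for [deconvolve()].
#' @param smoothing_sigma Post-deconvolution smoothing width in seconds
#'   (default 0.031), stored for [deconvolve()].
#' @return A `calcium_trace` list with fields `F`, `F_np`, `F0`, `f`,
#'   `frame_rate`, `tau_decay`, `smoothing_sigma`, `valid`. Units whose
#'   baseline is non-positive anywhere are flagged `valid = FALSE`.
#' @export
dff <- function(F, F_np = NULL, frame_rate = 22.9, neuropil_fraction = 0.7,
                percentile = 3, baseline_filter_sigma = 2,
                baseline_window = 60, tau_decay = 2, smoothing_sigma = 0.031) {
  if (is.null(F_np)) F_np <- numeric(length(F))
  stopifnot(length(F) == length(F_np),
            neuropil_fraction >= 0, neuropil_fraction <= 1)
  Fc <- F - neuropil_fraction * F_np
  dt <- 1 / frame_rate
  Fg <- gaussian_smooth(Fc, baseline_filter_sigma, dt)
  win <- max(3L, round(baseline_window / dt))
  F0 <- zoo::rollapply(zoo::zoo(Fg), width = win,
                       FUN = stats::quantile, probs = percentile / 100,
                       names = FALSE, partial = TRUE, align = "center")
  F0 <- as.numeric(F0)
  valid <- all(F0 > 0)
  f <- if (valid) (Fc - F0) / F0 else rep(NA_real_, length(F))
  structure(list(F = F, F_np = F_np, F0 = F0, f = f,
                 frame_rate = frame_rate, tau_decay = tau_decay,
                 smoothing_sigma = smoothing_sigma, valid = valid),
            class = "calcium_trace")
}

#' Linear deconvolution of a calcium trace
#'
#' Firing-rate proxy r(t) = f'(t) + f(t)/tau, with the derivative taken by
#' central differences (one-sided at the ends), then Gaussian-smoothed.
#' This removes the slow indicator decay; it does not correct for the
#' indicator rise time.
#'
#' @param trace A `calcium_trace` from [dff()], or a numeric dF/F series.
#' @param frame_rate Sample rate in Hz (ignored for `calcium_trace` input).
#' @param tau_decay Decay constant in seconds (default 2).
#' @param smoothing_sigma Gaussian smoothing width in seconds (default
#'   0.031); set to 0 to disable.
#' @return Numeric rate-proxy series.
#' @export
deconvolve <- function(trace, frame_rate = NULL, tau_decay = 2,
                       smoothing_sigma = 0.031) {
  if (inherits(trace, "calcium_trace")) {
    if (!trace$valid) stop("cannot deconvolve a flagged (invalid-baseline) trace")
    f <- trace$f
    frame_rate <- trace$frame_rate
    tau_decay <- trace$tau_decay
    smoothing_sigma <- trace$smoothing_sigma
  } else {
    f <- as.numeric(trace)
    if (is.null(frame_rate)) stop("frame_rate required for numeric input")
  }
  n <- length(f)
  if (n < 3) stop("series too short to deconvolve (need >= 3 samples)")
  stopifnot(tau_decay > 0)
  dt <- 1 / frame_rate
  fp <- numeric(n)
  fp[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * dt)
  fp[1] <- (f[2] - f[1]) / dt
  fp[n] <- (f[n] - f[n - 1]) / dt
  r <- fp + f / tau_decay
  if (smoothing_sigma > 0) r <- gaussian_smooth(r, smoothing_sigma, dt)
  as.numeric(r)
}

modality_defaults <- function(modality) {
  switch(modality,
    ephys = list(window = c(-0.3, 1.0), baseline = c(-0.3, 0), bin_width = 0.001),
    imaging = list(window = c(-0.2, 0.8), baseline = c(-0.2, -0.02), bin_width = NA),
    stop("unknown modality: ", modality))
}

#' Extract baseline-subtracted single-trial responses
#'
#' Slices per-unit recordings into trials around each sound onset and
#' subtracts each trial's mean activity over the prestimulus baseline
#' window. Spike input is binned into PSTHs (1-ms bins, window
#' -0.3..1.0 s, baseline -0.3..0 s); imaging input is sliced on the frame
#' grid (window -0.2..0.8 s, baseline -0.2..-0.02 s).
#'
#' @param x For `modality = "ephys"`: a data frame with columns `unit_id`
#'   and `spike_time_s`. For `"imaging"`: a units x frames numeric matrix
#'   of deconvolved activity.
#' @param events Data frame with columns `sound_id` and `onset_s`, one row
#'   per presentation.
#' @param modality `"ephys"` or `"imaging"`.
#' @param frame_rate Frame rate in Hz (imaging input).
#' @param trials_per_sound Required complete trial count per sound
#'   (default: the minimum observed; sounds with fewer complete trials
#'   than this raise an error).
#' @param durations Optional named vector of stimulus durations (seconds)
#'   by sound_id, stored for analysis windows.
#' @param t_max End of the recording in seconds (ephys; default inferred).
#' @return A [trial_tensor()].
#' @export
extract_trials <- function(x, events, modality, frame_rate = 22.9,
                           trials_per_sound = NULL, durations = NULL,
                           t_max = NULL) {
  md <- modality_defaults(modality)
  win <- md$window
  sound_ids <- unique(events$sound_id)
  if (modality == "ephys") {
    stopifnot(all(c("unit_id", "spike_time_s") %in% names(x)))
    unit_ids <- sort(unique(as.character(x$unit_id)))
    t_max <- t_max %||% max(x$spike_time_s, events$onset_s + win[2])
    bw <- md$bin_width
    edges <- seq(win[1], win[2], by = bw)
    nb <- length(edges) - 1L
    complete <- events$onset_s + win[1] >= 0 & events$onset_s + win[2] <= t_max
    spk <- split(x$spike_time_s, factor(as.character(x$unit_id), levels = unit_ids))
    per_sound <- split(which(complete), events$sound_id[complete])
    n_complete <- vapply(sound_ids, function(s) length(per_sound[[s]] %||% integer()), 0L)
    R <- trials_per_sound %||% min(n_complete)
    if (any(n_complete < R)) {
      stop("sounds with fewer than ", R, " complete trials: ",
           paste(sound_ids[n_complete < R], collapse = ", "))
    }
    vals <- array(0, c(length(unit_ids), length(sound_ids), R, nb))
    bl_bins <- which(edges[-length(edges)] >= md$baseline[1] &
                       edges[-1] <= md$baseline[2])
    for (si in seq_along(sound_ids)) {
      evs <- per_sound[[sound_ids[si]]][seq_len(R)]
      for (ri in seq_along(evs)) {
        on <- events$onset_s[evs[ri]]
        for (ui in seq_along(unit_ids)) {
          rel <- spk[[ui]] - on
          rel <- rel[rel >= win[1] & rel < win[2]]
          h <- if (length(rel)) tabulate(floor((rel - win[1]) / bw) + 1L, nbins = nb)
               else numeric(nb)
          vals[ui, si, ri, ] <- h - mean(h[bl_bins])
        }
      }
    }
  } else {
    stopifnot(is.matrix(x))
    unit_ids <- rownames(x) %||% paste0("unit_", seq_len(nrow(x)))
    bw <- 1 / frame_rate
    off <- seq(floor(win[1] / bw), ceiling(win[2] / bw) - 1L)
    nb <- length(off)
    n_frames <- ncol(x)
    on_frames <- round(events$onset_s * frame_rate) + 1L
    complete <- on_frames + off[1] >= 1 & on_frames + off[nb] <= n_frames
    per_sound <- split(which(complete), events$sound_id[complete])
    n_complete <- vapply(sound_ids, function(s) length(per_sound[[s]] %||% integer()), 0L)
    R <- trials_per_sound %||% min(n_complete)
    if (any(n_complete < R)) {
      stop("sounds with fewer than ", R, " complete trials: ",
           paste(sound_ids[n_complete < R], collapse = ", "))
    }
    vals <- array(0, c(nrow(x), length(sound_ids), R, nb))
    tcents <- (off + 0.5) * bw
    bl_bins <- which(tcents >= md$baseline[1] & tcents <= md$baseline[2])
    for (si in seq_along(sound_ids)) {
      evs <- per_sound[[sound_ids[si]]][seq_len(R)]
      for (ri in seq_along(evs)) {
        sl <- x[, on_frames[evs[ri]] + off, drop = FALSE]
        vals[, si, ri, ] <- sl - rowMeans(sl[, bl_bins, drop = FALSE])
      }
    }
    win <- c(off[1] * bw, (off[nb] + 1) * bw)
  }
  dur <- if (!is.null(durations)) unname(durations[sound_ids]) else NULL
  trial_tensor(vals, bw, win, modality, sound_ids = sound_ids,
               unit_ids = unit_ids, durations = dur)
}

# Rebin the time axis into groups of `factor` bins (summed).
rebin_tensor_values <- function(values, factor) {
  if (factor <= 1) return(values)
  d <- dim(values)
  ng <- d[4] %/% factor
  v <- values[, , , seq_len(ng * factor), drop = FALSE]
  dim(v) <- c(d[1] * d[2] * d[3], factor, ng)
  out <- colSums(aperm(v, c(2, 1, 3)))
  dim(out) <- c(d[1], d[2], d[3], ng)
  out
}

#' Trial-to-trial reliability of each unit
#'
#' For each unit and sound, the temporal response is rebinned to
#' `reliability_bin` and Pearson-correlated across all trial pairs;
#' correlations undefined because of zero-variance traces count as 0
#' (conservative toward rejection). The unit's reliability is the mean
#' over sounds of the mean trial-pair correlation.
#'
#' @param tensor A [trial_tensor()].
#' @param reliability_bin Rebinning width in seconds (default 0.005 for
#'   ephys, 0.042 for imaging).
#' @return Numeric vector of per-unit reliabilities.
#' @export
unit_reliability <- function(tensor, reliability_bin = NULL) {
  rb <- reliability_bin %||% switch(tensor$modality, ephys = 0.005, imaging = 0.042)
  fac <- max(1L, round(rb / tensor$bin_width))
  v <- rebin_tensor_values(tensor$values, fac)
  d <- dim(v)
  rel <- numeric(d[1])
  for (ui in seq_len(d[1])) {
    per_sound <- numeric(d[2])
    for (si in seq_len(d[2])) {
      m <- matrix(v[ui, si, , ], nrow = d[3])
      cc <- suppressWarnings(stats::cor(t(m)))
      cc[!is.finite(cc)] <- 0
      per_sound[si] <- mean(cc[upper.tri(cc)])
    }
    rel[ui] <- mean(per_sound)
  }
  rel
}

#' Keep units with minimally reliable sound responses
#'
#' Subsets a trial tensor to the units whose average inter-trial temporal
#' correlation across all sounds exceeds a threshold: 0.05 with 5-ms bins
#' for electrophysiology, 0.3 with 42-ms bins for two-photon imaging.
#'
#' @param tensor A [trial_tensor()].
#' @param threshold Reliability threshold (default by modality).
#' @param reliability_bin Rebinning width in seconds (default by modality).
#' @return The subset `trial_tensor`, with attribute `reliability`.
#' @export
select_reliable_units <- function(tensor, threshold = NULL,
                                  reliability_bin = NULL) {
  thr <- threshold %||% switch(tensor$modality, ephys = 0.05, imaging = 0.3)
  rel <- unit_reliability(tensor, reliability_bin)
  keep <- which(rel > thr)
  if (!length(keep)) {
    stop("no unit passes the reliability threshold ", thr)
  }
  out <- tensor
  out$values <- tensor$values[keep, , , , drop = FALSE]
  out$unit_ids <- tensor$unit_ids[keep]
  if (!is.null(tensor$unit_meta)) out$unit_meta <- tensor$unit_meta[keep, , drop = FALSE]
  attr(out, "reliability") <- rel[keep]
  out
}

#' Pool sessions into a virtual population
#'
#' Concatenates units across recording sessions and independently permutes
#' trial order within each (unit, sound), breaking single-trial noise
#' correlations between units recorded together.
#'
#' @param tensors List of [trial_tensor()]s sharing the same sounds, trial
#'   count, window and bin grid.
#' @param seed Integer seed for the trial permutations.
#' @return The pooled, trial-shuffled `trial_tensor`.
#' @export
pool_virtual_population <- function(tensors, seed = 1L) {
  stopifnot(length(tensors) >= 1)
  ref <- tensors[[1]]
  for (tns in tensors[-1]) {
    if (!identical(tns$sound_ids, ref$sound_ids) ||
        tns$trials_per_sound != ref$trials_per_sound ||
        dim(tns$values)[4] != dim(ref$values)[4]) {
      stop("sessions have mismatched catalogs, trial counts or bin grids")
    }
  }
  vals <- do.call(abind4, lapply(tensors, function(tns) tns$values))
  out <- ref
  out$values <- vals
  out$unit_ids <- make.unique(unlist(lapply(tensors, function(tns) tns$unit_ids)))
  metas <- lapply(tensors, function(tns) tns$unit_meta)
  out$unit_meta <- if (all(!vapply(metas, is.null, TRUE))) do.call(rbind, metas) else NULL
  d <- dim(vals)
  withr::with_seed(as.integer(seed), {
    for (ui in seq_len(d[1])) for (si in seq_len(d[2])) {
      out$values[ui, si, , ] <- out$values[ui, si, sample.int(d[3]), ]
    }
  })
  out
}

# rbind for 4-d arrays along the unit dimension
abind4 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, c(total, d[2], d[3], d[4]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
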