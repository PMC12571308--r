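# Shared fixtures built in code at test time.

# Small catalog subsets keep the estimator tests fast.
catalog_default <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_catalog(seed = 1L)
    val
  }
})

catalog_subset <- function(categories = NULL, level = NULL, ids = NULL) {
  cat0 <- catalog_default()
  keep <- rep(TRUE, nrow(cat0))
  if (!is.null(categories)) keep <- keep & cat0$category %in% categories
  if (!is.null(level)) keep <- keep & cat0$level == level
  if (!is.null(ids)) keep <- keep & cat0$sound_id %in% ids
  out <- cat0[keep, ]
  rownames(out) <- NULL
  out
}

rms_db <- function(w) pa_to_db_spl(sqrt(mean(w^2)))

# Deterministic tensor: trials identical to a given unit x sound pattern
# (optionally with a time course), useful for degenerate-noise checks.
pattern_tensor <- function(patterns, R = 12, nb = 1, bin_width = 0.05) {
  nu <- nrow(patterns); ns <- ncol(patterns)
  vals <- array(0, c(nu, ns, R, nb))
  for (ri in seq_len(R)) for (bi in seq_len(nb)) vals[, , ri, bi] <- patterns
  trial_tensor(vals, bin_width, c(0, nb * bin_width), "imaging")
}

# Mini-catalog: one chord plus pure tones at exactly its component
# frequencies (needed for exact linearity checks).
chord_with_tones_catalog <- function(chord_id = "chord_harmonic_05") {
  cat0 <- catalog_default()
  ch <- cat0[cat0$sound_id == chord_id, ]
  freqs <- ch$params[[1]]$freqs_khz
  tones <- cat0[rep(which(cat0$sound_id == "tone_2k_70dB"), length(freqs)), ]
  for (k in seq_along(freqs)) {
    tones$sound_id[k] <- sprintf("tone_at_%gk", freqs[k])
    tones$params[[k]]$freq_khz <- freqs[k]
    tones$params[[k]]$freq_content_khz <- freqs[k]
    tones$duration[k] <- ch$duration
  }
  out <- rbind(tones, ch)
  rownames(out) <- NULL
  out
}
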