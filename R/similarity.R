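# Noise-corrected representational similarity.
#
# The estimator: trials of each sound are split into two random halves;
# the Pearson correlation between cross-sound half-average population
# vectors (numerator) is divided by the geometric mean of the two sounds'
# split-half reliabilities (denominator), cancelling the attenuation that
# trial-to-trial variability induces in the naive trial-averaged
# correlation. Splits are redrawn 20 times; the numerator and the two
# reliabilities are each averaged across resamples before taking the
# ratio. Values are clipped to [-1, 1]; if a mean reliability is <= 0 the
# pair is noise-dominated and the result is marked undefined (NA) rather
# than clipped, and excluded from downstream pair averages.

#' Pearson correlation with explicit undefined handling
#'
#' Standard product-moment correlation; returns `NA` (undefined) when
#' either vector has zero variance instead of warning.
#'
#' @param u,v Equal-length numeric vectors (length >= 2).
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson <- function(u, v) {
  if (length(u) != length(v)) stop("pearson: length mismatch")
  if (length(u) < 2) stop("pearson: need length >= 2")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
  stats::cor(u, v)
}

# Analysis bins for one sound: sound onset to 100 ms after offset (when
# the stimulus duration is known), restricted to the extracted window.
analysis_bins <- function(tensor, sound_index) {
  nb <- dim(tensor$values)[4]
  cents <- tensor$window[1] + (seq_len(nb) - 0.5) * tensor$bin_width
  t_end <- if (!is.null(tensor$durations)) {
    min(tensor$durations[sound_index] + 0.1, tensor$window[2])
  } else tensor$window[2]
  which(cents > 0 & cents < t_end)
}

# Population vector(s) from a set of trials of one sound.
# Returns a matrix (dim_vec x n_groups) of group-averaged vectors.
half_vectors <- function(tensor, sound_index, halves, code, bins) {
  v <- tensor$values[, sound_index, , bins, drop = FALSE]
  d <- dim(v)
  out <- matrix(0, if (code == "spatial") d[1] else d[1] * d[4], length(halves))
  for (g in seq_along(halves)) {
    m <- array(v[, 1, halves[[g]], , drop = FALSE], c(d[1], length(halves[[g]]), d[4]))
    avg <- colMeans(aperm(m, c(2, 1, 3)))    # unit x bin
    out[, g] <- if (code == "spatial") rowMeans(avg) else as.numeric(avg)
  }
  out
}

split_halves <- function(R) {
  p <- sample.int(R)
  h1 <- p[seq_len(R %/% 2 + (R %% 2) * stats::rbinom(1, 1, 0.5))]
  list(h1, setdiff(p, h1))
}

#' Noise-corrected similarity between two sounds' representations
#'
#' @param tensor A [trial_tensor()].
#' @param sound_a,sound_b Sound identifiers or indices.
#' @param code `"spatial"` (time-averaged per unit) or `"spatiotemporal"`
#'   (all time bins concatenated).
#' @param n_resamples Number of random split-half resamples (default 20).
#' @param seed Integer seed for the splits.
#' @return Similarity in `[-1, 1]`, or `NA` when the estimate is
#'   undefined (non-positive mean reliability); attributes carry the mean
#'   numerator and the two reliabilities.
#' @export
noise_corrected_similarity <- function(tensor, sound_a, sound_b,
                                       code = c("spatial", "spatiotemporal"),
                                       n_resamples = 20, seed = 1L) {
  code <- match.arg(code)
  ia <- sound_index(tensor, sound_a)
  ib <- sound_index(tensor, sound_b)
  R <- tensor$trials_per_sound
  if (R < 4) stop("need at least 4 trials per sound (two non-empty halves)")
  bins_a <- analysis_bins(tensor, ia)
  bins_b <- analysis_bins(tensor, ib)
  acc <- c(cross = 0, rel_a = 0, rel_b = 0)
  nacc <- c(cross = 0L, rel_a = 0L, rel_b = 0L)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n_resamples)) {
      ha <- split_halves(R); hb <- split_halves(R)
      ab <- half_vectors(tensor, ia, ha, code, bins_a)
      cd <- half_vectors(tensor, ib, hb, code, bins_b)
      cross <- c(pearson(ab[, 1], cd[, 1]), pearson(ab[, 1], cd[, 2]),
                 pearson(ab[, 2], cd[, 1]), pearson(ab[, 2], cd[, 2]))
      rel_a <- pearson(ab[, 1], ab[, 2])
      rel_b <- pearson(cd[, 1], cd[, 2])
      if (any(fin <- is.finite(cross))) {
        acc["cross"] <- acc["cross"] + sum(cross[fin]) / sum(fin)
        nacc["cross"] <- nacc["cross"] + 1L
      }
      if (is.finite(rel_a)) { acc["rel_a"] <- acc["rel_a"] + rel_a; nacc["rel_a"] <- nacc["rel_a"] + 1L }
      if (is.finite(rel_b)) { acc["rel_b"] <- acc["rel_b"] + rel_b; nacc["rel_b"] <- nacc["rel_b"] + 1L }
    }
  })
  if (any(nacc == 0)) return(NA_real_)
  m <- acc / nacc
  if (m["rel_a"] <= 0 || m["rel_b"] <= 0) {
    return(structure(NA_real_, cross = unname(m["cross"]),
                     rel_a = unname(m["rel_a"]), rel_b = unname(m["rel_b"])))
  }
  structure(clip1(unname(m["cross"] / sqrt(m["rel_a"] * m["rel_b"]))),
            cross = unname(m["cross"]), rel_a = unname(m["rel_a"]),
            rel_b = unname(m["rel_b"]))
}

sound_index <- function(tensor, sound) {
  if (is.character(sound)) {
    i <- match(sound, tensor$sound_ids)
    if (is.na(i)) stop("unknown sound: ", sound)
    i
  } else as.integer(sound)
}

#' Full RSA matrix of noise-corrected similarities
#'
#' Evaluates the noise-corrected estimator for every unordered sound pair.
#' Within each resample one split-half partition is drawn per sound and
#' shared across all pairs, which lets all pairwise correlations be
#' computed in a single matrix operation; diagonal entries use a second
#' independent partition of the same sound so that self-similarity is an
#' honest split-to-split estimate (~1 for reliable populations).
#'
#' @inheritParams noise_corrected_similarity
#' @return A `similarity_matrix` object: list with `values` (sounds x
#'   sounds, `NA` = undefined), `sound_ids`, `code`, `n_resamples`,
#'   `seed`, `reliability` (per-sound mean split-half reliability) and
#'   `combine = "ratio_of_means"`.
#' @export
rsa_matrix <- function(tensor, code = c("spatial", "spatiotemporal"),
                       n_resamples = 20, seed = 1L) {
  code <- match.arg(code)
  R <- tensor$trials_per_sound
  if (R < 4) stop("need at least 4 trials per sound")
  ns <- n_sounds(tensor)
  bins <- lapply(seq_len(ns), function(si) analysis_bins(tensor, si))
  cross_sum <- matrix(0, ns, ns); cross_n <- matrix(0L, ns, ns)
  rel_sum <- numeric(ns); rel_n <- integer(ns)
  diag_sum <- numeric(ns); diag_n <- integer(ns)
  rel2_sum <- numeric(ns); rel2_n <- integer(ns)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n_resamples)) {
      M1 <- M2 <- N1 <- N2 <- vector("list", ns)
      for (si in seq_len(ns)) {
        h <- split_halves(R)
        hv <- half_vectors(tensor, si, h, code, bins[[si]])
        M1[[si]] <- hv[, 1]; M2[[si]] <- hv[, 2]
        h2 <- split_halves(R)
        hv2 <- half_vectors(tensor, si, h2, code, bins[[si]])
        N1[[si]] <- hv2[, 1]; N2[[si]] <- hv2[, 2]
      }
      if (code == "spatial") {
        A1 <- do.call(cbind, M1); A2 <- do.call(cbind, M2)
        B1 <- do.call(cbind, N1); B2 <- do.call(cbind, N2)
        cc <- suppressWarnings(
          (stats::cor(A1, B1) + stats::cor(A1, B2) +
             stats::cor(A2, B1) + stats::cor(A2, B2)) / 4)
        rel <- suppressWarnings(diag_cor(A1, A2))
        rel2 <- suppressWarnings(diag_cor(B1, B2))
      } else {
        # spatio-temporal vectors can differ in length across sounds
        # (per-sound analysis windows); correlate pairwise
        cc <- matrix(NA_real_, ns, ns)
        for (i in seq_len(ns)) for (j in seq_len(ns)) {
          ni <- min(length(M1[[i]]), length(N1[[j]]))
          cc[i, j] <- mean(c(pearson(M1[[i]][1:ni], N1[[j]][1:ni]),
                             pearson(M1[[i]][1:ni], N2[[j]][1:ni]),
                             pearson(M2[[i]][1:ni], N1[[j]][1:ni]),
                             pearson(M2[[i]][1:ni], N2[[j]][1:ni])), na.rm = TRUE)
        }
        rel <- vapply(seq_len(ns), function(si) pearson(M1[[si]], M2[[si]]), 0)
        rel2 <- vapply(seq_len(ns), function(si) pearson(N1[[si]], N2[[si]]), 0)
      }
      fin <- is.finite(cc)
      cross_sum[fin] <- cross_sum[fin] + cc[fin]; cross_n <- cross_n + fin
      fr <- is.finite(rel)
      rel_sum[fr] <- rel_sum[fr] + rel[fr]; rel_n <- rel_n + fr
      fr2 <- is.finite(rel2)
      rel2_sum[fr2] <- rel2_sum[fr2] + rel2[fr2]; rel2_n <- rel2_n + fr2
      dd <- diag(cc)
      fd <- is.finite(dd)
      diag_sum[fd] <- diag_sum[fd] + dd[fd]; diag_n <- diag_n + fd
    }
  })
  rel_mean <- ifelse(rel_n + rel2_n > 0, (rel_sum + rel2_sum) / (rel_n + rel2_n), NA)
  cross_mean <- ifelse(cross_n > 0, cross_sum / cross_n, NA)
  # off-diagonal: use the first-partition splits (cross terms vs the
  # independent second partition of the other sound)
  den <- sqrt(outer(pmax(rel_mean, 0), pmax(rel_mean, 0)))
  vals <- clip1(cross_mean / den)
  vals[!is.finite(vals)] <- NA
  vals[outer(rel_mean <= 0 | !is.finite(rel_mean),
             rel_mean <= 0 | !is.finite(rel_mean), `|`)] <- NA
  vals <- (vals + t(vals)) / 2   # symmetrise (cc is near- but not exactly symmetric)
  structure(list(values = vals, sound_ids = tensor$sound_ids, code = code,
                 n_resamples = n_resamples, seed = seed,
                 reliability = rel_mean, combine = "ratio_of_means"),
            class = "similarity_matrix")
}

diag_cor <- function(A, B) {
  vapply(seq_len(ncol(A)), function(j) {
    if (stats::sd(A[, j]) == 0 || stats::sd(B[, j]) == 0) NA_real_
    else stats::cor(A[, j], B[, j])
  }, 0)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  nund <- sum(is.na(x$values[upper.tri(x$values)]))
  cat(sprintf("<similarity_matrix> %d sounds, %s code, %d resamples, %d undefined pairs\n",
              nrow(x$values), x$code, x$n_resamples, nund))
  invisible(x)
}

#' Mean similarity over sound pairs
#'
#' Arithmetic mean and SEM of the noise-corrected similarity across a set
#' of unordered off-diagonal pairs; undefined (NA) entries are excluded
#' and the contributing pair count reported.
#'
#' @param matrix A `similarity_matrix` (or plain numeric matrix).
#' @param pairs Optional 2-column matrix/data.frame of pair indices (or a
#'   logical selection matrix); default all off-diagonal unordered pairs.
#' @return List with `mean`, `sem`, `n`.
#' @export
mean_similarity <- function(matrix, pairs = NULL) {
  m <- if (inherits(matrix, "similarity_matrix")) matrix$values else matrix
  if (is.null(pairs)) {
    vals <- m[upper.tri(m)]
  } else {
    pairs <- as.matrix(pairs)
    if (!nrow(pairs)) stop("empty pair subset")
    vals <- m[pairs]
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no defined similarity values in the requested subset")
  list(mean = mean(vals), sem = sem(vals), n = length(vals))
}

#' Export a similarity matrix as CSV
#'
#' @param matrix A `similarity_matrix`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_similarity <- function(matrix, path) {
  m <- matrix$values
  dimnames(m) <- list(matrix$sound_ids, matrix$sound_ids)
  utils::write.csv(m, path)
  invisible(path)
}
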