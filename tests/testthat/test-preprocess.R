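# dF/F, deconvolution, trial extraction, reliability screen, pooling.

test_that("dF/F is zero for a constant trace and linear in neuropil subtraction", {
  n <- 2000
  tr <- dff(rep(5, n), rep(0, n), frame_rate = 22.9)
  expect_true(tr$valid)
  expect_equal(max(abs(tr$f)), 0, tolerance = 1e-12)

  F <- rep(10, n)
  Fnp <- F / 2
  tr0 <- dff(F, Fnp, neuropil_fraction = 0)
  tr7 <- dff(F, Fnp, neuropil_fraction = 0.7)
  # corrected traces differ by 0.7 * 0.5 * F = 0.35 * F
  expect_equal((F - 0 * Fnp) - (F - 0.7 * Fnp), rep(0.35 * F[1], n))
  expect_equal(tr0$F0 / tr7$F0, rep(10 / 6.5, n), tolerance = 1e-9)
})

test_that("dF/F peak of a transient over constant baseline matches a direct percentile oracle", {
  fr <- 22.9
  n <- round(fr * 240)
  F <- rep(8, n)
  spike_at <- round(n / 2)
  tim <- seq_len(200)
  F[spike_at + tim] <- F[spike_at + tim] + 4 * exp(-tim / (2 * fr))
  tr <- dff(F, frame_rate = fr, baseline_filter_sigma = 2, baseline_window = 60)
  # oracle: direct sliding percentile on the same Gaussian-filtered trace
  Fg <- gaussian_smooth(F, 2, 1 / fr)
  w <- round(60 * fr)
  F0_mid <- quantile(Fg[(spike_at - w / 2):(spike_at + w / 2)], 0.03, names = FALSE)
  expect_equal(max(tr$f), (max(F) - F0_mid) / F0_mid, tolerance = 0.02)
  # peak dF/F ~ transient / baseline
  expect_equal(max(tr$f), 4 / 8, tolerance = 0.05)
})

test_that("dF/F flags units with non-positive baseline instead of silent NaN", {
  n <- 2000
  tr <- dff(rep(0, n), rep(0, n))
  expect_false(tr$valid)
  expect_error(deconvolve(tr), "flagged")
})

test_that("deconvolution inverts the indicator kernel", {
  fr <- 100; tau <- 2
  t <- seq(0, 20, by = 1 / fr)
  # constant f -> r = c / tau (before smoothing)
  r <- deconvolve(rep(0.6, length(t)), frame_rate = fr, tau_decay = tau,
                  smoothing_sigma = 0)
  expect_equal(r, rep(0.6 / tau, length(t)), tolerance = 1e-12)
  # f = exp(-t/tau): f' = -f/tau exactly, so r ~ 0 up to discretisation
  r <- deconvolve(exp(-t / tau), frame_rate = fr, tau_decay = tau,
                  smoothing_sigma = 0)
  expect_lt(max(abs(r[2:(length(r) - 1)])), 1e-5)
  # linear ramp f = a t -> r = a + a t / tau on interior points
  a <- 0.3
  r <- deconvolve(a * t, frame_rate = fr, tau_decay = tau, smoothing_sigma = 0)
  expect_equal(r[2:(length(r) - 1)], (a + a * t / tau)[2:(length(t) - 1)],
               tolerance = 1e-9)
  expect_error(deconvolve(c(1, 2), frame_rate = fr), "too short")
})

test_that("deconvolution recovers an impulse rate from its calcium transient", {
  fr <- 100; tau <- 2
  t <- seq(0, 10, by = 1 / fr)
  rate <- numeric(length(t)); rate[300] <- 1
  kern <- exp(-(seq(0, 8, by = 1 / fr)) / tau)
  f <- stats::convolve(rate, rev(kern), type = "open")[seq_along(t)]
  r <- deconvolve(f, frame_rate = fr, tau_decay = tau, smoothing_sigma = 0.031)
  expect_equal(which.max(r), 300, tolerance = 2)
  # mass concentrated at the impulse, not spread over the decay
  expect_gt(sum(r[295:305]), 0.8 * sum(r[r > 0]))
})

test_that("spike-train extraction bins and baseline-subtracts per trial", {
  # deterministic 10-spike burst at +50 ms on every trial, silence elsewhere
  onsets <- seq(1, by = 2, length.out = 12)
  spikes <- data.frame(
    unit_id = "u1",
    spike_time_s = as.numeric(vapply(onsets, function(o) o + 0.050 + (0:9) * 1e-4,
                                     numeric(10))))
  events <- data.frame(sound_id = "s1", onset_s = onsets)
  tt <- extract_trials(spikes, events, "ephys", t_max = 30)
  expect_s3_class(tt, "trial_tensor")
  expect_equal(dim(tt$values), c(1, 1, 12, 1300))
  # 10 spikes fall in bins covering 50-60 ms post-onset
  cents <- tt$window[1] + (seq_len(1300) - 0.5) * tt$bin_width
  burst <- which(cents > 0.049 & cents < 0.061)
  base <- 10 / 1300  # subtracted baseline-window mean (baseline has 0 spikes,
                     # but each trial's own baseline mean is 0 here)
  expect_equal(sum(tt$values[1, 1, 1, burst] - min(tt$values[1, 1, 1, ])), 10,
               tolerance = 1e-9)
  # prestimulus bins are (0 - baseline mean) = 0
  pre <- which(cents < 0)
  expect_equal(unique(round(tt$values[1, 1, 1, pre], 12)), 0)
})

test_that("stationary Poisson activity averages to ~0 after baseline subtraction", {
  set.seed(7)
  rate <- 20; t_max <- 120
  spikes <- data.frame(unit_id = "u1",
                       spike_time_s = sort(runif(rate * t_max, 0, t_max)))
  onsets <- seq(1, 100, by = 2)
  events <- data.frame(sound_id = rep(c("a", "b"), length.out = length(onsets)),
                       onset_s = onsets)
  tt <- extract_trials(spikes, events, "ephys", t_max = t_max)
  post <- tt$values[1, , , (301:1300)]
  expect_lt(abs(mean(post)), 0.005)   # counts per 1-ms bin
})

test_that("imaging extraction equals hand-sliced windows", {
  fr <- 20
  n_frames <- 2000
  x <- matrix(rnorm(2 * n_frames), nrow = 2)
  x[1, 501:520] <- x[1, 501:520] + 5    # step response at onset frame 501
  events <- data.frame(sound_id = rep(c("a", "b"), 6),
                       onset_s = seq(25, 80, by = 5))
  tt <- extract_trials(x, events, "imaging", frame_rate = fr)
  # oracle: index arithmetic on the fixture
  on_f <- round(events$onset_s[1] * fr) + 1
  off <- seq(floor(-0.2 * fr), ceiling(0.8 * fr) - 1)
  sl <- x[, on_f + off]
  tcent <- (off + 0.5) / fr
  bl <- which(tcent >= -0.2 & tcent <= -0.02)
  expect_equal(tt$values[, 1, 1, ], sl - rowMeans(sl[, bl]), tolerance = 1e-12)
})

test_that("incomplete trials near recording edges are dropped; too few trials error", {
  spikes <- data.frame(unit_id = "u1", spike_time_s = seq(0.5, 19.5, by = 0.1))
  events <- data.frame(sound_id = "a", onset_s = c(0.1, seq(2, 18, by = 2)))
  tt <- extract_trials(spikes, events, "ephys", t_max = 19.5)
  expect_equal(dim(tt$values)[3], 9)    # the 0.1-s onset is incomplete
  expect_error(extract_trials(spikes, events, "ephys", trials_per_sound = 12,
                              t_max = 19.5), "fewer than 12")
})

test_that("reliability screen keeps reproducible units and rejects noise units", {
  set.seed(3)
  R <- 12; nb <- 200
  trace <- sin(seq(0, 3 * pi, length.out = nb))   # nonconstant template
  vals <- array(0, c(2, 3, R, nb))
  for (si in 1:3) for (ri in 1:R) {
    vals[1, si, ri, ] <- trace                    # identical trials
    vals[2, si, ri, ] <- rnorm(nb)                # independent noise
  }
  tt <- trial_tensor(vals, 0.001, c(0, 0.2), "ephys")
  rel <- unit_reliability(tt)
  expect_equal(rel[1], 1, tolerance = 1e-9)
  expect_lt(abs(rel[2]), 0.05)
  kept <- select_reliable_units(tt)
  expect_equal(dim(kept$values)[1], 1L)
  expect_error(select_reliable_units(tt, threshold = 2), "threshold")
})

test_that("reliability screen is monotone in the threshold", {
  set.seed(11)
  vals <- array(rnorm(8 * 4 * 8 * 50), c(8, 4, 8, 50))
  for (ui in 1:4) vals[ui, , , ] <- vals[ui, , , ] +
    rep(sin(seq_len(50) / 5) * ui / 2, each = 4 * 8)
  tt <- trial_tensor(vals, 0.005, c(0, 0.25), "ephys")
  rel <- unit_reliability(tt)
  kept_sizes <- vapply(c(-1, 0.05, 0.2, 0.5), function(th) {
    sum(rel > th)
  }, 0)
  expect_true(all(diff(kept_sizes) <= 0))
})

test_that("virtual-population pooling concatenates units and shuffles trials", {
  set.seed(5)
  mk <- function(nu) trial_tensor(array(rnorm(nu * 2 * 6 * 10), c(nu, 2, 6, 10)),
                                  0.01, c(0, 0.1), "ephys")
  a <- mk(3); b <- mk(4)
  pooled <- pool_virtual_population(list(a, b), seed = 9)
  expect_equal(dim(pooled$values)[1], 7)
  # shuffling is deterministic given the seed
  pooled2 <- pool_virtual_population(list(a, b), seed = 9)
  expect_identical(pooled$values, pooled2$values)
  # per-(unit, sound) trial means unchanged by permutation
  expect_equal(apply(pooled$values[1:3, , , ], c(1, 2), mean),
               apply(a$values, c(1, 2), mean), tolerance = 1e-12)
  # trial order actually permuted somewhere
  expect_false(identical(pooled$values[1:3, , , ], a$values))
  bad <- mk(3); bad$sound_ids <- c("x", "y")
  expect_error(pool_virtual_population(list(a, bad)), "mismatched")
})
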