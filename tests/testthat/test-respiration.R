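# Smoothing, extrema and breath separation, CWT artifact criterion, and
# Gaussian breath gating.

test_that("the low-pass filter has unit DC gain and the specified roll-off", {
  fs <- 30
  expect_equal(smooth_signal(rep(5, 100), fs), rep(5, 100), tolerance = 1e-8)
  t <- (0:(fs * 40 - 1)) / fs
  in_band <- sin(2 * pi * 0.25 * t)
  out <- smooth_signal(in_band, fs)
  mid <- seq(fs * 5, fs * 35)           # steady-state section
  expect_equal(diff(range(out[mid])) / 2, 1, tolerance = 0.02)
  stop_band <- sin(2 * pi * 5 * t)
  out5 <- smooth_signal(stop_band, fs)
  expect_lt(diff(range(out5[mid])) / 2, 0.01)
  expect_error(smooth_signal(rep(1, 10), fs), "too short")
})

test_that("extrema detection counts a 4 s sine over 60 s correctly", {
  t <- (0:1799) / 30
  e <- detect_extrema(sin(2 * pi * t / 4))
  expect_identical(length(e$maxima), 15L)
  expect_true(abs(length(e$minima) - 15L) <= 1)
  expect_true(all(diff(sort(c(e$minima, e$maxima))) > 0))
})

test_that("monotone signals have no interior extrema", {
  e <- detect_extrema(seq(0, 5, length.out = 100))
  expect_identical(length(e$maxima), 0L)
  expect_identical(length(e$minima), 0L)
})

test_that("plateaus yield a single extremum at their left edge", {
  x <- c(0, 1, 2, 2, 2, 1, 0)
  e <- detect_extrema(x)
  expect_identical(e$maxima, 3L)
  xm <- c(3, 2, 1, 1, 1, 2, 3)
  em <- detect_extrema(xm)
  expect_identical(em$minima, 3L)
})

test_that("extrema alternate strictly on arbitrary smooth signals", {
  set.seed(42)
  for (rep_ in 1:5) {
    x <- smooth_signal(cumsum(rnorm(600)), 30, cutoff = 2)
    e <- detect_extrema(x)
    merged <- sort(c(e$minima, e$maxima))
    types <- ifelse(merged %in% e$minima, "min", "max")
    expect_true(all(types[-1] != types[-length(types)]))
  }
})

test_that("breaths span consecutive central minima with shared indices", {
  # synthetic smoothed trace with minima at 10, 40, 70
  x <- rep(1, 80)
  x[10] <- 0; x[40] <- -0.5; x[70] <- 0.2
  x[25] <- 2; x[55] <- 3
  ext <- list(minima = c(10L, 40L, 70L), maxima = c(25L, 55L))
  br <- separate_breaths(x, ext, 30)
  expect_identical(nrow(br), 2L)
  expect_equal(br$start, c(10, 40))
  expect_equal(br$end, c(40, 70))
  expect_equal(br$period_s, c(1, 1))
  expect_equal(br$amplitude_cm[1], 2 - 0.5 * (0 + -0.5))
  # fewer than two minima: zero breaths with a warning
  expect_warning(none <- separate_breaths(x, list(minima = 10L, maxima = integer()), 30),
                 "fewer than 2")
  expect_identical(nrow(none), 0L)
})

test_that("the Morlet wavelet matches its closed form", {
  expect_identical(morlet(0), 1)
  expect_equal(morlet(1), exp(-1) * cos(pi * sqrt(2 / log(2))))
  expect_equal(morlet(-2:2), morlet(2:-2))  # even symmetry
})

test_that("the scalogram matches a direct discretized integral", {
  set.seed(7)
  x <- sin(2 * pi * 0.25 * (0:149) / 30) + rnorm(150, 0, 0.1)
  scales <- c(4, 15, 60)
  W <- compute_scalogram(x, scales)
  oracle <- function(a, b) {
    n <- length(x); L <- ceiling(4 * a)
    idx <- seq(1 - L, n + L)
    q <- (idx - 1) %% (2 * n)
    xp <- x[ifelse(q < n, q + 1, 2 * n - q)]
    abs(sum(xp * morlet((idx - b) / a)) / sqrt(a))
  }
  for (si in seq_along(scales)) for (b in c(1, 43, 150))
    expect_lt(abs(W[si, b] - oracle(scales[si], b)), 1e-5)  # FFT roundoff
  expect_equal(max(compute_scalogram(rep(0, 50), scales)), 0)
  expect_error(compute_scalogram(x, c(-1, 2)), "positive")
  expect_error(compute_scalogram(numeric(), 2), "empty")
})

test_that("the dominant scale of a 0.25 Hz tone maps to 0.25 Hz", {
  fs <- 30
  x <- sin(2 * pi * 0.25 * (0:(fs * 60 - 1)) / fs)
  scales <- cwt_scales(fs)
  W <- compute_scalogram(x, scales)
  prof <- rowMeans(W[, seq(fs * 10, fs * 50)])   # avoid edges
  f_hat <- attr(scales, "pseudo_freq")[which.max(prof)]
  expect_lt(abs(f_hat - 0.25) / 0.25, 0.1)
})

test_that("the 99th-percentile rule flags exactly 1 percent of samples", {
  set.seed(11)
  r <- matrix(rnorm(1000), 1000, 1)
  res <- detect_artifact_samples(r, frame_rate = 30)
  expect_identical(sum(res$masks), 10L)
  expect_identical(res$merged, res$masks[, 1])
})

test_that("artifact breath removal follows the merged mask", {
  br <- data.frame(breath_id = 1:3, start = c(10L, 40L, 70L),
                   max_idx = c(25L, 55L, 85L), end = c(40L, 70L, 100L),
                   period_s = 1, amplitude_cm = 1)
  none <- remove_artifact_breaths(br, rep(FALSE, 100))
  expect_true(all(none$retained))
  mask <- rep(FALSE, 100); mask[50] <- TRUE   # interior of breath 2 only
  one <- remove_artifact_breaths(br, mask)
  expect_identical(one$retained, c(TRUE, FALSE, TRUE))
  expect_error(remove_artifact_breaths(br, rep(TRUE, 100)), "no clean breathing")
})

test_that("Gaussian gating keeps the shared pattern and cuts only the tail", {
  set.seed(21)
  feats <- data.frame(period_s = rnorm(80, 2, 0.2),
                      amplitude_cm = rnorm(80, 1.5, 0.08))
  g <- gate_breaths(feats, feats)
  expect_gte(mean(g$keep_a), 0.95)
  expect_identical(g$keep_a, g$keep_b)
  # a 10-SD shift leaves (nearly) nothing
  far <- data.frame(period_s = feats$period_s + 10 * sd(feats$period_s),
                    amplitude_cm = feats$amplitude_cm)
  g2 <- gate_breaths(feats, far)
  expect_lte(mean(g2$keep_a), 0.02)
  expect_lte(mean(g2$keep_b), 0.02)
})

test_that("membership at the 5 percent contour is inclusive", {
  model <- list(mean = c(2, 1.5), cov = diag(2), n = 50)
  d95 <- sqrt(qchisq(0.95, df = 2))
  on_contour <- data.frame(period_s = 2 + d95, amplitude_cm = 1.5)
  p <- membership_probability(on_contour, model)
  expect_equal(p, 0.05, tolerance = 1e-12)
  expect_true(p >= 0.05)
})

test_that("degenerate feature directions gate by tolerance, not error", {
  feats <- data.frame(period_s = rep(2, 10), amplitude_cm = rep(1.5, 10))
  g <- gate_breaths(feats, feats)
  expect_true(all(g$keep_a))
  expect_error(gate_breaths(feats[1:3, ]), ">= 5 breaths")
})
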