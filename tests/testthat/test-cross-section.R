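# Cross-section extraction, interpolation, areas, the IQR outlier cascade,
# medoid representative selection, and the session metrics.

fake_breaths <- function(samples) {
  data.frame(breath_id = seq_along(samples), start = samples - 5L,
             max_idx = samples, end = samples + 5L,
             period_s = 1, amplitude_cm = 1)
}

test_that("constant signals yield flat cross-sections at the right samples", {
  sig <- constant_signals(n = 40, depth = 5)
  br <- fake_breaths(c(10L, 20L, 30L))
  cs <- extract_cross_sections(sig, br, "inspiration")
  expect_identical(nrow(cs), 3L * 3L * 7L)
  expect_true(all(cs$depth_cm == 5))
  expect_setequal(unique(cs$sample), c(10, 20, 30))
  # the three levels of one breath share the time sample
  triplet <- cs[cs$breath_id == 1, ]
  expect_identical(length(unique(triplet$sample)), 1L)
  # expiration uses the breath's end minimum
  cse <- extract_cross_sections(sig, br, "expiration")
  expect_setequal(unique(cse$sample), c(15, 25, 35))
  expect_error(extract_cross_sections(sig, fake_breaths(100L), "inspiration"),
               "out of signal range")
})

test_that("inspiration depths dominate expiration depths on the phantom", {
  fx <- default_session()
  s <- fx$session
  kept <- s$breaths[s$breaths$retained, ]
  insp <- extract_cross_sections(s$signals, kept, "inspiration")
  exp_ <- extract_cross_sections(s$signals, kept, "expiration")
  key <- function(d) paste(d$breath_id, d$level, d$j)
  m <- match(key(exp_), key(insp))
  expect_true(all(insp$depth_cm[m] >= exp_$depth_cm - 0.05))
})

test_that("linear interpolation reproduces nodes, midpoints and lines", {
  y <- seq(-9, 9, length.out = 7)
  depth <- c(4, 6, 5, 5, 7, 3, 4)
  expect_equal(interpolate_cs(y, depth, (y[1] + y[2]) / 2), 5)
  expect_equal(interpolate_cs(y, depth, y), depth)
  line <- 2 + 0.5 * y
  qs <- runif(20, -9, 9)
  expect_equal(interpolate_cs(y, line, qs), 2 + 0.5 * qs)
  expect_error(interpolate_cs(y, depth, 10), "extrapolation")
})

test_that("trapezoidal areas are exact for rectangles and triangles", {
  y <- seq(0, 18, length.out = 7)
  expect_equal(cs_area(y, rep(5, 7)), 90)
  expect_equal(cs_area(y, seq(0, 6, length.out = 7)), 54)
})

test_that("area is invariant under resampling of the piecewise-linear curve", {
  set.seed(3)
  for (rep_ in 1:20) {
    y <- sort(runif(7, -9, 9))
    depth <- runif(7, 2, 10)
    fine <- seq(y[1], y[7], by = 0.1)
    fine <- unique(sort(c(fine, y)))   # include the knots
    a1 <- cs_area(y, depth)
    a2 <- cs_area(fine, interpolate_cs(y, depth, fine))
    expect_equal(a1, a2, tolerance = 1e-9)
  }
})

test_that("IQR fences flag exactly the constructed outliers and propagate", {
  sig <- constant_signals(n = 200, depth = 8)
  # member depths spread evenly (no natural fence violations); one CS gets a
  # far-out node at level 1, j = 4
  samples <- seq(10L, 190L, by = 10L)
  r <- sig$r
  spread <- seq(-0.1, 0.1, length.out = length(samples))
  for (k in seq_along(samples)) r[samples[k], ] <- 8 + spread[k]
  target <- samples[7]
  v <- r[samples, "r_1_4"]
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  r[target, "r_1_4"] <- q[2] + 2 * (q[2] - q[1])
  sig$r <- r
  cs <- extract_cross_sections(sig, fake_breaths(samples), "inspiration")
  flagged <- flag_outliers(cs)
  out_samples <- unique(flagged$sample[flagged$outlier])
  expect_identical(out_samples, target)
  # the partner CSs at the other levels share the flag (cascade)
  for (lv in 1:3)
    expect_true(all(flagged$outlier[flagged$sample == target & flagged$level == lv]))
  # identical members produce no flags
  cs0 <- extract_cross_sections(constant_signals(n = 50), fake_breaths(c(10L, 20L, 30L, 40L)),
                                "inspiration")
  expect_false(any(flag_outliers(cs0)$outlier))
  expect_error(flag_outliers(cs0[cs0$sample < 25, ]), "fewer than 4")
})

test_that("IQR flags agree with a quartile oracle on random groups", {
  set.seed(9)
  for (rep_ in 1:5) {
    sig <- constant_signals(n = 400, depth = 8)
    samples <- seq(10L, 390L, by = 10L)
    sig$r[samples, ] <- 8 + matrix(rnorm(length(samples) * 21, 0, 0.5),
                                   length(samples), 21)
    cs <- extract_cross_sections(sig, fake_breaths(samples), "inspiration")
    flagged <- flag_outliers(cs)
    # oracle: recompute fences per level x location from the raw matrix
    bad <- rep(FALSE, length(samples))
    for (lv in c(1, 3, 5)) for (jj in 1:7) {
      v <- sig$r[samples, sprintf("r_%d_%d", lv, jj)]
      q <- quantile(v, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      bad <- bad | v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr
    }
    got <- sort(unique(flagged$sample[flagged$outlier]))
    expect_identical(got, sort(samples[bad]))
  }
})

test_that("the medoid matches brute force and breaks ties by time", {
  # collinear areas 0, 1, 10: the middle point is the medoid
  pts <- rbind(c(0, 0, 0), c(1, 1, 1), c(10, 10, 10)) / sqrt(3)
  sig <- constant_signals(n = 100)
  samples <- c(10L, 20L, 30L)
  for (k in 1:3) {
    depths <- pts[k, ] / 18   # area = depth * 18
    for (li in 1:3) sig$r[samples[k], (li - 1) * 7 + 1:7] <- depths[li]
  }
  cs <- extract_cross_sections(sig, fake_breaths(samples), "inspiration")
  rep_ <- select_representative(cs)
  expect_equal(rep_$sample, 20)
  # single triplet: itself
  one <- select_representative(cs[cs$sample == 10, ])
  expect_equal(one$sample, 10)
  # random groups vs exhaustive oracle
  set.seed(13)
  for (rep_i in 1:10) {
    n <- sample(5:40, 1)
    sig2 <- constant_signals(n = 10 * n + 20)
    samples2 <- seq(10L, by = 10L, length.out = n)
    A <- matrix(runif(3 * n, 50, 150), n, 3)
    for (k in seq_len(n)) for (li in 1:3)
      sig2$r[samples2[k], (li - 1) * 7 + 1:7] <- A[k, li] / 18
    cs2 <- extract_cross_sections(sig2, fake_breaths(samples2), "inspiration")
    got <- select_representative(cs2)
    # oracle: explicit double loop over sum of Euclidean distances
    tot <- vapply(seq_len(n), function(i)
      sum(vapply(seq_len(n), function(j) sqrt(sum((A[i, ] - A[j, ])^2)),
                 numeric(1))), numeric(1))
    expect_identical(got$sample, samples2[which.min(tot)])
  }
})

test_that("dispersion follows the sample-standard-deviation convention", {
  sig <- constant_signals(n = 50, depth = 5)
  cs <- extract_cross_sections(sig, fake_breaths(c(10L, 20L, 30L, 40L)),
                               "inspiration")
  d <- cs_dispersion(cs[cs$level == 1, ])
  expect_equal(d$cv_location, rep(0, 7))
  expect_equal(d$cv_area, 0)
  # two members with node depths 8 and 12: CV = 100 * sd / mean = 28.28...
  sig$r[10, ] <- 8; sig$r[20, ] <- 12
  cs2 <- extract_cross_sections(sig, fake_breaths(c(10L, 20L)), "inspiration")
  d2 <- cs_dispersion(cs2[cs2$level == 1, ])
  expect_equal(d2$cv_location, rep(100 * sd(c(8, 12)) / 10, 7))
  expect_equal(d2$cv_area, 100 * sd(c(8, 12) * 18) / (10 * 18))
  sigz <- constant_signals(n = 50, depth = 0)
  csz <- extract_cross_sections(sigz, fake_breaths(c(10L, 20L)), "inspiration")
  expect_error(cs_dispersion(csz[csz$level == 1, ]), "zero mean")
})

test_that("mobility and morphology-change percentages follow their formulas", {
  rep_max <- list(areas = c(105, 110, 120))
  rep_min <- list(areas = c(100, 110, 100))
  mob <- chest_mobility(rep_max, rep_min)
  expect_equal(mob$dsess_pct, c(5, 0, 20))
  expect_error(chest_mobility(rep_max, list(areas = c(0, 1, 1))),
               "non-positive")
  d <- morphology_change(list(areas = c(100, 100, 100)),
                         list(areas = c(95, 100, 103)))
  expect_equal(d$d_pct, c(-5, 0, 3))
  expect_equal(morphology_change(rep_max, rep_max)$d_pct, c(0, 0, 0))
  expect_error(morphology_change(list(areas = c(-1, 1, 1)), rep_max),
               "non-positive")
})
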