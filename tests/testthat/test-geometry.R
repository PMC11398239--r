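# Table-plane fitting, rigid alignment, grid construction, and depth-signal
# extraction.

plane_frame <- function(normal = c(0, 0, 1), d = 53, sigma = 0, n_side = 40) {
  xs <- seq(-10, 10, length.out = n_side)
  xy <- cbind(rep(xs, times = n_side), rep(xs, each = n_side))
  normal <- normal / sqrt(sum(normal^2))
  z <- (d - normal[1] * xy[, 1] - normal[2] * xy[, 2]) / normal[3]
  if (sigma > 0) z <- z + rnorm(nrow(xy), 0, sigma)
  frame(cbind(xy, z), matrix(128, nrow(xy), 3))
}

everything <- function() roi_box()

test_that("an exact horizontal plane is recovered perfectly", {
  fr <- plane_frame()
  pl <- fit_table_plane(fr, everything())
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$d, 53, tolerance = 1e-12)
  expect_lt(pl$residual, 1e-10)
})

test_that("a 2-degree tilt is recovered to within 0.01 degrees", {
  n_true <- c(sin(2 * pi / 180), 0, cos(2 * pi / 180))
  fr <- plane_frame(normal = n_true)
  pl <- fit_table_plane(fr, everything())
  angle <- acos(min(1, sum(pl$normal * n_true))) * 180 / pi
  expect_lt(angle, 0.01)
})

test_that("plane-fit residual reflects the noise level", {
  set.seed(8)
  fr <- plane_frame(sigma = 0.1)
  pl <- fit_table_plane(fr, everything())
  expect_equal(pl$residual, 0.1, tolerance = 0.02)
})

test_that("degenerate table regions are rejected", {
  fr <- plane_frame(n_side = 8)   # 64 points < 100
  expect_error(fit_table_plane(fr, everything()), "need >= 100")
  set.seed(8)
  noisy <- plane_frame(sigma = 2)
  expect_error(fit_table_plane(noisy, everything()), "residual")
})

test_that("alignment is the identity for already-aligned input", {
  pl <- fit_table_plane(plane_frame(), everything())
  mk <- rbind(left_nipple = c(0, -9, 44), right_nipple = c(0, 9, 44),
              navel = c(18, 0, 45))
  tf <- compute_alignment(mk, pl)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-9)
})

test_that("alignment forces equal nipple x-coordinates and is rigid", {
  pl <- list(normal = c(0.05, -0.03, 1) / sqrt(1 + 0.05^2 + 0.03^2), d = 53)
  mk <- rbind(left_nipple = c(0, -10, 44), right_nipple = c(1, 10, 44.4),
              navel = c(18, 0.5, 45))
  tf <- compute_alignment(mk, pl)
  out <- apply_transform(tf, mk)
  expect_lt(abs(out[1, 1] - out[2, 1]), 1e-9)
  expect_gt(out[2, 2], out[1, 2])   # left nipple at the smaller y
  # pairwise distances are preserved to 1e-9
  d0 <- dist(mk); d1 <- dist(out)
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # rotation is orthonormal with det +1
  expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-12)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-12)
})

test_that("collinear markers cannot define an alignment", {
  pl <- list(normal = c(0, 0, 1), d = 53)
  mk <- rbind(c(0, 0, 44), c(1, 1, 44), c(2, 2, 44))
  expect_error(compute_alignment(mk, pl), "collinear")
})

test_that("the grid partitions nipples-to-navel equidistantly", {
  mk <- rbind(left_nipple = c(0, -9), right_nipple = c(0, 9), navel = c(18, 0))
  g <- build_grid(mk)
  expect_equal(diff(g$row_x), rep(3, 6))
  expect_equal(diff(g$col_y), rep(3, 6))
  expect_identical(nrow(g$centers), 49L)
  # center (4,4) sits at the grid midpoint
  c44 <- g$centers[g$centers[, "i"] == 4 & g$centers[, "j"] == 4, ]
  expect_equal(unname(c44[c("x", "y")]), c(9, 0))
  # rows of interest select exactly 21 channels
  roi_rows <- g$centers[, "i"] %in% g$rows_of_interest
  expect_identical(sum(roi_rows), 21L)
  expect_error(build_grid(rbind(c(0, -0.5), c(0, 0.5), c(18, 0))),
               "separation")
  expect_error(build_grid(rbind(c(0, -9), c(0, 9), c(1, 0))),
               "navel")
})

test_that("depth extraction averages d - z over each ROI", {
  # lattice covering the grid; z chosen so r alternates between 4 and 6
  xs <- seq(-1.4, 19.4, by = 0.4)
  ys <- seq(-10.4, 10.4, by = 0.4)
  xy <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  d <- 53
  mk_tracks <- data.frame(frame = 1,
                          marker = c("left_nipple", "right_nipple", "navel"),
                          x = c(0, 0, 18), y = c(-9, 9, 0), z = d - 5)
  pl <- structure(list(normal = c(0, 0, 1), d = d, residual = 0,
                       n_points = 1000), class = "table_plane")
  # all points at the table level: r identically 0
  seq0 <- sequence_from_frames(list(frame(cbind(xy, d), matrix(128, nrow(xy), 3))), 30)
  sig0 <- extract_depth_signals(seq0, mk_tracks, pl)
  expect_equal(max(abs(sig0$r)), 0)
  # alternating depths 4 and 6 average to 5
  z <- d - ifelse(seq_len(nrow(xy)) %% 2 == 0, 4, 6)
  seq1 <- sequence_from_frames(list(frame(cbind(xy, z), matrix(128, nrow(xy), 3))), 30)
  sig1 <- extract_depth_signals(seq1, mk_tracks, pl)
  expect_equal(unname(colMeans(sig1$r)), rep(5, 21), tolerance = 0.2)
  expect_true(all(sig1$n_points >= 20))
  # an ROI emptied by cropping is reported with channel and frame
  roi <- roi_box(x = c(-2, 16))   # removes row 7... row 5 band survives; row 1 ok
  expect_error(extract_depth_signals(seq1, mk_tracks, pl,
                                     roi = roi_box(x = c(2, 20))),
               "empty ROI")
})

test_that("extracted signals are invariant to the phantom's global pose", {
  base <- generate_sequence(phantom_config(duration = 1, seed = 12,
                                           noise_sigma = 0))
  posed <- generate_sequence(phantom_config(duration = 1, seed = 12,
                                            noise_sigma = 0,
                                            tilt = c(2.5, -1.5), yaw = 4,
                                            offset = c(0.8, -0.6)))
  s_base <- process_session_quiet(base$sequence, base$truth$markers,
                                  table_patches())
  s_posed <- process_session_quiet(posed$sequence, posed$truth$markers,
                                   table_patches(offset_y = -0.6))
  expect_equal(s_posed$signals$r, s_base$signals$r, tolerance = 0.02)
})
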