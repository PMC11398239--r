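# Rigid alignment and depth-variation signal extraction.
#
# Each frame is rigidly rotated so that (a) the fitted table plane becomes
# horizontal (normal +z, tilt correction) and (b) the nipple-to-nipple line
# runs along the camera's y axis. In the aligned frame the table sits at a
# constant z = d, the grid of 7 x 7 square channels spans nipples-to-navel
# and left-to-right nipple, and the depth-variation signal of a channel is
# the ROI mean of d - z over its points.

#' Rigid transform (rotation + translation)
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix or length-3 vector.
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Fit the table plane by least squares
#'
#' @param frame a `cm_frame`.
#' @param table_region `cm_roi_box` (or a list of them) containing only table
#'   points, operator supplied. Patches on both sides of the patient are
#'   recommended: a one-sided patch leaves the plane free to pivot about it,
#'   which biases depths across the torso through the lever arm.
#' @param min_points minimal number of table points.
#' @param max_residual maximal admissible residual standard deviation (cm).
#' @return A `table_plane`: unit `normal` (oriented with positive z),
#'   camera-to-table distance `d` (plane offset along the normal), `residual`
#'   (cm), and `n_points`.
#' @export
fit_table_plane <- function(frame, table_region, min_points = 100,
                            max_residual = 0.5) {
  if (inherits(table_region, "cm_roi_box")) table_region <- list(table_region)
  p <- do.call(rbind, lapply(table_region, function(b)
    suppressMessages(crop(frame, b))$points))
  if (nrow(p) < min_points)
    stop("table region contains only ", nrow(p), " points (need >= ",
         min_points, ")")
  X <- cbind(1, p[, 1], p[, 2])
  beta <- qr.coef(qr(X), p[, 3])        # z = c + a x + b y
  resid <- p[, 3] - X %*% beta
  rsd <- sqrt(mean(resid^2))
  if (rsd > max_residual)
    stop("table plane fit residual ", signif(rsd, 3), " cm exceeds ",
         max_residual, " cm; the region probably contains non-table points")
  nvec <- c(-beta[2], -beta[3], 1)
  nvec <- nvec / sqrt(sum(nvec^2))
  d <- beta[1] * nvec[3]                 # n . p is constant = c * n_z
  structure(list(normal = unname(nvec), d = unname(d), residual = rsd,
                 n_points = nrow(p)),
            class = "table_plane")
}

#' Compute the per-frame alignment transform
#'
#' After applying the returned transform, the table plane normal is (0,0,1)
#' with the table at z = d, and the left and right nipple centers share the
#' same x coordinate (the nipple line runs along +y, left nipple at the
#' smaller y).
#'
#' @param markers 3 x 3 matrix of 3-D marker centers in camera coordinates,
#'   rows `left_nipple`, `right_nipple`, `navel`.
#' @param plane a `table_plane`.
#' @return A `rigid_transform`.
#' @export
compute_alignment <- function(markers, plane) {
  markers <- as.matrix(markers)
  if (nrow(markers) != 3 || ncol(markers) != 3)
    stop("`markers` must be a 3 x 3 matrix of 3-D centers")
  v1 <- markers[2, ] - markers[1, ]; v2 <- markers[3, ] - markers[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cr^2)) < 1e-6 * sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    stop("marker centers are collinear; cannot define the alignment")
  r1 <- rotation_to_z(plane$normal)
  nip <- (markers[2, ] - markers[1, ]) %*% t(r1)
  theta <- atan2(nip[1], nip[2])   # rotate so the nipple vector has x = 0, y > 0
  rigid_transform(rot_z(theta) %*% r1)
}

#' Build the 7 x 7 grid of channels from aligned markers
#'
#' Rows are equidistant lines parallel to the y axis spanning the nipple line
#' (row 1) to the navel (row 7); columns are equidistant lines parallel to
#' the x axis spanning the left (column 1) to the right nipple (column 7).
#'
#' @param markers aligned marker centers: 3 x 2 (or 3 x 3) matrix, rows
#'   `left_nipple`, `right_nipple`, `navel`.
#' @param roi_half_size half the ROI square side (cm); default 1, i.e. the
#'   2 cm square channel.
#' @param rows_of_interest grid rows used for cross-section derivation.
#' @return A `channel_grid`: `row_x` (7), `col_y` (7), `roi_half_size`,
#'   `rows_of_interest`, and the 49 centers.
#' @export
build_grid <- function(markers, roi_half_size = 1, rows_of_interest = c(1, 3, 5)) {
  markers <- as.matrix(markers)
  x_nip <- mean(markers[1:2, 1])
  x_nav <- markers[3, 1]
  y_l <- markers[1, 2]; y_r <- markers[2, 2]
  if (abs(y_r - y_l) < 2)
    stop("nipple separation below 2 cm; ROIs would overlap degenerately")
  if (abs(x_nav - x_nip) < 2)
    stop("nipple-to-navel distance below 2 cm; ROIs would overlap degenerately")
  row_x <- seq(x_nip, x_nav, length.out = 7)
  col_y <- seq(y_l, y_r, length.out = 7)
  centers <- cbind(x = rep(row_x, each = 7), y = rep(col_y, times = 7),
                   i = rep(1:7, each = 7), j = rep(1:7, times = 7))
  structure(list(row_x = row_x, col_y = col_y, roi_half_size = roi_half_size,
                 rows_of_interest = rows_of_interest, centers = centers),
            class = "channel_grid")
}

#' Extract per-channel depth-variation signals
#'
#' For every frame, the alignment is recomputed from that frame's tracked
#' markers (the grid follows the breathing motion of the markers), the cloud
#' is rigidly aligned, and each channel's signal sample is the mean of
#' d - z over the N points in its 2 cm square ROI.
#'
#' @param sequence a `cm_sequence`.
#' @param tracks marker tracks as returned by [track_markers()] (columns
#'   `frame`, `marker`, `x`, `y`, `z`), in camera coordinates.
#' @param plane `table_plane` fitted on the first frame (d is held fixed for
#'   the trial).
#' @param roi a `cm_roi_box` applied to every frame before alignment, or
#'   `NULL`.
#' @param config a [run_config()]; supplies `roi_half_size`,
#'   `rows_of_interest` and the central channel.
#' @return A `depth_signals` object: matrix `r` (frames x 21 channels, cm),
#'   matrix `n_points`, per-frame grid rows/columns (`row_x`, `col_y`),
#'   `frame_rate`, `d`, `channels` table and the central channel name.
#' @export
extract_depth_signals <- function(sequence, tracks, plane, roi = NULL,
                                  config = run_config()) {
  n <- n_frames(sequence)
  rows_i <- config$rows_of_interest
  half <- config$roi_half_size
  channels <- expand.grid(j = 1:7, i = rows_i)[, c("i", "j")]
  ch_names <- sprintf("r_%d_%d", channels$i, channels$j)
  nch <- nrow(channels)
  r <- matrix(NA_real_, n, nch, dimnames = list(NULL, ch_names))
  npts <- matrix(NA_integer_, n, nch, dimnames = list(NULL, ch_names))
  row_x_all <- matrix(NA_real_, n, 7)
  col_y_all <- matrix(NA_real_, n, 7)
  marker_names <- c("left_nipple", "right_nipple", "navel")
  tr_split <- split(tracks[, c("frame", "x", "y", "z")], tracks$marker)
  for (i in seq_len(n)) {
    mk <- t(vapply(marker_names, function(nm) {
      row <- tr_split[[nm]][tr_split[[nm]]$frame == i, ]
      c(row$x, row$y, row$z)
    }, numeric(3)))
    tf <- compute_alignment(mk, plane)
    fr <- get_frame(sequence, i)
    if (!is.null(roi)) fr <- suppressMessages(crop(fr, roi))
    p <- apply_transform(tf, fr$points)
    mk_a <- apply_transform(tf, mk)
    grid <- build_grid(mk_a, half, rows_i)
    row_x_all[i, ] <- grid$row_x
    col_y_all[i, ] <- grid$col_y
    # disjoint 2 cm bands around rows of interest and all columns
    col_breaks <- as.vector(rbind(grid$col_y - half, grid$col_y + half))
    if (is.unsorted(col_breaks))
      stop("grid columns closer than the ROI size at frame ", i)
    jb <- findInterval(p[, 2], col_breaks)
    jj <- ifelse(jb %% 2 == 1, (jb + 1) %/% 2, NA_integer_)
    for (ri in seq_along(rows_i)) {
      xr <- grid$row_x[rows_i[ri]]
      inrow <- which(abs(p[, 1] - xr) <= half & !is.na(jj))
      depth <- plane$d - p[inrow, 3]
      jrow <- jj[inrow]
      cnt <- tabulate(jrow, 7)
      if (any(cnt == 0)) {
        j0 <- which(cnt == 0)[1]
        stop("empty ROI at channel (", rows_i[ri], ", ", j0, ") in frame ", i)
      }
      sums <- vapply(split(depth, jrow), sum, numeric(1))
      cols <- (ri - 1) * 7 + as.integer(names(sums))
      r[i, cols] <- sums / cnt[as.integer(names(sums))]
      npts[i, cols] <- cnt[as.integer(names(sums))]
    }
  }
  central <- sprintf("r_%d_%d", config$central_channel[1], config$central_channel[2])
  if (!central %in% ch_names)
    stop("central channel ", central, " is not among the channels of interest")
  structure(list(r = r, n_points = npts, row_x = row_x_all, col_y = col_y_all,
                 frame_rate = sequence$frame_rate, d = plane$d,
                 channels = channels, central = central),
            class = "depth_signals")
}

#' @export
print.depth_signals <- function(x, ...) {
  cat("<depth_signals> ", nrow(x$r), " samples @ ", x$frame_rate, " Hz, ",
      ncol(x$r), " channels, d = ", signif(x$d, 5), " cm\n", sep = "")
  invisible(x)
}
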