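# Circular-marker detection and tracking.
#
# The three matte circular markers (left nipple, right nipple, navel) are
# found on the saturation channel of the point cloud projected to the x-y
# plane, with a circular Hough transform whose search window is seeded by
# the operator on frame 1 and by the previous frame's corrected center
# afterwards. The final 3-D marker center is the centroid of the cloud
# points that project inside the detected circle.

#' Operator marker seed for the first frame
#'
#' @param left_nipple,right_nipple,navel 2-D centers (x, y) in cm.
#' @export
marker_triplet <- function(left_nipple, right_nipple, navel) {
  m <- rbind(left_nipple = left_nipple, right_nipple = right_nipple,
             navel = navel)
  if (ncol(m) != 2) stop("marker centers must be 2-D (x, y)")
  v1 <- m[2, ] - m[1, ]; v2 <- m[3, ] - m[1, ]
  if (abs(v1[1] * v2[2] - v1[2] * v2[1]) < 1e-6)
    stop("marker centers are collinear")
  structure(m, class = c("marker_triplet", class(m)))
}

#' Project a point cloud to a raster image in the x-y plane
#'
#' Each pixel takes the color of the point nearest the camera (smallest z)
#' among the points that map to it; empty pixels are flagged and may be
#' filled by nearest-neighbor dilation.
#'
#' @param frame a `cm_frame`.
#' @param pixel_pitch pixel size (cm/px).
#' @param fill_radius fill empty pixels by iterative neighbor averaging up to
#'   this many passes (0 disables).
#' @return A `projected_image`: list with `r`, `g`, `b` matrices (rows = y,
#'   cols = x), `saturation`, `filled` mask, `pixel_pitch`, and the cm
#'   coordinates of pixel centers (`x0`, `y0`).
#' @export
project_to_image <- function(frame, pixel_pitch = 0.1, fill_radius = 3) {
  p <- frame$points
  if (nrow(p) == 0) stop("cannot project an empty frame")
  rx <- range(p[, 1]); ry <- range(p[, 2])
  if (diff(rx) < pixel_pitch || diff(ry) < pixel_pitch)
    stop("degenerate point extent; cannot project")
  x0 <- rx[1]; y0 <- ry[1]
  nxp <- floor((rx[2] - x0) / pixel_pitch) + 1L
  nyp <- floor((ry[2] - y0) / pixel_pitch) + 1L
  ix <- pmin(floor((p[, 1] - x0) / pixel_pitch) + 1L, nxp)
  iy <- pmin(floor((p[, 2] - y0) / pixel_pitch) + 1L, nyp)
  lin <- iy + (ix - 1L) * nyp
  # z-buffer: write in decreasing z so the nearest point lands last
  ord <- order(p[, 3], decreasing = TRUE)
  ch <- function(k) {
    m <- matrix(NA_real_, nyp, nxp)
    m[lin[ord]] <- frame$colors[ord, k]
    m
  }
  r <- ch(1); g <- ch(2); b <- ch(3)
  filled <- !is.na(r)
  for (pass in seq_len(fill_radius)) {
    if (all(!is.na(r))) break
    r <- fill_pass(r); g <- fill_pass(g); b <- fill_pass(b)
  }
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  s <- ifelse(is.na(mx) | mx <= 0, 0, (mx - mn) / mx)
  structure(list(r = r, g = g, b = b, saturation = s, filled = filled,
                 pixel_pitch = pixel_pitch, x0 = x0, y0 = y0),
            class = "projected_image")
}

# one nearest-neighbor fill pass: empty pixels take the mean of their
# non-empty 8-neighbors
fill_pass <- function(m) {
  na <- is.na(m)
  if (!any(na)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  v <- ifelse(na, 0, m); w <- !na
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    vr <- shift_mat(v, s[1], s[2]); wr <- shift_mat(w, s[1], s[2])
    acc <- acc + vr; cnt <- cnt + wr
  }
  out <- m
  fixable <- na & cnt > 0
  out[fixable] <- acc[fixable] / cnt[fixable]
  out
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# pixel <-> cm mapping (pixel centers)
px_to_cm <- function(img, row, col)
  c(img$x0 + (col - 0.5) * img$pixel_pitch,
    img$y0 + (row - 0.5) * img$pixel_pitch)

cm_to_px <- function(img, xy)
  c(row = (xy[2] - img$y0) / img$pixel_pitch + 0.5,
    col = (xy[1] - img$x0) / img$pixel_pitch + 0.5)

#' Detect one circular marker near an initial guess
#'
#' Circular Hough transform on the saturation channel: saturation-gradient
#' edge pixels vote for circle centers along their gradient direction at
#' each candidate radius; the best-supported center within the search window
#' wins. The score is the fraction of the ideal circumference that voted.
#'
#' @param image a `projected_image`.
#' @param initial_center 2-D initial guess (x, y in cm).
#' @param search_radius admissible distance of the center from the guess (cm).
#' @param radius_range candidate circle radii (cm), `c(min, max)`.
#' @param score_threshold minimal accumulator score; below it a
#'   detection-failure error is raised carrying the search window.
#' @return list with `center` (cm), `radius` (cm), `score`.
#' @export
detect_marker <- function(image, initial_center, search_radius = 2,
                          radius_range = c(0.5, 1.5), score_threshold = 0.25) {
  if (any(radius_range <= 0) || radius_range[1] > radius_range[2])
    stop("`radius_range` must be positive and increasing")
  pitch <- image$pixel_pitch
  s <- image$saturation
  nr <- nrow(s); nc <- ncol(s)
  c0 <- cm_to_px(image, initial_center)
  if (c0[1] < 1 || c0[1] > nr || c0[2] < 1 || c0[2] > nc)
    stop("initial center lies outside the projected image")
  win_px <- (search_radius + radius_range[2]) / pitch + 2
  r_lo <- max(2L, floor(c0[1] - win_px)); r_hi <- min(nr - 1L, ceiling(c0[1] + win_px))
  c_lo <- max(2L, floor(c0[2] - win_px)); c_hi <- min(nc - 1L, ceiling(c0[2] + win_px))
  sub <- s[(r_lo - 1L):(r_hi + 1L), (c_lo - 1L):(c_hi + 1L)]
  nsr <- nrow(sub); nsc <- ncol(sub)
  inner_r <- 2:(nsr - 1); inner_c <- 2:(nsc - 1)
  gy <- (sub[inner_r + 1, inner_c] - sub[inner_r - 1, inner_c]) / 2
  gx <- (sub[inner_r, inner_c + 1] - sub[inner_r, inner_c - 1]) / 2
  gmag <- sqrt(gx^2 + gy^2)
  fail <- function() stop("marker detection failed: no circle above score ",
                          score_threshold, " within ", search_radius,
                          " cm of (", paste(signif(initial_center, 4), collapse = ", "),
                          ")")
  thr <- max(0.05, 0.4 * max(gmag))
  edges <- which(gmag > thr)
  if (length(edges) == 0) fail()
  er <- ((edges - 1) %% nrow(gmag)) + 1
  ec <- ((edges - 1) %/% nrow(gmag)) + 1
  ux <- gx[edges] / gmag[edges]; uy <- gy[edges] / gmag[edges]
  radii_px <- seq(radius_range[1] / pitch, radius_range[2] / pitch, by = 1)
  acc_nr <- nsr - 2L; acc_nc <- nsc - 2L
  # stage 1: all radii vote (both gradient directions) into one accumulator;
  # the true center collects the inward votes of every rim pixel
  votes <- integer(acc_nr * acc_nc)
  for (rp in radii_px) for (sgn in c(-1, 1)) {
    vr <- round(er + sgn * rp * uy)
    vc <- round(ec + sgn * rp * ux)
    ok <- vr >= 1 & vr <= acc_nr & vc >= 1 & vc <= acc_nc
    votes <- votes + tabulate(vr[ok] + (vc[ok] - 1L) * acc_nr,
                              nbins = acc_nr * acc_nc)
  }
  acc <- matrix(votes, acc_nr, acc_nc)
  accs <- fill_smooth3(acc)
  # candidate-center admissibility (within search_radius of the seed)
  seed_r <- c0[1] - (r_lo - 1L); seed_c <- c0[2] - (c_lo - 1L)
  dr <- seq_len(acc_nr) - seed_r; dc <- seq_len(acc_nc) - seed_c
  accs[outer(dr^2, dc^2, `+`) > (search_radius / pitch)^2] <- -Inf
  k <- which.max(accs)
  if (!is.finite(accs[k])) fail()
  pr <- ((k - 1) %% acc_nr) + 1
  pc <- ((k - 1) %/% acc_nr) + 1
  # stage 2: subpixel center and radius by an iterated least-squares circle
  # fit (Kasa) to the rim pixels around the best-supported radius
  cen <- c(pr, pc)
  rad_px <- NA_real_
  for (it in 1:3) {
    dist_px <- sqrt((er - cen[1])^2 + (ec - cen[2])^2)
    support <- vapply(radii_px, function(rp) sum(abs(dist_px - rp) <= 1.5),
                      numeric(1))
    if (max(support) < 6) fail()
    rbest <- radii_px[which.max(support)]
    on_rim <- abs(dist_px - rbest) <= 2
    A <- cbind(2 * er[on_rim], 2 * ec[on_rim], 1)
    sol <- qr.coef(qr(A), er[on_rim]^2 + ec[on_rim]^2)
    cen <- sol[1:2]
    rad_px <- sqrt(sol[3] + sum(cen^2))
  }
  dist_px <- sqrt((er - cen[1])^2 + (ec - cen[2])^2)
  score <- sum(abs(dist_px - rad_px) <= 1.5) / (2 * pi * rad_px)
  if (!is.finite(score) || score < score_threshold) fail()
  if (sqrt((cen[1] - seed_r)^2 + (cen[2] - seed_c)^2) >
      search_radius / pitch + 2) fail()
  center <- px_to_cm(image, cen[1] + (r_lo - 1L), cen[2] + (c_lo - 1L))
  list(center = center, radius = rad_px * pitch, score = score)
}

fill_smooth3 <- function(m) {
  out <- m
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) out <- out + shift_mat(m, s[1], s[2])
  out
}

# 3-D marker center: centroid of cloud points whose x-y projection falls
# inside the detected circle
marker_centroid <- function(frame, center, radius) {
  p <- frame$points
  inside <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 <= radius^2
  if (!any(inside)) return(NULL)
  colMeans(p[inside, , drop = FALSE])
}

#' Track the three markers across a frame sequence
#'
#' Frame 1 is seeded by the operator triplet and corrected by the detector;
#' every following frame is seeded by the previous frame's corrected center,
#' which narrows the search area. The three markers are tracked
#' independently; a failure on any frame raises an error naming the frame
#' and marker (no silent extrapolation).
#'
#' @param sequence a `cm_sequence`.
#' @param operator_seed a [marker_triplet()] for frame 1.
#' @param pixel_pitch projection pixel pitch (cm/px).
#' @param search_radius seed-to-center search radius (cm).
#' @param marker_radius nominal marker radius (cm); the Hough radius range is
#'   this value +/- 50 percent.
#' @param score_threshold minimal detection score.
#' @return data.frame with one row per frame and marker: `frame`, `marker`,
#'   `x`, `y`, `z` (3-D centroid, cm), `u`, `v` (detected 2-D center),
#'   `radius`, `score`.
#' @export
track_markers <- function(sequence, operator_seed, pixel_pitch = 0.1,
                          search_radius = 2, marker_radius = 1,
                          score_threshold = 0.25) {
  stopifnot(inherits(operator_seed, "marker_triplet"))
  n <- n_frames(sequence)
  radius_range <- marker_radius * c(0.5, 1.5)
  markers <- rownames(operator_seed)
  seeds <- lapply(seq_len(3), function(m) operator_seed[m, ])
  out <- vector("list", n)
  pad <- search_radius + radius_range[2] + 0.5
  for (i in seq_len(n)) {
    fr <- get_frame(sequence, i)
    rows <- vector("list", 3)
    for (m in 1:3) {
      seed <- seeds[[m]]
      box <- roi_box(x = c(seed[1] - pad, seed[1] + pad),
                     y = c(seed[2] - pad, seed[2] + pad))
      sub <- suppressMessages(crop(fr, box))
      det <- tryCatch(
        detect_marker(project_to_image(sub, pixel_pitch), seed,
                      search_radius, radius_range, score_threshold),
        error = function(e) stop("marker '", markers[m], "' lost at frame ",
                                 i, ": ", conditionMessage(e), call. = FALSE))
      cen3 <- marker_centroid(sub, det$center, det$radius)
      if (is.null(cen3))
        stop("marker '", markers[m], "' lost at frame ", i,
             ": no cloud points inside the detected circle", call. = FALSE)
      seeds[[m]] <- cen3[1:2]
      rows[[m]] <- data.frame(frame = i, marker = markers[m],
                              x = cen3[1], y = cen3[2], z = cen3[3],
                              u = det$center[1], v = det$center[2],
                              radius = det$radius, score = det$score)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
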