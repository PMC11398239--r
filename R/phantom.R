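# Synthetic breathing-torso phantom.
#
# Emulates a supine patient on a table under a downward-looking depth camera:
# a planar table at fixed camera distance, a smooth torso dome above it with
# three circular matte markers (two nipples, one navel), quasi-periodic
# breathing with row-dependent amplitude, i.i.d. depth noise, a small camera
# tilt, and injectable motion artifacts. Every run carries full ground truth
# (marker tracks, per-channel depth signals, breath extrema, artifact masks)
# so the processing chain can be validated end to end.
#
# Units: cm throughout, camera frame, z increasing away from the camera.

#' Phantom configuration
#'
#' Defaults encode a quietly breathing young child: torso dome depth around
#' 9 cm, breathing amplitude growing from the chest (row 1) toward the
#' abdomen (row 7), a mean breathing period of 2 s with 0.2 s jitter
#' (about 30 breaths/min), and 0.1 cm per-point depth noise.
#'
#' @param camera_to_table_distance camera-to-table distance d (cm).
#' @param table_extent table size (x, y) in cm, centered on the optical axis.
#' @param marker_positions 3 x 2 matrix of marker centers (x, y) on the torso
#'   surface, rows `left_nipple`, `right_nipple`, `navel`. Must be
#'   non-collinear; the two nipples must share their x coordinate.
#' @param marker_radius marker radius (cm).
#' @param torso_peak_depth 7 static dome depths (cm), one per grid row
#'   (row 1 at the nipple line, row 7 at the navel).
#' @param breathing_amplitude 7 breathing amplitudes (cm), one per grid row.
#' @param mean_period,period_jitter mean breathing period and the standard
#'   deviation of the per-cycle period (s).
#' @param amplitude_jitter relative standard deviation of the per-cycle
#'   breathing depth (breath-to-breath tidal variability; 0 gives a strictly
#'   repeating waveform).
#' @param noise_sigma i.i.d. Gaussian depth noise per point (cm).
#' @param tilt rotations of the scene about the camera x and y axes (deg).
#' @param yaw rotation about the camera z axis (deg).
#' @param offset in-plane translation (x, y) of the scene (cm).
#' @param frame_rate frames per second.
#' @param duration trial duration (s).
#' @param point_pitch lattice pitch of generated points (cm); 0.25 cm keeps
#'   at least 49 points in every 2 cm region of interest.
#' @param torso_halfwidth,torso_flat_halfwidth torso half-width in y: depth is
#'   constant for `|y| <= torso_flat_halfwidth` and tapers smoothly to zero at
#'   `torso_halfwidth`.
#' @param torso_taper taper length (cm) beyond the nipple/navel rows in x.
#' @param depth_scale global multiplier on torso depth (1 = nominal); used to
#'   emulate a uniform morphology change between sessions.
#' @param marker_drift marker drift velocity (x, y) in cm per frame.
#' @param artifacts list of [artifact_spec()] objects.
#' @param seed integer seed; identical configs (same seed) generate
#'   bit-identical sequences.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(camera_to_table_distance = 53,
                           table_extent = c(40, 32),
                           marker_positions = rbind(left_nipple = c(-9, -9),
                                                    right_nipple = c(-9, 9),
                                                    navel = c(9, 0)),
                           marker_radius = 1,
                           torso_peak_depth = c(8.5, 8.8, 9, 9.2, 9.3, 9.2, 9),
                           breathing_amplitude = c(0.9, 1.2, 1.5, 1.7, 1.9, 2, 2.1),
                           mean_period = 2,
                           period_jitter = 0.2,
                           amplitude_jitter = 0.05,
                           noise_sigma = 0.1,
                           tilt = c(0, 0),
                           yaw = 0,
                           offset = c(0, 0),
                           frame_rate = 30,
                           duration = 60,
                           point_pitch = 0.25,
                           torso_halfwidth = 13,
                           torso_flat_halfwidth = 10.5,
                           torso_taper = 6,
                           depth_scale = 1,
                           marker_drift = c(0, 0),
                           artifacts = list(),
                           seed = 1) {
  mp <- as.matrix(marker_positions)
  if (nrow(mp) != 3 || ncol(mp) != 2)
    stop("`marker_positions` must be a 3 x 2 matrix")
  if (is.null(rownames(mp)))
    rownames(mp) <- c("left_nipple", "right_nipple", "navel")
  # collinearity: cross product of the two edge vectors
  v1 <- mp[2, ] - mp[1, ]; v2 <- mp[3, ] - mp[1, ]
  if (abs(v1[1] * v2[2] - v1[2] * v2[1]) < 1e-6)
    stop("marker positions are collinear")
  if (abs(mp[1, 1] - mp[2, 1]) > 1e-9)
    stop("the two nipple markers must share their x coordinate")
  if (marker_radius <= 0) stop("`marker_radius` must be positive")
  if (frame_rate <= 0) stop("`frame_rate` must be positive")
  if (duration <= 0) stop("`duration` must be positive")
  if (length(torso_peak_depth) != 7 || length(breathing_amplitude) != 7)
    stop("`torso_peak_depth` and `breathing_amplitude` need 7 values (one per row)")
  if (any(breathing_amplitude < 0)) stop("breathing amplitudes must be >= 0")
  if (amplitude_jitter < 0) stop("`amplitude_jitter` must be >= 0")
  if (min(torso_peak_depth) <= max(breathing_amplitude))
    stop("peak torso depth must exceed the largest breathing amplitude")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  for (a in artifacts) {
    if (!inherits(a, "artifact_spec")) stop("`artifacts` must contain artifact_spec objects")
    if (a$onset_time + a$duration > duration)
      stop("artifact window exceeds the sequence duration")
  }
  structure(list(camera_to_table_distance = camera_to_table_distance,
                 table_extent = table_extent, marker_positions = mp,
                 marker_radius = marker_radius,
                 torso_peak_depth = torso_peak_depth,
                 breathing_amplitude = breathing_amplitude,
                 mean_period = mean_period, period_jitter = period_jitter,
                 amplitude_jitter = amplitude_jitter,
                 noise_sigma = noise_sigma, tilt = tilt, yaw = yaw,
                 offset = offset, frame_rate = frame_rate, duration = duration,
                 point_pitch = point_pitch, torso_halfwidth = torso_halfwidth,
                 torso_flat_halfwidth = torso_flat_halfwidth,
                 torso_taper = torso_taper, depth_scale = depth_scale,
                 marker_drift = marker_drift, artifacts = artifacts,
                 seed = seed),
            class = "phantom_config")
}

#' Motion-artifact specification
#'
#' Artifacts displace the torso surface toward the camera during a time
#' window, with magnitudes larger than the breathing amplitude so that they
#' stand out as sudden, large-amplitude events in the depth signals.
#'
#' @param onset_time artifact onset (s from trial start).
#' @param duration artifact duration (s).
#' @param kind one of `"step"` (constant shift), `"spike"` (triangular pulse)
#'   or `"drift"` (linear ramp).
#' @param magnitude peak displacement toward the camera (cm).
#' @param rows integer subset of grid rows (1..7) affected, or `NULL` for the
#'   whole torso.
#' @export
artifact_spec <- function(onset_time, duration, kind = c("step", "spike", "drift"),
                          magnitude, rows = NULL) {
  kind <- match.arg(kind)
  if (onset_time < 0 || duration <= 0) stop("invalid artifact window")
  if (magnitude <= 0) stop("artifact magnitude must be positive")
  if (!is.null(rows) && (!all(rows %in% 1:7)))
    stop("`rows` must be a subset of 1..7")
  structure(list(onset_time = onset_time, duration = duration, kind = kind,
                 magnitude = magnitude, rows = rows),
            class = "artifact_spec")
}

# raised-cosine taper: 1 inside, smooth fall to 0 over `width`
cos_taper <- function(dist_outside, width) {
  w <- clamp(dist_outside / width, 0, 1)
  0.5 + 0.5 * cos(pi * w)
}

# Per-cycle raised-cosine breathing waveform; each cycle starts at a maximum
# (full inspiration) and dips to 0 (end expiration) at mid-cycle. Cycle
# periods and depths are jittered: quiet breathing has breath-to-breath
# variability in both rate and tidal depth.
phantom_breathing <- function(config) {
  n_cycles <- ceiling(config$duration / (0.5 * config$mean_period)) + 3
  cyc <- with_seed(config$seed * 2 + 1, {
    p <- stats::rnorm(n_cycles, config$mean_period, config$period_jitter)
    f <- stats::rnorm(n_cycles, 1, config$amplitude_jitter)
    list(periods = pmax(p, 0.5 * config$mean_period), factors = pmax(f, 0.2))
  })
  periods <- cyc$periods
  starts <- cumsum(c(0, periods))
  tt <- (seq_len(round(config$frame_rate * config$duration)) - 1) / config$frame_rate
  k <- findInterval(tt, starts)
  tau <- tt - starts[k]
  b <- cyc$factors[k] * (0.5 + 0.5 * cos(2 * pi * tau / periods[k]))
  fs <- config$frame_rate
  n <- length(tt)
  idx_of <- function(times) {
    i <- round(times * fs) + 1
    i[i > 1 & i < n]
  }
  mids <- starts[-length(starts)] + periods / 2
  list(b = b, t = tt,
       max_idx = idx_of(starts[starts < config$duration]),
       min_idx = idx_of(mids[mids < config$duration]))
}

# Static surface profiles on the generation lattice; everything is separable:
# depth(x, y, t) = scale * (P(x) + A(x) * b(t)) * env_y(y).
phantom_surface <- function(config) {
  ex <- config$table_extent[1] / 2; ey <- config$table_extent[2] / 2
  # half-pitch offset keeps lattice points off the exact ROI boundaries
  # (a knife-edge that would flip membership under sub-milliradian rotations)
  xs <- seq(-ex + config$point_pitch / 2, ex, by = config$point_pitch)
  ys <- seq(-ey + config$point_pitch / 2, ey, by = config$point_pitch)
  x_nip <- config$marker_positions[1, 1]
  x_nav <- config$marker_positions[3, 1]
  row_x <- seq(x_nip, x_nav, length.out = 7)
  col_y <- seq(config$marker_positions[1, 2], config$marker_positions[2, 2],
               length.out = 7)
  p_fun <- stats::splinefun(row_x, config$torso_peak_depth, method = "natural")
  a_fun <- stats::splinefun(row_x, config$breathing_amplitude, method = "natural")
  lo <- min(row_x); hi <- max(row_x)
  env_x <- cos_taper(pmax(lo - xs, xs - hi, 0), config$torso_taper)
  env_x[xs < lo - config$torso_taper | xs > hi + config$torso_taper] <- 0
  pvx <- p_fun(clamp(xs, lo, hi)) * env_x
  avx <- a_fun(clamp(xs, lo, hi)) * env_x
  env_y <- cos_taper(pmax(abs(ys) - config$torso_flat_halfwidth, 0),
                     config$torso_halfwidth - config$torso_flat_halfwidth)
  env_y[abs(ys) > config$torso_halfwidth] <- 0
  list(xs = xs, ys = ys, row_x = row_x, col_y = col_y,
       pvx = pvx, avx = avx, env_y = env_y,
       p_at = function(x, y) {
         ex_ <- cos_taper(pmax(lo - x, x - hi, 0), config$torso_taper) *
           (x >= lo - config$torso_taper & x <= hi + config$torso_taper)
         ey_ <- cos_taper(pmax(abs(y) - config$torso_flat_halfwidth, 0),
                          config$torso_halfwidth - config$torso_flat_halfwidth) *
           (abs(y) <= config$torso_halfwidth)
         p_fun(clamp(x, lo, hi)) * ex_ * ey_
       },
       a_at = function(x, y) {
         ex_ <- cos_taper(pmax(lo - x, x - hi, 0), config$torso_taper) *
           (x >= lo - config$torso_taper & x <= hi + config$torso_taper)
         ey_ <- cos_taper(pmax(abs(y) - config$torso_flat_halfwidth, 0),
                          config$torso_halfwidth - config$torso_flat_halfwidth) *
           (abs(y) <= config$torso_halfwidth)
         a_fun(clamp(x, lo, hi)) * ex_ * ey_
       })
}

# Artifact displacement profile (cm toward camera) for every frame of one
# spec, plus the set of affected grid rows (integer(0) means whole torso).
artifact_profile <- function(spec, n, frame_rate) {
  tt <- (seq_len(n) - 1) / frame_rate
  inside <- tt >= spec$onset_time & tt < spec$onset_time + spec$duration
  frac <- (tt - spec$onset_time) / spec$duration
  shape <- switch(spec$kind,
                  step = as.numeric(inside),
                  spike = inside * (1 - abs(2 * frac - 1)),
                  drift = inside * frac)
  spec$magnitude * shape
}

#' Generate a synthetic phantom sequence with ground truth
#'
#' Produces a lazy frame sequence (frames are computed on demand and are
#' bit-identical across calls for the same config) together with the ground
#' truth needed to validate the processing chain: true marker tracks in
#' camera coordinates, true noise-free depth-variation signals on the 21
#' channels of interest, true breath extrema, and per-channel artifact masks.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `sequence` (a `cm_sequence`) and `truth`.
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- round(config$frame_rate * config$duration)
  surf <- phantom_surface(config)
  br <- phantom_breathing(config)
  d <- config$camera_to_table_distance
  scl <- config$depth_scale

  nx <- length(surf$xs); ny <- length(surf$ys)
  # column-major layout matching as.vector(outer(f(x), g(y)))
  xy <- cbind(x = rep(surf$xs, times = ny), y = rep(surf$ys, each = nx))
  npts <- nx * ny

  # artifact bookkeeping ----------------------------------------------------
  specs <- config$artifacts
  rows_of_interest <- c(1, 3, 5)
  channels <- expand.grid(j = 1:7, i = rows_of_interest)[, c("i", "j")]
  ch_names <- sprintf("r_%d_%d", channels$i, channels$j)
  art_mask <- matrix(FALSE, n, nrow(channels), dimnames = list(NULL, ch_names))
  art_dz <- vector("list", length(specs))
  art_region <- vector("list", length(specs))
  half_sp <- if (length(surf$row_x) > 1) diff(surf$row_x[1:2]) / 2 else 1
  seen_regions <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    art_dz[[k]] <- artifact_profile(sp, n, config$frame_rate)
    if (is.null(sp$rows)) {
      region <- rep(TRUE, npts)
      ch_hit <- rep(TRUE, nrow(channels))
    } else {
      xb <- range(surf$row_x[sp$rows]) + c(-half_sp, half_sp)
      region <- xy[, 1] >= xb[1] & xy[, 1] < xb[2]
      ch_hit <- channels$i %in% sp$rows
    }
    key <- paste(sort(which(ch_hit)), collapse = ",")
    win <- art_dz[[k]] > 0
    for (prev in seen_regions)
      if (identical(prev$key, key) && any(win & prev$win))
        warning("overlapping artifact specs on the same region; effects are summed")
    seen_regions[[length(seen_regions) + 1]] <- list(key = key, win = win)
    art_region[[k]] <- region
    art_mask[win, ch_hit] <- TRUE
  }

  # colors (constant unless the markers drift) ------------------------------
  footprint <- as.vector(outer(surf$pvx > 1e-3, surf$env_y > 1e-3, `&`))
  colors_at <- function(i) {
    cols <- matrix(rep(c(128, 128, 128), each = npts), npts, 3,
                   dimnames = list(NULL, c("r", "g", "b")))  # table gray
    cols[footprint, 1] <- 210; cols[footprint, 2] <- 180
    cols[footprint, 3] <- 160                                    # skin tone
    centers <- config$marker_positions +
      matrix(config$marker_drift * (i - 1), 3, 2, byrow = TRUE)
    for (m in 1:3) {
      inside <- (xy[, 1] - centers[m, 1])^2 + (xy[, 2] - centers[m, 2])^2 <=
        config$marker_radius^2
      cols[inside, 1] <- 230; cols[inside, 2] <- 20; cols[inside, 3] <- 20
    }
    cols
  }
  static_colors <- if (all(config$marker_drift == 0)) colors_at(1) else NULL

  # pose --------------------------------------------------------------------
  rot <- rot_z(deg2rad(config$yaw)) %*% rot_y(deg2rad(config$tilt[2])) %*%
    rot_x(deg2rad(config$tilt[1]))
  has_pose <- any(config$tilt != 0) || config$yaw != 0 || any(config$offset != 0)
  pivot <- c(0, 0, d)
  pose <- function(p) {
    if (!has_pose) return(p)
    q <- sweep(p, 2, pivot) %*% t(rot)
    sweep(q, 2, pivot + c(config$offset, 0), `+`)
  }

  make_frame <- function(i) {
    b <- br$b[i]
    depth <- scl * as.vector(outer(surf$pvx + surf$avx * b, surf$env_y))
    for (k in seq_along(specs)) {
      dz <- art_dz[[k]][i]
      if (dz > 0) depth[art_region[[k]]] <- depth[art_region[[k]]] + dz
    }
    z <- d - depth
    if (config$noise_sigma > 0)
      z <- z + with_seed((config$seed * 100003 + i * 7919) %% 2147483647,
                         stats::rnorm(npts, 0, config$noise_sigma))
    pts <- pose(cbind(xy, z = z))
    structure(list(points = pts,
                   colors = static_colors %||% colors_at(i),
                   timestamp = (i - 1) / config$frame_rate),
              class = "cm_frame")
  }

  sequence <- frame_sequence(make_frame, n, config$frame_rate,
                             meta = list(config = config_echo(config),
                                         config_obj = config))

  # ground truth ------------------------------------------------------------
  roi_half <- 1
  mean_band <- function(v, grid, centers)
    vapply(centers, function(c0) mean(v[grid >= c0 - roi_half & grid <= c0 + roi_half]),
           numeric(1))
  mpx <- mean_band(surf$pvx, surf$xs, surf$row_x)
  max_ <- mean_band(surf$avx, surf$xs, surf$row_x)
  mey <- mean_band(surf$env_y, surf$ys, surf$col_y)
  base <- scl * mpx[channels$i] * mey[channels$j]
  gain <- scl * max_[channels$i] * mey[channels$j]
  r_true <- outer(br$b, gain) + matrix(base, n, length(base), byrow = TRUE)
  colnames(r_true) <- ch_names

  centers0 <- config$marker_positions
  drift <- outer(seq_len(n) - 1, config$marker_drift)
  marker_tracks <- do.call(rbind, lapply(1:3, function(m) {
    cx <- centers0[m, 1] + drift[, 1]
    cy <- centers0[m, 2] + drift[, 2]
    depth_m <- scl * (surf$p_at(cx, cy) + surf$a_at(cx, cy) * br$b)
    p <- pose(cbind(cx, cy, d - depth_m))
    data.frame(frame = seq_len(n), marker = rownames(centers0)[m],
               x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  marker_tracks <- marker_tracks[order(marker_tracks$frame), ]
  rownames(marker_tracks) <- NULL

  truth <- list(markers = marker_tracks, r = r_true, b = br$b,
                max_idx = br$max_idx, min_idx = br$min_idx,
                channels = channels, row_x = surf$row_x, col_y = surf$col_y,
                artifact_masks = art_mask,
                artifact_windows = if (length(specs))
                  data.frame(onset = vapply(specs, `[[`, 0, "onset_time"),
                             duration = vapply(specs, `[[`, 0, "duration"))
                  else data.frame(onset = numeric(), duration = numeric()),
                d = d)
  list(sequence = sequence, truth = truth)
}

# config echo safe for JSON
config_echo <- function(config) {
  out <- unclass(config)
  out$marker_positions <- apply(config$marker_positions, 1, as.list,
                                simplify = FALSE)
  out$artifacts <- lapply(config$artifacts, unclass)
  out
}

#' Inject motion artifacts into an existing phantom run
#'
#' Regenerates the phantom with the given artifact specs embedded, returning
#' the displaced sequence and per-channel sample masks that mark contaminated
#' samples (the ground-truth bookkeeping used to validate artifact removal).
#'
#' @param phantom result of [generate_sequence()].
#' @param specs list of [artifact_spec()] objects.
#' @return A list like [generate_sequence()]'s, with `masks` attached.
#' @export
inject_artifacts <- function(phantom, specs) {
  config <- phantom$sequence$meta$config_obj
  if (is.null(config)) stop("sequence does not carry a phantom config")
  if (length(specs) == 0)
    return(c(phantom, list(masks = phantom$truth$artifact_masks)))
  args <- unclass(config)
  args$artifacts <- c(config$artifacts, specs)
  out <- generate_sequence(do.call(phantom_config, args))
  c(out, list(masks = out$truth$artifact_masks))
}
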