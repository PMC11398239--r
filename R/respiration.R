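# Breath analysis of depth-variation signals.
#
# The central-channel signal is low-pass filtered (4th-order Butterworth,
# 1 Hz cutoff, zero phase) and its alternating local minima/maxima define
# the breath segmentation shared by every channel. Artifacts (patient
# motion, sensor dropouts) are detected on the unsmoothed signals with a
# continuous wavelet transform: the scalogram magnitudes summed across
# scales form a 1-D criterion whose largest 1 percent of values marks
# artifact onsets; breaths touched by a flagged sample on any channel are
# removed. Finally, breaths are gated by a Gaussian model of the (period,
# amplitude) features so that only the dominant breathing pattern, shared
# by the two sessions under comparison, is kept.

#' Zero-phase Butterworth low-pass smoothing
#'
#' The filter (coefficients from [signal::butter()]) is applied forward and
#' backward over an odd-reflection-padded copy of the signal, so extrema
#' timing is preserved and edge transients are suppressed. A constant signal
#' passes through unchanged (DC gain 1).
#'
#' @param x numeric signal.
#' @param frame_rate sampling rate (Hz).
#' @param cutoff low-pass cutoff (Hz).
#' @param order filter order.
#' @export
smooth_signal <- function(x, frame_rate, cutoff = 1, order = 4) {
  n <- length(x)
  if (n < 30) stop("signal too short to filter (need >= 30 samples)")
  bf <- signal::butter(order, cutoff / (frame_rate / 2))
  pad <- min(n - 1, max(27, round(3 * frame_rate / cutoff)))
  # odd (point-symmetric) extension about the end samples
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(front, x, back)
  # steady-state initial conditions: the filter has DC gain 1, so priming
  # both delay lines with the first sample removes the start-up transient
  run <- function(v) signal::filter(bf, v, init.x = rep(v[1], order),
                                    init.y = rep(v[1], order))
  y <- run(xp)
  y <- rev(run(rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Locate alternating local extrema of a smoothed signal
#'
#' Local maxima are samples larger than both neighbors (minima: maxima of
#' the inverted signal); on a plateau the leftmost sample is taken. The
#' merged sequence is repaired to strict min/max alternation by keeping the
#' more extreme of two consecutive same-type extrema. Endpoints are
#' excluded.
#'
#' @param x numeric signal (typically the smoothed central channel).
#' @return list with integer vectors `minima` and `maxima`.
#' @export
detect_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(minima = integer(), maxima = integer()))
  s <- sign(diff(x))
  # plateau rule: a zero step takes the sign of the next nonzero step, so a
  # rise-flat-fall pattern peaks at the plateau's left edge
  nz <- s != 0
  if (!any(nz)) return(list(minima = integer(), maxima = integer()))
  filled <- s
  nxt <- rev(cummin(rev(ifelse(nz, seq_along(s), Inf))))  # next nonzero step
  fixup <- !nz & is.finite(nxt)
  filled[fixup] <- s[nxt[fixup]]
  i <- 2:(n - 1)
  maxima <- i[filled[i - 1] > 0 & filled[i] < 0]
  minima <- i[filled[i - 1] < 0 & filled[i] > 0]
  if (length(maxima) + length(minima) == 0)
    return(list(minima = integer(), maxima = integer()))
  # alternation repair
  idx <- c(maxima, minima)
  typ <- rep(c(1L, -1L), c(length(maxima), length(minima)))
  o <- order(idx)
  idx <- idx[o]; typ <- typ[o]
  keep_idx <- integer(0); keep_typ <- integer(0)
  for (k in seq_along(idx)) {
    m <- length(keep_idx)
    if (m > 0 && typ[k] == keep_typ[m]) {
      better <- if (typ[k] > 0) x[idx[k]] > x[keep_idx[m]]
                else x[idx[k]] < x[keep_idx[m]]
      if (better) keep_idx[m] <- idx[k]
    } else {
      keep_idx <- c(keep_idx, idx[k]); keep_typ <- c(keep_typ, typ[k])
    }
  }
  list(minima = keep_idx[keep_typ < 0], maxima = keep_idx[keep_typ > 0])
}

#' Separate breaths at the central channel's minima
#'
#' One breath spans two consecutive minima of the central channel; the same
#' index triple (start minimum, maximum, end minimum) segments every other
#' channel, which guarantees an equal breath count on all channels. The
#' amplitude is the smoothed central value at the maximum minus the mean of
#' the two bounding minima.
#'
#' @param smoothed_central smoothed central-channel signal.
#' @param extrema result of [detect_extrema()] on that signal.
#' @param frame_rate sampling rate (Hz).
#' @return data.frame with `breath_id`, `start`, `max_idx`, `end`,
#'   `period_s`, `amplitude_cm`.
#' @export
separate_breaths <- function(smoothed_central, extrema, frame_rate) {
  mins <- extrema$minima
  if (length(mins) < 2) {
    warning("fewer than 2 minima: no breaths detected")
    return(data.frame(breath_id = integer(), start = integer(),
                      max_idx = integer(), end = integer(),
                      period_s = numeric(), amplitude_cm = numeric()))
  }
  starts <- mins[-length(mins)]
  ends <- mins[-1]
  max_idx <- vapply(seq_along(starts), function(k) {
    cand <- extrema$maxima[extrema$maxima > starts[k] & extrema$maxima < ends[k]]
    if (length(cand) == 0) return(NA_integer_)
    cand[which.max(smoothed_central[cand])]
  }, integer(1))
  ok <- !is.na(max_idx)
  data.frame(breath_id = seq_len(sum(ok)),
             start = starts[ok], max_idx = max_idx[ok], end = ends[ok],
             period_s = (ends[ok] - starts[ok]) / frame_rate,
             amplitude_cm = smoothed_central[max_idx[ok]] -
               0.5 * (smoothed_central[starts[ok]] + smoothed_central[ends[ok]]))
}

#' Morlet analyzing wavelet
#'
#' The real Morlet wavelet `exp(-t^2) * cos(pi * sqrt(2/ln 2) * t)`; its
#' center (pseudo) frequency is `sqrt(2/ln 2) / 2` cycles per unit time.
#'
#' @param t numeric time points.
#' @export
morlet <- function(t) exp(-t^2) * cos(pi * sqrt(2 / log(2)) * t)

morlet_center_freq <- function() sqrt(2 / log(2)) / 2

#' Logarithmically spaced CWT scales for a frequency band
#'
#' @param frame_rate sampling rate (Hz).
#' @param n_scales number of scales.
#' @param freq_range pseudo-frequency band (Hz) the scales span.
#' @return numeric scales (samples), attribute `pseudo_freq` in Hz.
#' @export
cwt_scales <- function(frame_rate, n_scales = 64, freq_range = c(0.05, 5)) {
  f <- exp(seq(log(freq_range[2]), log(freq_range[1]), length.out = n_scales))
  a <- morlet_center_freq() * frame_rate / f
  attr(a, "pseudo_freq") <- f
  a
}

#' Continuous wavelet transform scalogram
#'
#' `W(a, b) = sum_t x(t) * (1/sqrt(a)) * psi((t - b)/a)` with the Morlet
#' wavelet; the 1/sqrt(a) factor keeps wavelet energy equal across scales.
#' The signal is extended by mirror reflection to temper edge effects.
#'
#' @param x numeric signal.
#' @param scales positive scales in samples (see [cwt_scales()]).
#' @return matrix of coefficient magnitudes `|W|`, `length(scales)` rows by
#'   `length(x)` columns, with the scales as an attribute.
#' @export
compute_scalogram <- function(x, scales) {
  if (length(x) == 0) stop("empty signal")
  if (any(scales <= 0)) stop("scales must be positive")
  n <- length(x)
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    L <- ceiling(4 * a)
    w <- morlet((-L:L) / a) / sqrt(a)
    xp <- reflect_pad(x, L)
    co <- stats::convolve(xp, w, conj = TRUE, type = "open")
    # correlation with a symmetric kernel: centered samples of the full conv
    out[si, ] <- abs(co[(2 * L + 1):(2 * L + n)])
  }
  attr(out, "scales") <- scales
  out
}

#' Flag artifact samples on every channel via the CWT criterion
#'
#' Per channel, the criterion is the column sum of scalogram magnitudes
#' across scales of the (mean-removed, unsmoothed) signal; samples whose
#' criterion exceeds its 99th percentile (linear-interpolation estimator)
#' are flagged as artifact onsets. The merged mask is the union over
#' channels.
#'
#' @param r matrix of depth-variation signals (frames x channels) or a
#'   `depth_signals` object.
#' @param frame_rate sampling rate (Hz); taken from `r` when it is a
#'   `depth_signals`.
#' @param percentile flagging percentile (default 0.99).
#' @param scales CWT scales; default [cwt_scales()] spanning 0.05-5 Hz.
#' @return list with `masks` (logical frames x channels), `merged` (union),
#'   `criteria` (numeric matrix), `thresholds`.
#' @export
detect_artifact_samples <- function(r, frame_rate = NULL, percentile = 0.99,
                                    scales = NULL) {
  if (inherits(r, "depth_signals")) {
    frame_rate <- r$frame_rate
    r <- r$r
  }
  if (is.null(frame_rate)) stop("`frame_rate` is required for plain matrices")
  if (is.null(scales)) scales <- cwt_scales(frame_rate)
  n <- nrow(r); nch <- ncol(r)
  masks <- matrix(FALSE, n, nch, dimnames = dimnames(r))
  criteria <- matrix(NA_real_, n, nch, dimnames = dimnames(r))
  thresholds <- numeric(nch)
  for (ch in seq_len(nch)) {
    x <- r[, ch] - mean(r[, ch])
    sc <- compute_scalogram(x, scales)
    crit <- colSums(sc)
    thr <- stats::quantile(crit, percentile, names = FALSE, type = 7)
    criteria[, ch] <- crit
    thresholds[ch] <- thr
    masks[, ch] <- crit > thr
  }
  list(masks = masks, merged = rowSums(masks) > 0, criteria = criteria,
       thresholds = thresholds)
}

#' Remove breaths contaminated by artifacts
#'
#' A breath is removed iff any sample in its `[start, end]` span is flagged
#' on the merged mask; since all channels share the central segmentation,
#' every channel retains the identical breath set.
#'
#' @param breaths data.frame from [separate_breaths()].
#' @param merged_mask logical vector over samples.
#' @return `breaths` with logical column `retained` added.
#' @export
remove_artifact_breaths <- function(breaths, merged_mask) {
  if (nrow(breaths) == 0) return(cbind(breaths, retained = logical(0)))
  flagged <- which(merged_mask)
  retained <- vapply(seq_len(nrow(breaths)), function(k)
    !any(flagged >= breaths$start[k] & flagged <= breaths$end[k]),
    logical(1))
  if (!any(retained))
    stop("no clean breathing detected: every breath overlaps an artifact")
  breaths$retained <- retained
  breaths
}

# Gaussian breath-feature model with tolerance handling of degenerate
# (zero-variance) directions: a jitter-free phantom produces identical
# features, which must still gate as full members.
fit_breath_model <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 5)
    stop("need >= 5 breaths to estimate the feature covariance; ",
         "record a longer trial")
  mu <- colMeans(x)
  sigma <- stats::cov(x)
  structure(list(mean = mu, cov = sigma, n = nrow(x)), class = "breath_model")
}

# squared Mahalanobis distance with degenerate-direction tolerance
mahalanobis_sq <- function(x, model) {
  x <- as.matrix(x)
  e <- eigen(model$cov, symmetric = TRUE)
  scale_ref <- max(e$values, sum(model$mean^2), 1e-12)
  tol <- 1e-10 * scale_ref
  centered <- sweep(x, 2, model$mean) %*% e$vectors
  d2 <- numeric(nrow(x))
  for (k in seq_along(e$values)) {
    if (e$values[k] > tol) {
      d2 <- d2 + centered[, k]^2 / e$values[k]
    } else {
      off <- abs(centered[, k]) > sqrt(tol)
      d2[off] <- Inf
    }
  }
  d2
}

#' Membership probability of breaths under a Gaussian feature model
#'
#' Defined as the probability mass outside the point's density contour:
#' `1 - F(D^2)` with `D^2` the squared Mahalanobis distance and `F` the
#' chi-square CDF with as many degrees of freedom as features.
#'
#' @param features data.frame/matrix of breath features.
#' @param model a model fitted by `gate_breaths()`.
#' @export
membership_probability <- function(features, model) {
  d2 <- mahalanobis_sq(features, model)
  p <- 1 - stats::pchisq(d2, df = length(model$mean))
  p[is.infinite(d2)] <- 0
  p
}

#' Gate breaths on the intersection of two Gaussian feature models
#'
#' One Gaussian is fitted per session on the (period, amplitude) features of
#' its retained breaths; a breath is kept iff its membership probability is
#' at least `floor` under BOTH models (the 5 percent contour is inclusive).
#' With a single session the gate degenerates to self-gating against the
#' session's own model.
#'
#' @param features_a,features_b data.frames with columns `period_s` and
#'   `amplitude_cm` (`features_b` may be `NULL`).
#' @param floor membership probability floor (default 0.05).
#' @return list with logical `keep_a`, `keep_b`, and the fitted `model_a`,
#'   `model_b`.
#' @export
gate_breaths <- function(features_a, features_b = NULL, floor = 0.05) {
  cols <- c("period_s", "amplitude_cm")
  fa <- features_a[, cols]
  model_a <- fit_breath_model(fa)
  if (is.null(features_b)) {
    keep_a <- membership_probability(fa, model_a) >= floor
    return(list(keep_a = keep_a, keep_b = NULL, model_a = model_a,
                model_b = NULL))
  }
  fb <- features_b[, cols]
  model_b <- fit_breath_model(fb)
  keep_a <- membership_probability(fa, model_a) >= floor &
            membership_probability(fa, model_b) >= floor
  keep_b <- membership_probability(fb, model_a) >= floor &
            membership_probability(fb, model_b) >= floor
  list(keep_a = keep_a, keep_b = keep_b, model_a = model_a, model_b = model_b)
}
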