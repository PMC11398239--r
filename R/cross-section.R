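# Transverse cross-section morphometry.
#
# For each retained breath, the depth-variation values of one grid row at
# the breath's inspiration maximum (or expiration end-minimum) form a
# 7-node transverse cross-section (CS); CS1/CS2/CS3 are grid rows 1/3/5.
# Groups of CSs are cleaned with a 1.5-IQR per-location outlier rule whose
# flags propagate to the same-time-sample CSs at the other levels, a medoid
# triplet in (area1, area2, area3) space represents the session, and
# dispersion is summarized by coefficients of variation per location and of
# the CS area.

cs_levels <- function(rows_of_interest = c(1, 3, 5)) {
  data.frame(level = seq_along(rows_of_interest), row_i = rows_of_interest)
}

#' Extract all cross-sections of a phase
#'
#' Node j of a CS is the row's channel signal at the breath's maximum
#' (inspiration) or end minimum (expiration); node positions are the grid
#' column coordinates at that time sample.
#'
#' @param signals a `depth_signals` object.
#' @param breaths data.frame of breaths to use (already gated/cleaned).
#' @param phase `"inspiration"` or `"expiration"`.
#' @return Long data.frame: `phase`, `level` (1..3), `row_i`, `breath_id`,
#'   `sample`, `j`, `y_cm`, `depth_cm`, `outlier` (initialized FALSE).
#' @export
extract_cross_sections <- function(signals, breaths,
                                   phase = c("inspiration", "expiration")) {
  phase <- match.arg(phase)
  lv <- cs_levels(unique(signals$channels$i))
  samples <- if (phase == "inspiration") breaths$max_idx else breaths$end
  if (any(samples < 1 | samples > nrow(signals$r)))
    stop("breath sample index out of signal range")
  out <- vector("list", nrow(lv) * nrow(breaths))
  k <- 0
  for (li in seq_len(nrow(lv))) {
    cols <- sprintf("r_%d_%d", lv$row_i[li], 1:7)
    for (bi in seq_len(nrow(breaths))) {
      k <- k + 1
      smp <- samples[bi]
      out[[k]] <- data.frame(phase = phase, level = lv$level[li],
                             row_i = lv$row_i[li],
                             breath_id = breaths$breath_id[bi],
                             sample = smp, j = 1:7,
                             y_cm = signals$col_y[smp, ],
                             depth_cm = unname(signals$r[smp, cols]),
                             outlier = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Linear interpolation along a cross-section
#'
#' @param y_nodes,depths the 7 node positions (strictly increasing, cm) and
#'   depths (cm).
#' @param query query positions (cm) within `[y_nodes[1], y_nodes[7]]`;
#'   extrapolation is rejected.
#' @export
interpolate_cs <- function(y_nodes, depths, query) {
  if (any(query < min(y_nodes) | query > max(y_nodes)))
    stop("query outside the cross-section span; extrapolation is not defined")
  stats::approx(y_nodes, depths, xout = query)$y
}

#' Area under a cross-section curve
#'
#' Trapezoidal rule over the 7 nodes, exact for the piecewise-linear CS.
#'
#' @param y_nodes,depths node positions and depths (cm).
#' @return area in cm^2.
#' @export
cs_area <- function(y_nodes, depths) trapz(y_nodes, depths)

# per-CS areas of a long CS table
cs_area_table <- function(cs_long) {
  key <- interaction(cs_long$phase, cs_long$level, cs_long$sample, drop = TRUE)
  parts <- split(cs_long, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    p <- p[order(p$j), ]
    data.frame(phase = p$phase[1], level = p$level[1],
               breath_id = p$breath_id[1], sample = p$sample[1],
               outlier = any(p$outlier),
               area = cs_area(p$y_cm, p$depth_cm))
  }))
  rownames(out) <- NULL
  out
}

#' Flag outlier cross-sections (1.5-IQR cascade)
#'
#' Per phase, level and location j, quartiles are computed once over the
#' whole group; a CS with any node outside `[Q1 - f*IQR, Q3 + f*IQR]` is
#' flagged. Flags propagate to the CSs of the other levels that share the
#' time sample (same phase), iterating until no new flags arise; quartiles
#' are not refitted after removals.
#'
#' @param cs_long long CS table from [extract_cross_sections()] (one phase
#'   or both).
#' @param iqr_factor fence multiplier (default 1.5).
#' @return `cs_long` with the `outlier` column updated.
#' @export
flag_outliers <- function(cs_long, iqr_factor = 1.5) {
  cs_long$outlier <- FALSE
  for (ph in unique(cs_long$phase)) {
    sel <- cs_long$phase == ph
    sub <- cs_long[sel, ]
    n_members <- length(unique(sub$sample))
    if (n_members < 4)
      stop("fewer than 4 cross-sections in phase '", ph,
           "': quartiles are not meaningful")
    flagged_samples <- character(0)
    for (lv in unique(sub$level)) {
      for (jj in 1:7) {
        v <- sub$depth_cm[sub$level == lv & sub$j == jj]
        q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
        fence <- c(q[1] - iqr_factor * (q[2] - q[1]),
                   q[2] + iqr_factor * (q[2] - q[1]))
        bad <- sub$level == lv & sub$j == jj &
          (sub$depth_cm < fence[1] | sub$depth_cm > fence[2])
        flagged_samples <- union(flagged_samples,
                                 as.character(sub$sample[bad]))
      }
    }
    # propagation: a flagged time sample removes the whole triplet; with
    # sample-level flags one pass reaches the fixed point, kept as a loop
    # for clarity of the contract
    repeat {
      new_flags <- as.character(sub$sample) %in% flagged_samples
      if (identical(new_flags, sub$outlier)) break
      sub$outlier <- new_flags
    }
    cs_long$outlier[sel] <- sub$outlier
  }
  cs_long
}

#' Select the representative cross-section triplet (medoid)
#'
#' Every clean triplet (the CS1/CS2/CS3 extracted at one time sample) is a
#' point (A1, A2, A3) in area feature space; the triplet minimizing the sum
#' of Euclidean distances to all other points is the medoid. Ties are broken
#' by the earliest time sample.
#'
#' @param cs_long long CS table of one phase with outliers flagged.
#' @return list with `sample`, `breath_id`, `areas` (length 3), and `nodes`
#'   (per level, data.frame of y/depth).
#' @export
select_representative <- function(cs_long) {
  ph <- unique(cs_long$phase)
  if (length(ph) != 1) stop("representative selection works per phase")
  clean <- cs_long[!cs_long$outlier, ]
  if (nrow(clean) == 0) stop("no clean cross-section triplets in phase ", ph)
  at <- cs_area_table(clean)
  wide <- stats::reshape(at[, c("sample", "level", "area")],
                         idvar = "sample", timevar = "level",
                         direction = "wide")
  wide <- wide[order(wide$sample), ]
  pts <- as.matrix(wide[, -1])
  if (anyNA(pts)) stop("incomplete triplets: a level is missing for some samples")
  if (nrow(pts) == 1) {
    med <- 1
  } else {
    dd <- as.matrix(stats::dist(pts))
    tot <- rowSums(dd)
    med <- which(tot == min(tot))[1]   # earliest sample on ties
  }
  smp <- wide$sample[med]
  nodes <- lapply(sort(unique(clean$level)), function(lv) {
    p <- clean[clean$sample == smp & clean$level == lv, ]
    p <- p[order(p$j), ]
    data.frame(j = p$j, y_cm = p$y_cm, depth_cm = p$depth_cm)
  })
  list(phase = ph, sample = smp,
       breath_id = clean$breath_id[clean$sample == smp][1],
       areas = unname(pts[med, ]), nodes = nodes)
}

#' Dispersion of a cross-section group
#'
#' Coefficient of variation (100 * sample sd / mean) of the depth at each
#' location j over the clean members, and of the CS area.
#'
#' @param cs_long long CS table of one phase and one level with outliers
#'   flagged.
#' @return list with `cv_location` (length 7, percent) and `cv_area`
#'   (percent) plus the clean member count.
#' @export
cs_dispersion <- function(cs_long) {
  if (length(unique(cs_long$level)) != 1 || length(unique(cs_long$phase)) != 1)
    stop("dispersion is computed per phase and level")
  clean <- cs_long[!cs_long$outlier, ]
  n <- length(unique(clean$sample))
  if (n < 2) stop("need >= 2 clean members for dispersion")
  cv_loc <- vapply(1:7, function(jj) {
    v <- clean$depth_cm[clean$j == jj]
    m <- mean(v)
    if (m == 0) stop("zero mean depth at location ", jj)
    100 * stats::sd(v) / m
  }, numeric(1))
  areas <- cs_area_table(clean)$area
  m <- mean(areas)
  if (m == 0) stop("zero mean area")
  list(cv_location = cv_loc, cv_area = 100 * stats::sd(areas) / m, n = n)
}

#' Chest mobility within a session
#'
#' Percentage excess of the representative inspiration CS area over the
#' representative expiration CS area, per level:
#' `Dsess = 100 * (A_max - A_min) / A_min`.
#'
#' @param rep_insp,rep_exp representatives from [select_representative()].
#' @return data.frame with `level` and `dsess_pct`.
#' @export
chest_mobility <- function(rep_insp, rep_exp) {
  if (any(rep_exp$areas <= 0)) stop("non-positive expiration area")
  data.frame(level = seq_along(rep_insp$areas),
             dsess_pct = 100 * (rep_insp$areas - rep_exp$areas) / rep_exp$areas)
}

#' Inter-session morphology change
#'
#' Percentage change of the representative CS area from session 1 to
#' session 2, per level: `D = 100 * (A_sess2 - A_sess1) / A_sess1`.
#'
#' @param rep_sess1,rep_sess2 representatives of the same phase from the two
#'   sessions.
#' @return data.frame with `level` and `d_pct`.
#' @export
morphology_change <- function(rep_sess1, rep_sess2) {
  if (any(rep_sess1$areas <= 0)) stop("non-positive session-1 area")
  data.frame(level = seq_along(rep_sess1$areas),
             d_pct = 100 * (rep_sess2$areas - rep_sess1$areas) / rep_sess1$areas)
}
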