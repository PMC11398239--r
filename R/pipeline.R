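# Pipeline orchestration: trial processing, single-session analysis, and
# inter-session comparison, plus the run configuration holding every
# tunable with its default.

#' Run configuration
#'
#' Central container of processing tunables. Defaults are the method's
#' reference values: 2 cm square ROIs, 1 Hz 4th-order low-pass smoothing,
#' 99th-percentile CWT artifact criterion, 5 percent Gaussian membership
#' floor, 1.5-IQR outlier fences.
#'
#' @param pixel_pitch projection pixel size (cm/px).
#' @param search_radius marker search radius around the seed (cm).
#' @param marker_radius nominal marker radius (cm).
#' @param score_threshold minimal Hough detection score.
#' @param roi_half_size half the channel ROI side (cm).
#' @param rows_of_interest grid rows used for cross-sections.
#' @param central_channel (i, j) of the central location.
#' @param filter_cutoff,filter_order Butterworth smoothing parameters.
#' @param n_scales,freq_range CWT scale count and pseudo-frequency band (Hz).
#' @param artifact_percentile criterion flagging percentile.
#' @param membership_floor Gaussian gate probability floor.
#' @param iqr_factor outlier fence multiplier.
#' @export
run_config <- function(pixel_pitch = 0.1, search_radius = 2, marker_radius = 1,
                       score_threshold = 0.25, roi_half_size = 1,
                       rows_of_interest = c(1, 3, 5),
                       central_channel = c(3, 4),
                       filter_cutoff = 1, filter_order = 4,
                       n_scales = 64, freq_range = c(0.05, 5),
                       artifact_percentile = 0.99, membership_floor = 0.05,
                       iqr_factor = 1.5) {
  structure(list(pixel_pitch = pixel_pitch, search_radius = search_radius,
                 marker_radius = marker_radius,
                 score_threshold = score_threshold,
                 roi_half_size = roi_half_size,
                 rows_of_interest = rows_of_interest,
                 central_channel = central_channel,
                 filter_cutoff = filter_cutoff, filter_order = filter_order,
                 n_scales = n_scales, freq_range = freq_range,
                 artifact_percentile = artifact_percentile,
                 membership_floor = membership_floor,
                 iqr_factor = iqr_factor),
            class = "run_config")
}

#' Process one trial into breaths and depth signals
#'
#' Runs the full chain on a frame sequence: table plane fit on frame 1,
#' marker tracking (or operator-supplied tracks), per-frame rigid alignment
#' and grid construction, depth-signal extraction, smoothing, extrema-based
#' breath separation, CWT artifact flagging, and artifact-breath removal.
#'
#' @param sequence a `cm_sequence` (or a manifest path).
#' @param markers either a [marker_triplet()] operator seed (tracking is
#'   run), or a precomputed tracks data.frame with columns `frame`,
#'   `marker`, `x`, `y`, `z` (e.g. phantom ground truth).
#' @param table_region `cm_roi_box` containing only table points.
#' @param roi optional `cm_roi_box` crop applied to every frame (selected on
#'   the first frame of the trial).
#' @param config a [run_config()].
#' @return A `cm_session` list: `signals`, `smoothed_central`, `extrema`,
#'   `breaths` (with `retained` flags), `artifact`, `plane`, `tracks`,
#'   `counts`, `config`.
#' @export
process_session <- function(sequence, markers, table_region, roi = NULL,
                            config = run_config()) {
  if (is.character(sequence)) sequence <- read_sequence(sequence)
  frame1 <- get_frame(sequence, 1)
  plane <- fit_table_plane(frame1, table_region)
  tracks <- if (inherits(markers, "marker_triplet")) {
    track_markers(sequence, markers, pixel_pitch = config$pixel_pitch,
                  search_radius = config$search_radius,
                  marker_radius = config$marker_radius,
                  score_threshold = config$score_threshold)
  } else {
    need <- c("frame", "marker", "x", "y", "z")
    if (!all(need %in% names(markers)))
      stop("precomputed tracks need columns ", paste(need, collapse = ", "))
    markers
  }
  signals <- extract_depth_signals(sequence, tracks, plane, roi = roi,
                                   config = config)
  central <- signals$r[, signals$central]
  smoothed <- smooth_signal(central, signals$frame_rate,
                            cutoff = config$filter_cutoff,
                            order = config$filter_order)
  extrema <- detect_extrema(smoothed)
  breaths <- separate_breaths(smoothed, extrema, signals$frame_rate)
  artifact <- detect_artifact_samples(signals,
                                      percentile = config$artifact_percentile,
                                      scales = cwt_scales(signals$frame_rate,
                                                          config$n_scales,
                                                          config$freq_range))
  breaths <- remove_artifact_breaths(breaths, artifact$merged)
  counts <- list(breaths_initial = nrow(breaths),
                 breaths_retained = sum(breaths$retained))
  structure(list(signals = signals, smoothed_central = smoothed,
                 extrema = extrema, breaths = breaths, artifact = artifact,
                 plane = plane, tracks = tracks, counts = counts,
                 config = config),
            class = "cm_session")
}

#' @export
print.cm_session <- function(x, ...) {
  cat("<cm_session> ", nrow(x$signals$r), " samples, breaths: ",
      x$counts$breaths_initial, " initial / ", x$counts$breaths_retained,
      " retained after artifact removal\n", sep = "")
  invisible(x)
}

# cross-section analysis of one session given the final breath subset
analyze_cross_sections <- function(session, breaths) {
  out <- list()
  for (ph in c("inspiration", "expiration")) {
    cs <- extract_cross_sections(session$signals, breaths, ph)
    cs <- flag_outliers(cs, session$config$iqr_factor)
    rep_ <- select_representative(cs)
    disp <- lapply(sort(unique(cs$level)), function(lv)
      cs_dispersion(cs[cs$level == lv, ]))
    out[[ph]] <- list(cs = cs, representative = rep_, dispersion = disp,
                      n_initial = length(unique(cs$sample)),
                      n_clean = length(unique(cs$sample[!cs$outlier])))
  }
  out
}

#' Analyze a single session (self-gated)
#'
#' Gates the session's artifact-free breaths against its own Gaussian
#' feature model, derives inspiration and expiration cross-sections at the
#' three levels, removes outliers, selects representatives, and computes
#' dispersion and chest mobility.
#'
#' @param session a `cm_session` from [process_session()].
#' @return A session report list (counts, per-phase CS groups, dispersion,
#'   representatives, `mobility`).
#' @export
analyze_session <- function(session) {
  kept <- session$breaths[session$breaths$retained, ]
  gate <- gate_breaths(kept, floor = session$config$membership_floor)
  gated <- kept[gate$keep_a, ]
  phases <- analyze_cross_sections(session, gated)
  mobility <- chest_mobility(phases$inspiration$representative,
                             phases$expiration$representative)
  list(counts = c(session$counts,
                  list(breaths_gated = nrow(gated)),
                  cs_initial = phases$inspiration$n_initial,
                  cs_clean_insp = phases$inspiration$n_clean,
                  cs_clean_exp = phases$expiration$n_clean),
       phases = phases, gate = gate, mobility = mobility)
}

#' Compare two sessions
#'
#' Gates the two sessions' breaths on the intersection of their Gaussian
#' feature models, re-derives cross-sections and representatives on the
#' gated breaths, and reports chest mobility per session plus the
#' inter-session morphology change per level and phase.
#'
#' @param session1,session2 `cm_session` objects.
#' @return list with `report1`, `report2` (per-session phase analyses),
#'   `mobility1`, `mobility2`, `change` (data.frame level x phase), and the
#'   gate.
#' @export
compare_sessions <- function(session1, session2) {
  k1 <- session1$breaths[session1$breaths$retained, ]
  k2 <- session2$breaths[session2$breaths$retained, ]
  gate <- gate_breaths(k1, k2, floor = session1$config$membership_floor)
  g1 <- k1[gate$keep_a, ]
  g2 <- k2[gate$keep_b, ]
  if (nrow(g1) == 0 || nrow(g2) == 0)
    stop("gating removed every breath in one session; the breathing ",
         "patterns are incompatible")
  ph1 <- analyze_cross_sections(session1, g1)
  ph2 <- analyze_cross_sections(session2, g2)
  change <- do.call(rbind, lapply(c("inspiration", "expiration"), function(ph) {
    d <- morphology_change(ph1[[ph]]$representative, ph2[[ph]]$representative)
    cbind(phase = ph, d)
  }))
  list(report1 = ph1, report2 = ph2,
       mobility1 = chest_mobility(ph1$inspiration$representative,
                                  ph1$expiration$representative),
       mobility2 = chest_mobility(ph2$inspiration$representative,
                                  ph2$expiration$representative),
       change = change, gate = gate,
       counts = list(gated1 = nrow(g1), gated2 = nrow(g2)))
}

#' Generate a phantom trial and write it to disk
#'
#' Thin wrapper over [generate_sequence()] that writes the PLY frames, the
#' JSON manifest, and the ground truth (marker tracks, true channel
#' signals, breath extrema) as CSV.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory.
#' @return The manifest path, invisibly.
#' @export
simulate_phantom_run <- function(config, out_dir) {
  ph <- generate_sequence(config)
  manifest <- write_sequence(ph$sequence, out_dir)
  utils::write.csv(ph$truth$markers,
                   file.path(out_dir, "truth_markers.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ph$truth$r),
                   file.path(out_dir, "truth_signals.csv"), row.names = FALSE)
  utils::write.csv(data.frame(kind = rep(c("max", "min"),
                                         c(length(ph$truth$max_idx),
                                           length(ph$truth$min_idx))),
                              sample = c(ph$truth$max_idx, ph$truth$min_idx)),
                   file.path(out_dir, "truth_extrema.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write a session report as JSON
#'
#' @param report result of [analyze_session()].
#' @param path output path.
#' @export
write_session_report <- function(report, path) {
  out <- list(counts = report$counts,
              mobility = report$mobility,
              phases = lapply(report$phases, function(p)
                list(n_initial = p$n_initial, n_clean = p$n_clean,
                     representative = list(sample = p$representative$sample,
                                           areas = p$representative$areas),
                     cv_location = lapply(p$dispersion, `[[`, "cv_location"),
                     cv_area = vapply(p$dispersion, `[[`, 0, "cv_area"))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
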