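# Colorized point-cloud frames, PLY sequence input/output, and ROI cropping.
#
# A frame is the raw unit of input: one colorized point cloud per time step.
# Sequences are kept lazy (a frame-producing closure) so that a 60 s trial at
# 30 fps never has to be materialized in memory at once.

#' Construct a colorized point-cloud frame
#'
#' @param points numeric matrix with columns x, y, z in cm (camera
#'   coordinates, z increasing away from the camera).
#' @param colors numeric matrix with columns r, g, b in `[0, 255]`, one row
#'   per point.
#' @param timestamp acquisition time in seconds.
#' @param drop_nonfinite drop points with any non-finite coordinate (depth
#'   holes); the number dropped is reported via a message.
#' @return An object of class `cm_frame`.
#' @export
frame <- function(points, colors, timestamp = 0, drop_nonfinite = TRUE) {
  points <- as.matrix(points)
  colors <- as.matrix(colors)
  if (ncol(points) != 3) stop("`points` must have 3 columns (x, y, z)")
  if (ncol(colors) != 3) stop("`colors` must have 3 columns (r, g, b)")
  if (nrow(points) != nrow(colors))
    stop("`points` and `colors` must have the same number of rows")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  dimnames(colors) <- list(NULL, c("r", "g", "b"))
  if (drop_nonfinite) {
    ok <- is.finite(points[, 1]) & is.finite(points[, 2]) & is.finite(points[, 3])
    if (!all(ok)) {
      message(sum(!ok), " non-finite point(s) dropped")
      points <- points[ok, , drop = FALSE]
      colors <- colors[ok, , drop = FALSE]
    }
  }
  structure(list(points = points, colors = colors, timestamp = timestamp),
            class = "cm_frame")
}

#' @export
print.cm_frame <- function(x, ...) {
  cat("<cm_frame> ", nrow(x$points), " points, t = ",
      format(x$timestamp), " s\n", sep = "")
  invisible(x)
}

#' Construct a frame sequence from a frame producer
#'
#' @param get function of a frame index returning a `cm_frame`.
#' @param n number of frames.
#' @param frame_rate frames per second.
#' @param meta optional metadata list.
#' @return An object of class `cm_sequence`.
#' @export
frame_sequence <- function(get, n, frame_rate, meta = list()) {
  structure(list(get = get, n = as.integer(n), frame_rate = frame_rate,
                 meta = meta),
            class = "cm_sequence")
}

#' Frame sequence backed by an in-memory list of frames
#' @param frames list of `cm_frame` objects.
#' @param frame_rate frames per second.
#' @export
sequence_from_frames <- function(frames, frame_rate) {
  frame_sequence(function(i) frames[[i]], length(frames), frame_rate)
}

#' Number of frames in a sequence
#' @param x a `cm_sequence`.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.cm_sequence <- function(x) x$n

#' Materialize one frame of a sequence
#' @param x a `cm_sequence`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(x, i) UseMethod("get_frame")

#' @export
get_frame.cm_sequence <- function(x, i) {
  if (i < 1 || i > x$n) stop("frame index ", i, " out of range 1..", x$n)
  x$get(i)
}

#' @export
print.cm_sequence <- function(x, ...) {
  cat("<cm_sequence> ", x$n, " frames @ ", x$frame_rate, " fps\n", sep = "")
  invisible(x)
}

#' Axis-aligned region-of-interest box (half-open intervals)
#'
#' Points with `min <= coord < max` on every axis are inside. The half-open
#' convention avoids double-counting points on shared boundaries.
#'
#' @param x,y,z length-2 numeric intervals in cm; default unbounded.
#' @export
roi_box <- function(x = c(-Inf, Inf), y = c(-Inf, Inf), z = c(-Inf, Inf)) {
  for (iv in list(x, y, z))
    if (length(iv) != 2 || !(iv[1] < iv[2]))
      stop("each interval must satisfy min < max")
  structure(list(x = x, y = y, z = z), class = "cm_roi_box")
}

#' Crop a frame to a region of interest
#'
#' Retains exactly the points inside the half-open box, keeping colors in
#' correspondence. An empty result is legal but reported via a message.
#'
#' @param frame a `cm_frame`.
#' @param box a `cm_roi_box`.
#' @export
crop <- function(frame, box) {
  p <- frame$points
  keep <- p[, 1] >= box$x[1] & p[, 1] < box$x[2] &
          p[, 2] >= box$y[1] & p[, 2] < box$y[2] &
          p[, 3] >= box$z[1] & p[, 3] < box$z[2]
  if (!any(keep)) message("crop produced an empty frame")
  structure(list(points = p[keep, , drop = FALSE],
                 colors = frame$colors[keep, , drop = FALSE],
                 timestamp = frame$timestamp),
            class = "cm_frame")
}

# ---------------------------------------------------------------------------
# PLY
# ---------------------------------------------------------------------------

#' Write a frame as binary little-endian PLY
#'
#' Per-vertex layout: x, y, z as float32 and red, green, blue as uchar.
#'
#' @param frame a `cm_frame`.
#' @param path output file path.
#' @export
write_ply <- function(frame, path) {
  n <- nrow(frame$points)
  header <- c(
    "ply",
    "format binary_little_endian 1.0",
    "comment chestmorph point cloud frame (units cm)",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  xyz <- writeBin(as.vector(t(frame$points)), raw(), size = 4,
                  endian = "little")
  rgb <- as.raw(as.vector(t(round(frame$colors))))
  # interleave 12 coordinate bytes + 3 color bytes per vertex
  rec <- raw(n * 15L)
  xyz_pos <- as.vector(vapply(seq_len(n), function(i) (i - 1L) * 15L + 1:12,
                              integer(12)))
  rgb_pos <- as.vector(vapply(seq_len(n), function(i) (i - 1L) * 15L + 13:15,
                              integer(3)))
  rec[xyz_pos] <- xyz
  rec[rgb_pos] <- rgb
  writeBin(rec, con)
  invisible(path)
}

ply_type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)

#' Read a PLY point cloud frame
#'
#' Accepts the ascii and binary_little_endian dialects. The vertex element
#' must carry x/y/z coordinates and red/green/blue colors; a missing property
#' is reported by name. Non-finite points are dropped with a message.
#'
#' @param path PLY file path.
#' @param timestamp timestamp to attach to the frame (s).
#' @export
read_ply <- function(path, timestamp = 0) {
  if (!file.exists(path)) stop("PLY file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fmt <- NULL; n <- NULL; props <- character(); types <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed PLY header (no end_header): ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      types <- c(types, tok[2]); props <- c(props, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format in ", path, ": ", fmt %||% "<missing>")
  if (is.null(n)) stop("malformed PLY header (no vertex element): ", path)
  need <- c("x", "y", "z", "red", "green", "blue")
  missing_p <- setdiff(need, props)
  if (length(missing_p))
    stop("PLY ", path, " lacks required propert",
         if (length(missing_p) > 1) "ies: " else "y: ",
         paste(missing_p, collapse = ", "))

  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = n * length(props), quiet = TRUE)
    m <- matrix(vals, ncol = length(props), byrow = TRUE)
    colnames(m) <- props
  } else {
    sizes <- ply_type_size[types]
    if (anyNA(sizes)) stop("unsupported PLY property type in ", path)
    rowbytes <- sum(sizes)
    rawdat <- readBin(con, raw(), n = n * rowbytes)
    if (length(rawdat) < n * rowbytes) stop("truncated PLY data in ", path)
    offsets <- cumsum(c(0, sizes[-length(sizes)]))
    m <- matrix(0, n, length(props), dimnames = list(NULL, props))
    base <- (seq_len(n) - 1L) * rowbytes
    for (k in seq_along(props)) {
      sz <- sizes[k]
      idx <- rep(base, each = sz) + offsets[k] + seq_len(sz)
      bytes <- rawdat[idx]
      m[, k] <- switch(types[k],
        float = , float32 = readBin(bytes, numeric(), n = n, size = 4,
                                    endian = "little"),
        double = , float64 = readBin(bytes, numeric(), n = n, size = 8,
                                     endian = "little"),
        uchar = , uint8 = as.numeric(bytes),
        readBin(bytes, integer(), n = n, size = sz, endian = "little"))
    }
  }
  frame(m[, c("x", "y", "z"), drop = FALSE],
        m[, c("red", "green", "blue"), drop = FALSE],
        timestamp = timestamp)
}

#' Write a frame sequence as PLY files plus a JSON manifest
#'
#' @param sequence a `cm_sequence`.
#' @param dir output directory (created if needed).
#' @param config_echo optional list echoed into the manifest for provenance.
#' @return The manifest path, invisibly.
#' @export
write_sequence <- function(sequence, dir, config_echo = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_frames(sequence)
  files <- sprintf("frame_%05d.ply", seq_len(n))
  for (i in seq_len(n))
    write_ply(get_frame(sequence, i), file.path(dir, files[i]))
  manifest <- list(frame_rate = sequence$frame_rate, units = "cm",
                   n_frames = n, frames = files,
                   config = config_echo %||% sequence$meta$config)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a frame sequence from a JSON manifest
#'
#' Frames are loaded lazily, in manifest order, one PLY file per frame.
#'
#' @param manifest path to a manifest written by [write_sequence()].
#' @export
read_sequence <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  paths <- file.path(dir, m$frames)
  missing_f <- paths[!file.exists(paths)]
  if (length(missing_f))
    stop("manifest references missing frame file(s): ",
         paste(basename(missing_f), collapse = ", "))
  fr <- as.numeric(m$frame_rate)
  frame_sequence(function(i) read_ply(paths[i], timestamp = (i - 1) / fr),
                 length(paths), fr,
                 meta = list(manifest = manifest, config = m$config))
}
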