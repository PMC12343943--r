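#' Reference corner signatures for the three cardinal planes
#'
#' Each cine frame carries a plane-specific intensity pattern in its top-right
#' corner; the absolute intensities vary between monitoring sessions but the
#' pattern is stable per plane. `plane_glyph()` returns the binary reference
#' pattern for one plane, and `default_plane_templates()` the full template
#' set used by [classify_plane()]. The same glyphs are stamped by the fixture
#' generator, making them normative for fixtures; for real sessions the
#' templates can be re-learned from a labelled sample and passed in.
#'
#' The three glyphs are mutually near-orthogonal band patterns: horizontal
#' bars (coronal), vertical bars (sagittal), and a checkerboard (axial).
#'
#' @param plane One of `"coronal"`, `"sagittal"`, `"axial"`.
#' @param size Patch side length in pixels (default 32).
#' @return `plane_glyph()`: a `size x size` 0/1 matrix.
#'   `default_plane_templates()`: named list of such matrices.
#' @export
plane_glyph <- function(plane = c("coronal", "sagittal", "axial"), size = 32L) {
  plane <- match.arg(plane)
  r <- matrix(rep(0:(size - 1L), times = size), size, size)   # row index, 0-based
  cc <- matrix(rep(0:(size - 1L), each = size), size, size)   # col index
  band <- 4L
  g <- switch(plane,
    coronal  = (r %/% band) %% 2L,
    sagittal = (cc %/% band) %% 2L,
    axial    = ((r %/% band) + (cc %/% band)) %% 2L
  )
  storage.mode(g) <- "integer"
  g
}

#' @rdname plane_glyph
#' @export
default_plane_templates <- function(size = 32L) {
  planes <- c("coronal", "sagittal", "axial")
  stats::setNames(lapply(planes, plane_glyph, size = size), planes)
}

# Extract the top-right corner patch used for plane classification.
corner_patch <- function(pixels, size = 32L) {
  if (nrow(pixels) < size || ncol(pixels) < size) {
    stop(sprintf("frame (%d x %d) is smaller than the %d-pixel corner patch",
                 nrow(pixels), ncol(pixels), size), call. = FALSE)
  }
  pixels[seq_len(size), (ncol(pixels) - size + 1L):ncol(pixels), drop = FALSE]
}

# Binarize a patch at the Otsu threshold, mapping any positive intensity
# scaling of the same pattern to the same 0/1 matrix. Returns NULL for a
# constant (signal-free) patch.
normalize_signature <- function(patch) {
  rng <- range(patch)
  if (diff(rng) <= 0) return(NULL)
  scaled <- (patch - rng[1]) / diff(rng)
  th <- EBImage::otsu(scaled, range = c(0, 1))
  (scaled > th) * 1L
}

#' Classify the imaging plane of a cine frame from its corner signature
#'
#' Extracts the fixed top-right corner patch, binarizes it at the Otsu
#' threshold (making the signature invariant to session-level intensity
#' scaling), and correlates it against per-plane reference templates. The
#' best-matching plane is returned with a confidence score in `[0, 1]`
#' (the Pearson correlation of the binarized patch with the template,
#' clamped at 0); below `threshold` the frame is labelled `"unknown"` rather
#' than guessed.
#'
#' @param pixels Frame pixel matrix (raw, before the centering shift).
#' @param templates Named list of 0/1 template matrices, one per plane
#'   (default [default_plane_templates()]).
#' @param threshold Minimum confidence to accept a label (default 0.8).
#' @return List with `plane` (character) and `confidence` (numeric).
#' @export
classify_plane <- function(pixels, templates = default_plane_templates(),
                           threshold = 0.8) {
  size <- nrow(templates[[1]])
  patch <- corner_patch(pixels, size)
  sig <- normalize_signature(patch)
  if (is.null(sig)) return(list(plane = "unknown", confidence = 0))
  scores <- vapply(templates, function(tmpl) {
    s <- stats::cor(as.vector(sig), as.vector(tmpl))
    if (is.na(s)) 0 else max(0, s)
  }, numeric(1))
  best <- which.max(scores)
  if (scores[best] < threshold) {
    list(plane = "unknown", confidence = unname(scores[best]))
  } else {
    list(plane = names(templates)[best], confidence = unname(scores[best]))
  }
}

#' Apply the fixed centering shift to a decoded frame
#'
#' Frames decoded from the binary files are offset from their correct
#' centered position by exactly 22 pixels; this translates the image content
#' by 22 pixels along the negative column direction (the default; direction
#' and axis are configurable), filling vacated pixels with 0. Output
#' dimensions are unchanged.
#'
#' @param pixels Pixel matrix, at least 23 pixels wide along the shift axis.
#' @param shift Signed pixel shift; the default `-centering_shift_pixels()`
#'   moves content from column `c` to column `c - 22`.
#' @param axis `"col"` (default) or `"row"`.
#' @return Shifted matrix of identical dimensions.
#' @export
apply_centering_shift <- function(pixels, shift = -centering_shift_pixels(),
                                  axis = c("col", "row")) {
  axis <- match.arg(axis)
  n <- if (axis == "col") ncol(pixels) else nrow(pixels)
  if (n <= abs(shift)) {
    stop(sprintf("frame has only %d pixels along the %s axis; need more than %d",
                 n, axis, abs(shift)), call. = FALSE)
  }
  out <- matrix(0L, nrow(pixels), ncol(pixels))
  s <- abs(shift)
  if (axis == "col") {
    if (shift < 0) out[, seq_len(ncol(pixels) - s)] <- pixels[, (s + 1L):ncol(pixels)]
    else if (shift > 0) out[, (s + 1L):ncol(pixels)] <- pixels[, seq_len(ncol(pixels) - s)]
    else out <- pixels
  } else {
    if (shift < 0) out[seq_len(nrow(pixels) - s), ] <- pixels[(s + 1L):nrow(pixels), ]
    else if (shift > 0) out[(s + 1L):nrow(pixels), ] <- pixels[seq_len(nrow(pixels) - s), ]
    else out <- pixels
  }
  storage.mode(out) <- storage.mode(pixels)
  out
}

#' Direction cosines for the three cardinal planes
#'
#' DICOM LPS convention. `row_dir` is the in-plane direction along which the
#' column index increases (the first ImageOrientationPatient vector);
#' `col_dir` the direction along which the row index increases; `normal`
#' their cross product.
#'
#' @param plane `"coronal"`, `"sagittal"` or `"axial"`.
#' @return List with unit vectors `row_dir`, `col_dir`, `normal`.
#' @export
plane_orientation <- function(plane = c("coronal", "sagittal", "axial")) {
  plane <- match.arg(plane)
  o <- switch(plane,
    axial    = list(row_dir = c(1, 0, 0), col_dir = c(0, 1, 0)),
    coronal  = list(row_dir = c(1, 0, 0), col_dir = c(0, 0, -1)),
    sagittal = list(row_dir = c(0, 1, 0), col_dir = c(0, 0, -1))
  )
  o$normal <- c(
    o$row_dir[2] * o$col_dir[3] - o$row_dir[3] * o$col_dir[2],
    o$row_dir[3] * o$col_dir[1] - o$row_dir[1] * o$col_dir[3],
    o$row_dir[1] * o$col_dir[2] - o$row_dir[2] * o$col_dir[1]
  )
  o
}

#' Assign 3D patient-space geometry to a classified frame
#'
#' Cine frames are acquired through the centroid of the target structure, so
#' the continuous image center — pixel-center coordinate
#' `((rows-1)/2, (cols-1)/2)`, 0-based — is placed at the session's target
#' centroid. The origin (world coordinate of the first pixel's center)
#' follows as `centroid - row_dir*(cols-1)/2*spacing_col -
#' col_dir*(rows-1)/2*spacing_row` with the plane's direction cosines from
#' [plane_orientation()].
#'
#' @param pixels Pixel matrix (after the centering shift).
#' @param plane `"coronal"`, `"sagittal"` or `"axial"`; `"unknown"` is an
#'   error (such frames are quarantined upstream).
#' @param spacing Numeric `c(row, col)` pixel spacing in mm.
#' @param centroid Target centroid, length-3 mm LPS (see
#'   [parse_target_centroid()]).
#' @param timestamp_ms Acquisition timestamp, milliseconds since epoch.
#' @param frame_uid Optional frame identifier string.
#' @return A `geo_frame` object: list with `pixels`, `plane`, `spacing`
#'   (named `row`/`col`), `origin`, `row_dir`, `col_dir`, `normal`,
#'   `timestamp_ms`, `frame_uid`.
#' @export
assign_geometry <- function(pixels, plane, spacing, centroid,
                            timestamp_ms = NA_real_, frame_uid = NULL) {
  if (identical(plane, "unknown")) {
    stop("cannot assign geometry to a frame with unknown plane", call. = FALSE)
  }
  o <- plane_orientation(plane)
  stopifnot(length(spacing) == 2L, all(spacing > 0), length(centroid) == 3L)
  spacing <- stats::setNames(as.numeric(spacing), c("row", "col"))
  rows <- nrow(pixels); cols <- ncol(pixels)
  origin <- as.numeric(centroid) -
    o$row_dir * (cols - 1) / 2 * spacing[["col"]] -
    o$col_dir * (rows - 1) / 2 * spacing[["row"]]
  structure(list(
    pixels = pixels,
    plane = plane,
    spacing = spacing,
    origin = origin,
    row_dir = o$row_dir,
    col_dir = o$col_dir,
    normal = o$normal,
    timestamp_ms = as.numeric(timestamp_ms),
    frame_uid = frame_uid
  ), class = "geo_frame")
}

#' @export
print.geo_frame <- function(x, ...) {
  cat(sprintf("<geo_frame> %s, %d x %d px @ %.4g x %.4g mm, origin (%.2f, %.2f, %.2f)\n",
              x$plane, nrow(x$pixels), ncol(x$pixels),
              x$spacing[["row"]], x$spacing[["col"]],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Map 0-based pixel indices to world coordinates
#'
#' `world(r, c) = origin + row_dir * c * spacing_col + col_dir * r *
#' spacing_row`; indices may be fractional (pixel-center convention).
#'
#' @param frame A `geo_frame`.
#' @param r,c 0-based (possibly fractional) row and column indices.
#' @return Length-3 world coordinate in mm (or a 3-column matrix for
#'   vector input).
#' @export
pixel_to_world <- function(frame, r, c) {
  if (length(r) == 1L) {
    frame$origin + frame$row_dir * c * frame$spacing[["col"]] +
      frame$col_dir * r * frame$spacing[["row"]]
  } else {
    t(vapply(seq_along(r), function(i) {
      frame$origin + frame$row_dir * c[i] * frame$spacing[["col"]] +
        frame$col_dir * r[i] * frame$spacing[["row"]]
    }, numeric(3)))
  }
}

# In-plane (u, v) coordinates of a world point: projections onto the frame's
# row and column direction vectors. u varies along columns, v along rows.
world_to_inplane <- function(frame, p) {
  c(u = sum((p - 0) * frame$row_dir), v = sum((p - 0) * frame$col_dir))
}
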