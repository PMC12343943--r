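#' Acquisition geometry of a cine monitoring session
#'
#' Builds the per-session geometry record from the pixel counts and physical
#' slice dimensions carried in the ExamCard JSON. Pixel spacing is derived as
#' physical dimension divided by pixel count, with the X slice dimension
#' spanning columns (horizontal) and the Y dimension spanning rows
#' (vertical).
#'
#' @param rows,columns Pixel counts (positive integers).
#' @param slice_dim_x_mm,slice_dim_y_mm Physical slice dimensions in mm; X
#'   spans columns, Y spans rows.
#' @return An object of class `acquisition_geometry`: a list with fields
#'   `rows`, `columns`, `slice_dim_x_mm`, `slice_dim_y_mm`,
#'   `pixel_spacing_row_mm`, `pixel_spacing_col_mm`.
#' @examples
#' acquisition_geometry(256, 256, 400, 400)$pixel_spacing_col_mm # 1.5625
#' @export
acquisition_geometry <- function(rows, columns, slice_dim_x_mm, slice_dim_y_mm) {
  vals <- c(rows = rows, columns = columns,
            slice_dim_x_mm = slice_dim_x_mm, slice_dim_y_mm = slice_dim_y_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("acquisition_geometry: all of rows, columns and slice dimensions must be positive, got (",
         paste(names(vals), vals, sep = "=", collapse = ", "), ")", call. = FALSE)
  }
  structure(list(
    rows = as.integer(rows),
    columns = as.integer(columns),
    slice_dim_x_mm = as.numeric(slice_dim_x_mm),
    slice_dim_y_mm = as.numeric(slice_dim_y_mm),
    pixel_spacing_row_mm = as.numeric(slice_dim_y_mm) / rows,
    pixel_spacing_col_mm = as.numeric(slice_dim_x_mm) / columns
  ), class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("<acquisition_geometry> %d x %d px, %.4f x %.4f mm/px (row x col)\n",
              x$rows, x$columns, x$pixel_spacing_row_mm, x$pixel_spacing_col_mm))
  invisible(x)
}

#' Parse the ExamCard acquisition-parameter JSON
#'
#' The ExamCard sidecar (`MotionMonitoring2DImages.ExamCardInfo.json` in the
#' session's `ExamCards` folder) records the pixel counts under `"Rows"` and
#' `"Columns"` and the physical slice dimensions under
#' `"SliceDimensionXInmm"` and `"SliceDimensionYInmm"`.
#'
#' @param x Either a path to the JSON file or an already-parsed list.
#' @return An [acquisition_geometry()] object.
#' @export
parse_examcard <- function(x) {
  doc <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE) else x
  needed <- c("Rows", "Columns", "SliceDimensionXInmm", "SliceDimensionYInmm")
  missing <- setdiff(needed, names(doc))
  if (length(missing)) {
    stop("ExamCard JSON is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  acquisition_geometry(
    rows = as.numeric(doc$Rows),
    columns = as.numeric(doc$Columns),
    slice_dim_x_mm = as.numeric(doc$SliceDimensionXInmm),
    slice_dim_y_mm = as.numeric(doc$SliceDimensionYInmm)
  )
}

#' Parse the target-structure centroid JSON
#'
#' Cine frames are acquired through the centroid of the target structure; the
#' centroid (mm, DICOM LPS) is read from the session's `BinaryMasks` folder.
#' The key schema used here (`structure`, `centroid_mm` with `x`/`y`/`z`,
#' `coordinate_system`) is the one written by [generate_session()] and is
#' normative for fixtures; real vendor sessions may differ.
#'
#' @param x Path to the JSON file or a parsed list.
#' @return Numeric length-3 vector `c(x, y, z)` in mm (LPS), with class
#'   `target_centroid`.
#' @export
parse_target_centroid <- function(x) {
  doc <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE) else x
  c3 <- doc$centroid_mm
  if (is.null(c3)) stop("BinaryMasks JSON has no 'centroid_mm' entry", call. = FALSE)
  cen <- unlist(c3[c("x", "y", "z")], use.names = FALSE)
  if (length(cen) != 3L || any(!is.finite(as.numeric(cen)))) {
    stop("BinaryMasks centroid must be three finite numbers (x, y, z), got: ",
         paste(unlist(c3), collapse = ", "), call. = FALSE)
  }
  structure(as.numeric(cen), names = c("x", "y", "z"), class = "target_centroid")
}

#' Decode the pixel payload of one binary cine frame
#'
#' Skips the opaque 4,084-byte header and reads `rows * columns` little-endian
#' unsigned 16-bit integers, returned as a `rows x columns` integer matrix
#' (row-major payload order). Decoding is lossless: re-encoding the matrix
#' reproduces the payload bytes.
#'
#' @param path Path to the binary frame file.
#' @param geometry An [acquisition_geometry()] for the session.
#' @return Integer matrix with `geometry$rows` rows and `geometry$columns`
#'   columns; values in `[0, 65535]`.
#' @export
read_frame_pixels <- function(path, geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (!file.exists(path)) stop("cannot read frame file: ", path, call. = FALSE)
  n_px <- geometry$rows * geometry$columns
  need <- cine_header_length() + cine_bytes_per_pixel() * n_px
  have <- file.size(path)
  if (have < need) {
    stop(sprintf("truncated frame file '%s': expected at least %d bytes (4084 header + %d payload), found %d",
                 path, need, need - cine_header_length(), have), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = cine_header_length()))
  vals <- readBin(con, integer(), n = n_px, size = 2L, signed = FALSE,
                  endian = "little")
  # payload is row-major; R matrices are column-major
  matrix(vals, nrow = geometry$rows, ncol = geometry$columns, byrow = TRUE)
}

# Inverse of read_frame_pixels on the payload: row-major little-endian uint16
# bytes for a pixel matrix. Shared by the fixture generator and round-trip
# tests so reader and writer cannot diverge.
encode_frame_payload <- function(pixels) {
  stopifnot(is.matrix(pixels))
  v <- as.integer(round(as.vector(t(pixels))))
  if (any(v < 0L | v > 65535L)) stop("pixel values outside [0, 65535]", call. = FALSE)
  writeBin(v, raw(), size = 2L, endian = "little")
}

#' Discover cine sessions under a root directory
#'
#' Scans `root` for per-fraction subdirectories (any directory containing
#' binary frame files, an `ExamCards` folder or a `BinaryMasks` folder) and
#' assembles one session layout per fraction. Fractions missing a required
#' sidecar are returned flagged invalid with a reason rather than silently
#' dropped.
#'
#' @param root Directory containing fraction subfolders.
#' @param timestamp_source `"manifest"` (default) reads per-frame millisecond
#'   timestamps from the session's `frame_manifest.json`; `"filesystem"`
#'   falls back to file modification times (best effort, second-level
#'   resolution on some filesystems).
#' @return A list of `session_layout` objects. Each has fields `root`,
#'   `fraction_id`, `examcard_path`, `binarymasks_path`, `frame_files`
#'   (tibble: `path`, `byte_length`, `timestamp_ms`), `session_uid`, `valid`,
#'   `invalid_reason`.
#' @export
discover_session <- function(root, timestamp_source = c("manifest", "filesystem")) {
  timestamp_source <- match.arg(timestamp_source)
  if (!dir.exists(root)) stop("session root does not exist: ", root, call. = FALSE)
  fn <- session_file_names()
  subdirs <- list.dirs(root, recursive = FALSE)
  is_fraction <- vapply(subdirs, function(d) {
    length(list.files(d, pattern = "\\.bin$")) > 0 ||
      dir.exists(file.path(d, "ExamCards")) ||
      dir.exists(file.path(d, "BinaryMasks"))
  }, logical(1))
  lapply(subdirs[is_fraction], function(d) {
    fraction_id <- basename(d)
    examcard <- file.path(d, fn$examcard)
    masks <- file.path(d, fn$binarymasks)
    manifest <- file.path(d, fn$manifest)
    frames <- sort(list.files(d, pattern = "\\.bin$", full.names = TRUE))
    valid <- TRUE; reason <- NA_character_
    if (!file.exists(examcard)) { valid <- FALSE; reason <- "missing ExamCard geometry" }
    else if (!file.exists(masks)) { valid <- FALSE; reason <- "missing centroid" }
    else if (!length(frames)) { valid <- FALSE; reason <- "no frame files" }

    ts <- rep(NA_real_, length(frames))
    session_uid <- paste0("session-", fraction_id)
    if (timestamp_source == "manifest" && file.exists(manifest)) {
      man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
      if (!is.null(man$session_uid)) session_uid <- man$session_uid
      idx <- match(basename(frames), names(man$timestamps_ms))
      ts <- as.numeric(unlist(man$timestamps_ms, use.names = FALSE))[idx]
      if (length(frames) && anyNA(ts)) { valid <- FALSE; reason <- "manifest missing timestamps for some frames" }
    } else if (timestamp_source == "filesystem") {
      ts <- as.numeric(file.mtime(frames)) * 1000
    } else if (length(frames)) {
      valid <- FALSE; reason <- "missing frame manifest"
    }
    structure(list(
      root = d,
      fraction_id = fraction_id,
      examcard_path = examcard,
      binarymasks_path = masks,
      frame_files = tibble::tibble(
        path = frames,
        byte_length = if (length(frames)) file.size(frames) else numeric(0),
        timestamp_ms = if (length(frames)) ts else numeric(0)
      ),
      session_uid = session_uid,
      valid = valid,
      invalid_reason = reason
    ), class = "session_layout")
  })
}

#' @export
print.session_layout <- function(x, ...) {
  cat(sprintf("<session_layout> fraction '%s': %d frame file(s)%s\n",
              x$fraction_id, nrow(x$frame_files),
              if (x$valid) "" else paste0(" [INVALID: ", x$invalid_reason, "]")))
  invisible(x)
}

#' Time-order the frame files of a session
#'
#' Sorts frame records ascending by millisecond timestamp; ties are broken
#' deterministically by lexicographic file name (with a warning, since true
#' simultaneity is impossible at ~5 frames/s). Frames whose byte length is
#' too small for the session geometry are rejected with a warning. The result
#' is invariant under permutation of the input order.
#'
#' @param files Tibble with columns `path`, `byte_length`, `timestamp_ms`
#'   (as in `session_layout$frame_files`).
#' @param geometry Optional [acquisition_geometry()]; when given, undersized
#'   files are rejected.
#' @return The input tibble, filtered and sorted, with a 0-based
#'   `sequence_index` column.
#' @export
order_frames <- function(files, geometry = NULL) {
  stopifnot(is.data.frame(files))
  if (!is.null(geometry)) {
    need <- cine_header_length() +
      cine_bytes_per_pixel() * geometry$rows * geometry$columns
    bad <- files$byte_length < need
    if (any(bad)) {
      warning(sprintf("rejecting %d frame file(s) shorter than %d bytes: %s",
                      sum(bad), need,
                      paste(basename(files$path[bad]), collapse = ", ")),
              call. = FALSE)
      files <- files[!bad, , drop = FALSE]
    }
  }
  if (anyDuplicated(files$timestamp_ms)) {
    warning("duplicate frame timestamps; breaking ties by file name", call. = FALSE)
  }
  ord <- order(files$timestamp_ms, basename(files$path))
  out <- files[ord, , drop = FALSE]
  out$sequence_index <- seq_len(nrow(out)) - 1L
  tibble::as_tibble(out)
}
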