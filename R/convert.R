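#' Convert one cine session to MHA and/or DICOM
#'
#' Runs the full per-frame pipeline: decode the binary payload, classify the
#' imaging plane from the raw corner signature, apply the 22-pixel centering
#' shift, assign patient-space geometry from the session's target centroid,
#' and write the requested output formats. Frames whose plane cannot be
#' classified confidently are quarantined (recorded with their score in
#' `quarantine.json`), never written with a guessed label and never aborting
#' the session. Outputs are deterministic for a fixed session and seed.
#'
#' @param layout A `session_layout` from [discover_session()].
#' @param out_dir Output directory (created if needed).
#' @param format `"both"` (default), `"mha"` or `"dicom"`.
#' @param templates Plane templates for [classify_plane()].
#' @param threshold Classification confidence threshold.
#' @param seed Integer salt for deterministic DICOM UID generation.
#' @return A `conversion_report`: list with `fraction_id`, `n_input`,
#'   `n_converted`, `n_quarantined`, `counts` (tibble plane/n), `frames`
#'   (tibble with per-frame paths, plane, confidence, timestamp), and
#'   `out_dir`. `n_converted + n_quarantined == n_input` always holds.
#' @export
convert_session <- function(layout, out_dir, format = c("both", "mha", "dicom"),
                            templates = default_plane_templates(),
                            threshold = 0.8, seed = 0L) {
  format <- match.arg(format)
  stopifnot(inherits(layout, "session_layout"))
  if (!layout$valid) {
    stop("cannot convert invalid session '", layout$fraction_id, "': ",
         layout$invalid_reason, call. = FALSE)
  }
  geometry <- parse_examcard(layout$examcard_path)
  centroid <- parse_target_centroid(layout$binarymasks_path)
  ctx <- series_context(layout$session_uid, salt = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  frames <- order_frames(layout$frame_files, geometry)
  spacing <- c(geometry$pixel_spacing_row_mm, geometry$pixel_spacing_col_mm)

  rows <- vector("list", nrow(frames))
  instance_counter <- c(coronal = 0L, sagittal = 0L, axial = 0L)
  for (i in seq_len(nrow(frames))) {
    rec <- frames[i, ]
    px <- read_frame_pixels(rec$path, geometry)
    cls <- classify_plane(px, templates, threshold)
    row <- list(source = rec$path, sequence_index = rec$sequence_index,
                timestamp_ms = rec$timestamp_ms, plane = cls$plane,
                confidence = cls$confidence, mha = NA_character_,
                dicom = NA_character_)
    if (cls$plane == "unknown") {
      rows[[i]] <- row
      next
    }
    shifted <- apply_centering_shift(px)
    frame <- assign_geometry(shifted, cls$plane, spacing, centroid,
                             timestamp_ms = rec$timestamp_ms,
                             frame_uid = basename(rec$path))
    instance_counter[cls$plane] <- instance_counter[cls$plane] + 1L
    plane_dir <- file.path(out_dir, cls$plane)
    dir.create(plane_dir, showWarnings = FALSE)
    stem <- sprintf("%s_%05d", cls$plane, instance_counter[cls$plane])
    if (format %in% c("both", "mha")) {
      row$mha <- file.path(plane_dir, paste0(stem, ".mha"))
      write_mha(frame, row$mha)
    }
    if (format %in% c("both", "dicom")) {
      row$dicom <- file.path(plane_dir, paste0(stem, ".dcm"))
      write_dicom(frame, ctx, row$dicom,
                  instance_number = instance_counter[cls$plane])
    }
    rows[[i]] <- row
  }

  frame_tbl <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (!nrow(frame_tbl)) {
    frame_tbl <- tibble::tibble(source = character(), sequence_index = integer(),
                                timestamp_ms = numeric(), plane = character(),
                                confidence = numeric(), mha = character(),
                                dicom = character())
  }
  quarantined <- frame_tbl[frame_tbl$plane == "unknown", , drop = FALSE]
  jsonlite::write_json(
    list(fraction_id = layout$fraction_id,
         quarantined = quarantined[, c("source", "confidence")]),
    file.path(out_dir, "quarantine.json"), auto_unbox = TRUE, digits = NA)
  index <- frame_tbl[frame_tbl$plane != "unknown",
                     c("plane", "sequence_index", "timestamp_ms", "mha", "dicom")]
  jsonlite::write_json(
    list(session_uid = layout$session_uid, frames = index),
    file.path(out_dir, "series_index.json"), auto_unbox = TRUE, digits = NA)

  counts <- frame_tbl |>
    dplyr::filter(.data$plane != "unknown") |>
    dplyr::count(.data$plane)
  structure(list(
    fraction_id = layout$fraction_id,
    n_input = nrow(frame_tbl),
    n_converted = sum(frame_tbl$plane != "unknown"),
    n_quarantined = nrow(quarantined),
    counts = counts,
    frames = frame_tbl,
    out_dir = out_dir
  ), class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf("<conversion_report> fraction '%s': %d in, %d converted, %d quarantined\n",
              x$fraction_id, x$n_input, x$n_converted, x$n_quarantined))
  if (nrow(x$counts)) {
    cat(paste(sprintf("  %s: %d", x$counts$plane, x$counts$n), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Load a converted series back as geo_frames
#'
#' Reads the `series_index.json` written by [convert_session()] and loads
#' the MHA frames of one plane in acquisition order, re-attaching plane
#' labels and timestamps (which MetaImage itself does not carry).
#'
#' @param out_dir Conversion output directory.
#' @param plane Plane to load.
#' @return List of `geo_frame`s in time order.
#' @export
read_converted_series <- function(out_dir, plane) {
  idx <- jsonlite::read_json(file.path(out_dir, "series_index.json"),
                             simplifyVector = TRUE)
  fr <- idx$frames
  fr <- fr[fr$plane == plane, , drop = FALSE]
  fr <- fr[order(fr$timestamp_ms), , drop = FALSE]
  lapply(seq_len(nrow(fr)), function(i) {
    read_mha(fr$mha[i], plane = plane, timestamp_ms = fr$timestamp_ms[i])
  })
}
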