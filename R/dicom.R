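# Minimal DICOM Part-10 writer (explicit VR little endian). The package
# emits secondary MR image objects carrying the geometry tags downstream
# tools need: ImagePositionPatient, ImageOrientationPatient, PixelSpacing,
# FrameOfReferenceUID and millisecond-resolution AcquisitionTime. No
# installed R package writes DICOM, so the encoder lives here; tests
# round-trip every field through pydicom as an independent reader.

MR_IMAGE_STORAGE_UID <- "1.2.840.10008.5.1.4.1.1.4"
EXPLICIT_VR_LE_UID <- "1.2.840.10008.1.2.1"

# Deterministic positive integer hash of a string (FNV-1a style, 31-bit) so
# fixture UIDs are reproducible across runs and platforms.
string_hash31 <- function(s) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) h <- (bitwXor(as.integer(h), b) * 16777619) %% 2147483647
  as.integer(h)
}

#' Deterministic DICOM UID generation
#'
#' UIDs are derived from a configurable numeric root plus 31-bit hashes of
#' the context and item strings, so identical sessions yield identical UIDs
#' and a `salt` (seed) produces a fresh, still deterministic family.
#'
#' @param context,item Strings identifying the scope (e.g. session) and the
#'   object (e.g. frame index) of the UID.
#' @param salt Integer mixed into the hash (default 0).
#' @param root Numeric UID root prefix.
#' @return A valid UID string (digits and dots, < 64 chars).
#' @export
cine_uid <- function(context, item = "", salt = 0L,
                     root = "1.2.826.0.1.3680043.10.1437") {
  paste(root, string_hash31(paste0(context, "\r", salt)),
        string_hash31(paste0(item, "\n", salt)), sep = ".")
}

#' Series context for DICOM export
#'
#' Groups the identifiers shared by all frames of one converted session: one
#' FrameOfReferenceUID and StudyInstanceUID per session, one
#' SeriesInstanceUID per imaging plane, plus placeholder demographics
#' (anonymized by default; real demographics are out of scope).
#'
#' @param session_uid Session identifier string.
#' @param salt Integer UID salt (seed) for reproducible UID families.
#' @param patient_name,patient_id Placeholder demographics.
#' @return A `series_context` list.
#' @export
series_context <- function(session_uid, salt = 0L,
                           patient_name = "PHANTOM^QA", patient_id = "ANON") {
  planes <- c("coronal", "sagittal", "axial")
  structure(list(
    session_uid = session_uid,
    study_uid = cine_uid(session_uid, "study", salt),
    frame_of_reference_uid = cine_uid(session_uid, "for", salt),
    series_uids = stats::setNames(
      vapply(planes, function(p) cine_uid(session_uid, paste0("series-", p), salt), ""),
      planes),
    patient_name = patient_name,
    patient_id = patient_id,
    salt = as.integer(salt)
  ), class = "series_context")
}

# --- element encoders (explicit VR little endian) ---------------------------

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# Short-form element: tag, VR, 16-bit length, value.
dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L) stop("DICOM value length must be even")
  if (vr %in% c("OB", "OW", "UN", "SQ", "UT")) {
    c(dcm_u16(group), dcm_u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      dcm_u32(length(value_raw)), value_raw)
  } else {
    c(dcm_u16(group), dcm_u16(elem), charToRaw(vr),
      dcm_u16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) {
  v <- charToRaw(s)
  if (length(v) %% 2L) v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  dcm_element(group, elem, vr, v)
}

dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", dcm_u16(x))

dcm_ds <- function(group, elem, xs) {
  dcm_str(group, elem, "DS",
          paste(formatC(xs, format = "g", digits = 10), collapse = "\\"))
}

# HHMMSS.FFF from milliseconds since epoch (UTC).
dicom_time_string <- function(timestamp_ms) {
  secs <- floor(timestamp_ms / 1000)
  ms <- round(timestamp_ms - secs * 1000)
  t <- as.POSIXct(secs, origin = "1970-01-01", tz = "UTC")
  sprintf("%s.%03d", format(t, "%H%M%S"), as.integer(ms))
}

dicom_date_string <- function(timestamp_ms) {
  format(as.POSIXct(floor(timestamp_ms / 1000), origin = "1970-01-01", tz = "UTC"),
         "%Y%m%d")
}

#' Write a frame as a DICOM secondary MR image
#'
#' Emits an explicit-VR little-endian Part-10 file (MR Image Storage SOP
#' class, derived/secondary image type) with Rows/Columns, PixelSpacing,
#' ImagePositionPatient = frame origin, ImageOrientationPatient = the row
#' and column direction cosines, per-plane SeriesInstanceUID, per-session
#' FrameOfReferenceUID, and AcquisitionTime carrying fractional seconds at
#' millisecond resolution.
#'
#' @param frame A `geo_frame` with a known plane and timestamp.
#' @param ctx A [series_context()].
#' @param path Output file path.
#' @param instance_number 1-based instance number within the series.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(frame, ctx, path, instance_number = 1L) {
  stopifnot(inherits(frame, "geo_frame"), inherits(ctx, "series_context"))
  if (!frame$plane %in% names(ctx$series_uids)) {
    stop("frame plane '", frame$plane, "' has no series in this context", call. = FALSE)
  }
  ts <- if (is.finite(frame$timestamp_ms)) frame$timestamp_ms else 0
  sop_uid <- cine_uid(ctx$session_uid,
                      paste0("sop-", frame$plane, "-", instance_number), ctx$salt)
  series_uid <- ctx$series_uids[[frame$plane]]
  series_number <- match(frame$plane, names(ctx$series_uids))

  body <- c(
    dcm_str(0x0008, 0x0008, "CS", "DERIVED\\SECONDARY"),
    dcm_str(0x0008, 0x0016, "UI", MR_IMAGE_STORAGE_UID),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0020, "DA", dicom_date_string(ts)),
    dcm_str(0x0008, 0x0030, "TM", dicom_time_string(ts)),
    dcm_str(0x0008, 0x0032, "TM", dicom_time_string(ts)),
    dcm_str(0x0008, 0x0060, "CS", "MR"),
    dcm_str(0x0008, 0x0070, "LO", "cinemr"),
    dcm_str(0x0008, 0x103E, "LO", paste("cine", frame$plane)),
    dcm_str(0x0010, 0x0010, "PN", ctx$patient_name),
    dcm_str(0x0010, 0x0020, "LO", ctx$patient_id),
    dcm_str(0x0020, 0x000D, "UI", ctx$study_uid),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0010, "SH", "1"),
    dcm_str(0x0020, 0x0011, "IS", as.character(series_number)),
    dcm_str(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_ds(0x0020, 0x0032, frame$origin),
    dcm_ds(0x0020, 0x0037, c(frame$row_dir, frame$col_dir)),
    dcm_str(0x0020, 0x0052, "UI", ctx$frame_of_reference_uid),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, nrow(frame$pixels)),
    dcm_us(0x0028, 0x0011, ncol(frame$pixels)),
    dcm_ds(0x0028, 0x0030, c(frame$spacing[["row"]], frame$spacing[["col"]])),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 16L),
    dcm_us(0x0028, 0x0102, 15L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_element(0x7FE0, 0x0010, "OW", encode_frame_payload(frame$pixels))
  )

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", MR_IMAGE_STORAGE_UID),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", EXPLICIT_VR_LE_UID),
    dcm_str(0x0002, 0x0012, "UI", cine_uid("cinemr-implementation", "", 0L)),
    dcm_str(0x0002, 0x0013, "SH", "cinemr")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_u32(length(meta))), meta)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}
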