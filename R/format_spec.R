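#' The cine frame binary dialect
#'
#' Every on-disk cine frame is a single file consisting of an opaque header of
#' exactly 4,084 bytes followed by the pixel payload: `rows * columns`
#' little-endian unsigned 16-bit integers in row-major order (all columns of
#' row 1, then row 2, ...). The header carries no information used by this
#' package; only its length matters. Because no sample of the real vendor
#' format is publicly available, the fixture generator
#' ([generate_session()]) is the normative counterpart of the reader: both
#' sides of the dialect are defined by the constants documented here.
#'
#' `cine_header_sentinel()` returns the fixed repeating byte pattern the
#' fixture generator writes into the header. It is chosen so that an
#' off-by-one header/payload misalignment moves recognizable bytes into the
#' decoded pixels and fails loudly in tests.
#'
#' @return `cine_header_length()` returns the integer 4084;
#'   `cine_header_sentinel()` a raw vector of that length.
#' @export
cine_header_length <- function() 4084L

#' @rdname cine_header_length
#' @export
cine_header_sentinel <- function() {
  # 0xC1 0x7E ("cine") repeated; 4084 is even so the pattern tiles exactly
  rep(as.raw(c(0xC1, 0x7E)), length.out = cine_header_length())
}

# Bytes per pixel of the unsigned 16-bit payload (hard-coded; no autodetection)
cine_bytes_per_pixel <- function() 2L

# Number of pixels the centering shift moves image content along the
# negative column direction.
#' Centering shift width in pixels
#'
#' Decoded frames are offset by a fixed 22 pixels relative to their correct
#' centered position; [apply_centering_shift()] removes the offset.
#'
#' @return The integer 22.
#' @export
centering_shift_pixels <- function() 22L

#' File names used inside a session fraction folder
#'
#' The on-disk layout emulated (and written) by the package is one directory
#' per treatment fraction containing: binary frame files (`*.bin`), an
#' `ExamCards/` folder with the acquisition-geometry JSON, a `BinaryMasks/`
#' folder with the target-centroid JSON, a frame manifest carrying per-file
#' millisecond timestamps, and (fixtures only) a machine-readable
#' ground-truth JSON.
#'
#' @return A named list of relative paths.
#' @export
session_file_names <- function() {
  list(
    examcard     = file.path("ExamCards", "MotionMonitoring2DImages.ExamCardInfo.json"),
    binarymasks  = file.path("BinaryMasks", "target_structure.json"),
    manifest     = "frame_manifest.json",
    ground_truth = "ground_truth.json"
  )
}
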