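#' Write a frame as a MetaImage (.mha) file
#'
#' Serializes a `geo_frame` as a single-slice 3D MetaImage so the full 3D
#' placement (offset and direction cosines) survives: `NDims = 3`,
#' `DimSize = cols rows 1`, `Offset` = the frame origin, `TransformMatrix`
#' rows = column-axis, row-axis and normal direction cosines,
#' `ElementSpacing` = (col, row, thickness) mm, `ElementType = MET_USHORT`,
#' raw little-endian pixel data appended locally. Any standard MetaImage
#' reader (ITK, SimpleITK) recovers pixels and geometry exactly.
#'
#' @param frame A `geo_frame`.
#' @param path Output file path (conventionally `.mha`).
#' @param slice_thickness_mm Third spacing component (default 1).
#' @return `path`, invisibly.
#' @export
write_mha <- function(frame, path, slice_thickness_mm = 1) {
  stopifnot(inherits(frame, "geo_frame"))
  num <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", num(c(frame$row_dir, frame$col_dir, frame$normal))),
    paste("Offset =", num(frame$origin)),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =",
          num(c(frame$spacing[["col"]], frame$spacing[["row"]], slice_thickness_mm))),
    paste("DimSize =", paste(c(ncol(frame$pixels), nrow(frame$pixels), 1L), collapse = " ")),
    "ElementType = MET_USHORT",
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  # x (column index) fastest: identical byte order to the row-major payload
  writeBin(encode_frame_payload(frame$pixels), con)
  invisible(path)
}

#' Read a single-slice MetaImage written by [write_mha()]
#'
#' A minimal MetaImage reader for the dialect this package emits (local,
#' uncompressed, MET_USHORT, single slice). Used for round trips and for
#' feeding converted series into the motion-QA routines.
#'
#' @param path Path to the `.mha` file.
#' @param plane Optional plane label to attach (MetaImage itself does not
#'   carry one); defaults to `"unknown"`.
#' @param timestamp_ms Optional timestamp to attach.
#' @return A `geo_frame`.
#' @export
read_mha <- function(path, plane = "unknown", timestamp_ms = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unexpected end of MetaImage header in ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(fields$ElementDataFile, "LOCAL"))
    stop("only local-data MetaImage files are supported", call. = FALSE)
  if (!identical(fields$ElementType, "MET_USHORT"))
    stop("only MET_USHORT MetaImage files are supported, got ",
         fields$ElementType, call. = FALSE)
  nums <- function(key) as.numeric(strsplit(fields[[key]], "\\s+")[[1]])
  dims <- nums("DimSize")
  cols <- dims[1]; rows <- dims[2]
  tm <- nums("TransformMatrix")
  sp <- nums("ElementSpacing")
  vals <- readBin(con, integer(), n = rows * cols, size = 2L, signed = FALSE,
                  endian = "little")
  structure(list(
    pixels = matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
    plane = plane,
    spacing = c(row = sp[2], col = sp[1]),
    origin = nums("Offset"),
    row_dir = tm[1:3],
    col_dir = tm[4:6],
    normal = tm[7:9],
    timestamp_ms = as.numeric(timestamp_ms),
    frame_uid = NULL
  ), class = "geo_frame")
}
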