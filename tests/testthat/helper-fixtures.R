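# Shared fixture builders. All sessions are generated in tempdirs at test
# time; nothing binary ships with the package.

fixture_geometry <- function() acquisition_geometry(256, 256, 256, 256)

# Write a raw frame file by hand: sentinel header + row-major LE uint16.
write_raw_frame <- function(path, pixels, header = cine_header_sentinel()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  v <- as.integer(t(pixels))
  writeBin(v, con, size = 2L, endian = "little")
  invisible(path)
}

# A quick single-fraction session in a fresh tempdir.
make_session <- function(..., root = tempfile("sess-")) {
  layout <- generate_session(root, ...)
  list(root = root, layout = layout)
}

# Run a short python program and parse the JSON object it prints on the
# last line. Used to cross-check MHA/DICOM files with SimpleITK/pydicom as
# independent readers.
py_json <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- system2("python", f, stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python oracle failed:\n", paste(out, collapse = "\n"))
  }
  jsonlite::fromJSON(out[length(out)])
}

# Random frame with a stamped plane glyph on a noisy background; cheap input
# for classification tests (no phantom render needed).
glyph_frame <- function(plane, scale = 1, size = 64L) {
  px <- matrix(round(runif(size * size) * 120 * scale), size, size)
  g <- plane_glyph(plane)
  n <- nrow(g)
  px[seq_len(n), (size - n + 1L):size] <- round((50 + g * 850) * scale)
  storage.mode(px) <- "integer"
  px
}
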