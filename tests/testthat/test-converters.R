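make_random_frame <- function(plane = "sagittal", centroid = c(10, -20, 5),
                              rows = 64, cols = 48, ts = 1.7552e12 + 123456) {
  set.seed(17)
  px <- matrix(sample(0:65535, rows * cols, replace = TRUE), rows, cols)
  assign_geometry(px, plane, c(2, 1.5), centroid, timestamp_ms = ts)
}

test_that("MHA files round-trip pixels and 3D placement exactly", {
  f <- make_random_frame()
  path <- tempfile(fileext = ".mha")
  write_mha(f, path)
  back <- read_mha(path, plane = f$plane)
  expect_identical(back$pixels, f$pixels)
  expect_equal(back$origin, f$origin)
  expect_equal(back$spacing, f$spacing)
  expect_equal(back$row_dir, f$row_dir)
  expect_equal(back$col_dir, f$col_dir)

  # zero 4x4 frame centred at the world origin
  z <- assign_geometry(matrix(0L, 4, 4), "axial", c(1, 1), c(0, 0, 0))
  zp <- tempfile(fileext = ".mha")
  write_mha(z, zp)
  zb <- read_mha(zp)
  expect_equal(pixel_to_world(zb, 1.5, 1.5), c(0, 0, 0))

  # timestamps are not part of the MHA payload: byte-identical files
  f1 <- make_random_frame(ts = 1); f2 <- make_random_frame(ts = 2)
  p1 <- tempfile(fileext = ".mha"); p2 <- tempfile(fileext = ".mha")
  write_mha(f1, p1); write_mha(f2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("an independent MetaImage reader recovers geometry within 1e-6", {
  f <- make_random_frame()
  path <- tempfile(fileext = ".mha")
  write_mha(f, path)
  res <- py_json(sprintf('
import SimpleITK as sitk, json
im = sitk.ReadImage(%s)
a = sitk.GetArrayFromImage(im)
print(json.dumps({"size": list(im.GetSize()), "spacing": list(im.GetSpacing()),
  "origin": list(im.GetOrigin()), "direction": list(im.GetDirection()),
  "sum": int(a.sum()), "dtype": str(a.dtype)}))', deparse(path)))
  expect_equal(res$size, c(ncol(f$pixels), nrow(f$pixels), 1))
  expect_lt(max(abs(res$origin - f$origin)), 1e-6)
  expect_lt(max(abs(res$spacing[1:2] -
                      c(f$spacing[["col"]], f$spacing[["row"]]))), 1e-6)
  dir <- matrix(res$direction, 3, 3, byrow = TRUE)
  expect_lt(max(abs(dir[, 1] - f$row_dir)), 1e-6)
  expect_lt(max(abs(dir[, 2] - f$col_dir)), 1e-6)
  expect_identical(res$dtype, "uint16")
  expect_identical(res$sum, sum(f$pixels))
})

test_that("an independent DICOM reader recovers geometry, pixels and ms timing", {
  ctx <- series_context("dicom-oracle", salt = 5)
  f <- make_random_frame()
  path <- tempfile(fileext = ".dcm")
  write_dicom(f, ctx, path, instance_number = 3)
  res <- py_json(sprintf('
import pydicom, numpy as np, json
ds = pydicom.dcmread(%s)
print(json.dumps({"ipp": [float(v) for v in ds.ImagePositionPatient],
  "iop": [float(v) for v in ds.ImageOrientationPatient],
  "ps": [float(v) for v in ds.PixelSpacing],
  "rows": int(ds.Rows), "cols": int(ds.Columns),
  "modality": str(ds.Modality), "sop": str(ds.SOPClassUID),
  "series": str(ds.SeriesInstanceUID), "for_uid": str(ds.FrameOfReferenceUID),
  "acq": str(ds.AcquisitionTime), "inst": int(ds.InstanceNumber),
  "sum": int(ds.pixel_array.astype(np.int64).sum())}))', deparse(path)))
  expect_lt(max(abs(res$ipp - f$origin)), 1e-6)
  expect_lt(max(abs(res$iop - c(f$row_dir, f$col_dir))), 1e-6)
  expect_equal(res$ps, c(f$spacing[["row"]], f$spacing[["col"]]))
  expect_equal(c(res$rows, res$cols), dim(f$pixels))
  expect_identical(res$modality, "MR")
  expect_identical(res$sop, "1.2.840.10008.5.1.4.1.1.4")
  expect_identical(res$series, unname(ctx$series_uids[["sagittal"]]))
  expect_identical(res$for_uid, ctx$frame_of_reference_uid)
  expect_identical(res$sum, sum(f$pixels))
  expect_equal(res$inst, 3)
  # fractional seconds carry the milliseconds
  expect_match(res$acq, "\\.456$")

  # axial orientation is the DICOM identity row/column pair
  fa <- make_random_frame(plane = "axial")
  pa <- tempfile(fileext = ".dcm")
  write_dicom(fa, ctx, pa)
  resa <- py_json(sprintf('
import pydicom, json
ds = pydicom.dcmread(%s)
print(json.dumps([float(v) for v in ds.ImageOrientationPatient]))', deparse(pa)))
  expect_equal(resa, c(1, 0, 0, 0, 1, 0))
})

test_that("converted DICOM series have strictly increasing 0.2 s acquisition times", {
  s <- make_session(program = motion_program("static", n_frames = 8L),
                    planes = "coronal", seed = 3)
  rep <- convert_session(s$layout, file.path(s$root, "out"), format = "dicom")
  files <- sort(list.files(file.path(s$root, "out", "coronal"),
                           full.names = TRUE, pattern = "\\.dcm$"))
  res <- py_json(sprintf('
import pydicom, json
fs = %s
ts = []
for f in fs:
    t = pydicom.dcmread(f).AcquisitionTime
    h, m, s = float(t[0:2]), float(t[2:4]), float(t[4:])
    ts.append(h*3600 + m*60 + s)
print(json.dumps(ts))',
    paste0("[", paste(sprintf("'%s'", files), collapse = ","), "]")))
  expect_equal(diff(res), rep(0.2, 7), tolerance = 1e-9)
})

test_that("session conversion conserves counts and quarantines corrupt frames", {
  s <- make_session(program = motion_program("static", n_frames = 60L),
                    planes = c("coronal", "sagittal", "axial"), seed = 4)
  rep <- convert_session(s$layout, file.path(s$root, "out"))
  expect_equal(rep$n_input, 60)
  expect_equal(rep$n_quarantined, 0)
  expect_equal(sort(rep$counts$plane), c("axial", "coronal", "sagittal"))
  expect_equal(rep$counts$n, rep(20L, 3))
  expect_equal(rep$n_converted + rep$n_quarantined, rep$n_input)

  # corrupt one frame's corner signature: quarantined, session not aborted
  geometry <- parse_examcard(s$layout$examcard_path)
  victim <- s$layout$frame_files$path[1]
  px <- read_frame_pixels(victim, geometry)
  px[1:32, (ncol(px) - 31):ncol(px)] <- 0L
  write_raw_frame(victim, px)
  rep2 <- convert_session(s$layout, file.path(s$root, "out2"))
  expect_equal(rep2$n_quarantined, 1)
  expect_equal(rep2$n_converted, 59)
  expect_equal(rep2$n_converted + rep2$n_quarantined, rep2$n_input)
  q <- jsonlite::read_json(file.path(s$root, "out2", "quarantine.json"),
                           simplifyVector = TRUE)
  expect_equal(basename(q$quarantined$source), basename(victim))

  # empty (frame-less) session: all-zero report, no error
  empty <- s$layout
  empty$frame_files <- empty$frame_files[0, ]
  rep3 <- convert_session(empty, file.path(s$root, "out3"))
  expect_equal(rep3$n_input, 0)
  expect_equal(rep3$n_converted, 0)
  expect_equal(rep3$n_quarantined, 0)

  # invalid layouts abort with the recorded reason
  bad <- s$layout
  bad$valid <- FALSE; bad$invalid_reason <- "missing centroid"
  expect_error(convert_session(bad, tempfile()), "missing centroid")
})

test_that("re-running a conversion reproduces value-identical outputs", {
  s <- make_session(program = motion_program("static", n_frames = 6L),
                    planes = c("coronal", "axial"), seed = 12)
  r1 <- convert_session(s$layout, file.path(s$root, "o1"), seed = 7)
  r2 <- convert_session(s$layout, file.path(s$root, "o2"), seed = 7)
  f1 <- list.files(file.path(s$root, "o1"), recursive = TRUE, full.names = TRUE,
                   pattern = "\\.(mha|dcm)$")
  f2 <- list.files(file.path(s$root, "o2"), recursive = TRUE, full.names = TRUE,
                   pattern = "\\.(mha|dcm)$")
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
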