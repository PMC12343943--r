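#' Ground-truth geometry of the synthetic QA phantom
#'
#' Describes the rendered motion-management phantom: a rectangular body shell
#' whose interior measures `body_inner_length_mm` along the horizontal image
#' axis, a bright cylindrical rod (the moving target) of
#' `rod_inner_diameter_mm`, and a spine-mimicking block with a smooth
#' sinusoidal vertebra/disc intensity texture used by the registration
#' scenarios. Intensity levels are in arbitrary units on the 16-bit scale.
#'
#' @param rod_inner_diameter_mm Rod (target) diameter; default 58.5.
#' @param body_inner_length_mm Interior body length; default 150.1.
#' @param body_inner_width_mm Interior body width; default 110.
#' @param wall_mm Body wall thickness; default 10.
#' @param spine_center_mm,spine_half_mm Spine-block center `(u, v)` and half
#'   sizes `(u, v)` in phantom coordinates.
#' @param levels Named intensity levels (`background`, `wall`, `interior`,
#'   `rod`, `spine_lo`, `spine_hi`).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(rod_inner_diameter_mm = 58.5,
                         body_inner_length_mm = 150.1,
                         body_inner_width_mm = 110,
                         wall_mm = 10,
                         spine_center_mm = c(0, 42),
                         spine_half_mm = c(15, 12),
                         levels = c(background = 60, wall = 400, interior = 120,
                                    rod = 900, spine_lo = 300, spine_hi = 800)) {
  stopifnot(rod_inner_diameter_mm > 0, body_inner_length_mm > 0,
            body_inner_width_mm > 0, wall_mm > 0,
            rod_inner_diameter_mm < body_inner_length_mm,
            rod_inner_diameter_mm < body_inner_width_mm)
  structure(list(
    rod_inner_diameter_mm = rod_inner_diameter_mm,
    body_inner_length_mm = body_inner_length_mm,
    body_inner_width_mm = body_inner_width_mm,
    wall_mm = wall_mm,
    spine_center_mm = spine_center_mm,
    spine_half_mm = spine_half_mm,
    levels = levels
  ), class = "phantom_spec")
}

#' Programmed phantom motion for a fixture session
#'
#' `"static"` keeps everything still; `"periodic"` moves the rod along the
#' horizontal in-plane axis with the given amplitude (peak displacement from
#' rest) and period, emulating respiratory target motion; `"shifted"`
#' translates the whole phantom (body, spine and rod) by a constant offset,
#' emulating a couch shift.
#'
#' @param kind `"static"`, `"periodic"` or `"shifted"`.
#' @param amplitude_mm Peak displacement from rest (periodic).
#' @param period_s Motion period in seconds; default 4.
#' @param shift_mm Constant whole-phantom shift (shifted).
#' @param frame_interval_s Frame interval in seconds; default 0.2 (~5 frames/s).
#' @param n_frames Number of frames to generate.
#' @param waveform `"sine"` (default) or `"triangle"`.
#' @param noise_sd Additive Gaussian intensity noise, as a fraction of the
#'   rod/background contrast; default 0 (exact renders).
#' @param intensity_scale Session-wide multiplicative intensity factor.
#' @return A `motion_program` list.
#' @export
motion_program <- function(kind = c("static", "periodic", "shifted"),
                           amplitude_mm = 0, period_s = 4, shift_mm = 0,
                           frame_interval_s = 0.2, n_frames = 50L,
                           waveform = c("sine", "triangle"),
                           noise_sd = 0, intensity_scale = 1) {
  kind <- match.arg(kind); waveform <- match.arg(waveform)
  stopifnot(frame_interval_s > 0, amplitude_mm >= 0, shift_mm >= 0,
            n_frames >= 1, intensity_scale > 0, noise_sd >= 0)
  structure(list(kind = kind, amplitude_mm = amplitude_mm, period_s = period_s,
                 shift_mm = shift_mm, frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames), waveform = waveform,
                 noise_sd = noise_sd, intensity_scale = intensity_scale),
            class = "motion_program")
}

# Rod displacement (u, v) in mm at time t for a program.
program_displacement <- function(program, t_s) {
  if (program$kind != "periodic") return(c(0, 0))
  ph <- 2 * pi * t_s / program$period_s
  u <- switch(program$waveform,
    sine = program$amplitude_mm * sin(ph),
    triangle = program$amplitude_mm * (2 / pi) * asin(sin(ph))
  )
  c(u, 0)
}

# Linear-ramp area coverage from a signed distance (mm, positive inside),
# with the transition spread over one pixel.
edge_coverage <- function(d, px_mm) pmin(1, pmax(0, 0.5 + d / px_mm))

#' Render one synthetic phantom frame
#'
#' Produces the raw (pre-conversion) pixel matrix of a cine frame: the
#' anti-aliased phantom scene, offset 22 pixels along the positive column
#' direction so that the converter's centering shift lands it centered, with
#' the plane's corner signature stamped top-right. Deterministic for fixed
#' inputs; optional seeded Gaussian noise is added before the glyph stamp.
#'
#' @param spec A [phantom_spec()].
#' @param plane Imaging plane whose glyph to stamp.
#' @param displacement_mm Rod (target) in-plane displacement `c(u, v)` mm.
#' @param geometry An [acquisition_geometry()].
#' @param body_offset_mm Whole-phantom in-plane offset `c(u, v)` mm
#'   (couch-shift scenarios).
#' @param intensity_scale Session-wide intensity factor.
#' @param noise_sd Gaussian noise sd as a fraction of rod/background
#'   contrast (uses the current RNG state).
#' @param stamp_glyph Stamp the plane's corner signature (default TRUE).
#' @return Integer pixel matrix (`rows x columns`).
#' @export
render_phantom_frame <- function(spec, plane, displacement_mm, geometry,
                                 body_offset_mm = c(0, 0), intensity_scale = 1,
                                 noise_sd = 0, stamp_glyph = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(geometry, "acquisition_geometry"))
  rows <- geometry$rows; cols <- geometry$columns
  sp_r <- geometry$pixel_spacing_row_mm; sp_c <- geometry$pixel_spacing_col_mm
  px <- (sp_r + sp_c) / 2
  lv <- spec$levels

  # in-plane mm coordinates of pixel centers, phantom-centered after the
  # 22-pixel inverse offset
  u <- (0:(cols - 1) - (cols - 1) / 2 - centering_shift_pixels()) * sp_c
  v <- (0:(rows - 1) - (rows - 1) / 2) * sp_r
  U <- matrix(u, rows, cols, byrow = TRUE)
  V <- matrix(v, rows, cols)

  half_len <- spec$body_inner_length_mm / 2
  half_wid <- spec$body_inner_width_mm / 2
  out_hl <- half_len + spec$wall_mm
  out_hw <- half_wid + spec$wall_mm
  bu <- body_offset_mm[1]; bv <- body_offset_mm[2]
  if (bu + out_hl > max(u) || bu - out_hl < min(u) ||
      bv + out_hw > max(v) || bv - out_hw < min(v)) {
    stop("phantom exceeds the field of view for this geometry", call. = FALSE)
  }

  img <- matrix(lv[["background"]], rows, cols)
  blend <- function(img, a, level) img * (1 - a) + level * a

  a_outer <- edge_coverage(pmin(out_hl - abs(U - bu), out_hw - abs(V - bv)), px)
  img <- blend(img, a_outer, lv[["wall"]])
  a_inner <- edge_coverage(pmin(half_len - abs(U - bu), half_wid - abs(V - bv)), px)
  img <- blend(img, a_inner, lv[["interior"]])

  sc <- spec$spine_center_mm; sh <- spec$spine_half_mm
  a_spine <- edge_coverage(pmin(sh[1] - abs(U - bu - sc[1]),
                                sh[2] - abs(V - bv - sc[2])), px)
  spine_level <- lv[["spine_lo"]] + (lv[["spine_hi"]] - lv[["spine_lo"]]) *
    0.5 * (1 + sin(2 * pi * (V - bv - sc[2]) / 8))
  img <- img * (1 - a_spine) + spine_level * a_spine

  ru <- bu + displacement_mm[1]; rv <- bv + displacement_mm[2]
  a_rod <- edge_coverage(spec$rod_inner_diameter_mm / 2 -
                           sqrt((U - ru)^2 + (V - rv)^2), px)
  img <- blend(img, a_rod, lv[["rod"]])

  img <- img * intensity_scale
  if (noise_sd > 0) {
    contrast <- (lv[["rod"]] - lv[["background"]]) * intensity_scale
    img <- img + stats::rnorm(length(img), sd = noise_sd * contrast)
  }
  if (stamp_glyph) {
    g <- plane_glyph(plane)
    n <- nrow(g)
    img[seq_len(n), (cols - n + 1L):cols] <-
      (50 + g * 850) * intensity_scale
  }
  m <- round(pmin(pmax(img, 0), 65535))
  storage.mode(m) <- "integer"
  m
}

#' Write a complete synthetic cine session to disk
#'
#' Emits a fraction folder in the documented on-disk dialect: binary frame
#' files (4,084-byte sentinel header + little-endian uint16 row-major
#' payload) under permuted file names (so disk order differs from time
#' order), the ExamCard geometry JSON, the BinaryMasks centroid JSON, a
#' frame manifest with per-file millisecond timestamps at the programmed
#' interval interleaved across the requested planes, and a machine-readable
#' ground-truth JSON (true per-frame displacements, planes and timestamps).
#' Identical `(spec, program, geometry, seed)` produce byte-identical trees.
#'
#' @param out_dir Session root directory (the fraction folder is created
#'   inside it).
#' @param spec A [phantom_spec()].
#' @param program A [motion_program()].
#' @param geometry An [acquisition_geometry()].
#' @param planes Character vector of planes to interleave.
#' @param centroid Target centroid `c(x, y, z)` mm (LPS).
#' @param seed Integer RNG seed (noise, name permutation, timestamp base).
#' @param fraction_id Fraction folder name.
#' @return The discovered `session_layout` for the written fraction.
#' @export
generate_session <- function(out_dir, spec = phantom_spec(),
                             program = motion_program("static"),
                             geometry = acquisition_geometry(256, 256, 256, 256),
                             planes = "coronal", centroid = c(0, 0, 0),
                             seed = 1L, fraction_id = "fraction_001") {
  stopifnot(all(planes %in% c("coronal", "sagittal", "axial")))
  froot <- file.path(out_dir, fraction_id)
  fn <- session_file_names()
  dir.create(file.path(froot, "ExamCards"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(froot, "BinaryMasks"), recursive = TRUE, showWarnings = FALSE)

  jsonlite::write_json(list(
    Rows = geometry$rows, Columns = geometry$columns,
    SliceDimensionXInmm = geometry$slice_dim_x_mm,
    SliceDimensionYInmm = geometry$slice_dim_y_mm
  ), file.path(froot, fn$examcard), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(list(
    structure = "target", coordinate_system = "LPS",
    centroid_mm = list(x = centroid[1], y = centroid[2], z = centroid[3])
  ), file.path(froot, fn$binarymasks), auto_unbox = TRUE, digits = NA)

  n <- program$n_frames
  body_off <- if (program$kind == "shifted") c(program$shift_mm, 0) else c(0, 0)

  with_preserved_seed(seed, {
    t0 <- 1.7552e12 + (seed %% 997) * 13
    name_perm <- sample.int(n)
    filenames <- sprintf("cine_%05d.bin", name_perm)
    timestamps <- t0 + (0:(n - 1)) * round(program$frame_interval_s * 1000)
    truth <- vector("list", n)
    for (k in 0:(n - 1)) {
      plane <- planes[(k %% length(planes)) + 1L]
      disp <- program_displacement(program, k * program$frame_interval_s)
      px <- render_phantom_frame(spec, plane, disp, geometry,
                                 body_offset_mm = body_off,
                                 intensity_scale = program$intensity_scale,
                                 noise_sd = program$noise_sd)
      con <- file(file.path(froot, filenames[k + 1L]), "wb")
      writeBin(cine_header_sentinel(), con)
      writeBin(encode_frame_payload(px), con)
      close(con)
      truth[[k + 1L]] <- list(file = filenames[k + 1L], plane = plane,
                              timestamp_ms = timestamps[k + 1L],
                              rod_u_mm = disp[1] + body_off[1],
                              rod_v_mm = disp[2] + body_off[2],
                              body_u_mm = body_off[1], body_v_mm = body_off[2])
    }
    session_uid <- sprintf("cine-%s-%d", fraction_id, seed)
    jsonlite::write_json(list(
      session_uid = session_uid,
      timestamps_ms = stats::setNames(as.list(timestamps), filenames)
    ), file.path(froot, fn$manifest), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      program = unclass(program), planes = planes,
      centroid_mm = centroid, seed = seed,
      rod_inner_diameter_mm = spec$rod_inner_diameter_mm,
      body_inner_length_mm = spec$body_inner_length_mm,
      frames = truth
    ), file.path(froot, fn$ground_truth), auto_unbox = TRUE, digits = NA)
  })

  layouts <- discover_session(out_dir)
  layouts[[which(vapply(layouts, function(l) l$fraction_id, "") == fraction_id)]]
}
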