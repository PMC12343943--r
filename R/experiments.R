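# End-to-end verification experiments on synthetic sessions. Each wrapper
# generates a fixture session, pushes it through the full conversion
# pipeline, and measures the result with the motion-QA routines — the same
# workflow a physicist would run against scanner data.

# Default fixture geometry: 256 x 256 pixels at 1 mm spacing.
default_fixture_geometry <- function() acquisition_geometry(256, 256, 256, 256)

# ROI (1-based r0, r1, c0, c1) covering the rod through its full programmed
# excursion (<= 20 mm) at the default geometry, excluding the spine block.
rod_roi <- function() c(96L, 161L, 74L, 183L)

# ROI around the spine block (the vertebral surrogate) with room for shifts
# up to ~6 mm.
spine_roi <- function() c(156L, 186L, 100L, 158L)

#' Measure the phantom dimensions on a converted frame
#'
#' Generates a static axial fixture session at the phantom's documented
#' ground-truth geometry, converts it with the full pipeline, and measures
#' the rod inner diameter and the body inner length on the converted frame
#' with the half-maximum edge-profile routine.
#'
#' @param seed Integer seed for the fixture session.
#' @param geometry Acquisition geometry (default 256 x 256 at 1 mm).
#' @param spec A [phantom_spec()].
#' @return Tibble with columns `item`, `measured_mm`, `truth_mm`, `error_mm`.
#' @export
measure_phantom_dimensions <- function(seed = 1L,
                                       geometry = default_fixture_geometry(),
                                       spec = phantom_spec()) {
  work <- tempfile("dimqa-")
  on.exit(unlink(work, recursive = TRUE))
  layout <- generate_session(work, spec = spec,
                             program = motion_program("static", n_frames = 2L),
                             geometry = geometry, planes = "axial",
                             centroid = c(0, 0, 0), seed = seed)
  rep <- convert_session(layout, file.path(work, "out"), format = "mha")
  frame <- read_converted_series(rep$out_dir, "axial")[[1]]

  # axial: world x spans columns (u), world y spans rows (v); centroid (0,0,0)
  rod <- measure_distance(frame, c(-45, 0, 0), c(45, 0, 0))
  body <- measure_distance(frame, c(-spec$body_inner_length_mm / 2 - 5, -40, 0),
                           c(spec$body_inner_length_mm / 2 + 5, -40, 0))
  tibble::tibble(
    item = c("rod_inner_diameter", "body_inner_length"),
    measured_mm = c(rod, body),
    truth_mm = c(spec$rod_inner_diameter_mm, spec$body_inner_length_mm),
    error_mm = measured_mm - truth_mm
  )
}

#' Rerun the periodic-motion verification experiment
#'
#' For each programmed amplitude, generates a coronal cine session of the
#' phantom with the rod reciprocating at the given period, converts it,
#' tracks the target centroid against a stationary reference session, and
#' estimates the motion amplitude.
#'
#' @param amplitudes_mm Programmed amplitudes (default 5, 10, 15, 20).
#' @param seed Integer seed.
#' @param n_frames Frames per sequence (default 100: five 4-s cycles at
#'   0.2 s).
#' @param period_s,frame_interval_s Motion period and frame interval.
#' @param noise_sd Intensity noise as a fraction of contrast (default 0.05,
#'   emulating acquisition noise).
#' @param waveform Motion waveform (default `"sine"`).
#' @return Tibble with `amplitude_mm`, `estimated_mm`, `sd_mm`, `n_cycles`,
#'   `error_mm`.
#' @export
run_motion_experiment <- function(amplitudes_mm = c(5, 10, 15, 20), seed = 42L,
                                  n_frames = 100L, period_s = 4,
                                  frame_interval_s = 0.2, noise_sd = 0.05,
                                  waveform = "sine") {
  geometry <- default_fixture_geometry()
  work <- tempfile("motionqa-")
  on.exit(unlink(work, recursive = TRUE))

  static <- generate_session(file.path(work, "static"),
                             program = motion_program("static", n_frames = 10L,
                                                      noise_sd = noise_sd),
                             geometry = geometry, planes = "coronal",
                             seed = seed)
  static_rep <- convert_session(static, file.path(work, "static", "out"),
                                format = "mha")
  static_frames <- read_converted_series(static_rep$out_dir, "coronal")
  ref_pts <- vapply(static_frames,
                    function(f) segment_target(f, rod_roi())$centroid_mm,
                    numeric(3))
  reference <- rowMeans(ref_pts)

  rows <- lapply(seq_along(amplitudes_mm), function(i) {
    a <- amplitudes_mm[i]
    dir_i <- file.path(work, sprintf("amp%02d", i))
    layout <- generate_session(
      dir_i,
      program = motion_program("periodic", amplitude_mm = a,
                               period_s = period_s,
                               frame_interval_s = frame_interval_s,
                               n_frames = n_frames, waveform = waveform,
                               noise_sd = noise_sd),
      geometry = geometry, planes = "coronal", seed = seed + i)
    rep <- convert_session(layout, file.path(dir_i, "out"), format = "mha")
    frames <- read_converted_series(rep$out_dir, "coronal")
    trace <- track_centroid(frames, rod_roi(), reference)
    est <- estimate_amplitude(trace)
    tibble::tibble(amplitude_mm = a, estimated_mm = est$mean_mm,
                   sd_mm = est$sd_mm, n_cycles = est$n_cycles,
                   error_mm = est$mean_mm - a)
  })
  dplyr::bind_rows(rows)
}

#' Rerun the translation verification experiment
#'
#' Renders sagittal frames of the phantom at a reference position and
#' translated by each programmed shift (subpixel rendering), converts them,
#' and recovers each shift by translation-only registration of the spine
#' block against the reference frame.
#'
#' @param shifts_mm Programmed whole-phantom shifts (default 0.5, 1, 2, 3, 5).
#' @param seed Integer seed.
#' @return Tibble with `shift_mm`, `recovered_mm`, `error_mm`, `score`.
#' @export
run_shift_experiment <- function(shifts_mm = c(0.5, 1, 2, 3, 5), seed = 42L) {
  geometry <- default_fixture_geometry()
  work <- tempfile("shiftqa-")
  on.exit(unlink(work, recursive = TRUE))

  load_one <- function(dir, program, s) {
    layout <- generate_session(dir, program = program, geometry = geometry,
                               planes = "sagittal", seed = s)
    rep <- convert_session(layout, file.path(dir, "out"), format = "mha")
    read_converted_series(rep$out_dir, "sagittal")[[1]]
  }
  ref <- load_one(file.path(work, "ref"),
                  motion_program("static", n_frames = 1L), seed)
  rows <- lapply(seq_along(shifts_mm), function(i) {
    mov <- load_one(file.path(work, sprintf("shift%02d", i)),
                    motion_program("shifted", shift_mm = shifts_mm[i],
                                   n_frames = 1L), seed + i)
    reg <- register_translation(ref, mov, roi = spine_roi())
    tibble::tibble(shift_mm = shifts_mm[i],
                   recovered_mm = reg$shift_mm[["u"]],
                   error_mm = reg$shift_mm[["u"]] - shifts_mm[i],
                   score = reg$score)
  })
  dplyr::bind_rows(rows)
}
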