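# cinemr

Convert 2D cine MR frames recorded during 1.5 T MR-linac treatments from
their proprietary binary format into MHA (MetaImage) and DICOM, and verify
the geometric fidelity of the conversion with motion-QA analyses.

## The problem

MR-guided radiotherapy systems acquire rapid 2D cine MR frames (~5 frames/s,
0.2 s interval, interleaved coronal/sagittal/axial planes) during beam
delivery to monitor target motion. On the vendor's data server these frames
are stored as headered binary files that no standard imaging software can
open, locking the data away from motion research and clinical QA. `cinemr`
is for medical physicists and researchers who need those frames as ordinary
images with correct patient-space geometry.

The conversion pipeline is:

1. **Decode** — skip the opaque 4,084-byte header and read
   `rows x columns` little-endian unsigned 16-bit pixels. Pixel counts and
   physical slice dimensions come from the session's ExamCard JSON
   (`Rows`, `Columns`, `SliceDimensionXInmm`, `SliceDimensionYInmm`);
   pixel spacing is `SliceDimension / pixel count`.
2. **Order** — frames carry no internal clock, so per-file millisecond
   timestamps (from a session manifest, or filesystem metadata) put the
   interleaved planes back in acquisition order.
3. **Classify** — each frame's imaging plane is identified from the
   intensity pattern stamped in its top-right corner: the corner patch is
   binarized at the Otsu threshold (making it invariant to session-level
   intensity scaling) and correlated against per-plane templates; frames
   below a 0.8 confidence threshold are quarantined, never guessed.
4. **Center** — decoded frames are offset by exactly 22 pixels; the
   centering shift removes it.
5. **Place** — frames are acquired through the centroid of the target
   structure (read from the BinaryMasks JSON, mm, DICOM LPS), so the
   continuous image center `((rows-1)/2, (cols-1)/2)` is mapped onto that
   centroid: `origin = centroid - row_dir * (cols-1)/2 * s_col -
   col_dir * (rows-1)/2 * s_row`, with per-plane direction cosines
   (axial `(1,0,0)/(0,1,0)`, coronal `(1,0,0)/(0,0,-1)`, sagittal
   `(0,1,0)/(0,0,-1)`).
6. **Write** — single-slice 3D MetaImage and/or DICOM MR objects
   (ImagePositionPatient, ImageOrientationPatient, PixelSpacing,
   per-plane SeriesInstanceUID, millisecond AcquisitionTime).

The motion-QA half of the package measures what the converted images show:
half-maximum edge-profile distance measurement, Otsu-based target
segmentation and centroid tracking, per-cycle motion-amplitude estimation
(cycles delimited by zero crossings of the displacement about a stationary
reference; amplitude = peak displacement per cycle), and translation-only
registration (FFT cross-correlation peak refined to subpixel by maximizing
the correlation under a Fourier phase-shift resampler).

Because no real vendor data is publicly available, the package includes a
deterministic synthetic session generator: an anti-aliased rendering of a
motion-management QA phantom (cylindrical rod of inner diameter 58.5 mm
inside a body of inner length 150.1 mm, plus a spine-mimicking block) with
programmed periodic motion or whole-phantom shifts, written in the exact
binary dialect the reader parses. The generator is the normative format
reference and the oracle for the test suite.

## Worked example

Generate a synthetic session of a phantom whose target reciprocates with a
10 mm amplitude every 4 s, convert it, and measure the motion back:

```r
library(cinemr)

root <- file.path(tempdir(), "demo")
layout <- generate_session(
  root,
  program = motion_program("periodic", amplitude_mm = 10,
                           n_frames = 100, noise_sd = 0.05),
  planes = "coronal", seed = 7)

report <- convert_session(layout, file.path(root, "converted"))
report
#> <conversion_report> fraction 'fraction_001': 100 in, 100 converted, 0 quarantined
#>   coronal: 100

frames <- read_converted_series(file.path(root, "converted"), "coronal")
trace  <- track_centroid(frames, roi = c(96, 161, 74, 183),
                         reference = c(0, 0, 0))
estimate_amplitude(trace)
#> <amplitude_estimate> 10.03 +/- 0.05 mm (peak, 4 cycles, period 4.00 s)
```

The estimate recovers the programmed 10 mm amplitude to 0.03 mm and the
4 s period exactly; `autoplot(trace)` draws the displacement trace.
Static-geometry fidelity is checked the same way:

```r
measure_phantom_dimensions(seed = 1)
#> # A tibble: 2 x 4
#>   item               measured_mm truth_mm error_mm
#> 1 rod_inner_diameter        58.3     58.5  -0.173
#> 2 body_inner_length        150.     150.   -0.0474
```

Both dimensions are recovered well within one pixel (1 mm) of the rendered
ground truth. A thin command-line front end is installed with the package
(`inst/cli/cinemr`) with `convert`, `classify` and `make-fixture`
subcommands.

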