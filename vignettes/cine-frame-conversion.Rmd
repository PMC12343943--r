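---
title: "Converting MR-linac cine frames: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting MR-linac cine frames: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinemr)
```

This vignette records how `cinemr` models the cine-frame conversion
problem, which conventions it fixes where the vendor format leaves them
open, and what the synthetic fixtures do and do not demonstrate about real
scanner data.

## The binary dialect and its fixed conventions

A cine frame file is an opaque header of exactly 4,084 bytes followed by
`rows x columns` unsigned 16-bit pixels. Several details of the real format
are not publicly documented, so the package fixes them once and treats its
own fixture generator as the normative counterpart of the reader — both
sides share the constants in `cine_header_length()` and
`encode_frame_payload()`, so the dialects cannot drift apart:

* **Byte order** is little-endian. **Pixel order** is row-major. Neither is
  observable from the header; both are stated prominently here because a
  real scanner could in principle differ, and `read_frame_pixels()` would
  then need a one-line change.
* **Axis mapping**: `SliceDimensionXInmm` spans columns (horizontal),
  `SliceDimensionYInmm` spans rows, consistent with the `Rows`/`Columns`
  naming. Column spacing is `X/columns`, row spacing `Y/rows`.
* **Header content** is never interpreted; only its length matters. The
  generator fills it with a repeating two-byte sentinel so that any
  header/payload misalignment shifts recognizable bytes into the decoded
  image and fails loudly in the byte-conservation tests.
* **Timestamps**: frame files carry no internal clock, and filesystem
  creation times are not portable across operating systems. The reader
  therefore accepts a pluggable timestamp source: a per-session JSON
  manifest (default, written by the generator) or filesystem modification
  times (best-effort production mode). Ties are broken by lexicographic
  file name with a warning — at ~5 frames/s across interleaved planes,
  true simultaneity would indicate a timestamping problem upstream.
* **BinaryMasks schema**: the centroid sidecar's key structure is defined
  by this package (`structure`, `coordinate_system`, `centroid_mm`) and is
  fixture-normative only; real sessions may use different key names, which
  is a known compatibility risk isolated inside `parse_target_centroid()`.

## Plane classification

Each frame announces its imaging plane through a stable intensity pattern
in its top-right corner; absolute intensities vary per monitoring session.
The classifier extracts a fixed 32 x 32 corner patch, binarizes it at the
Otsu threshold — which removes any positive session-level intensity
scaling — and correlates the result against one reference template per
plane. The shipped templates are the three near-orthogonal band patterns
the fixture generator stamps (horizontal bars, vertical bars,
checkerboard); for real sessions the same machinery accepts templates
re-learned from a labelled sample. The default acceptance threshold is a
correlation of 0.8: below it a frame is labelled `unknown` and quarantined
rather than guessed, because a silently misclassified plane would be
written with wrong orientation vectors and corrupt every downstream
geometric analysis. On fixtures the classifier is exact (the test suite
checks 1,050 frames over five intensity scales for 100% accuracy); this
demonstrates scale invariance and template discrimination, not performance
on real corner glyphs, which no public data exists to test.

## Centering and patient-space placement

Decoded frames sit 22 pixels off their correct centered position. The
direction of that correction is not externally documented; the package
applies it along the negative column direction by default (configurable),
and the generator pre-applies the matching inverse offset so that
conversion round trips are exact. After the shift, the continuous image
center — pixel-center coordinate `((rows-1)/2, (cols-1)/2)`, 0-based — is
mapped onto the session's target centroid. This midpoint convention makes
the centroid invariant exact for both odd and even image dimensions. Plane
orientations use the standard DICOM LPS direction cosines for the three
cardinal planes; orientation vectors are constant within a session and
orthonormal by construction.

MetaImage output uses `NDims = 3` with a single-slice extent rather than a
2D image, because 2D MetaImage cannot carry a full off-axis 3D origin and
orientation. DICOM output uses the MR Image Storage SOP class with
derived/secondary image-type tags for maximal viewer compatibility, and
AcquisitionTime carries fractional seconds so the ~0.2 s cadence survives.
UIDs are derived deterministically from the session identifier, a salt and
the frame index, so re-running a conversion is reproducible; pass a
different seed for a fresh UID family.

## Motion QA

* **Distance measurement** samples a world-space line profile (bilinear
  interpolation, 0.05 mm steps) and reports the distance between the first
  and last crossings of 50% of the profile's min-max range — the standard
  full-width-half-maximum edge criterion. Uniform profiles and profiles
  with fewer than two crossings are errors, not numbers.
* **Target segmentation** replaces manual contouring with Otsu
  thresholding inside a user-chosen rectangular ROI followed by
  largest-connected-component selection and an intensity-weighted center
  of mass. On the phantom's high-contrast rod this surrogate is accurate
  to well under a tenth of a pixel; it is not a general tumor segmenter.
* **Amplitude estimation** projects the centroid displacement onto its
  principal axis, delimits cycles by upward zero crossings about the
  stationary reference, and averages per-cycle amplitudes. "Amplitude"
  means peak displacement from the stationary reference per cycle;
  a `peak_to_peak` mode reports the full excursion instead. Crossings
  closer than three samples are merged to keep sensor noise near the zero
  line from fabricating micro-cycles. At least two complete cycles are
  required; estimates from fewer are refused.
* **Registration** recovers in-plane translation by normalized
  cross-correlation: the integer FFT correlation peak is refined by
  maximizing the correlation of the fixed image against the moving image
  resampled with a Fourier phase shift. The phase-shift resampler is used
  deliberately instead of bilinear interpolation, whose systematic bias
  (zero at integer and half-integer shifts, up to ~0.1 px between) would
  dominate the subpixel error budget. Degenerate (constant) inputs are
  refused. Registration is typically restricted to an ROI around the
  spine block, mirroring vertebral-body alignment, and the ROI should be
  chosen so its borders sit in flat background — the resampler is
  circular, and a strong intensity step across opposite ROI edges would
  leak ringing into the interior.

## The synthetic phantom

`render_phantom_frame()` draws an anti-aliased (signed-distance, one-pixel
edge ramp) scene: a rectangular body shell of inner length 150.1 mm and
wall thickness 10 mm, a rod of diameter 58.5 mm at the programmed
displacement, and a 30 x 18 mm spine block with a smooth 8 mm-period
sinusoidal vertebra/disc texture that gives the registration something to
lock onto. Periodic programs move only the rod (respiratory-target
scenario); shift programs translate the whole phantom (couch-shift
scenario). The default study conditions mirror the physical experiment the
package is designed to reproduce: amplitudes of 5/10/15/20 mm with a 4 s
period sampled at 0.2 s, and shifts of 0.5/1/2/3/5 mm. The default
waveform is a sinusoid (the physical rod is only specified as moving "every
4 s"; a triangular option exists). Optional Gaussian intensity noise is
expressed as a fraction of the rod/background contrast; the generator's
default is off so format tests are bit-exact, while the motion experiment
wrapper uses 5% as a plausible acquisition-noise stand-in.

What the renderer does **not** model: MR physics of any kind — no bFFE
contrast, no coil shading, no dark-band artifacts at plane intersections
(their correction is explicitly out of scope), no geometric distortion.
Passing fixture tests therefore demonstrates that the conversion and
measurement chain is internally exact and self-consistent, not that the
classifier or registration would survive those artifacts on patient data.

## Problem sizes and numerical choices

The experiments run at 256 x 256 pixels and 1 mm spacing, with 100-frame
sequences (five 4 s cycles) per amplitude and 10-frame stationary
references — enough cycles for a meaningful per-cycle spread while keeping
a full rerun of every experiment in well under a minute each. Geometry
invariants are asserted to 1e-6 mm (floating-point scale), format checks
to the byte, spacing consistency to 1e-9 mm. Degenerate inputs
(truncated files, missing sidecars, unknown planes, constant images,
edgeless profiles, sub-two-cycle traces) are all hard errors or quarantine
paths rather than silent guesses; every such path is exercised in the test
suite.

## Known limitations

* The BinaryMasks key schema, the payload's row-major order and the shift
  direction are fixture-normative decisions; real vendor sessions could
  differ in any of them, and each is isolated behind one small function.
* Template re-learning for real corner glyphs is implemented but untested
  by construction (no public data).
* Registration is translation-only; rotation and deformation are out of
  scope, as is any gating logic.
* The filesystem timestamp source inherits the resolution of the
  underlying filesystem and should only be used where a manifest is
  unavailable.
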