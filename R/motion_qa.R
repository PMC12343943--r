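#' Segment the bright target within a region of interest
#'
#' Automated surrogate for manual target contouring: thresholds the ROI at
#' the Otsu level, keeps the largest connected bright component, and returns
#' its intensity-weighted center of mass mapped to world millimetres.
#'
#' @param frame A `geo_frame`.
#' @param roi Integer vector `c(r0, r1, c0, c1)`, 1-based inclusive pixel
#'   rectangle; default the whole frame.
#' @return List with `mask` (logical matrix, full frame size), `centroid_mm`
#'   (length-3 world coordinate) and `centroid_px` (0-based fractional
#'   `c(r, c)`).
#' @export
segment_target <- function(frame, roi = NULL) {
  px <- frame$pixels
  if (is.null(roi)) roi <- c(1L, nrow(px), 1L, ncol(px))
  stopifnot(length(roi) == 4L)
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(px) || roi[4] > ncol(px) ||
      roi[1] > roi[2] || roi[3] > roi[4]) {
    stop("roi must be a c(r0, r1, c0, c1) rectangle inside the frame", call. = FALSE)
  }
  sub <- px[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  rng <- range(sub)
  if (diff(rng) <= 0) stop("no target found: roi is uniform", call. = FALSE)
  scaled <- (sub - rng[1]) / diff(rng)
  th <- EBImage::otsu(scaled, range = c(0, 1))
  bin <- scaled > th
  if (!any(bin)) stop("no target found: nothing above threshold", call. = FALSE)
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)

  w <- (scaled - th) * comp
  w[w < 0] <- 0
  idx <- which(comp, arr.ind = TRUE)
  wts <- w[comp]
  # 0-based full-frame pixel coordinates
  r_cm <- sum((idx[, 1] + roi[1] - 2) * wts) / sum(wts)
  c_cm <- sum((idx[, 2] + roi[3] - 2) * wts) / sum(wts)
  mask <- matrix(FALSE, nrow(px), ncol(px))
  mask[roi[1]:roi[2], roi[3]:roi[4]] <- comp
  list(mask = mask,
       centroid_mm = pixel_to_world(frame, r_cm, c_cm),
       centroid_px = c(r = r_cm, c = c_cm))
}

#' Track the target centroid across a cine sequence
#'
#' Segments the target in every frame of a single-plane sequence and returns
#' the time-ordered trace of in-plane centroid positions (mm), with
#' displacements relative to a stationary reference. Frames where
#' segmentation fails are recorded as gaps (NA), never fabricated.
#'
#' @param frames List of `geo_frame`s, one plane, time-ordered.
#' @param roi Pixel rectangle passed to [segment_target()].
#' @param reference Either a length-3 world coordinate (mm) or a list of
#'   stationary `geo_frame`s whose mean segmented centroid becomes the
#'   reference.
#' @return A `motion_trace`: tibble with columns `time_s`, `u_mm`, `v_mm`
#'   (in-plane world coordinates), `du_mm`, `dv_mm` (displacement from
#'   reference), and attributes `reference_mm`, `plane`.
#' @export
track_centroid <- function(frames, roi = NULL, reference) {
  stopifnot(length(frames) >= 2L)
  planes <- unique(vapply(frames, function(f) f$plane, ""))
  if (length(planes) != 1L) {
    stop("track_centroid expects frames from a single plane, got: ",
         paste(planes, collapse = ", "), call. = FALSE)
  }
  if (is.list(reference)) {
    ref_pts <- vapply(reference, function(f) segment_target(f, roi)$centroid_mm,
                      numeric(3))
    reference <- rowMeans(ref_pts)
  }
  stopifnot(length(reference) == 3L)
  ts <- vapply(frames, function(f) f$timestamp_ms, numeric(1))
  if (any(diff(ts) <= 0)) stop("frame timestamps must be strictly increasing", call. = FALSE)
  ref_uv <- world_to_inplane(frames[[1]], reference)
  pos <- t(vapply(frames, function(f) {
    cen <- tryCatch(segment_target(f, roi)$centroid_mm, error = function(e) rep(NA_real_, 3))
    if (anyNA(cen)) c(NA_real_, NA_real_) else world_to_inplane(f, cen)
  }, numeric(2)))
  out <- tibble::tibble(
    time_s = (ts - ts[1]) / 1000,
    u_mm = pos[, 1], v_mm = pos[, 2],
    du_mm = pos[, 1] - ref_uv[["u"]],
    dv_mm = pos[, 2] - ref_uv[["v"]]
  )
  structure(out, reference_mm = reference, plane = planes,
            class = c("motion_trace", class(out)))
}

# Signed displacement along the principal motion axis of a trace.
principal_displacement <- function(trace) {
  d <- cbind(trace$du_mm, trace$dv_mm)
  ok <- stats::complete.cases(d)
  ax <- eigen(stats::cov(d[ok, , drop = FALSE]))$vectors[, 1]
  s <- as.vector(d %*% ax)
  # orient the axis so the largest excursion is positive
  if (abs(min(s, na.rm = TRUE)) > max(s, na.rm = TRUE)) s <- -s
  s
}

#' Estimate periodic motion amplitude from a centroid trace
#'
#' Projects the displacement onto its principal axis, delimits motion cycles
#' by upward zero crossings of the displacement about the stationary
#' reference, and reports the per-cycle amplitude: by default the peak
#' displacement from the reference within each cycle (`mode = "peak"`), or
#' the full max-minus-min excursion with `mode = "peak_to_peak"`.
#'
#' @param trace A `motion_trace`.
#' @param mode `"peak"` (default) or `"peak_to_peak"`.
#' @return An `amplitude_estimate`: list with `mean_mm`, `sd_mm`,
#'   `n_cycles`, `mode` and `per_cycle` (tibble `cycle`, `amplitude_mm`).
#' @export
estimate_amplitude <- function(trace, mode = c("peak", "peak_to_peak")) {
  mode <- match.arg(mode)
  s <- principal_displacement(trace)
  t <- trace$time_s
  ok <- !is.na(s)
  s <- s[ok]; t <- t[ok]
  if (length(s) < 4L || stats::sd(s) < 1e-9) {
    stop("insufficient cycles: trace shows no motion", call. = FALSE)
  }
  up <- which(s[-length(s)] <= 0 & s[-1] > 0)
  # merge spurious double-crossings closer than 3 samples
  if (length(up) > 1L) up <- up[c(TRUE, diff(up) >= 3L)]
  if (length(up) < 2L) {
    stop("insufficient cycles: need at least 2 detected motion cycles, found ",
         max(0L, length(up) - 1L), call. = FALSE)
  }
  amp <- vapply(seq_len(length(up) - 1L), function(j) {
    seg <- s[(up[j] + 1L):up[j + 1L]]
    if (mode == "peak") max(abs(seg)) else max(seg) - min(seg)
  }, numeric(1))
  structure(list(
    mean_mm = mean(amp), sd_mm = stats::sd(amp),
    n_cycles = length(amp), mode = mode,
    period_s = mean(diff(t[up])),
    per_cycle = tibble::tibble(cycle = seq_along(amp), amplitude_mm = amp)
  ), class = "amplitude_estimate")
}

#' @export
print.amplitude_estimate <- function(x, ...) {
  cat(sprintf("<amplitude_estimate> %.2f +/- %.2f mm (%s, %d cycles, period %.2f s)\n",
              x$mean_mm, x$sd_mm, x$mode, x$n_cycles, x$period_s))
  invisible(x)
}

#' Translation-only registration of two frames
#'
#' Recovers the in-plane translation of `moving` relative to `fixed` by
#' normalized cross-correlation: a coarse integer shift from the FFT
#' correlation peak, refined to subpixel precision by directly maximizing
#' the correlation of the fixed image with the bilinearly resampled moving
#' image. Mirrors a rigid vertebral-body alignment when given a spine ROI.
#'
#' @param fixed,moving `geo_frame`s in the same plane with equal spacing.
#' @param roi Optional `c(r0, r1, c0, c1)` rectangle (applied to both
#'   images) restricting the registration, e.g. to the vertebral block.
#' @param max_shift_px Largest shift considered (default 32).
#' @return A `translation_offset`: list with `shift_mm` (named `u`, `v`:
#'   content displacement of moving vs fixed along the column and row
#'   axes), `shift_px` (`r`, `c`) and `score` (correlation at optimum,
#'   in `[-1, 1]`).
#' @export
register_translation <- function(fixed, moving, roi = NULL, max_shift_px = 32) {
  if (fixed$plane != "unknown" && moving$plane != "unknown" &&
      fixed$plane != moving$plane) {
    stop("cannot register frames from different planes", call. = FALSE)
  }
  if (max(abs(fixed$spacing - moving$spacing)) > 1e-9) {
    stop("cannot register frames with different pixel spacing", call. = FALSE)
  }
  A <- fixed$pixels; B <- moving$pixels
  if (!is.null(roi)) {
    A <- A[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
    B <- B[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  }
  A <- A - mean(A); B <- B - mean(B)
  if (stats::sd(A) < 1e-12 || stats::sd(B) < 1e-12) {
    stop("no structure to register: constant image", call. = FALSE)
  }
  # circular cross-correlation; peak at lag d means content moved by -d
  cc <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  lag <- peak - 1L
  lag <- ifelse(lag > dim(A) / 2, lag - dim(A), lag)
  shift0 <- -as.numeric(lag)  # (dr, dc): content displacement fixed -> moving
  if (any(abs(shift0) > max_shift_px)) {
    stop("correlation peak beyond max_shift_px; images may be unrelated", call. = FALSE)
  }

  # subpixel resampling by Fourier phase shift (exact translation operator,
  # free of the systematic bias of low-order interpolation)
  fft_shift <- function(img, s) {
    nr <- nrow(img); nc <- ncol(img)
    kr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[1:nr]
    kc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[1:nc]
    ph <- exp(2i * pi * (outer(kr, rep(1, nc)) * s[1] / nr +
                           outer(rep(1, nr), kc) * s[2] / nc))
    Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (nr * nc)
  }
  margin <- ceiling(max(abs(shift0))) + 4
  rs <- (margin + 1):(nrow(A) - margin)
  cs <- (margin + 1):(ncol(A) - margin)
  if (length(rs) < 4 || length(cs) < 4) {
    stop("roi too small for the detected shift", call. = FALSE)
  }
  ncc_at <- function(s) {
    bs <- fft_shift(B, s)
    stats::cor(as.vector(A[rs, cs]), as.vector(bs[rs, cs]))
  }
  opt <- stats::optim(shift0, function(s) -ncc_at(s), method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 300))
  s <- opt$par
  list(
    shift_px = c(r = s[1], c = s[2]),
    shift_mm = c(u = s[2] * fixed$spacing[["col"]],
                 v = s[1] * fixed$spacing[["row"]]),
    score = -opt$value
  )
}

#' Measure a distance by half-maximum edge crossings
#'
#' Samples the image intensity along a world-space line segment (bilinear
#' interpolation, 0.05 mm steps) and returns the distance between the first
#' and last crossings of the half-maximum level — 50% of the profile's
#' min-max range, the full-width-half-maximum convention.
#'
#' @param frame A `geo_frame`.
#' @param p0,p1 Length-3 world endpoints (mm) of the profile, in the frame's
#'   plane.
#' @param step_mm Sampling step (default 0.05).
#' @return Distance in mm between the outermost half-maximum crossings.
#' @export
measure_distance <- function(frame, p0, p1, step_mm = 0.05) {
  stopifnot(length(p0) == 3L, length(p1) == 3L)
  L <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(L / step_mm) + 1L)
  tt <- seq(0, 1, length.out = n)
  pts <- outer(tt, p1 - p0) + matrix(p0, n, 3, byrow = TRUE)
  rel <- sweep(pts, 2, frame$origin)
  cpix <- as.vector(rel %*% frame$row_dir) / frame$spacing[["col"]]
  rpix <- as.vector(rel %*% frame$col_dir) / frame$spacing[["row"]]
  if (any(cpix < 0 | cpix > ncol(frame$pixels) - 1 |
          rpix < 0 | rpix > nrow(frame$pixels) - 1)) {
    stop("profile segment extends outside the frame", call. = FALSE)
  }
  prof <- bilinear_sample(frame$pixels, rpix, cpix)
  if (diff(range(prof)) < 1e-9 * max(1, max(abs(prof)))) {
    stop("no edges found: profile is uniform", call. = FALSE)
  }
  level <- (min(prof) + max(prof)) / 2
  d <- prof - level
  cross <- which(d[-n] * d[-1] < 0)
  if (length(cross) < 2L) {
    stop("no edges found: profile crosses the half-maximum level fewer than twice",
         call. = FALSE)
  }
  # linear interpolation of each crossing position along the profile (mm)
  pos <- vapply(cross, function(i) {
    f <- if (d[i] == 0) 0 else d[i] / (d[i] - d[i + 1])
    (tt[i] + f * (tt[i + 1] - tt[i])) * L
  }, numeric(1))
  max(pos) - min(pos)
}
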