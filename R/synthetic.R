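# Forward simulator: ground-truthed synthetic datasets with the statistical
# structure of a far-field ptychography benchmark — a complex object built
# from two grayscale images, a circular constant-phase probe, a jittered
# raster scan and optional Poisson counting noise.

#' Procedural phantom image pair
#'
#' Deterministic grayscale test images (values in \[0, 1\]) used as magnitude
#' and phase sources when no external images are supplied: a mix of smooth
#' gradients, disks and bar strokes giving both low- and high-frequency
#' content. Purely a function of the requested shape, so CI needs no assets.
#'
#' @param shape Length-2 integer (H, W).
#' @return List with matrices `magnitude` and `phase`.
#' @export
phantom_images <- function(shape) {
  h <- shape[1]; w <- shape[2]
  y <- matrix(seq(0, 1, length.out = h), h, w)
  x <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  disk <- function(cy, cx, r, v) v * ((y - cy)^2 + (x - cx)^2 < r^2)
  bar <- function(y0, y1, x0, x1, v) v * (y >= y0 & y < y1 & x >= x0 & x < x1)

  mag <- 0.35 + 0.25 * x + 0.15 * sin(2 * pi * 3 * y) +
    disk(0.30, 0.30, 0.16, 0.30) + disk(0.70, 0.65, 0.12, -0.25) +
    bar(0.55, 0.62, 0.10, 0.45, 0.35) + bar(0.15, 0.45, 0.78, 0.84, -0.30)
  pha <- 0.5 - 0.3 * y + 0.2 * cos(2 * pi * 2 * (x + y)) +
    disk(0.62, 0.25, 0.14, 0.35) + disk(0.30, 0.72, 0.18, -0.30) +
    bar(0.80, 0.88, 0.30, 0.85, 0.40)
  clip01 <- function(m) pmin(pmax(m, 0), 1)
  list(magnitude = clip01(mag), phase = clip01(pha))
}

#' Complex object from projected refractive-index maps
#'
#' Builds the thin-sample transmission function from projected refractive
#' index decrements: \eqn{O = e^{-k \beta_p} e^{-i k \delta_p}} with
#' \eqn{k = 2\pi/\lambda}, where \eqn{\delta_p} and \eqn{\beta_p} are the
#' beam-direction projections (index decrement x thickness, dimensionless).
#'
#' @param delta_map,beta_map Matrices of projected real/imaginary refractive
#'   index decrements; must share a shape.
#' @param wavelength_m Wavelength (m).
#' @param pixel_m Effective pixel size recorded on the object.
#' @return A [ptycho_object()]. Negative `beta_map` entries (unphysical
#'   amplification) trigger a warning but are computed.
#' @export
object_from_refraction <- function(delta_map, beta_map, wavelength_m,
                                   pixel_m = 1e-9) {
  if (!all(dim(delta_map) == dim(beta_map)))
    stop_ptychor("delta_map and beta_map must share a shape",
                 class = "ptychor_invalid_input")
  if (any(!is.finite(delta_map)) || any(!is.finite(beta_map)))
    stop_ptychor("refraction maps must be finite", class = "ptychor_invalid_input")
  if (any(beta_map < 0))
    warning("negative projected beta: amplification is unphysical", call. = FALSE)
  check_positive_scalar(wavelength_m, "wavelength_m")
  k <- 2 * pi / wavelength_m
  ptycho_object(exp(-k * beta_map) * exp(-1i * k * delta_map), pixel_m)
}

#' Complex object from a magnitude and a phase image
#'
#' Rescales a magnitude image to `mag_range` and a phase image to
#' `phase_range` (radians) and combines them as
#' \eqn{O = m \, e^{i \phi}}. The rescale bounds are recorded in the
#' `"rescale"` attribute. Images are resized to `object_shape` by
#' nearest-neighbour sampling when needed.
#'
#' @param magnitude_image,phase_image Grayscale matrices (any range).
#' @param object_shape Target (H, W); defaults to the magnitude image shape.
#' @param mag_range Magnitude bounds, default `c(0.2, 1)` — keeps the object
#'   away from the zero-amplitude pathology.
#' @param phase_range Phase bounds in radians, default `c(0, pi/2)` — stays
#'   unwrapped.
#' @param pixel_m Effective pixel size recorded on the object.
#' @return A [ptycho_object()].
#' @export
object_from_images <- function(magnitude_image, phase_image,
                               object_shape = dim(magnitude_image),
                               mag_range = c(0.2, 1),
                               phase_range = c(0, pi / 2),
                               pixel_m = 1e-9) {
  resize_nn <- function(im, shape) {
    if (all(dim(im) == shape)) return(im)
    ri <- round(seq(1, nrow(im), length.out = shape[1]))
    ci <- round(seq(1, ncol(im), length.out = shape[2]))
    im[ri, ci, drop = FALSE]
  }
  rescale <- function(im, lo, hi) {
    rng <- range(im)
    if (rng[1] == rng[2]) {
      if (hi == 1 && lo == 1)
        warning("constant image with unit magnitude: degenerate contrast",
                call. = FALSE)
      return(matrix((lo + hi) / 2, nrow(im), ncol(im)))
    }
    lo + (im - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
  }
  m <- rescale(resize_nn(magnitude_image, object_shape), mag_range[1], mag_range[2])
  p <- rescale(resize_nn(phase_image, object_shape), phase_range[1], phase_range[2])
  out <- ptycho_object(m * exp(1i * p), pixel_m)
  attr(out, "rescale") <- list(mag_range = mag_range, phase_range = phase_range)
  out
}

#' Circular top-hat probe
#'
#' A single-mode probe equal to one inside a centred disk of the given
#' diameter and zero outside (constant phase). An optional defocus propagates
#' the disk by `defocus_m` with the angular-spectrum method.
#'
#' @param probe_side Frame side M (px).
#' @param diameter_px Disk diameter in pixels; must be in (0, M\].
#' @param wavelength_m,pixel_m Needed only when `defocus_m` is nonzero.
#' @param defocus_m Optional defocus distance (m).
#' @return A [ptycho_probe()] with one mode.
#' @export
probe_circular <- function(probe_side, diameter_px,
                           wavelength_m = NULL, pixel_m = NULL,
                           defocus_m = NULL) {
  probe_side <- as.integer(probe_side)
  if (diameter_px <= 0)
    stop_ptychor("diameter_px must be positive (all-zero probe rejected)",
                 class = "ptychor_invalid_input")
  if (diameter_px > probe_side)
    stop_ptychor("diameter_px exceeds probe frame", class = "ptychor_invalid_input")
  ctr <- floor(probe_side / 2) + 1L
  idx <- seq_len(probe_side) - ctr
  r2 <- outer(idx^2, idx^2, `+`)
  disk <- (r2 < (diameter_px / 2)^2) + 0i
  if (!is.null(defocus_m) && defocus_m != 0) {
    spec <- propagator("near_field_asm", wavelength_m = wavelength_m,
                       distance_m = defocus_m, pixel_m = pixel_m,
                       frame_shape = c(probe_side, probe_side))
    disk <- to_detector(disk, spec)
  }
  ptycho_probe(disk)
}

#' Jittered raster scan
#'
#' Regular raster grid of probe positions with i.i.d. normal offsets added to
#' each coordinate to break the raster-grid pathology (degenerate periodic
#' solutions on perfectly periodic scans). Positions are generated in object
#' pixels and converted to metric coordinates with `pixel_m`. Windows pushed
#' outside the canvas by the jitter are clamped; the clamp count is recorded
#' in the `"n_clamped"` attribute of the returned pattern.
#'
#' @param grid_shape Length-2 integer (rows, cols) of the raster grid.
#' @param step_px Grid step in object pixels.
#' @param jitter_sigma_px Standard deviation of the normal jitter (px); 0
#'   gives the exact raster grid.
#' @param probe_side Probe frame side M (px), for the clamping bound.
#' @param canvas_dim Object canvas (rows, cols) the windows must fit in.
#' @param pixel_m Effective pixel size (m).
#' @param margin_px Offset of the grid origin from the canvas corner.
#' @param seed RNG seed; the pattern is a pure function of (arguments, seed).
#' @return A [scan_pattern()] with metric positions.
#' @export
scan_raster_jittered <- function(grid_shape, step_px, jitter_sigma_px,
                                 probe_side, canvas_dim, pixel_m,
                                 margin_px = 0, seed = 1L) {
  if (jitter_sigma_px < 0)
    stop_ptychor("jitter_sigma_px must be >= 0", class = "ptychor_invalid_input")
  gr <- grid_shape[1]; gc <- grid_shape[2]
  base <- cbind(row = rep(seq_len(gr) - 1L, each = gc) * step_px + margin_px,
                col = rep(seq_len(gc) - 1L, times = gr) * step_px + margin_px)
  if (jitter_sigma_px > 0) {
    set.seed(seed)
    base <- base + matrix(stats::rnorm(2 * nrow(base), sd = jitter_sigma_px),
                          ncol = 2)
  }
  hi <- c(canvas_dim[1] - probe_side, canvas_dim[2] - probe_side)
  clamped <- base
  clamped[, 1] <- pmin(pmax(base[, 1], 0), hi[1])
  clamped[, 2] <- pmin(pmax(base[, 2], 0), hi[2])
  n_clamped <- sum(rowSums(clamped != base) > 0)
  # pixel (row, col) -> metric (x, y)
  out <- scan_pattern(cbind(clamped[, 2], clamped[, 1]) * pixel_m, pixel_m)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Simulate far-field diffraction intensities
#'
#' Applies the multiplicative forward model: for each scan position the exit
#' wave is \eqn{\psi_{im} = P_m \cdot O} restricted to the probe window, and
#' the recorded frame is the incoherent sum over probe modes of the
#' propagated intensities \eqn{I_i = \sum_m |D_d\{\psi_{im}\}|^2}.
#'
#' @param object A [ptycho_object()]; its `pixel_m` must equal the geometry's
#'   effective pixel so that metric positions map onto the canvas.
#' @param probe A [ptycho_probe()].
#' @param scan A [scan_pattern()].
#' @param geometry A [detector_geometry()].
#' @return A [diffraction_stack()] with all-ones masks.
#' @export
forward_intensities <- function(object, probe, scan, geometry) {
  stopifnot(inherits(object, "ptycho_object"), inherits(probe, "ptycho_probe"))
  m <- dim(probe$modes)[1]
  if (!all(geometry$frame_shape == c(m, m)))
    stop_ptychor("probe frame does not match detector frame",
                 class = "ptychor_invalid_input")
  offsets <- positions_to_pixel_offsets(scan, object$pixel_m)
  check_windows_inside(offsets, m, dim(object$values))
  spec <- propagator_for_geometry(geometry)
  n <- nrow(offsets)
  intensities <- array(0, dim = c(m, m, n))
  for (i in seq_len(n)) {
    psi <- exit_wave(object, probe, offsets[i, ])
    acc <- matrix(0, m, m)
    for (k in seq_len(dim(psi)[3]))
      acc <- acc + Mod(to_detector(psi[, , k], spec))^2
    intensities[, , i] <- acc
  }
  diffraction_stack(intensities, scan, geometry)
}

#' Apply Poisson counting noise
#'
#' Scales every frame so the mean per-frame total equals the requested photon
#' budget, draws Poisson counts, and rescales back to the original intensity
#' scale. The scale factor is recorded in the `"photon_scale"` attribute.
#'
#' @param stack A [diffraction_stack()].
#' @param photons_per_frame Target mean photons per frame (> 0).
#' @param seed RNG seed; frames are reproducible under a fixed seed.
#' @return A new [diffraction_stack()] with noisy intensities.
#' @export
apply_counting_noise <- function(stack, photons_per_frame, seed = 1L) {
  check_positive_scalar(photons_per_frame, "photons_per_frame")
  scale <- photons_per_frame / mean(apply(stack$intensities, 3, sum))
  set.seed(seed)
  counts <- stats::rpois(length(stack$intensities),
                         as.vector(stack$intensities) * scale)
  noisy <- array(counts / scale, dim = dim(stack$intensities))
  out <- diffraction_stack(noisy, stack$scan, stack$geometry, stack$masks)
  attr(out, "photon_scale") <- scale
  out
}

benchmark_spec <- function(preset) {
  switch(preset,
    full_benchmark = list(
      object_shape = c(400L, 400L), probe_side = 180L,
      grid_shape = c(20L, 20L), step_px = 11, jitter_sigma_px = 0.25 * 11,
      margin_px = 5, diameter_px = 135,
      energy_keV = 12, distance_m = 1.1, det_pixel_m = 55e-6,
      mag_range = c(0.2, 1), phase_range = c(0, pi / 2), noise = "none"),
    small_test = list(
      object_shape = c(64L, 64L), probe_side = 32L,
      grid_shape = c(5L, 5L), step_px = 8, jitter_sigma_px = 0.25 * 8,
      margin_px = 0, diameter_px = 24,
      energy_keV = 12, distance_m = 1.1, det_pixel_m = 55e-6,
      mag_range = c(0.2, 1), phase_range = c(0, pi / 2), noise = "none"),
    stop_ptychor("unknown preset: ", preset, class = "ptychor_invalid_input"))
}

#' Generate a ground-truthed benchmark dataset
#'
#' End-to-end simulation with fixed presets: `"full_benchmark"` (400 x 400
#' object, 180 x 180 circular probe, 400 jittered raster positions) and
#' `"small_test"` (64 x 64 object, 32 x 32 probe, 25 positions, sized for
#' fast test runs). A custom spec list (same fields as the presets) may be
#' passed instead of a preset name. The manifest reports the linear overlap
#' ratio `1 - step/diameter` and warns below 60%.
#'
#' @param preset `"full_benchmark"`, `"small_test"`, or a spec list.
#' @param seed RNG seed; the dataset is a pure function of (spec, seed).
#' @param photons_per_frame Optional Poisson photon budget; `NULL` keeps the
#'   data noiseless.
#' @param out Optional directory; when given, the dataset and ground truth
#'   are written with [save_dataset()].
#' @return List with `stack`, `ground_truth` (object + probe), `spec`, and
#'   `manifest` (frame count, overlap, clamp count, seed).
#' @export
generate_benchmark_dataset <- function(preset = "small_test", seed = 1L,
                                       photons_per_frame = NULL, out = NULL) {
  spec <- if (is.list(preset)) preset else benchmark_spec(preset)
  m <- spec$probe_side
  geometry <- detector_geometry(spec$energy_keV, spec$distance_m,
                                spec$det_pixel_m, c(m, m))
  px <- effective_pixel_size(geometry)
  imgs <- phantom_images(spec$object_shape)
  object <- object_from_images(imgs$magnitude, imgs$phase,
                               object_shape = spec$object_shape,
                               mag_range = spec$mag_range,
                               phase_range = spec$phase_range, pixel_m = px)
  probe <- probe_circular(m, spec$diameter_px)
  scan <- scan_raster_jittered(spec$grid_shape, spec$step_px,
                               spec$jitter_sigma_px, m, spec$object_shape,
                               px, margin_px = spec$margin_px, seed = seed)
  stack <- forward_intensities(object, probe, scan, geometry)
  if (!is.null(photons_per_frame))
    stack <- apply_counting_noise(stack, photons_per_frame, seed = seed + 1L)
  overlap <- 1 - spec$step_px / spec$diameter_px
  if (overlap < 0.6)
    warning(sprintf("linear overlap %.0f%% below 60%%: reconstruction may fail",
                    100 * overlap), call. = FALSE)
  manifest <- list(n_frames = n_frames(stack), overlap_linear = overlap,
                   n_clamped = attr(scan, "n_clamped"), seed = seed,
                   effective_pixel_m = px,
                   photons_per_frame = photons_per_frame)
  result <- list(stack = stack,
                 ground_truth = list(object = object, probe = probe),
                 spec = spec, manifest = manifest)
  if (!is.null(out)) {
    save_dataset(stack, out, ground_truth = result$ground_truth,
                 config = manifest)
    jsonlite::write_json(manifest, file.path(out, "simulation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
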