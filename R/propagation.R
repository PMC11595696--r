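#' Free-space propagator specification
#'
#' Describes the operator that carries a wavefront from the sample exit plane
#' to the detector plane. In the far field this is a centred, unitary 2-D
#' Fourier transform (the sample-detector distance only fixes the effective
#' real-space pixel, not the operator). In the near field the angular-spectrum
#' method (ASM) multiplies the spectrum by the transfer function
#' \eqn{H(f) = \exp(i 2 \pi d \sqrt{1/\lambda^2 - |f|^2})}, zeroing evanescent
#' components.
#'
#' @param regime `"far_field"` or `"near_field_asm"`.
#' @param wavelength_m Wavelength (m); required for ASM.
#' @param distance_m Propagation distance (m); required for ASM, may be
#'   negative (back-propagation).
#' @param pixel_m Pixel size of the wavefront plane (m); required for ASM.
#' @param frame_shape Length-2 frame dimensions.
#' @return Object of class `propagator_spec`.
#' @export
propagator <- function(regime = c("far_field", "near_field_asm"),
                       wavelength_m = NULL, distance_m = NULL,
                       pixel_m = NULL, frame_shape = NULL) {
  regime <- match.arg(regime)
  if (regime == "near_field_asm") {
    check_positive_scalar(wavelength_m, "wavelength_m")
    check_positive_scalar(pixel_m, "pixel_m")
    if (is.null(distance_m) || !is.finite(distance_m))
      stop_ptychor("distance_m required for the angular-spectrum propagator",
                   class = "ptychor_invalid_input")
  }
  structure(list(regime = regime, wavelength_m = wavelength_m,
                 distance_m = distance_m, pixel_m = pixel_m,
                 frame_shape = frame_shape),
            class = "propagator_spec")
}

#' Propagator for a detector geometry
#'
#' Convenience constructor mapping a [detector_geometry()] to the matching
#' [propagator()]: far-field geometries use the Fourier operator; near-field
#' geometries use ASM over the sample-detector distance at the detector pixel.
#'
#' @param geometry A [detector_geometry()].
#' @return A `propagator_spec`.
#' @export
propagator_for_geometry <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (geometry$regime == "far_field")
    propagator("far_field", frame_shape = geometry$frame_shape)
  else
    propagator("near_field_asm", wavelength_m = geometry$wavelength_m,
               distance_m = geometry$distance_m, pixel_m = geometry$pixel_m,
               frame_shape = geometry$frame_shape)
}

asm_transfer <- function(spec, dims, distance_m) {
  fy <- fft_freqs(dims[1], spec$pixel_m)
  fx <- fft_freqs(dims[2], spec$pixel_m)
  f2 <- outer(fy^2, fx^2, `+`)
  kz2 <- 1 / spec$wavelength_m^2 - f2
  h <- complex_matrix(dims[1], dims[2])
  prop <- kz2 > 0
  h[prop] <- exp(2i * pi * distance_m * sqrt(kz2[prop]))
  h
}

asm_sampling_ok <- function(spec, dims) {
  # standard aliasing bound for the ASM transfer function sampling
  crit <- abs(spec$distance_m) * spec$wavelength_m /
    (min(dims) * spec$pixel_m^2)
  if (crit > 1)
    warning(sprintf(paste0("angular-spectrum sampling criterion violated: ",
                           "lambda*d/(M*p^2) = %.3g > 1"), crit),
            call. = FALSE)
  invisible(crit)
}

propagate_asm <- function(wavefront, spec, distance_m) {
  asm_sampling_ok(spec, dim(wavefront))
  h <- asm_transfer(spec, dim(wavefront), distance_m)
  stats::fft(h * stats::fft(wavefront), inverse = TRUE) / length(wavefront)
}

#' Propagate a wavefront to the detector plane
#'
#' @param wavefront Complex matrix matching the propagator frame.
#' @param spec A [propagator()].
#' @return Complex matrix of the same shape (detector-plane wavefront,
#'   zero frequency centred in the far-field case).
#' @export
to_detector <- function(wavefront, spec) {
  stopifnot(inherits(spec, "propagator_spec"))
  if (!is.null(spec$frame_shape) && !all(dim(wavefront) == spec$frame_shape))
    stop_ptychor("wavefront shape does not match propagator frame_shape",
                 class = "ptychor_invalid_input")
  if (spec$regime == "far_field") fft2_centered(wavefront)
  else propagate_asm(wavefront, spec, spec$distance_m)
}

#' Back-propagate a detector-plane wavefront to the sample plane
#'
#' Exact inverse of [to_detector()]: the adjoint Fourier transform in the far
#' field, ASM by \eqn{-d} in the near field.
#'
#' @inheritParams to_detector
#' @param detector_wavefront Complex matrix at the detector plane.
#' @return Complex matrix at the sample exit plane.
#' @export
from_detector <- function(detector_wavefront, spec) {
  stopifnot(inherits(spec, "propagator_spec"))
  if (!is.null(spec$frame_shape) &&
      !all(dim(detector_wavefront) == spec$frame_shape))
    stop_ptychor("wavefront shape does not match propagator frame_shape",
                 class = "ptychor_invalid_input")
  if (spec$regime == "far_field") ifft2_centered(detector_wavefront)
  else propagate_asm(detector_wavefront, spec, -spec$distance_m)
}
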