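#' Photon wavelength from energy
#'
#' Converts an X-ray photon energy to its wavelength via \eqn{\lambda = hc/E}
#' with \eqn{hc} fixed at 1.23984193 keV nm.
#'
#' @param energy_keV Photon energy in keV. Must be strictly positive.
#' @return Wavelength in meters.
#' @examples
#' wavelength_from_energy(12)      # ~1.033e-10 m
#' wavelength_from_energy(1.23984193)  # exactly 1 nm
#' @export
wavelength_from_energy <- function(energy_keV) {
  if (!is.numeric(energy_keV) || any(!is.finite(energy_keV)) || any(energy_keV <= 0))
    stop_ptychor("energy_keV must be positive and finite",
                 class = "ptychor_invalid_input")
  (HC_KEV_NM / energy_keV) * 1e-9
}

#' Detector geometry
#'
#' Bundles the physical acquisition geometry: photon energy, sample-detector
#' distance, detector pixel pitch and the (square, even) frame size. The
#' wavelength is derived from the energy and kept consistent.
#'
#' @param energy_keV Photon energy (keV).
#' @param distance_m Sample-detector distance (m).
#' @param pixel_m Detector pixel pitch (m).
#' @param frame_shape Integer length-2 vector (M, M); must be square and even.
#' @param regime `"far_field"` (Fraunhofer, Fourier-transform propagator) or
#'   `"near_field"` (angular-spectrum propagator).
#' @return Object of class `detector_geometry`.
#' @examples
#' g <- detector_geometry(12, 1.1, 55e-6, c(256, 256))
#' effective_pixel_size(g)  # ~8.07e-9 m
#' @export
detector_geometry <- function(energy_keV, distance_m, pixel_m,
                              frame_shape, regime = c("far_field", "near_field")) {
  regime <- match.arg(regime)
  check_positive_scalar(energy_keV, "energy_keV")
  check_positive_scalar(distance_m, "distance_m")
  check_positive_scalar(pixel_m, "pixel_m")
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) == 1L) frame_shape <- rep(frame_shape, 2L)
  if (length(frame_shape) != 2L || frame_shape[1] != frame_shape[2] ||
      frame_shape[1] <= 0L || frame_shape[1] %% 2L != 0L)
    stop_ptychor("frame_shape must be square with an even side",
                 class = "ptychor_invalid_input")
  structure(list(energy_keV = energy_keV,
                 wavelength_m = wavelength_from_energy(energy_keV),
                 distance_m = distance_m,
                 pixel_m = pixel_m,
                 frame_shape = frame_shape,
                 regime = regime),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("Detector geometry (", x$regime, ")\n", sep = "")
  cat(sprintf("  energy     : %g keV  (lambda = %.6g m)\n",
              x$energy_keV, x$wavelength_m))
  cat(sprintf("  distance   : %g m\n", x$distance_m))
  cat(sprintf("  pixel pitch: %g m\n", x$pixel_m))
  cat(sprintf("  frame      : %d x %d px\n", x$frame_shape[1], x$frame_shape[2]))
  if (x$regime == "far_field")
    cat(sprintf("  effective real-space pixel: %.6g m\n", effective_pixel_size(x)))
  invisible(x)
}

#' Real-space effective pixel size
#'
#' For far-field (Fraunhofer) geometry the real-space sampling interval of the
#' reconstruction is \eqn{\Delta x = \lambda d / (M p)} with detector distance
#' \eqn{d}, frame side \eqn{M} and detector pixel pitch \eqn{p}. This is the
#' object/probe pixel used to convert metric scan positions to pixel offsets.
#'
#' In the near-field regime the reconstruction pixel equals the detector
#' pixel; the detector pitch is returned with a message.
#'
#' @param geometry A [detector_geometry()].
#' @return Effective pixel size in meters.
#' @export
effective_pixel_size <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (geometry$regime != "far_field") {
    message("near-field regime: reconstruction pixel equals the detector pixel")
    return(geometry$pixel_m)
  }
  geometry$wavelength_m * geometry$distance_m /
    (geometry$frame_shape[1] * geometry$pixel_m)
}

#' Scan pattern of probe positions
#'
#' Stores the metric transverse scan coordinates \eqn{r_i = (x_i, y_i)} and,
#' once a pixel size is known, their (possibly fractional) object-pixel
#' offsets.
#'
#' @param positions_m N x 2 matrix of metric positions, columns `(x, y)`.
#' @param pixel_m Optional effective pixel size used to precompute pixel
#'   offsets.
#' @return Object of class `scan_pattern` with fields `positions_m` and
#'   (if `pixel_m` given) `positions_px`.
#' @export
scan_pattern <- function(positions_m, pixel_m = NULL) {
  positions_m <- as.matrix(positions_m)
  if (ncol(positions_m) != 2L || nrow(positions_m) < 1L)
    stop_ptychor("positions_m must be an N x 2 matrix with N >= 1",
                 class = "ptychor_invalid_input")
  if (any(!is.finite(positions_m)))
    stop_ptychor("positions_m must be finite", class = "ptychor_invalid_input")
  colnames(positions_m) <- c("x_m", "y_m")
  out <- structure(list(positions_m = positions_m, positions_px = NULL),
                   class = "scan_pattern")
  if (!is.null(pixel_m)) {
    check_positive_scalar(pixel_m, "pixel_m")
    out$positions_px <- positions_m / pixel_m
    colnames(out$positions_px) <- c("x_px", "y_px")
  }
  out
}

#' @export
print.scan_pattern <- function(x, ...) {
  cat("Scan pattern:", nrow(x$positions_m), "positions\n")
  cat(sprintf("  x range: [%.4g, %.4g] m;  y range: [%.4g, %.4g] m\n",
              min(x$positions_m[, 1]), max(x$positions_m[, 1]),
              min(x$positions_m[, 2]), max(x$positions_m[, 2])))
  invisible(x)
}

#' Convert metric scan positions to integer pixel offsets
#'
#' Divides metric coordinates by the effective pixel size and rounds to the
#' nearest integer pixel (ties toward even, the IEC 60559 convention used by
#' [round()]). Offsets are returned as 0-based `(row, col)` pairs giving the
#' top-left corner of each probe window on the object canvas; the row axis is
#' y and the column axis is x. Sub-pixel remainders are attached as the
#' `"residual_px"` attribute for diagnostics.
#'
#' @param scan A [scan_pattern()] or an N x 2 metric position matrix
#'   (columns x, y).
#' @param pixel_m Effective pixel size (m).
#' @return Integer N x 2 matrix with columns `(row, col)` and attribute
#'   `residual_px`.
#' @export
positions_to_pixel_offsets <- function(scan, pixel_m) {
  check_positive_scalar(pixel_m, "pixel_m")
  pos <- if (inherits(scan, "scan_pattern")) scan$positions_m else as.matrix(scan)
  px <- pos / pixel_m
  # (x, y) metric -> (row, col) = (y, x) pixel
  frac <- cbind(px[, 2], px[, 1])
  off <- round(frac)
  res <- frac - off
  storage.mode(off) <- "integer"
  colnames(off) <- c("row", "col")
  attr(off, "residual_px") <- res
  off
}

#' Default object canvas size for a scan
#'
#' The canvas must contain every probe window; the default adds a fixed
#' margin of 8 px on every side and shifts the offsets accordingly.
#'
#' @param offsets Integer offsets from [positions_to_pixel_offsets()].
#' @param probe_side Probe frame side M (px).
#' @param margin Margin in pixels added on each side.
#' @return List with `canvas_dim` (rows, cols) and shifted `offsets`.
#' @export
default_canvas <- function(offsets, probe_side, margin = 8L) {
  offsets <- offsets - rep(c(min(offsets[, 1]), min(offsets[, 2])),
                           each = nrow(offsets))
  offsets <- offsets + as.integer(margin)
  dimn <- c(max(offsets[, 1]) + probe_side + margin,
            max(offsets[, 2]) + probe_side + margin)
  list(canvas_dim = as.integer(dimn), offsets = offsets)
}
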