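#' Complex object field
#'
#' The object transmission function O(r) on a padded canvas, with the
#' effective real-space pixel size as metadata.
#'
#' @param values Complex H x W matrix.
#' @param pixel_m Effective pixel size (m).
#' @return Object of class `ptycho_object`.
#' @export
ptycho_object <- function(values, pixel_m) {
  values <- as.matrix(values)
  if (!is.complex(values)) values <- values + 0i
  if (any(!is.finite(values)))
    stop_ptychor("object values must be finite", class = "ptychor_invalid_input")
  check_positive_scalar(pixel_m, "pixel_m")
  structure(list(values = values, pixel_m = pixel_m), class = "ptycho_object")
}

#' @export
print.ptycho_object <- function(x, ...) {
  cat(sprintf("Object field: %d x %d px (pixel %.4g m)\n",
              nrow(x$values), ncol(x$values), x$pixel_m))
  cat(sprintf("  |O| in [%.4g, %.4g], phase in [%.4g, %.4g] rad\n",
              min(Mod(x$values)), max(Mod(x$values)),
              min(Arg(x$values)), max(Arg(x$values))))
  invisible(x)
}

#' Mixed-state probe
#'
#' Stack of K mutually incoherent probe modes sharing one M x M support grid.
#' Relative mode powers (occupancies) are stored in descending order and sum
#' to one after orthogonalization.
#'
#' @param modes Complex M x M matrix (single mode) or M x M x K array.
#' @param occupancies Optional numeric vector of relative powers; defaults to
#'   the normalized mode energies.
#' @return Object of class `ptycho_probe`.
#' @export
ptycho_probe <- function(modes, occupancies = NULL) {
  modes <- as_mode_array(modes)
  if (!is.complex(modes)) modes <- modes + 0i
  if (any(!is.finite(modes)))
    stop_ptychor("probe modes must be finite", class = "ptychor_invalid_input")
  if (dim(modes)[1] != dim(modes)[2])
    stop_ptychor("probe frame must be square", class = "ptychor_invalid_input")
  if (is.null(occupancies)) {
    p <- mode_powers(modes)
    occupancies <- if (sum(p) > 0) p / sum(p) else rep(1 / dim(modes)[3], dim(modes)[3])
  }
  if (length(occupancies) != dim(modes)[3])
    stop_ptychor("occupancies length must equal the number of modes",
                 class = "ptychor_invalid_input")
  structure(list(modes = modes, occupancies = occupancies), class = "ptycho_probe")
}

#' @export
print.ptycho_probe <- function(x, ...) {
  k <- dim(x$modes)[3]
  cat(sprintf("Probe: %d mode%s, %d x %d px\n", k, if (k > 1) "s" else "",
              dim(x$modes)[1], dim(x$modes)[2]))
  cat("  occupancies:", paste(sprintf("%.3f", x$occupancies), collapse = " "), "\n")
  invisible(x)
}

#' Diffraction dataset
#'
#' The data side of the problem: N nonnegative intensity frames, optional
#' per-frame (or shared) binary masks marking trusted detector pixels, the
#' scan pattern and the detector geometry.
#'
#' @param intensities M x M x N array of nonnegative measured intensities.
#' @param scan A [scan_pattern()] with N positions.
#' @param geometry A [detector_geometry()] whose frame matches the data.
#' @param masks Optional M x M matrix (shared) or M x M x N array of 0/1
#'   trusted-pixel masks. Missing masks default to all-ones.
#' @return Object of class `diffraction_stack`.
#' @export
diffraction_stack <- function(intensities, scan, geometry, masks = NULL) {
  stopifnot(inherits(scan, "scan_pattern"), inherits(geometry, "detector_geometry"))
  if (length(dim(intensities)) == 2L)
    intensities <- array(intensities, dim = c(dim(intensities), 1L))
  d <- dim(intensities)
  if (length(d) != 3L)
    stop_ptychor("intensities must be an M x M x N array",
                 class = "ptychor_invalid_input")
  if (any(d[1:2] != geometry$frame_shape))
    stop_ptychor("intensity frame shape ", d[1], "x", d[2],
                 " does not match detector geometry ",
                 geometry$frame_shape[1], "x", geometry$frame_shape[2],
                 class = "ptychor_invalid_input")
  if (d[3] != nrow(scan$positions_m))
    stop_ptychor("got ", d[3], " frames but ", nrow(scan$positions_m),
                 " scan positions", class = "ptychor_invalid_input")
  if (any(intensities < 0))
    stop_ptychor("intensities must be nonnegative",
                 class = "ptychor_invalid_data")
  if (is.null(masks)) {
    masks <- array(1, dim = d)
  } else {
    if (length(dim(masks)) == 2L)
      masks <- array(rep(masks, d[3]), dim = d)
    if (!all(dim(masks) == d))
      stop_ptychor("mask shape does not match intensities",
                   class = "ptychor_invalid_input")
    if (!all(masks %in% c(0, 1)))
      stop_ptychor("masks must be binary", class = "ptychor_invalid_input")
  }
  structure(list(intensities = intensities, masks = masks,
                 scan = scan, geometry = geometry),
            class = "diffraction_stack")
}

#' @export
print.diffraction_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("Diffraction stack: %d frames of %d x %d px\n", d[3], d[1], d[2]))
  cat(sprintf("  total counts %.4g, masked-out fraction %.3f\n",
              sum(x$intensities), 1 - mean(x$masks)))
  print(x$scan)
  invisible(x)
}

#' Number of frames in a diffraction stack
#' @param stack A [diffraction_stack()].
#' @return Integer frame count N.
#' @export
n_frames <- function(stack) dim(stack$intensities)[3]
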