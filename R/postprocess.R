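# Ambiguity removal and quality metrics. A far-field ptychographic
# reconstruction is only defined up to a global phase, a complex scale
# (traded between object and probe), a linear phase ramp (paired with a
# probe shift) and a rigid translation. These are removed here, never inside
# the engines.

weighted_phase_gradient <- function(values, weight) {
  # wrapped-phase-safe gradients via products of neighbouring pixels
  gy_full <- values[-1, , drop = FALSE] * Conj(values[-nrow(values), , drop = FALSE])
  gx_full <- values[, -1, drop = FALSE] * Conj(values[, -ncol(values), drop = FALSE])
  wy <- weight[-1, , drop = FALSE] * weight[-nrow(values), , drop = FALSE]
  wx <- weight[, -1, drop = FALSE] * weight[, -ncol(values), drop = FALSE]
  c(gy = Arg(sum(wy * gy_full)), gx = Arg(sum(wx * gx_full)))
}

#' Remove a linear phase ramp
#'
#' Fits a plane to the (magnitude-squared-weighted) phase gradient of the
#' object — wrapped-phase-safe, via products of neighbouring pixels — then
#' subtracts the integrated ramp and sets the weighted mean phase over the
#' mask to zero.
#'
#' @param object A [ptycho_object()] or complex matrix.
#' @param weight_mask Optional nonnegative weight matrix (defaults to
#'   \eqn{|O|^2}); must keep at least 3 pixels active.
#' @return List with the corrected `object` (same class as the input) and
#'   `ramp_coeffs = c(gy, gx, c)` — per-pixel phase slopes and the removed
#'   global phase.
#' @export
remove_phase_ramp <- function(object, weight_mask = NULL) {
  is_obj <- inherits(object, "ptycho_object")
  values <- if (is_obj) object$values else object
  weight <- weight_mask %||% Mod(values)^2
  if (sum(weight > 0) < 3)
    stop_ptychor("degenerate weight mask: fewer than 3 active pixels",
                 class = "ptychor_invalid_input")
  g <- weighted_phase_gradient(values, weight)
  rows <- seq_len(nrow(values)) - (floor(nrow(values) / 2) + 1)
  cols <- seq_len(ncol(values)) - (floor(ncol(values) / 2) + 1)
  ramp <- outer(rows * g["gy"], cols * g["gx"], `+`)
  corrected <- values * exp(-1i * ramp)
  global <- Arg(sum(weight * corrected))
  corrected <- corrected * exp(-1i * global)
  out <- if (is_obj) ptycho_object(corrected, object$pixel_m) else corrected
  list(object = out,
       ramp_coeffs = c(gy = unname(g["gy"]), gx = unname(g["gx"]),
                       c = global))
}

roll2 <- function(m, dr, dc) {
  n1 <- nrow(m); n2 <- ncol(m)
  dr <- ((dr %% n1) + n1) %% n1
  dc <- ((dc %% n2) + n2) %% n2
  if (dr > 0) m <- m[c((n1 - dr + 1):n1, 1:(n1 - dr)), , drop = FALSE]
  if (dc > 0) m <- m[, c((n2 - dc + 1):n2, 1:(n2 - dc)), drop = FALSE]
  m
}

probe_com <- function(probe) {
  mag <- matrix(0, dim(probe$modes)[1], dim(probe$modes)[2])
  for (k in seq_len(dim(probe$modes)[3])) mag <- mag + Mod(probe$modes[, , k])
  tot <- sum(mag)
  if (tot == 0)
    stop_ptychor("zero probe: center of mass undefined",
                 class = "ptychor_invalid_input")
  c(sum(row(mag) * mag), sum(col(mag) * mag)) / tot
}

#' Center a reconstruction by the probe's center of mass
#'
#' A loose probe support leaves the probe/object pair free to translate
#' rigidly. The center of mass of the summed probe magnitude is rolled to
#' the frame center (integer pixels only, avoiding interpolation) and the
#' object is rolled by the opposite amount; the sub-pixel remainder is
#' reported but not applied.
#'
#' @param result A `ptycho_recon` fit, or a list with `object`
#'   ([ptycho_object()]) and `probe` ([ptycho_probe()]).
#' @return The input with shifted `object`/`probe`, plus attribute
#'   `alignment` carrying `shift_px` (applied integer shift, rows/cols) and
#'   `residual_px`.
#' @export
align_by_probe_com <- function(result) {
  com <- probe_com(result$probe)
  m <- dim(result$probe$modes)[1]
  ctr <- rep(floor(m / 2) + 1, 2)
  shift <- round(ctr - com)
  residual <- (ctr - com) - shift
  modes <- result$probe$modes
  for (k in seq_len(dim(modes)[3]))
    modes[, , k] <- roll2(modes[, , k], shift[1], shift[2])
  result$probe <- ptycho_probe(modes, result$probe$occupancies)
  result$object <- ptycho_object(roll2(result$object$values,
                                       -shift[1], -shift[2]),
                                 result$object$pixel_m)
  attr(result, "alignment") <- list(shift_px = shift, residual_px = residual)
  result
}

#' Scan-coverage mask
#'
#' Canvas mask of pixels genuinely constrained by the data: the accumulated
#' probe intensity footprint over all scan windows, thresholded relative to
#' its maximum.
#'
#' @param offsets Integer 0-based probe-window offsets.
#' @param probe A [ptycho_probe()] or mode array.
#' @param canvas_dim Canvas (rows, cols).
#' @param threshold Relative coverage threshold.
#' @return Logical canvas matrix.
#' @export
scan_coverage_mask <- function(offsets, probe, canvas_dim, threshold = 0.1) {
  modes <- if (inherits(probe, "ptycho_probe")) probe$modes else as_mode_array(probe)
  m <- dim(modes)[1]
  p2 <- matrix(0, m, m)
  for (k in seq_len(dim(modes)[3])) p2 <- p2 + Mod(modes[, , k])^2
  cov <- matrix(0, canvas_dim[1], canvas_dim[2])
  for (i in seq_len(nrow(offsets))) {
    w <- window_index(offsets[i, ], m)
    cov[w$rows, w$cols] <- cov[w$rows, w$cols] + p2
  }
  cov > threshold * max(cov)
}

#' Normalized mean squared error against ground truth
#'
#' Masked NMSE between a reconstructed and a true complex object after
#' removing the inherent ambiguities: the relative linear phase ramp (fitted
#' on the masked product \eqn{O_{rec} \bar O_{true}}) and the global complex
#' scale (closed-form least squares). Returns
#' \eqn{\min_{s} \sum_M |s\,O_{rec} - O_{true}|^2 / \sum_M |O_{true}|^2}.
#'
#' @param recon,truth Complex matrices (or [ptycho_object()]s) of equal
#'   shape.
#' @param mask Optional logical/0-1 matrix restricting the comparison (e.g.
#'   [scan_coverage_mask()]); must not be empty.
#' @param fit_ramp Remove the relative linear phase ramp first?
#' @param shift_radius Integer rigid-registration radius: the NMSE is
#'   minimized over integer rolls of the reconstruction within this many
#'   pixels (0 disables the search). A reconstruction and its probe can
#'   translate together without changing any measurement, and probe-COM
#'   centering undoes that only up to the probe's own shape bias, so
#'   ground-truth registration searches the residual shift explicitly.
#' @return Scalar NMSE in \[0, ...); 0 for a perfect match up to the
#'   ambiguities.
#' @export
nmse_to_ground_truth <- function(recon, truth, mask = NULL, fit_ramp = TRUE,
                                 shift_radius = 0L) {
  rv0 <- if (inherits(recon, "ptycho_object")) recon$values else recon
  tv <- if (inherits(truth, "ptycho_object")) truth$values else truth
  if (!all(dim(rv0) == dim(tv)))
    stop_ptychor("recon and truth shapes differ", class = "ptychor_invalid_input")
  mk0 <- mask %||% matrix(TRUE, nrow(rv0), ncol(rv0))
  mk0 <- mk0 > 0
  if (!any(mk0))
    stop_ptychor("empty comparison mask", class = "ptychor_invalid_input")
  r <- as.integer(shift_radius)
  if (r > 0) {
    best <- Inf
    for (dr in -r:r) for (dc in -r:r) {
      v <- nmse_core(roll2(rv0, dr, dc), tv, mk0, fit_ramp)
      if (v < best) best <- v
    }
    return(best)
  }
  nmse_core(rv0, tv, mk0, fit_ramp)
}

nmse_core <- function(rv, tv, mk, fit_ramp) {
  if (fit_ramp) {
    rel <- rv * Conj(tv)
    w <- (Mod(tv)^2) * mk
    g <- weighted_phase_gradient(rel, w)
    rows <- seq_len(nrow(rv)) - (floor(nrow(rv) / 2) + 1)
    cols <- seq_len(ncol(rv)) - (floor(ncol(rv) / 2) + 1)
    rv <- rv * exp(-1i * outer(rows * g["gy"], cols * g["gx"], `+`))
  }
  num <- sum(Conj(rv[mk]) * tv[mk])
  den <- sum(Mod(rv[mk])^2)
  if (den == 0) return(1)
  s <- num / den
  sum(Mod(s * rv[mk] - tv[mk])^2) / sum(Mod(tv[mk])^2)
}
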