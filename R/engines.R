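# Projection-engine building blocks: exit waves, the modulus (data) projector,
# AP/DM/RAAR wavefront updates, global and sequential (rPIE) object/probe
# updates, probe support, mode orthogonalization and annealing position
# correction. The iteration driver lives in reconstruct.R.

#' Exit wave at one scan position
#'
#' Multiplicative approximation: \eqn{\psi_m = P_m \cdot O} restricted to the
#' probe window anchored at `offset`.
#'
#' @param object A [ptycho_object()] or complex canvas matrix.
#' @param probe A [ptycho_probe()] or complex mode array.
#' @param offset Integer 0-based `(row, col)` top-left window offset.
#' @return Complex M x M x K array of per-mode exit waves.
#' @export
exit_wave <- function(object, probe, offset) {
  ov <- if (inherits(object, "ptycho_object")) object$values else object
  modes <- if (inherits(probe, "ptycho_probe")) probe$modes else as_mode_array(probe)
  m <- dim(modes)[1]
  check_windows_inside(matrix(offset, ncol = 2), m, dim(ov))
  w <- window_index(offset, m)
  win <- ov[w$rows, w$cols]
  out <- modes
  for (k in seq_len(dim(modes)[3])) out[, , k] <- modes[, , k] * win
  out
}

# Modulus projection in the detector plane, shared by project_data and the
# engine updates. Operates on already-propagated detector wavefronts.
modulus_project_detector <- function(psi_det, intensity, mask) {
  k <- dim(psi_det)[3]
  s <- matrix(0, dim(psi_det)[1], dim(psi_det)[2])
  for (j in seq_len(k)) s <- s + Mod(psi_det[, , j])^2
  trusted <- mask > 0
  scale_idx <- trusted & s > 0
  zero_idx <- trusted & s == 0 & intensity > 0
  fac <- sqrt(intensity[scale_idx] / s[scale_idx])
  for (j in seq_len(k)) {
    pj <- psi_det[, , j]
    pj[scale_idx] <- pj[scale_idx] * fac
    # zero-amplitude pixels with measured signal: deposit sqrt(I/K), phase 0
    pj[zero_idx] <- sqrt(intensity[zero_idx] / k)
    psi_det[, , j] <- pj
  }
  psi_det
}

#' Data (modulus) projection of an exit-wave mode ensemble
#'
#' Propagates every probe mode to the detector plane, rescales the mode
#' ensemble at trusted pixels by \eqn{\sqrt{I / \sum_m |\Psi_m|^2}} (the
#' mixed-state modulus constraint, all modes sharing one factor), leaves
#' masked-out pixels unchanged, deposits \eqn{\sqrt{I/K}} at zero phase where
#' the model ensemble has zero amplitude but the measurement does not, and
#' back-propagates.
#'
#' @param psi Complex M x M (single mode) or M x M x K exit-wave array.
#' @param intensity M x M nonnegative measured frame.
#' @param mask M x M binary mask (1 = trusted pixel).
#' @param spec A [propagator()].
#' @return Projected exit-wave array, same shape as `psi`.
#' @export
project_data <- function(psi, intensity, mask, spec) {
  if (any(intensity < 0))
    stop_ptychor("negative intensities", class = "ptychor_invalid_data")
  psi <- as_mode_array(psi)
  det <- psi
  for (j in seq_len(dim(psi)[3])) det[, , j] <- to_detector(psi[, , j], spec)
  det <- modulus_project_detector(det, intensity, mask)
  out <- det
  for (j in seq_len(dim(psi)[3])) out[, , j] <- from_detector(det[, , j], spec)
  out
}

#' Alternating-projections wavefront update
#'
#' The AP (and PIE-family) wavefront update is exactly the data projection
#' \eqn{\psi' = D^{-1} \Pi_M D \psi}; kept as a named alias because the
#' engines name it.
#'
#' @inheritParams project_data
#' @return Updated exit-wave array.
#' @export
ap_update <- function(psi, intensity, mask, spec) {
  project_data(psi, intensity, mask, spec)
}

object_consistency_wave <- function(object_view, probe_modes) {
  out <- probe_modes
  for (k in seq_len(dim(probe_modes)[3]))
    out[, , k] <- probe_modes[, , k] * object_view
  out
}

#' Difference-map wavefront update
#'
#' \eqn{\psi' = \psi + \Pi_M\{2 \Pi_O \psi - \psi\} - \Pi_O \psi}, where
#' \eqn{\Pi_O \psi = P \cdot O} is the object-consistency wave formed from the
#' current object window and probe.
#'
#' @inheritParams project_data
#' @param object_view Complex M x M window of the current object.
#' @param probe A [ptycho_probe()] or mode array.
#' @return Updated exit-wave array.
#' @export
dm_update <- function(psi, intensity, mask, object_view, probe, spec) {
  psi <- as_mode_array(psi)
  modes <- if (inherits(probe, "ptycho_probe")) probe$modes else as_mode_array(probe)
  po <- object_consistency_wave(object_view, modes)
  pm <- project_data(2 * po - psi, intensity, mask, spec)
  psi + pm - po
}

#' RAAR wavefront update
#'
#' Relaxed averaged alternating reflections:
#' \eqn{\psi' = \beta(\psi + \Pi_M\{2 \Pi_O \psi - \psi\}) + (1 - 2\beta) \Pi_O \psi}
#' with relaxation \eqn{\beta \in [0, 1]}. At \eqn{\beta = 1} this coincides
#' with the difference-map update; at \eqn{\beta = 0} it returns
#' \eqn{\Pi_O \psi}.
#'
#' @inheritParams dm_update
#' @param beta Relaxation parameter in \[0, 1\].
#' @return Updated exit-wave array.
#' @export
raar_update <- function(psi, intensity, mask, object_view, probe, beta, spec) {
  if (beta < 0 || beta > 1)
    stop_ptychor("beta must lie in [0, 1]", class = "ptychor_invalid_input")
  psi <- as_mode_array(psi)
  modes <- if (inherits(probe, "ptycho_probe")) probe$modes else as_mode_array(probe)
  po <- object_consistency_wave(object_view, modes)
  pm <- project_data(2 * po - psi, intensity, mask, spec)
  beta * (psi + pm) + (1 - 2 * beta) * po
}

#' Partial normalized-misfit accumulation for a batch
#'
#' Accumulates the two scalars of the normalized intensity misfit
#' \eqn{\epsilon = \sum_i \sum_{uv} M (I_i - \sum_m |D \psi_{im}|^2)^2 / \sum_i \sum_{uv} M I_i}
#' for the supplied wavefronts. The amplitude-residual variant
#' (`metric = "amplitude"`) squares \eqn{\sqrt{I} - |D\psi|} instead.
#'
#' @param intensity_list List of M x M measured frames.
#' @param psi_list List of M x M x K exit-wave arrays (same length).
#' @param mask_list List of M x M binary masks.
#' @param spec A [propagator()].
#' @param metric `"intensity"` (printed form) or `"amplitude"`.
#' @return List with scalars `err_num` and `err_den`.
#' @export
batch_error <- function(intensity_list, psi_list, mask_list, spec,
                        metric = c("intensity", "amplitude")) {
  metric <- match.arg(metric)
  num <- 0; den <- 0
  for (i in seq_along(psi_list)) {
    psi <- as_mode_array(psi_list[[i]])
    model <- matrix(0, dim(psi)[1], dim(psi)[2])
    for (k in seq_len(dim(psi)[3]))
      model <- model + Mod(to_detector(psi[, , k], spec))^2
    mk <- mask_list[[i]]
    ii <- intensity_list[[i]]
    if (metric == "intensity") {
      num <- num + sum(mk * (ii - model)^2)
      den <- den + sum(mk * ii)
    } else {
      num <- num + sum(mk * (sqrt(ii) - sqrt(model))^2)
      den <- den + sum(mk * ii)
    }
  }
  list(err_num = num, err_den = den)
}

#' Fresh update accumulator
#'
#' Numerator/denominator canvases for the global object and probe updates,
#' plus the misfit scalars. Accumulators are additive under batch
#' concatenation, which is what makes batched and multi-worker reconstruction
#' exactly equivalent to the monolithic update.
#'
#' @param canvas_dim Object canvas (rows, cols).
#' @param probe_side Probe frame side M.
#' @param n_modes Number of probe modes K.
#' @return Object of class `update_accumulator`.
#' @export
new_accumulator <- function(canvas_dim, probe_side, n_modes = 1L) {
  structure(list(
    obj_num = complex_matrix(canvas_dim[1], canvas_dim[2]),
    obj_den = matrix(0, canvas_dim[1], canvas_dim[2]),
    probe_num = array(0 + 0i, dim = c(probe_side, probe_side, n_modes)),
    probe_den = matrix(0, probe_side, probe_side),
    err_num = 0, err_den = 0),
    class = "update_accumulator")
}

#' Add one batch of updated wavefronts into an accumulator
#'
#' For each scan index: `obj_num[window] += sum_m conj(P_m) psi_m`,
#' `obj_den[window] += sum_m |P_m|^2`, `probe_num_m += conj(O[window]) psi_m`,
#' `probe_den += |O[window]|^2`.
#'
#' @param psi_list List of updated M x M x K exit-wave arrays.
#' @param probe A [ptycho_probe()] or mode array (current iterate).
#' @param object A [ptycho_object()] or canvas matrix (current iterate).
#' @param offsets Integer 0-based offset matrix, one row per list element.
#' @param acc An [new_accumulator()] to add into.
#' @return The updated accumulator.
#' @export
accumulate_updates <- function(psi_list, probe, object, offsets, acc) {
  ov <- if (inherits(object, "ptycho_object")) object$values else object
  modes <- if (inherits(probe, "ptycho_probe")) probe$modes else as_mode_array(probe)
  m <- dim(modes)[1]
  nk <- dim(modes)[3]
  check_windows_inside(offsets, m, dim(ov))
  probe_abs2 <- matrix(0, m, m)
  for (k in seq_len(nk)) probe_abs2 <- probe_abs2 + Mod(modes[, , k])^2
  for (i in seq_along(psi_list)) {
    psi <- as_mode_array(psi_list[[i]])
    w <- window_index(offsets[i, ], m)
    win <- ov[w$rows, w$cols]
    num <- complex_matrix(m, m)
    for (k in seq_len(nk)) {
      num <- num + Conj(modes[, , k]) * psi[, , k]
      acc$probe_num[, , k] <- acc$probe_num[, , k] + Conj(win) * psi[, , k]
    }
    acc$obj_num[w$rows, w$cols] <- acc$obj_num[w$rows, w$cols] + num
    acc$obj_den[w$rows, w$cols] <- acc$obj_den[w$rows, w$cols] + probe_abs2
    acc$probe_den <- acc$probe_den + Mod(win)^2
  }
  acc
}

#' Apply the global (parallel) object and probe updates
#'
#' \eqn{O' = \sum_i P^* \psi_i / \sum_i |P|^2} and its probe analogue,
#' regularized by `eps_frac * max(denominator)` so empty denominators stay
#' harmless. Canvas pixels never visited by any probe window keep their prior
#' object value.
#'
#' @param acc A completed [new_accumulator()].
#' @param object,probe Prior iterates (used for unvisited pixels and when the
#'   probe update is frozen).
#' @param eps_frac Relative regularization of the divisions (scale-invariant).
#' @param update_probe Logical: apply the probe update this iteration?
#' @return List with updated `object` ([ptycho_object()]) and `probe`
#'   ([ptycho_probe()]).
#' @export
apply_global_updates <- function(acc, object, probe, eps_frac = 1e-6,
                                 update_probe = TRUE) {
  stopifnot(inherits(acc, "update_accumulator"))
  ov <- if (inherits(object, "ptycho_object")) object$values else object
  modes <- if (inherits(probe, "ptycho_probe")) probe$modes else as_mode_array(probe)
  eps_o <- eps_frac * max(acc$obj_den, 0)
  visited <- acc$obj_den > 0
  newo <- ov
  newo[visited] <- acc$obj_num[visited] / (acc$obj_den[visited] + eps_o)
  newp <- modes
  if (update_probe) {
    eps_p <- eps_frac * max(acc$probe_den, 0)
    for (k in seq_len(dim(modes)[3]))
      newp[, , k] <- acc$probe_num[, , k] / (acc$probe_den + eps_p)
  }
  list(object = ptycho_object(newo, if (inherits(object, "ptycho_object"))
         object$pixel_m else 1),
       probe = ptycho_probe(newp))
}

#' rPIE sequential object update
#'
#' \eqn{O' = O + s_o P^* (\psi' - \psi) / ((1 - r_o)|P|^2 + r_o |P|^2_{max})}
#' on the current window, with step size `s_o` and regularization
#' `r_o` in (0, 1\]. With several probe modes the numerator sums over modes
#' and \eqn{|P|^2} is the mode-summed probe intensity.
#'
#' @param object_view Complex M x M window of the current object.
#' @param probe A [ptycho_probe()] or mode array.
#' @param psi,psi_prime Exit-wave arrays before/after the data projection.
#' @param s_o Step size (> 0).
#' @param r_o Regularization in (0, 1\] (0 allowed only for nowhere-zero
#'   probes).
#' @return Updated M x M object window.
#' @export
rpie_object_update <- function(object_view, probe, psi, psi_prime, s_o, r_o) {
  modes <- if (inherits(probe, "ptycho_probe")) probe$modes else as_mode_array(probe)
  psi <- as_mode_array(psi); psi_prime <- as_mode_array(psi_prime)
  p2 <- matrix(0, dim(modes)[1], dim(modes)[2])
  num <- complex_matrix(dim(modes)[1], dim(modes)[2])
  for (k in seq_len(dim(modes)[3])) {
    p2 <- p2 + Mod(modes[, , k])^2
    num <- num + Conj(modes[, , k]) * (psi_prime[, , k] - psi[, , k])
  }
  den <- (1 - r_o) * p2 + r_o * max(p2)
  if (any(den == 0))
    stop_ptychor("rPIE object update: zero denominator (all-zero probe with r_o = 0)",
                 class = "ptychor_division_guard")
  object_view + s_o * num / den
}

#' rPIE sequential probe update
#'
#' Mirror of [rpie_object_update()]:
#' \eqn{P'_m = P_m + s_p O^* (\psi'_m - \psi_m) / ((1 - r_p)|O|^2 + r_p |O|^2_{max})}.
#'
#' @inheritParams rpie_object_update
#' @param s_p,r_p Probe step size and regularization.
#' @return Updated M x M x K mode array.
#' @export
rpie_probe_update <- function(object_view, probe, psi, psi_prime, s_p, r_p) {
  modes <- if (inherits(probe, "ptycho_probe")) probe$modes else as_mode_array(probe)
  psi <- as_mode_array(psi); psi_prime <- as_mode_array(psi_prime)
  o2 <- Mod(object_view)^2
  den <- (1 - r_p) * o2 + r_p * max(o2)
  if (any(den == 0))
    stop_ptychor("rPIE probe update: zero denominator (all-zero object window with r_p = 0)",
                 class = "ptychor_division_guard")
  out <- modes
  for (k in seq_len(dim(modes)[3]))
    out[, , k] <- modes[, , k] +
      s_p * Conj(object_view) * (psi_prime[, , k] - psi[, , k]) / den
  out
}

#' One momentum acceleration step (mPIE)
#'
#' Heavy-ball acceleration applied every fixed number of position updates:
#' `v <- friction * v + (x_now - x_checkpoint)`, then
#' `x <- x_now + friction * v`, after which the checkpoint is refreshed to the
#' pre-acceleration iterate `x_now` (so the next velocity term measures only
#' the plain-update progress, not the acceleration itself — refreshing to the
#' accelerated iterate double-counts the boost and destabilizes the sweep).
#' With `friction = 0` the iterate is unchanged (the documented no-op).
#'
#' @param x_now Current array (object canvas or probe modes).
#' @param x_checkpoint Value at the last momentum step.
#' @param velocity Velocity buffer (same shape; zeros at first call).
#' @param friction Friction coefficient in \[0, 1).
#' @return List with accelerated `x`, updated `velocity`, and the refreshed
#'   `checkpoint`.
#' @export
momentum_step <- function(x_now, x_checkpoint, velocity, friction) {
  v <- friction * velocity + (x_now - x_checkpoint)
  x <- x_now + friction * v
  list(x = x, velocity = v, checkpoint = x_now)
}

#' Circular probe support constraint
#'
#' Zeroes all probe modes outside a centred disk of the given physical
#' diameter. A disk at least as large as the frame diagonal cannot constrain
#' anything and is skipped with a message.
#'
#' @param probe A [ptycho_probe()].
#' @param diameter_m Support diameter (m).
#' @param pixel_m Probe-plane pixel size (m).
#' @return Constrained [ptycho_probe()]. Idempotent.
#' @export
apply_probe_support <- function(probe, diameter_m, pixel_m) {
  check_positive_scalar(diameter_m, "diameter_m")
  check_positive_scalar(pixel_m, "pixel_m")
  m <- dim(probe$modes)[1]
  d_px <- diameter_m / pixel_m
  if (d_px >= sqrt(2) * m) {
    message("probe support wider than the frame diagonal: no-op")
    return(probe)
  }
  ctr <- floor(m / 2) + 1L
  idx <- seq_len(m) - ctr
  inside <- outer(idx^2, idx^2, `+`) < (d_px / 2)^2
  modes <- probe$modes
  for (k in seq_len(dim(modes)[3])) modes[, , k] <- modes[, , k] * inside
  ptycho_probe(modes, probe$occupancies)
}

#' Orthogonalize probe modes
#'
#' Replaces the mode stack by an orthogonal set spanning the same space,
#' ordered by decreasing power, via the eigendecomposition of the K x K Gram
#' matrix. Total power is conserved; occupancies are refreshed from the
#' eigenvalues. A rank-deficient stack keeps its zero modes last with a
#' warning.
#'
#' @param probe A [ptycho_probe()] with K >= 2 modes (K = 1 returns as-is).
#' @return Orthogonalized [ptycho_probe()].
#' @export
orthogonalize_probe_modes <- function(probe) {
  modes <- probe$modes
  k <- dim(modes)[3]
  if (k < 2L) return(probe)
  x <- matrix(modes, ncol = k)           # M^2 x K
  gram <- crossprod(Conj(x), x)          # K x K Hermitian
  eig <- eigen(gram, symmetric = TRUE)
  vals <- pmax(Re(eig$values), 0)
  if (any(vals < 1e-12 * max(vals)))
    warning("rank-deficient probe mode stack: zero modes kept last",
            call. = FALSE)
  newx <- x %*% eig$vectors
  newmodes <- array(newx, dim = dim(modes))
  occ <- if (sum(vals) > 0) vals / sum(vals) else rep(1 / k, k)
  ptycho_probe(newmodes, occ)
}

# Split accumulation helpers used by the two-pass overlap update in the
# driver: the object numerator/denominator are accumulated with the current
# probe, the probe numerator/denominator afterwards with the already-updated
# object (the sequential form of the overlap constraint, which is what keeps
# the joint object/probe iteration stable).
accumulate_object_partial <- function(psi_list, probe_modes, offsets, acc) {
  m <- dim(probe_modes)[1]
  nk <- dim(probe_modes)[3]
  probe_abs2 <- matrix(0, m, m)
  for (k in seq_len(nk)) probe_abs2 <- probe_abs2 + Mod(probe_modes[, , k])^2
  for (i in seq_along(psi_list)) {
    psi <- psi_list[[i]]
    w <- window_index(offsets[i, ], m)
    num <- complex_matrix(m, m)
    for (k in seq_len(nk)) num <- num + Conj(probe_modes[, , k]) * psi[, , k]
    acc$obj_num[w$rows, w$cols] <- acc$obj_num[w$rows, w$cols] + num
    acc$obj_den[w$rows, w$cols] <- acc$obj_den[w$rows, w$cols] + probe_abs2
  }
  acc
}

accumulate_probe_partial <- function(psi_list, object_values, offsets, acc) {
  nk <- dim(acc$probe_num)[3]
  m <- dim(acc$probe_num)[1]
  for (i in seq_along(psi_list)) {
    psi <- psi_list[[i]]
    w <- window_index(offsets[i, ], m)
    win <- object_values[w$rows, w$cols]
    for (k in seq_len(nk))
      acc$probe_num[, , k] <- acc$probe_num[, , k] + Conj(win) * psi[, , k]
    acc$probe_den <- acc$probe_den + Mod(win)^2
  }
  acc
}

frame_residual <- function(object_values, probe_modes, offset, intensity,
                           mask, spec) {
  psi <- exit_wave(object_values, probe_modes, offset)
  model <- matrix(0, dim(psi)[1], dim(psi)[2])
  for (k in seq_len(dim(psi)[3]))
    model <- model + Mod(to_detector(psi[, , k], spec))^2
  sum(mask * (intensity - model)^2)
}

#' Annealing scan-position correction
#'
#' For every frame, evaluates the single-frame squared intensity residual at
#' the current integer offset and at candidate integer offsets within
#' `radius_px`, keeping the argmin (the current position wins ties, so exact
#' positions on noiseless data are never disturbed). Candidates are either
#' `trials` uniform random offsets (deterministic under `seed`) or the full
#' square neighbourhood (`trials = "exhaustive"`). The caller shrinks
#' `radius_px` by a cooling factor between outer iterations.
#'
#' @param object A [ptycho_object()] or canvas matrix.
#' @param probe A [ptycho_probe()] or mode array.
#' @param stack A [diffraction_stack()].
#' @param offsets Current integer offsets (0-based rows/cols).
#' @param radius_px Search radius in pixels; 0 is a no-op.
#' @param trials Number of random candidate offsets per frame, or
#'   `"exhaustive"`.
#' @param spec A [propagator()].
#' @param seed RNG seed for the candidate draws.
#' @return Updated offset matrix with attribute `n_moved`.
#' @export
anneal_positions <- function(object, probe, stack, offsets, radius_px = 2L,
                             trials = 8L, spec = NULL, seed = 1L) {
  if (radius_px <= 0) {
    attr(offsets, "n_moved") <- 0L
    return(offsets)
  }
  ov <- if (inherits(object, "ptycho_object")) object$values else object
  modes <- if (inherits(probe, "ptycho_probe")) probe$modes else as_mode_array(probe)
  m <- dim(modes)[1]
  spec <- spec %||% propagator_for_geometry(stack$geometry)
  r <- as.integer(ceiling(radius_px))
  if (identical(trials, "exhaustive")) {
    cand <- as.matrix(expand.grid(dr = -r:r, dc = -r:r))
    cand <- cand[!(cand[, 1] == 0 & cand[, 2] == 0), , drop = FALSE]
  } else {
    set.seed(seed)
    cand <- NULL
  }
  n_moved <- 0L
  for (i in seq_len(n_frames(stack))) {
    ci <- if (is.null(cand)) {
      cbind(sample(-r:r, trials, replace = TRUE),
            sample(-r:r, trials, replace = TRUE))
    } else cand
    best <- frame_residual(ov, modes, offsets[i, ], stack$intensities[, , i],
                           stack$masks[, , i], spec)
    best_off <- offsets[i, ]
    for (j in seq_len(nrow(ci))) {
      trial <- offsets[i, ] + ci[j, ]
      if (trial[1] < 0 || trial[2] < 0 ||
          trial[1] + m > nrow(ov) || trial[2] + m > ncol(ov)) next
      res <- frame_residual(ov, modes, trial, stack$intensities[, , i],
                            stack$masks[, , i], spec)
      if (res < best) { best <- res; best_off <- trial }
    }
    if (any(best_off != offsets[i, ])) n_moved <- n_moved + 1L
    offsets[i, ] <- best_off
  }
  attr(offsets, "n_moved") <- n_moved
  offsets
}
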