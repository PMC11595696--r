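# Cost-function refinement: gamma-parameterized intensity misfit with
# Poisson (gamma = 1/2) and Gaussian (gamma = 1) surrogates, analytic
# Wirtinger gradients, and a monotone backtracking descent loop. Typically
# warm-started from a projection-engine result.

ml_offsets <- function(object, stack) {
  px <- if (inherits(object, "ptycho_object")) object$pixel_m else
    effective_pixel_size(stack$geometry)
  positions_to_pixel_offsets(stack$scan, px)
}

#' Maximum-likelihood data misfit
#'
#' \eqn{C = \sum_i \sum_{uv} M_i ((\sum_m |D\{\psi_{im}\}|^2)^\gamma - I_i^\gamma)^2}
#' over all frames, with the mode-summed model intensity. `gamma = 1/2` is
#' the amplitude-domain (Poisson-surrogate) misfit, `gamma = 1` the
#' intensity-domain (Gaussian-surrogate) misfit.
#'
#' @param object A [ptycho_object()].
#' @param probe A [ptycho_probe()].
#' @param stack A [diffraction_stack()].
#' @param gamma 1/2 or 1.
#' @param offsets Optional precomputed integer offsets.
#' @return Scalar cost.
#' @export
ml_cost <- function(object, probe, stack, gamma = 0.5, offsets = NULL) {
  if (!gamma %in% c(0.5, 1))
    stop_ptychor("gamma must be 1/2 or 1", class = "ptychor_invalid_input")
  if (any(stack$intensities < 0))
    stop_ptychor("negative intensities", class = "ptychor_invalid_data")
  offsets <- offsets %||% ml_offsets(object, stack)
  spec <- propagator_for_geometry(stack$geometry)
  cost <- 0
  for (i in seq_len(n_frames(stack))) {
    psi <- exit_wave(object, probe, offsets[i, ])
    model <- matrix(0, dim(psi)[1], dim(psi)[2])
    for (k in seq_len(dim(psi)[3]))
      model <- model + Mod(to_detector(psi[, , k], spec))^2
    cost <- cost + sum(stack$masks[, , i] *
                         (model^gamma - stack$intensities[, , i]^gamma)^2)
  }
  cost
}

#' Analytic gradient of the maximum-likelihood misfit
#'
#' Exact gradient of [ml_cost()] with respect to the real and imaginary parts
#' of the object canvas and of each probe mode, assembled by back-propagating
#' the detector-plane residual through the adjoint (= inverse, the operator
#' being unitary) propagator and the multiplicative model. The returned
#' complex arrays `G` encode the real-parameter gradient as
#' `dC/dRe(z) = Re(G)`, `dC/dIm(z) = Im(G)` (i.e. `G = 2 dC/dz̄`). Pixels
#' where the model ensemble intensity vanishes contribute zero at
#' `gamma = 1/2` (subgradient convention). Masked-out pixels contribute
#' nothing.
#'
#' @inheritParams ml_cost
#' @return List with complex arrays `grad_object` (canvas-shaped) and
#'   `grad_probe` (mode-shaped).
#' @export
ml_gradient <- function(object, probe, stack, gamma = 0.5, offsets = NULL) {
  if (!gamma %in% c(0.5, 1))
    stop_ptychor("gamma must be 1/2 or 1", class = "ptychor_invalid_input")
  offsets <- offsets %||% ml_offsets(object, stack)
  spec <- propagator_for_geometry(stack$geometry)
  ov <- object$values
  modes <- probe$modes
  m <- dim(modes)[1]; nk <- dim(modes)[3]
  grad_o <- complex_matrix(nrow(ov), ncol(ov))
  grad_p <- array(0 + 0i, dim = dim(modes))
  for (i in seq_len(n_frames(stack))) {
    w <- window_index(offsets[i, ], m)
    win <- ov[w$rows, w$cols]
    det <- array(0 + 0i, dim = c(m, m, nk))
    model <- matrix(0, m, m)
    for (k in seq_len(nk)) {
      det[, , k] <- to_detector(modes[, , k] * win, spec)
      model <- model + Mod(det[, , k])^2
    }
    r <- model^gamma - stack$intensities[, , i]^gamma
    # dC/dPsi_bar = 2 gamma r model^(gamma-1) Psi, masked
    wgt <- if (gamma == 1) 2 * r else {
      out <- matrix(0, m, m)
      nz <- model > 0
      out[nz] <- r[nz] / sqrt(model[nz])
      out
    }
    wgt <- wgt * stack$masks[, , i]
    for (k in seq_len(nk)) {
      wk <- from_detector(wgt * det[, , k], spec)   # dC/dpsi_bar
      grad_o[w$rows, w$cols] <- grad_o[w$rows, w$cols] +
        2 * Conj(modes[, , k]) * wk
      grad_p[, , k] <- grad_p[, , k] + 2 * Conj(win) * wk
    }
  }
  list(grad_object = grad_o, grad_probe = grad_p)
}

#' Maximum-likelihood refinement loop
#'
#' Joint steepest descent on object and probe with either a fixed step or
#' Armijo backtracking (the default; guarantees a monotone non-increasing
#' cost sequence). Stops when the relative cost decrease falls below `tol`,
#' when `max_iters` is reached, or (fixed step only, with a diagnostic error)
#' when the cost doubles from its starting value.
#'
#' @inheritParams ml_cost
#' @param step_rule `"backtracking"` or `"fixed"`.
#' @param step0 Initial/fixed step size; `NULL` auto-scales from the first
#'   gradient (Cauchy-like `C / ||G||^2`).
#' @param armijo_c Armijo sufficient-decrease constant.
#' @param shrink Backtracking shrink factor.
#' @param max_iters Iteration cap.
#' @param tol Relative cost-decrease threshold; `Inf` returns after the
#'   initial cost evaluation.
#' @return List with refined `object`, `probe`, the `cost_trace` (first
#'   element is the warm-start cost) and `accepted_steps`.
#' @export
run_ml_refinement <- function(object, probe, stack, gamma = 0.5,
                              step_rule = c("backtracking", "fixed"),
                              step0 = NULL, armijo_c = 1e-4, shrink = 0.5,
                              max_iters = 50L, tol = 1e-6, offsets = NULL) {
  step_rule <- match.arg(step_rule)
  offsets <- offsets %||% ml_offsets(object, stack)
  cost <- ml_cost(object, probe, stack, gamma, offsets)
  trace <- cost
  steps <- numeric(0)
  if (is.infinite(tol))
    return(list(object = object, probe = probe, cost_trace = trace,
                accepted_steps = steps))
  alpha <- step0
  for (it in seq_len(max_iters)) {
    g <- ml_gradient(object, probe, stack, gamma, offsets)
    gnorm2 <- sum(Mod(g$grad_object)^2) + sum(Mod(g$grad_probe)^2)
    if (gnorm2 == 0) break
    if (is.null(alpha)) alpha <- cost / gnorm2
    if (step_rule == "fixed") {
      object$values <- object$values - alpha * g$grad_object
      probe$modes <- probe$modes - alpha * g$grad_probe
      cost_new <- ml_cost(object, probe, stack, gamma, offsets)
      if (cost_new > 2 * trace[1])
        stop_ptychor("divergent fixed-step descent: cost doubled (",
                     format(cost_new), " vs start ", format(trace[1]),
                     "); reduce step0", class = "ptychor_divergence")
      steps <- c(steps, alpha)
    } else {
      a <- alpha
      accepted <- FALSE
      for (bt in 1:40) {
        o_try <- object$values - a * g$grad_object
        p_try <- probe$modes - a * g$grad_probe
        cost_try <- ml_cost(ptycho_object(o_try, object$pixel_m),
                            ptycho_probe(p_try, probe$occupancies),
                            stack, gamma, offsets)
        if (cost_try <= cost - armijo_c * a * gnorm2) {
          object$values <- o_try
          probe$modes <- p_try
          cost_new <- cost_try
          steps <- c(steps, a)
          alpha <- a * 2          # optimistic growth for the next iteration
          accepted <- TRUE
          break
        }
        a <- a * shrink
      }
      if (!accepted) break        # no admissible step: converged/stalled
    }
    trace <- c(trace, cost_new)
    if ((cost - cost_new) <= tol * max(cost, .Machine$double.eps)) {
      cost <- cost_new
      break
    }
    cost <- cost_new
  }
  list(object = object, probe = probe, cost_trace = trace,
       accepted_steps = steps)
}
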