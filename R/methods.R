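# S3 methods of the fitted-reconstruction class.

#' @export
print.ptycho_recon <- function(x, ...) {
  cat("Ptychographic reconstruction\n")
  cat(sprintf("  engines   : %s\n",
              paste(sprintf("%s (%d it)", x$config$engine,
                            x$config$iterations), collapse = " -> ")))
  cat(sprintf("  frames    : %d of %d x %d px\n", n_frames(x$stack),
              x$stack$geometry$frame_shape[1], x$stack$geometry$frame_shape[2]))
  cat(sprintf("  object    : %d x %d px (pixel %.4g m)\n",
              nrow(x$object$values), ncol(x$object$values), x$object$pixel_m))
  cat(sprintf("  probe     : %d mode(s)\n", dim(x$probe$modes)[3]))
  if (length(x$error_trace))
    cat(sprintf("  misfit    : %.4g (final of %d iterations)\n",
                utils::tail(x$error_trace, 1), length(x$error_trace)))
  if (length(x$ml_cost_trace))
    cat(sprintf("  ML cost   : %.4g (final)\n",
                utils::tail(x$ml_cost_trace, 1)))
  invisible(x)
}

#' @export
summary.ptycho_recon <- function(object, ...) {
  x <- object
  res <- residuals(x)
  out <- list(
    engines = x$config$engine, iterations = x$config$iterations,
    n_frames = n_frames(x$stack),
    final_misfit = if (length(x$error_trace))
      utils::tail(x$error_trace, 1) else NA_real_,
    per_frame_misfit = summary(res),
    occupancies = x$probe$occupancies,
    canvas_dim = dim(x$object$values))
  class(out) <- "summary.ptycho_recon"
  out
}

#' @export
print.summary.ptycho_recon <- function(x, ...) {
  cat("Ptychographic reconstruction summary\n")
  cat("  engines:", paste(x$engines, collapse = " -> "), "\n")
  cat(sprintf("  final normalized misfit: %.4g over %d frames\n",
              x$final_misfit, x$n_frames))
  cat("  per-frame misfit quartiles:\n")
  print(x$per_frame_misfit)
  cat("  probe occupancies:",
      paste(sprintf("%.3f", x$occupancies), collapse = " "), "\n")
  invisible(x)
}

#' Model intensities of a fitted reconstruction
#'
#' Evaluates the forward model of the fitted object/probe at the (possibly
#' corrected) scan positions, returning the predicted intensity frames.
#'
#' @param object A `ptycho_recon` fit.
#' @param ... Unused.
#' @return M x M x N array of model intensities.
#' @export
predict.ptycho_recon <- function(object, ...) {
  x <- object
  spec <- propagator_for_geometry(x$stack$geometry)
  m <- x$stack$geometry$frame_shape[1]
  n <- nrow(x$offsets)
  out <- array(0, dim = c(m, m, n))
  for (i in seq_len(n)) {
    md <- model_detector_waves(x$object$values, x$probe$modes,
                               x$offsets[i, ], spec)
    out[, , i] <- md$model
  }
  out
}

#' Per-frame normalized residuals
#'
#' Masked normalized intensity misfit of each frame:
#' \eqn{\sum_{uv} M (I - \hat I)^2 / \sum_{uv} M I}.
#'
#' @param object A `ptycho_recon` fit.
#' @param ... Unused.
#' @return Numeric vector of length N.
#' @export
residuals.ptycho_recon <- function(object, ...) {
  x <- object
  model <- predict(x)
  vapply(seq_len(dim(model)[3]), function(i) {
    mk <- x$stack$masks[, , i]
    sum(mk * (x$stack$intensities[, , i] - model[, , i])^2) /
      sum(mk * x$stack$intensities[, , i])
  }, numeric(1))
}

#' Simulate noisy datasets from a fitted reconstruction
#'
#' Parametric simulation: draws Poisson counting noise around the fitted
#' model intensities at the requested photon budget.
#'
#' @param object A `ptycho_recon` fit.
#' @param nsim Number of simulated datasets.
#' @param seed RNG seed.
#' @param photons_per_frame Mean photon budget per frame.
#' @param ... Unused.
#' @return List of `nsim` [diffraction_stack()] objects.
#' @export
simulate.ptycho_recon <- function(object, nsim = 1, seed = 1L,
                                  photons_per_frame = 1e6, ...) {
  x <- object
  model <- predict(x)
  base <- diffraction_stack(model, x$positions, x$stack$geometry,
                            x$stack$masks)
  lapply(seq_len(nsim), function(k)
    apply_counting_noise(base, photons_per_frame, seed = seed + k - 1L))
}

#' Plot a fitted reconstruction
#'
#' Four panels: object magnitude, object phase, probe magnitude (principal
#' mode) and the convergence trace.
#'
#' @param x A `ptycho_recon` fit.
#' @param ... Unused.
#' @export
plot.ptycho_recon <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(2.5, 2.5, 2, 1))
  on.exit(graphics::par(op))
  img <- function(m, main) graphics::image(
    t(m[nrow(m):1, ]), col = grDevices::gray.colors(128), axes = FALSE,
    main = main, useRaster = TRUE)
  img(Mod(x$object$values), "object magnitude")
  img(Arg(x$object$values), "object phase")
  img(Mod(x$probe$modes[, , 1]), "probe magnitude (mode 1)")
  if (length(x$error_trace))
    graphics::plot(x$error_trace, type = "l", log = "y",
                   xlab = "iteration", ylab = "normalized misfit",
                   main = "convergence")
  invisible(x)
}
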