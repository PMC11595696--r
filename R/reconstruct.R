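# Iteration driver: one fitting front-end dispatching per engine, plus the
# S3 methods of the fitted-reconstruction class.

ENGINE_CHOICES <- c("ap", "dm", "raar", "rpie", "mpie", "ml")

default_object_init <- function(canvas_dim, pixel_m) {
  # random magnitude close to unity, constant (zero) phase
  mag <- matrix(stats::runif(prod(canvas_dim), 0.9, 1.0),
                canvas_dim[1], canvas_dim[2])
  ptycho_object(mag + 0i, pixel_m)
}

default_probe_init <- function(stack, spec, n_modes = 1L) {
  avg <- matrix(0, stack$geometry$frame_shape[1], stack$geometry$frame_shape[2])
  for (i in seq_len(n_frames(stack))) avg <- avg + stack$intensities[, , i]
  avg <- avg / n_frames(stack)
  # principal mode: back-propagated square root of the frame-averaged data
  p0 <- from_detector(sqrt(avg) + 0i, spec)
  m <- dim(p0)[1]
  modes <- array(0 + 0i, dim = c(m, m, n_modes))
  modes[, , 1] <- p0
  if (n_modes > 1L) {
    amp <- sqrt(sum(Mod(p0)^2) / (m * m)) * 0.1
    for (k in 2:n_modes)
      modes[, , k] <- amp * (matrix(stats::rnorm(m * m), m, m) +
                               1i * matrix(stats::rnorm(m * m), m, m))
  }
  ptycho_probe(modes)
}

model_detector_waves <- function(object_values, modes, offset, spec) {
  m <- dim(modes)[1]
  w <- window_index(offset, m)
  win <- object_values[w$rows, w$cols]
  det <- array(0 + 0i, dim = dim(modes))
  model <- matrix(0, m, m)
  for (k in seq_len(dim(modes)[3])) {
    det[, , k] <- to_detector(modes[, , k] * win, spec)
    model <- model + Mod(det[, , k])^2
  }
  list(det = det, model = model, win = win, w = w)
}

err_terms <- function(intensity, model, mask, metric) {
  if (metric == "intensity")
    c(sum(mask * (intensity - model)^2), sum(mask * intensity))
  else
    c(sum(mask * (sqrt(intensity) - sqrt(model))^2), sum(mask * intensity))
}

#' Reconstruction configuration
#'
#' Validates and bundles engine parameters. Most users call
#' [ptycho_reconstruct()] directly, which builds the configuration from its
#' arguments; `recon_config` exists for programmatic use and config echoes.
#'
#' @param engine Character vector of engine stages, each one of
#'   `"ap", "dm", "raar", "rpie", "mpie", "ml"`; several entries chain stages.
#' @param iterations Integer iteration count per stage (recycled to the
#'   number of stages).
#' @param beta RAAR relaxation in \[0, 1\].
#' @param step_o,step_p rPIE step sizes (> 0).
#' @param reg_o,reg_p rPIE regularizers in (0, 1\].
#' @param gamma ML exponent, 1/2 or 1.
#' @param batch_size Batch size B for the parallel engines; `NULL` means all
#'   frames in one batch. rPIE/mPIE are sequential by construction and force
#'   B = 1: requesting more is a validation error.
#' @param n_workers Emulated worker count W for the parallel engines.
#' @param probe_support_diameter_m Optional circular probe-support diameter.
#' @param probe_update_start First (cumulative) iteration at which the probe
#'   is updated; earlier iterations keep the initial probe (stabilization).
#' @param momentum `NULL`, `TRUE` (defaults: friction 0.3, interval = one
#'   sweep) or a list with `friction` and `interval`; mPIE enables it by
#'   default. Joint object+probe heavy-ball acceleration overshoots at high
#'   friction on densely overlapped scans, hence the conservative default.
#' @param position_correction `NULL`, `TRUE` (defaults: interval 5, radius
#'   2 px, 8 trials, cooling 0.95, start at iteration 15) or a list
#'   overriding those fields (`trials = "exhaustive"` searches the full
#'   neighbourhood).
#' @param orthogonalize_interval Orthogonalize probe modes every this many
#'   iterations (multi-mode runs only).
#' @param overlap_iters Inner object/probe alternations of the overlap
#'   update per outer iteration of the parallel engines (field practice uses
#'   a handful; 1 is the bare sequential update).
#' @param error_metric `"intensity"` (the printed normalized misfit) or
#'   `"amplitude"`.
#' @param seed RNG seed covering initialization, sweep ordering and position
#'   annealing.
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(engine = "dm", iterations = 100L, beta = 0.9,
                         step_o = 1, step_p = 1, reg_o = 0.1, reg_p = 0.1,
                         gamma = 0.5, batch_size = NULL, n_workers = 1L,
                         probe_support_diameter_m = NULL,
                         probe_update_start = 3L, momentum = NULL,
                         position_correction = NULL,
                         orthogonalize_interval = NULL,
                         overlap_iters = 3L,
                         error_metric = c("intensity", "amplitude"),
                         seed = 1L) {
  error_metric <- match.arg(error_metric)
  engine <- match.arg(engine, ENGINE_CHOICES, several.ok = TRUE)
  iterations <- rep_len(as.integer(iterations), length(engine))
  if (any(iterations < 0))
    stop_ptychor("iterations must be >= 0", class = "ptychor_invalid_input")
  if (beta < 0 || beta > 1)
    stop_ptychor("beta must lie in [0, 1]", class = "ptychor_invalid_input")
  if (!gamma %in% c(0.5, 1))
    stop_ptychor("gamma must be 1/2 or 1", class = "ptychor_invalid_input")
  if (step_o <= 0 || step_p <= 0 || reg_o <= 0 || reg_o > 1 ||
      reg_p <= 0 || reg_p > 1)
    stop_ptychor("rPIE steps must be > 0 and regularizers in (0, 1]",
                 class = "ptychor_invalid_input")
  if (!is.null(batch_size) && any(engine %in% c("rpie", "mpie")) &&
      batch_size > 1)
    stop_ptychor("rPIE/mPIE are sequential: batch_size must be 1",
                 class = "ptychor_config_error")
  if (isTRUE(momentum)) momentum <- list()
  if (is.list(momentum)) {
    momentum$friction <- momentum$friction %||% 0.3
    momentum$interval <- momentum$interval %||% NA_integer_  # NA = one sweep
  }
  if (isTRUE(position_correction)) position_correction <- list()
  if (is.list(position_correction)) {
    position_correction$interval <- position_correction$interval %||% 5L
    position_correction$radius_px <- position_correction$radius_px %||% 2
    position_correction$trials <- position_correction$trials %||% 8L
    position_correction$cooling <- position_correction$cooling %||% 0.95
    # annealing against a half-formed object relocates good positions too;
    # start only once the model has begun to settle
    position_correction$start <- position_correction$start %||% 15L
  }
  structure(list(engine = engine, iterations = iterations, beta = beta,
                 step_o = step_o, step_p = step_p, reg_o = reg_o,
                 reg_p = reg_p, gamma = gamma, batch_size = batch_size,
                 n_workers = as.integer(n_workers),
                 probe_support_diameter_m = probe_support_diameter_m,
                 probe_update_start = as.integer(probe_update_start),
                 momentum = momentum,
                 position_correction = position_correction,
                 orthogonalize_interval = orthogonalize_interval,
                 overlap_iters = max(1L, as.integer(overlap_iters)),
                 error_metric = error_metric, seed = as.integer(seed)),
            class = "recon_config")
}

#' Ptychographic reconstruction
#'
#' Fits the complex object transmission function and illumination probe to a
#' diffraction dataset. Parallel engines (`"ap"`, `"dm"`, `"raar"`) update
#' all wavefronts per iteration through batched accumulators that are reduced
#' and broadcast, so results are invariant to `batch_size`/`n_workers`;
#' sequential engines (`"rpie"`, `"mpie"`) sweep scan positions in random
#' order one at a time; `"ml"` runs gradient-based cost refinement. Stages
#' chain in order, e.g. `engine = c("rpie", "ap"), iterations = c(100, 300)`.
#'
#' Default initialization: object magnitudes uniform in \[0.9, 1\] with
#' constant zero phase; first probe mode the back-propagated square root of
#' the frame-averaged intensities.
#'
#' @param stack A [diffraction_stack()].
#' @param object,probe Optional initial guesses ([ptycho_object()] /
#'   [ptycho_probe()]); defaults per above.
#' @param n_modes Number of probe modes when the probe is auto-initialized.
#' @param canvas_dim Optional object canvas (rows, cols). By default the
#'   canvas is sized to the scan footprint.
#' @param config Optional prebuilt [recon_config()]; otherwise built
#'   from `...`.
#' @param verbose Print the per-iteration misfit.
#' @param ... Arguments forwarded to [recon_config()].
#' @return Object of class `ptycho_recon`: fields `object`, `probe`,
#'   `error_trace` (normalized model misfit per iteration),
#'   `ml_cost_trace` (when an ML stage ran), `positions` (final, possibly
#'   corrected [scan_pattern()]), `offsets`, `config` and the input `stack`.
#' @examples
#' sim <- generate_benchmark_dataset("small_test", seed = 7)
#' fit <- ptycho_reconstruct(sim$stack, engine = "dm", iterations = 20,
#'                           canvas_dim = dim(sim$ground_truth$object$values))
#' print(fit)
#' @export
ptycho_reconstruct <- function(stack, object = NULL, probe = NULL,
                               n_modes = 1L, canvas_dim = NULL,
                               config = NULL, verbose = FALSE, ...) {
  stopifnot(inherits(stack, "diffraction_stack"))
  cfg <- config %||% recon_config(...)
  stopifnot(inherits(cfg, "recon_config"))
  spec <- propagator_for_geometry(stack$geometry)
  px <- if (stack$geometry$regime == "far_field")
    effective_pixel_size(stack$geometry) else stack$geometry$pixel_m
  m <- stack$geometry$frame_shape[1]
  n <- n_frames(stack)

  offsets <- positions_to_pixel_offsets(stack$scan, px)
  if (is.null(canvas_dim)) {
    cv <- default_canvas(offsets, m, margin = 0L)
    offsets <- cv$offsets
    canvas_dim <- cv$canvas_dim
  } else {
    canvas_dim <- as.integer(canvas_dim)
    check_windows_inside(offsets, m, canvas_dim)
  }
  set.seed(cfg$seed)
  if (is.null(object)) object <- default_object_init(canvas_dim, px)
  if (!all(dim(object$values) == canvas_dim))
    stop_ptychor("object initial guess does not match canvas_dim",
                 class = "ptychor_invalid_input")
  if (is.null(probe)) probe <- default_probe_init(stack, spec, n_modes)

  state <- list(object = object, probe = probe, offsets = offsets,
                error_trace = numeric(0), ml_cost_trace = NULL,
                cum_iter = 0L,
                pc_radius = if (is.list(cfg$position_correction))
                  cfg$position_correction$radius_px else NULL)

  for (s in seq_along(cfg$engine)) {
    eng <- cfg$engine[s]
    iters <- cfg$iterations[s]
    if (iters == 0L) next
    state <- switch(eng,
      ap = , dm = , raar =
        run_projection_stage(state, stack, spec, eng, iters, cfg, verbose),
      rpie = , mpie =
        run_pie_stage(state, stack, spec, eng, iters, cfg, verbose),
      ml = {
        res <- run_ml_refinement(state$object, state$probe, stack,
                                 gamma = cfg$gamma, max_iters = iters,
                                 offsets = state$offsets)
        state$object <- res$object
        state$probe <- res$probe
        state$ml_cost_trace <- c(state$ml_cost_trace, res$cost_trace)
        state
      })
  }

  # final positions back in metric (x, y) coordinates
  final_scan <- scan_pattern(cbind(state$offsets[, 2], state$offsets[, 1]) * px,
                             px)
  structure(list(object = state$object, probe = state$probe,
                 error_trace = state$error_trace,
                 ml_cost_trace = state$ml_cost_trace,
                 positions = final_scan, offsets = state$offsets,
                 config = cfg, stack = stack, canvas_dim = canvas_dim),
            class = "ptycho_recon")
}

run_projection_stage <- function(state, stack, spec, engine, iters, cfg,
                                 verbose) {
  n <- n_frames(stack)
  m <- stack$geometry$frame_shape[1]
  b <- min(cfg$batch_size %||% n, n)
  plan <- schedule_batches(partition_batches(n, b), cfg$n_workers)
  nk <- dim(state$probe$modes)[3]
  needs_state <- engine %in% c("dm", "raar")
  psi_state <- if (needs_state)
    lapply(seq_len(n), function(i)
      exit_wave(state$object, state$probe, state$offsets[i, ]))

  for (it in seq_len(iters)) {
    state$cum_iter <- state$cum_iter + 1L
    partials <- lapply(seq_len(cfg$n_workers), function(w)
      new_accumulator(dim(state$object$values), m, nk))
    psi_store <- vector("list", n)
    # pass 1: wavefront updates + object-side accumulation
    for (bi in seq_along(plan$batches)) {
      w <- plan$assignments[bi]
      idx <- plan$batches[[bi]]
      psi_out <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        i <- idx[j]
        md <- model_detector_waves(state$object$values, state$probe$modes,
                                   state$offsets[i, ], spec)
        et <- err_terms(stack$intensities[, , i], md$model,
                        stack$masks[, , i], cfg$error_metric)
        partials[[w]]$err_num <- partials[[w]]$err_num + et[1]
        partials[[w]]$err_den <- partials[[w]]$err_den + et[2]
        if (engine == "ap") {
          det <- modulus_project_detector(md$det, stack$intensities[, , i],
                                          stack$masks[, , i])
          psi_new <- det
          for (k in seq_len(nk)) psi_new[, , k] <- from_detector(det[, , k], spec)
        } else {
          po <- object_consistency_wave(md$win, state$probe$modes)
          pm <- project_data(2 * po - psi_state[[i]],
                             stack$intensities[, , i], stack$masks[, , i],
                             spec)
          psi_new <- if (engine == "dm")
            psi_state[[i]] + pm - po
          else
            cfg$beta * (psi_state[[i]] + pm) + (1 - 2 * cfg$beta) * po
          psi_state[[i]] <- psi_new
        }
        psi_out[[j]] <- psi_new
        psi_store[[i]] <- psi_new
      }
      partials[[w]] <- accumulate_object_partial(
        psi_out, state$probe$modes, state$offsets[idx, , drop = FALSE],
        partials[[w]])
    }
    # overlap update: alternate object and probe against the fixed updated
    # wavefronts; the probe side always sees the freshly updated object (the
    # sequential form, which keeps the coupled iteration stable)
    update_probe <- state$cum_iter >= cfg$probe_update_start
    for (rep in seq_len(cfg$overlap_iters)) {
      if (rep > 1L) {
        # re-accumulate the object side with the probe refreshed last round
        partials <- lapply(seq_len(cfg$n_workers), function(w)
          new_accumulator(dim(state$object$values), m, nk))
        for (bi in seq_along(plan$batches)) {
          w <- plan$assignments[bi]
          idx <- plan$batches[[bi]]
          partials[[w]] <- accumulate_object_partial(
            psi_store[idx], state$probe$modes,
            state$offsets[idx, , drop = FALSE], partials[[w]])
        }
      }
      total <- tree_reduce(partials)
      if (rep == 1L) err_pair <- c(total$err_num, total$err_den)
      upd <- apply_global_updates(total, state$object, state$probe,
                                  update_probe = FALSE)
      state$object <- upd$object
      if (update_probe) {
        partials2 <- lapply(seq_len(cfg$n_workers), function(w)
          new_accumulator(dim(state$object$values), m, nk))
        for (bi in seq_along(plan$batches)) {
          w <- plan$assignments[bi]
          idx <- plan$batches[[bi]]
          partials2[[w]] <- accumulate_probe_partial(
            psi_store[idx], state$object$values,
            state$offsets[idx, , drop = FALSE], partials2[[w]])
        }
        total2 <- tree_reduce(partials2)
        total2$obj_num <- total$obj_num; total2$obj_den <- total$obj_den
        upd2 <- apply_global_updates(total2, state$object, state$probe,
                                     update_probe = TRUE)
        state$probe <- upd2$probe
      } else if (rep > 1L) break   # nothing changes without a probe update
    }
    invisible(broadcast_model(list(object = state$object,
                                   probe = state$probe), cfg$n_workers))
    state <- apply_hooks(state, stack, spec, cfg)
    state$error_trace <- c(state$error_trace, err_pair[1] / err_pair[2])
    if (verbose)
      cat(sprintf("[%s] iter %d  eps = %.4g\n", engine, state$cum_iter,
                  err_pair[1] / err_pair[2]))
    if (!is.null(state$refresh_psi) && state$refresh_psi && needs_state) {
      psi_state <- lapply(seq_len(n), function(i)
        exit_wave(state$object, state$probe, state$offsets[i, ]))
      state$refresh_psi <- FALSE
    }
  }
  state
}

run_pie_stage <- function(state, stack, spec, engine, iters, cfg, verbose) {
  n <- n_frames(stack)
  m <- stack$geometry$frame_shape[1]
  nk <- dim(state$probe$modes)[3]
  mom <- if (engine == "mpie") (cfg$momentum %||% list(friction = 0.3,
                                                       interval = NA_integer_))
         else cfg$momentum
  mom_buf <- NULL
  if (is.list(mom)) {
    interval <- mom$interval
    if (is.na(interval %||% NA)) interval <- n     # one full sweep
    mom_buf <- list(
      v_o = 0 * state$object$values, v_p = 0 * state$probe$modes,
      ck_o = state$object$values, ck_p = state$probe$modes,
      interval = interval, count = 0L)
  }
  for (it in seq_len(iters)) {
    state$cum_iter <- state$cum_iter + 1L
    err_num <- 0; err_den <- 0
    order <- sample.int(n)
    for (i in order) {
      md <- model_detector_waves(state$object$values, state$probe$modes,
                                 state$offsets[i, ], spec)
      et <- err_terms(stack$intensities[, , i], md$model,
                      stack$masks[, , i], cfg$error_metric)
      err_num <- err_num + et[1]; err_den <- err_den + et[2]
      det <- modulus_project_detector(md$det, stack$intensities[, , i],
                                      stack$masks[, , i])
      psi_prime <- det
      for (k in seq_len(nk)) psi_prime[, , k] <- from_detector(det[, , k], spec)
      po <- object_consistency_wave(md$win, state$probe$modes)
      new_win <- rpie_object_update(md$win, state$probe, po, psi_prime,
                                    cfg$step_o, cfg$reg_o)
      state$object$values[md$w$rows, md$w$cols] <- new_win
      if (state$cum_iter >= cfg$probe_update_start)
        state$probe$modes <- rpie_probe_update(md$win, state$probe, po,
                                               psi_prime, cfg$step_p,
                                               cfg$reg_p)
      if (!is.null(mom_buf)) {
        mom_buf$count <- mom_buf$count + 1L
        if (mom_buf$count %% mom_buf$interval == 0L) {
          so <- momentum_step(state$object$values, mom_buf$ck_o, mom_buf$v_o,
                              mom$friction)
          state$object$values <- so$x; mom_buf$v_o <- so$velocity
          mom_buf$ck_o <- so$checkpoint
          sp <- momentum_step(state$probe$modes, mom_buf$ck_p, mom_buf$v_p,
                              mom$friction)
          state$probe$modes <- sp$x; mom_buf$v_p <- sp$velocity
          mom_buf$ck_p <- sp$checkpoint
        }
      }
    }
    state <- apply_hooks(state, stack, spec, cfg)
    state$error_trace <- c(state$error_trace, err_num / err_den)
    if (verbose)
      cat(sprintf("[%s] iter %d  eps = %.4g\n", engine, state$cum_iter,
                  err_num / err_den))
  }
  state
}

apply_hooks <- function(state, stack, spec, cfg) {
  if (!is.null(cfg$probe_support_diameter_m))
    state$probe <- apply_probe_support(state$probe,
                                       cfg$probe_support_diameter_m,
                                       state$object$pixel_m)
  oi <- cfg$orthogonalize_interval
  if (!is.null(oi) && dim(state$probe$modes)[3] > 1L &&
      state$cum_iter %% oi == 0L)
    state$probe <- orthogonalize_probe_modes(state$probe)
  pc <- cfg$position_correction
  if (is.list(pc) && state$cum_iter >= pc$start &&
      state$cum_iter %% pc$interval == 0L && state$pc_radius >= 1) {
    new_off <- anneal_positions(state$object, state$probe, stack,
                                state$offsets, radius_px = state$pc_radius,
                                trials = pc$trials, spec = spec,
                                seed = cfg$seed + state$cum_iter)
    if (attr(new_off, "n_moved") > 0) state$refresh_psi <- TRUE
    state$offsets <- new_off
    state$pc_radius <- state$pc_radius * pc$cooling
  }
  state
}
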