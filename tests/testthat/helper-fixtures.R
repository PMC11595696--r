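# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (double loops, literal formulas) and never call the code
# paths they check.

rand_complex <- function(n1, n2 = n1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(complex(real = rnorm(n1 * n2), imaginary = rnorm(n1 * n2)), n1, n2)
}

# Brute-force centred unitary 2-D DFT: literal double sum with the phase
# referenced to the centre pixel floor(N/2)+1 on both axes.
dft2_centered_oracle <- function(x, inverse = FALSE) {
  n1 <- nrow(x); n2 <- ncol(x)
  c1 <- floor(n1 / 2) + 1; c2 <- floor(n2 / 2) + 1
  sgn <- if (inverse) 1 else -1
  out <- matrix(0 + 0i, n1, n2)
  for (u in seq_len(n1)) for (v in seq_len(n2)) {
    s <- 0 + 0i
    for (a in seq_len(n1)) for (b in seq_len(n2))
      s <- s + x[a, b] * exp(sgn * 2i * pi *
                               ((a - c1) * (u - c1) / n1 +
                                  (b - c2) * (v - c2) / n2))
    out[u, v] <- s
  }
  out / sqrt(n1 * n2)
}

test_geometry <- function(m = 32L) {
  detector_geometry(12, 1.1, 55e-6, c(m, m))
}

# Tiny end-to-end simulation for engine tests: object canvas, circular probe,
# raster scan. Cheap enough for repeated use.
tiny_sim <- function(seed = 7, object_side = 48L, probe_side = 16L,
                     grid = c(3L, 3L), step = 12, jitter = 1) {
  geometry <- detector_geometry(12, 1.1, 55e-6, c(probe_side, probe_side))
  px <- effective_pixel_size(geometry)
  imgs <- phantom_images(c(object_side, object_side))
  object <- object_from_images(imgs$magnitude, imgs$phase,
                               object_shape = c(object_side, object_side),
                               pixel_m = px)
  probe <- probe_circular(probe_side, round(probe_side * 0.75))
  scan <- scan_raster_jittered(grid, step, jitter, probe_side,
                               c(object_side, object_side), px, seed = seed)
  stack <- forward_intensities(object, probe, scan, geometry)
  list(stack = stack, object = object, probe = probe, scan = scan,
       geometry = geometry, px = px)
}

small_sim <- function(seed = 7) generate_benchmark_dataset("small_test",
                                                           seed = seed)

far_spec <- function(m) propagator(frame_shape = c(m, m))
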