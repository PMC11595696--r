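test_that("refraction-based objects follow the thin-sample transmission model", {
  z <- matrix(0, 8, 8)
  o <- object_from_refraction(z, z, 1e-10)
  expect_equal(o$values, matrix(1 + 0i, 8, 8))           # empty object

  delta <- matrix(runif(64, 0, 1e-6), 8, 8)
  o <- object_from_refraction(delta, z, 1e-10)
  expect_equal(Mod(o$values), matrix(1, 8, 8), tolerance = 1e-12)  # pure phase

  # scalar oracle: one pixel, thickness t, hand-evaluated phase -k t delta
  lam <- 1e-10; t_delta <- 3.2e-8 * 1e-5
  dm <- matrix(0, 4, 4); dm[2, 3] <- t_delta
  o <- object_from_refraction(dm, matrix(0, 4, 4), lam)
  expect_equal(Arg(o$values[2, 3]),
               ((-2 * pi / lam * t_delta + pi) %% (2 * pi)) - pi,
               tolerance = 1e-9)

  expect_warning(object_from_refraction(z, z - 1e-9, 1e-10), "unphysical")
})

test_that("image-based objects apply the documented rescale maps", {
  const <- matrix(0.5, 6, 6)
  o <- object_from_images(const, const)
  expect_equal(max(Mod(o$values - o$values[1, 1])), 0)   # constant object

  ramp <- matrix(seq(0, 1, length.out = 36), 6, 6)
  o <- object_from_images(ramp, ramp, phase_range = c(0, 0))
  expect_equal(max(abs(Im(o$values))), 0)                # zero phase -> real
  expect_true(all(Re(o$values) >= 0.2 - 1e-12))

  # elementwise oracle on checkerboard inputs
  chk <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  o <- object_from_images(chk, 1 - chk, mag_range = c(0.3, 0.9),
                          phase_range = c(0.1, 1.2))
  mag_expect <- 0.3 + chk * 0.6
  pha_expect <- 0.1 + (1 - chk) * 1.1
  expect_equal(Mod(o$values), mag_expect, tolerance = 1e-12)
  expect_equal(Arg(o$values), pha_expect, tolerance = 1e-12)
})

test_that("circular probes are top-hat disks of the right area", {
  m <- 64
  p <- probe_circular(m, m)
  count <- sum(Mod(p$modes[, , 1]) > 0)
  expect_lt(abs(count - pi * (m / 2)^2) / (pi * (m / 2)^2), 0.05)
  expect_true(all(p$modes %in% c(0 + 0i, 1 + 0i)))       # constant phase
  expect_error(probe_circular(m, 0), class = "ptychor_invalid_input")
  expect_error(probe_circular(m, m + 2), class = "ptychor_invalid_input")
})

test_that("jittered raster scans are reproducible and centred on the grid", {
  px <- 8e-9
  s0 <- scan_raster_jittered(c(4, 4), 8, 0, 16, c(64, 64), px)
  grid <- s0$positions_m / px
  expect_equal(sort(unique(grid[, 1])), c(0, 8, 16, 24))  # exact raster

  s1 <- scan_raster_jittered(c(4, 4), 8, 1.5, 16, c(64, 64), px, seed = 5)
  s2 <- scan_raster_jittered(c(4, 4), 8, 1.5, 16, c(64, 64), px, seed = 5)
  expect_identical(s1$positions_m, s2$positions_m)        # determinism
  expect_false(identical(s0$positions_m, s1$positions_m))

  # CLT bound on the jitter mean over many draws (interior grid, no clamping)
  sd_px <- 0.5
  s <- scan_raster_jittered(c(100, 100), 10, sd_px, 4, c(2000, 2000), px,
                            margin_px = 500, seed = 11)
  base <- scan_raster_jittered(c(100, 100), 10, 0, 4, c(2000, 2000), px,
                               margin_px = 500)
  offs <- (s$positions_m - base$positions_m) / px
  expect_lt(max(abs(colMeans(offs))), 3 * sd_px / 100)
  expect_identical(attr(s, "n_clamped"), 0L)
})

test_that("forward intensities obey the far-field model", {
  m <- 16
  geometry <- detector_geometry(12, 1.1, 55e-6, c(m, m))
  px <- effective_pixel_size(geometry)
  probe <- probe_circular(m, 12)
  spec <- far_spec(m)

  # O == 1: every frame equals the probe's diffraction pattern
  ones <- ptycho_object(matrix(1 + 0i, 40, 40), px)
  scan <- scan_raster_jittered(c(2, 2), 10, 0, m, c(40, 40), px)
  stack <- forward_intensities(ones, probe, scan, geometry)
  ref <- Mod(to_detector(probe$modes[, , 1], spec))^2
  for (i in 1:4)
    expect_equal(stack$intensities[, , i], ref, tolerance = 1e-12)

  # Parseval: detector-plane energy equals exit-wave energy
  sim <- tiny_sim(seed = 13)
  off <- positions_to_pixel_offsets(sim$scan, sim$px)
  for (i in c(1, 5)) {
    psi <- exit_wave(sim$object, sim$probe, off[i, ])
    expect_equal(sum(sim$stack$intensities[, , i]), sum(Mod(psi)^2),
                 tolerance = 1e-9)
  }

  # brute-force DFT oracle: 4x4 object, 2x2 probe, one position
  g2 <- detector_geometry(12, 1.1, 55e-6, c(2, 2))
  px2 <- effective_pixel_size(g2)
  ov <- rand_complex(4, seed = 21)
  obj <- ptycho_object(ov, px2)
  pm <- matrix(c(1 + 0i, 0.5i, -0.25 + 0i, 1 - 0.5i), 2, 2)
  probe2 <- ptycho_probe(pm)
  scan2 <- scan_pattern(matrix(c(1, 2) * px2, 1, 2))  # offset row 2, col 1
  stack2 <- forward_intensities(obj, probe2, scan2, g2)
  win <- ov[3:4, 2:3]
  expect_equal(stack2$intensities[, , 1],
               Mod(dft2_centered_oracle(pm * win))^2, tolerance = 1e-10)
})

test_that("intensity is invariant under splitting a mode by 1/sqrt(2)", {
  sim <- tiny_sim(seed = 17)
  m <- dim(sim$probe$modes)[1]
  dup <- array(0 + 0i, dim = c(m, m, 2))
  dup[, , 1] <- sim$probe$modes[, , 1] / sqrt(2)
  dup[, , 2] <- sim$probe$modes[, , 1] / sqrt(2)
  stack2 <- forward_intensities(sim$object, ptycho_probe(dup), sim$scan,
                                sim$geometry)
  expect_equal(stack2$intensities, sim$stack$intensities, tolerance = 1e-6)
})

test_that("Poisson noise is reproducible and vanishes at large budgets", {
  sim <- tiny_sim(seed = 19)
  n1 <- apply_counting_noise(sim$stack, 1e5, seed = 3)
  n2 <- apply_counting_noise(sim$stack, 1e5, seed = 3)
  expect_identical(n1$intensities, n2$intensities)
  expect_false(identical(n1$intensities,
                         apply_counting_noise(sim$stack, 1e5, seed = 4)$intensities))

  big <- apply_counting_noise(sim$stack, 1e9, seed = 5)
  expect_lt(sum(abs(big$intensities - sim$stack$intensities)) /
              sum(sim$stack$intensities), 1e-3)

  # Monte-Carlo mean of one pixel over replicates stays near the noiseless value
  pix <- sim$stack$intensities[5, 7, 1]
  reps <- vapply(1:300, function(k)
    apply_counting_noise(sim$stack, 1e4, seed = 100 + k)$intensities[5, 7, 1],
    numeric(1))
  scale <- attr(apply_counting_noise(sim$stack, 1e4, seed = 1), "photon_scale")
  se <- sqrt(pix / scale / 300)
  expect_lt(abs(mean(reps) - pix), 5 * se + 1e-12)
})

test_that("benchmark generation is pure in (spec, seed) and self-consistent", {
  a <- generate_benchmark_dataset("small_test", seed = 9)
  b <- generate_benchmark_dataset("small_test", seed = 9)
  expect_identical(a$stack$intensities, b$stack$intensities)
  expect_identical(a$ground_truth$object$values, b$ground_truth$object$values)
  expect_true(all(a$stack$intensities >= 0))
  expect_true(all(a$stack$masks == 1))
  expect_identical(a$manifest$n_frames, 25L)

  dir <- withr::local_tempdir()
  gen <- generate_benchmark_dataset("small_test", seed = 2, out = dir)
  got <- load_dataset(dir)
  expect_lt(max(abs(got$stack$intensities - gen$stack$intensities)),
            1e-6 * max(gen$stack$intensities))
  expect_lt(max(Mod(got$ground_truth$object$values -
                      gen$ground_truth$object$values)), 1e-5)
})

test_that("the full-size benchmark preset reports 400 frames", {
  spec <- ptychor:::benchmark_spec("full_benchmark")
  expect_identical(as.integer(prod(spec$grid_shape)), 400L)
  expect_identical(spec$object_shape, c(400L, 400L))
  expect_identical(spec$probe_side, 180L)
  # scan geometry fits the canvas without clamping
  px <- effective_pixel_size(detector_geometry(12, 1.1, 55e-6, c(180, 180)))
  s <- scan_raster_jittered(spec$grid_shape, spec$step_px,
                            spec$jitter_sigma_px, 180, c(400, 400), px,
                            margin_px = spec$margin_px, seed = 1)
  expect_identical(nrow(s$positions_m), 400L)
})
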