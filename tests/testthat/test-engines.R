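# Unit tests of the engine building blocks against naive oracles.

rand_state <- function(m = 8, k = 1, seed = 1) {
  set.seed(seed)
  psi <- array(complex(real = rnorm(m * m * k), imaginary = rnorm(m * m * k)),
               dim = c(m, m, k))
  intensity <- matrix(rexp(m * m), m, m)
  mask <- matrix(rbinom(m * m, 1, 0.9), m, m)
  object_view <- rand_complex(m, seed = seed + 100)
  probe <- array(complex(real = rnorm(m * m * k), imaginary = rnorm(m * m * k)),
                 dim = c(m, m, k))
  list(psi = psi, intensity = intensity, mask = mask,
       object_view = object_view, probe = probe, spec = far_spec(m))
}

test_that("exit waves are the windowed probe-object product", {
  sim <- tiny_sim(seed = 1)
  m <- dim(sim$probe$modes)[1]
  ones <- ptycho_object(matrix(1 + 0i, 30, 30), sim$px)
  psi <- exit_wave(ones, sim$probe, c(4L, 9L))
  expect_equal(psi, sim$probe$modes)                     # O == 1

  zero <- ptycho_probe(matrix(0 + 0i, m, m))
  expect_true(all(exit_wave(sim$object, zero, c(0L, 0L)) == 0))

  # elementwise loop oracle on a random 8x8 case
  ov <- rand_complex(12, seed = 5)
  pm <- rand_complex(8, seed = 6)
  psi <- exit_wave(ov, pm, c(2L, 3L))
  for (a in 1:8) for (b in 1:8)
    expect_equal(psi[a, b, 1], pm[a, b] * ov[2 + a, 3 + b])

  expect_error(exit_wave(ov, pm, c(7L, 0L)), class = "ptychor_canvas_error")
})

test_that("the data projector fixes consistent states and masked pixels", {
  st <- rand_state(seed = 2)
  # construct data exactly consistent with psi
  i_cons <- Mod(to_detector(st$psi[, , 1], st$spec))^2
  out <- project_data(st$psi, i_cons, matrix(1, 8, 8), st$spec)
  expect_lt(sqrt(mean(Mod(out - st$psi)^2)), 1e-6)       # fixed point

  out <- project_data(st$psi, st$intensity, matrix(0, 8, 8), st$spec)
  expect_lt(sqrt(mean(Mod(out - st$psi)^2)), 1e-10)      # full mask -> identity

  expect_error(project_data(st$psi, -st$intensity, matrix(1, 8, 8), st$spec),
               class = "ptychor_invalid_data")
})

test_that("the data projector matches a brute-force magnitude-replacement oracle", {
  m <- 2
  psi <- matrix(c(1 + 2i, -0.5 + 0i, 3 - 1i, 0.25i), 2, 2)
  intensity <- matrix(c(4, 1, 2.25, 9), 2, 2)
  mask <- matrix(1, 2, 2)
  got <- project_data(psi, intensity, mask, far_spec(2))[, , 1]
  # oracle: hand DFT, magnitude replacement, hand inverse DFT
  det <- dft2_centered_oracle(psi)
  det <- sqrt(intensity) * det / Mod(det)
  expect_lt(max(Mod(got - dft2_centered_oracle(det, inverse = TRUE))), 1e-10)
})

test_that("the data projector is idempotent and deposits sqrt(I/K) on zero pixels", {
  st <- rand_state(m = 16, k = 2, seed = 3)
  once <- project_data(st$psi, st$intensity, st$mask, propagator(frame_shape = c(16, 16)))
  twice <- project_data(once, st$intensity, st$mask, propagator(frame_shape = c(16, 16)))
  expect_lt(sqrt(mean(Mod(twice - once)^2)), 1e-6)

  # all-zero model with positive data: equal deposits with zero phase
  zero <- array(0 + 0i, dim = c(8, 8, 2))
  i8 <- matrix(2.5, 8, 8)
  out <- project_data(zero, i8, matrix(1, 8, 8), far_spec(8))
  det1 <- to_detector(out[, , 1], far_spec(8))
  expect_equal(Mod(det1), sqrt(i8 / 2), tolerance = 1e-10)
  expect_equal(out[, , 1], out[, , 2], tolerance = 1e-12)
})

test_that("DM and RAAR updates agree with their literal term-by-term forms", {
  for (seed in 1:5) {
    st <- rand_state(m = 4, seed = seed)
    po <- st$probe[, , 1] * st$object_view
    pm <- project_data(2 * array(po, c(4, 4, 1)) - st$psi, st$intensity,
                       st$mask, st$spec)
    # literal three-term RAAR combination, beta = 0.7
    beta <- 0.7
    oracle <- beta * (st$psi + pm) + (1 - 2 * beta) * array(po, c(4, 4, 1))
    got <- raar_update(st$psi, st$intensity, st$mask, st$object_view,
                       st$probe, beta, st$spec)
    expect_lt(max(Mod(got - oracle)), 1e-12)
    # literal difference-map combination
    oracle_dm <- st$psi + pm - array(po, c(4, 4, 1))
    got_dm <- dm_update(st$psi, st$intensity, st$mask, st$object_view,
                        st$probe, st$spec)
    expect_lt(max(Mod(got_dm - oracle_dm)), 1e-12)
  }
})

test_that("RAAR interpolates between the consistency projector and DM", {
  st <- rand_state(m = 8, seed = 11)
  po <- st$probe[, , 1] * st$object_view
  got0 <- raar_update(st$psi, st$intensity, st$mask, st$object_view,
                      st$probe, 0, st$spec)
  expect_lt(max(Mod(got0[, , 1] - po)), 1e-12)           # beta = 0 -> Pi_O

  got1 <- raar_update(st$psi, st$intensity, st$mask, st$object_view,
                      st$probe, 1, st$spec)
  dm <- dm_update(st$psi, st$intensity, st$mask, st$object_view,
                  st$probe, st$spec)
  expect_lt(max(Mod(got1 - dm)), 1e-12)
})

test_that("batch misfit accumulation matches scalar hand computation", {
  m <- 4
  spec <- far_spec(m)
  psi <- array(rand_complex(m, seed = 31), c(m, m, 1))
  model <- Mod(to_detector(psi[, , 1], spec))^2
  mask <- matrix(1, m, m)

  # perfect model
  e <- batch_error(list(model), list(psi), list(mask), spec)
  expect_equal(e$err_num / e$err_den, 0, tolerance = 1e-12)

  # psi == 0: eps = sum(I^2)/sum(I)
  intensity <- matrix(rexp(m * m), m, m)
  e <- batch_error(list(intensity), list(array(0 + 0i, c(m, m, 1))),
                   list(mask), spec)
  expect_equal(e$err_num / e$err_den, sum(intensity^2) / sum(intensity))

  # two-frame toy vs literal scalar loop
  i2 <- matrix(rexp(m * m), m, m)
  m2 <- matrix(rbinom(m * m, 1, 0.8), m, m)
  psi2 <- array(rand_complex(m, seed = 32), c(m, m, 1))
  e <- batch_error(list(intensity, i2), list(psi, psi2), list(mask, m2), spec)
  model2 <- Mod(dft2_centered_oracle(psi2[, , 1]))^2
  num <- sum(mask * (intensity - model)^2) + sum(m2 * (i2 - model2)^2)
  den <- sum(mask * intensity) + sum(m2 * i2)
  expect_equal(e$err_num, num, tolerance = 1e-9)
  expect_equal(e$err_den, den, tolerance = 1e-12)
})

test_that("update accumulators are additive and match a brute-force loop", {
  m <- 4
  probe <- rand_complex(m, seed = 41)
  ov <- rand_complex(10, seed = 42)
  offsets <- matrix(c(0L, 0L, 2L, 3L, 5L, 1L), 3, 2, byrow = TRUE)
  psi <- lapply(1:3, function(i) array(rand_complex(m, seed = 50 + i),
                                       c(m, m, 1)))
  acc <- accumulate_updates(psi, probe, ov, offsets,
                            new_accumulator(c(10, 10), m))

  # brute-force oracle
  on <- matrix(0 + 0i, 10, 10); od <- matrix(0, 10, 10)
  pn <- matrix(0 + 0i, m, m); pd <- matrix(0, m, m)
  for (i in 1:3) for (a in 1:m) for (b in 1:m) {
    r <- offsets[i, 1] + a; c <- offsets[i, 2] + b
    on[r, c] <- on[r, c] + Conj(probe[a, b]) * psi[[i]][a, b, 1]
    od[r, c] <- od[r, c] + Mod(probe[a, b])^2
    pn[a, b] <- pn[a, b] + Conj(ov[r, c]) * psi[[i]][a, b, 1]
    pd[a, b] <- pd[a, b] + Mod(ov[r, c])^2
  }
  expect_equal(acc$obj_num, on, tolerance = 1e-12)
  expect_equal(acc$obj_den, od, tolerance = 1e-12)
  expect_equal(acc$probe_num[, , 1], pn, tolerance = 1e-12)
  expect_equal(acc$probe_den, pd, tolerance = 1e-12)

  # additivity: union of single-position runs equals the joint run
  parts <- lapply(1:3, function(i)
    accumulate_updates(psi[i], probe, ov, offsets[i, , drop = FALSE],
                       new_accumulator(c(10, 10), m)))
  total <- tree_reduce(parts)
  expect_equal(total$obj_num, acc$obj_num, tolerance = 1e-12)
  expect_equal(total$probe_den, acc$probe_den, tolerance = 1e-12)
})

test_that("global updates divide accumulators and keep unvisited pixels", {
  m <- 4
  psi <- array(rand_complex(m, seed = 61), c(m, m, 1))
  ones <- array(1 + 0i, c(m, m, 1))
  prior <- ptycho_object(matrix(5 + 5i, 10, 10), 1e-9)
  acc <- accumulate_updates(list(psi), ones, prior$values,
                            matrix(c(1L, 2L), 1, 2),
                            new_accumulator(c(10, 10), m))
  upd <- apply_global_updates(acc, prior, ptycho_probe(ones))
  expect_equal(upd$object$values[2:5, 3:6], psi[, , 1], tolerance = 1e-5)
  expect_equal(upd$object$values[1, 1], 5 + 5i)          # unvisited pixel kept

  # uniform double coverage with identical wavefronts changes nothing
  acc2 <- accumulate_updates(list(psi, psi), ones, prior$values,
                             matrix(c(1L, 2L, 1L, 2L), 2, 2, byrow = TRUE),
                             new_accumulator(c(10, 10), m))
  upd2 <- apply_global_updates(acc2, prior, ptycho_probe(ones))
  expect_equal(upd2$object$values, upd$object$values, tolerance = 1e-5)
})

test_that("rPIE updates match their literal elementwise formulas", {
  m <- 4
  ov <- rand_complex(m, seed = 71)
  pm <- rand_complex(m, seed = 72)
  psi <- array(rand_complex(m, seed = 73), c(m, m, 1))
  psi2 <- array(rand_complex(m, seed = 74), c(m, m, 1))

  # psi' == psi leaves both factors unchanged
  expect_equal(rpie_object_update(ov, pm, psi, psi, 0.9, 0.2), ov)
  expect_equal(rpie_probe_update(ov, pm, psi, psi, 0.9, 0.2)[, , 1], pm)

  # elementwise oracle
  s_o <- 0.7; r_o <- 0.15
  got <- rpie_object_update(ov, pm, psi, psi2, s_o, r_o)
  p2 <- Mod(pm)^2
  oracle <- ov + s_o * Conj(pm) * (psi2[, , 1] - psi[, , 1]) /
    ((1 - r_o) * p2 + r_o * max(p2))
  expect_equal(got, oracle, tolerance = 1e-12)

  s_p <- 0.4; r_p <- 0.3
  gotp <- rpie_probe_update(ov, pm, psi, psi2, s_p, r_p)[, , 1]
  o2 <- Mod(ov)^2
  oraclep <- pm + s_p * Conj(ov) * (psi2[, , 1] - psi[, , 1]) /
    ((1 - r_p) * o2 + r_p * max(o2))
  expect_equal(gotp, oraclep, tolerance = 1e-12)

  # r = 1 makes the denominator constant
  got1 <- rpie_object_update(ov, pm, psi, psi2, s_o, 1)
  expect_equal(got1, ov + s_o * Conj(pm) * (psi2[, , 1] - psi[, , 1]) / max(p2),
               tolerance = 1e-12)

  zero <- matrix(0 + 0i, m, m)
  expect_error(rpie_object_update(ov, zero, psi, psi2, 1, 1),
               class = "ptychor_division_guard")
})

test_that("momentum follows the documented heavy-ball recurrence", {
  # scalar oracle: two identical consecutive steps, friction 0.9
  friction <- 0.9
  x0 <- 1; step <- 0.5
  v <- 0; ck <- x0
  x <- x0 + step
  s1 <- momentum_step(x, ck, v, friction)
  # oracle: v1 = 0.9*0 + 0.5 = 0.5; x1 = 1.5 + 0.45 = 1.95
  expect_equal(s1$x, 1.95)
  expect_equal(s1$checkpoint, 1.5)   # refreshed to the pre-acceleration iterate
  x <- s1$x + step
  s2 <- momentum_step(x, s1$checkpoint, s1$velocity, friction)
  # oracle: v2 = 0.9*0.5 + (2.45 - 1.5) = 1.4; x2 = 2.45 + 0.9*1.4 = 3.71
  expect_equal(s2$x, 3.71)

  # friction 0 is a no-op on the iterate
  s0 <- momentum_step(x, s1$checkpoint, s1$velocity, 0)
  expect_identical(s0$x, x)
})

test_that("probe support zeroes outside the disk and is idempotent", {
  m <- 32
  px <- 1e-8
  p <- ptycho_probe(matrix(1 + 0i, m, m))
  half <- apply_probe_support(p, diameter_m = m / 2 * px, pixel_m = px)
  ratio <- sum(Mod(half$modes)^2) / sum(Mod(p$modes)^2)
  expect_lt(abs(ratio - pi * (m / 4)^2 / m^2), 0.01)      # disk/frame area

  again <- apply_probe_support(half, diameter_m = m / 2 * px, pixel_m = px)
  expect_identical(again$modes, half$modes)               # idempotent

  expect_message(full <- apply_probe_support(p, 2 * m * px, px), "no-op")
  expect_identical(full$modes, p$modes)
})

test_that("mode orthogonalization conserves power and orders occupancies", {
  m <- 16
  modes <- array(0 + 0i, c(m, m, 3))
  modes[, , 1] <- rand_complex(m, seed = 81)
  modes[, , 2] <- rand_complex(m, seed = 82) * 0.5
  modes[, , 3] <- rand_complex(m, seed = 83) * 0.1
  p <- orthogonalize_probe_modes(ptycho_probe(modes))
  pw <- apply(p$modes, 3, function(x) sum(Mod(x)^2))
  expect_equal(sum(pw), sum(Mod(modes)^2), tolerance = 1e-9)  # power conserved
  expect_true(all(diff(pw) <= 1e-9))                           # descending
  expect_equal(p$occupancies, pw / sum(pw), tolerance = 1e-9)

  # Gram-matrix oracle: pairwise inner products vanish
  x <- matrix(p$modes, ncol = 3)
  g <- crossprod(Conj(x), x)
  offdiag <- g - diag(diag(g))
  expect_lt(max(Mod(offdiag)), 1e-6 * max(Mod(diag(g))))

  # duplicated mode pair collapses to rank one
  dup <- array(0 + 0i, c(m, m, 2))
  dup[, , 1] <- modes[, , 1]; dup[, , 2] <- modes[, , 1]
  expect_warning(pd <- orthogonalize_probe_modes(ptycho_probe(dup)),
                 "rank-deficient")
  pwd <- apply(pd$modes, 3, function(x) sum(Mod(x)^2))
  expect_lt(pwd[2], 1e-9 * pwd[1])

  # an already-orthogonal stack keeps its span and powers
  ortho <- array(0 + 0i, c(2, 2, 2))
  ortho[, , 1] <- matrix(c(2, 0, 0, 0), 2, 2)
  ortho[, , 2] <- matrix(c(0, 1, 0, 0), 2, 2)
  po <- orthogonalize_probe_modes(ptycho_probe(ortho))
  expect_equal(apply(po$modes, 3, function(x) sum(Mod(x)^2)), c(4, 1),
               tolerance = 1e-9)
})

test_that("annealing leaves true positions alone and recovers injected shifts", {
  sim <- tiny_sim(seed = 23)
  off <- positions_to_pixel_offsets(sim$scan, sim$px)
  spec <- propagator_for_geometry(sim$geometry)

  # noiseless data at true positions: nothing can beat residual 0
  out <- anneal_positions(sim$object, sim$probe, sim$stack, off,
                          radius_px = 2, trials = "exhaustive", spec = spec)
  expect_identical(unname(out[, ]), unname(off[, ]))
  expect_identical(attr(out, "n_moved"), 0L)

  # a 2-px injected offset on one frame is recovered exactly
  wrong <- off
  wrong[4, ] <- wrong[4, ] + c(2L, 0L)
  rec <- anneal_positions(sim$object, sim$probe, sim$stack, wrong,
                          radius_px = 3, trials = "exhaustive", spec = spec)
  expect_identical(unname(rec[4, ]), unname(off[4, ]))

  # random-trial mode is deterministic under a seed
  r1 <- anneal_positions(sim$object, sim$probe, sim$stack, wrong,
                         radius_px = 3, trials = 6, spec = spec, seed = 9)
  r2 <- anneal_positions(sim$object, sim$probe, sim$stack, wrong,
                         radius_px = 3, trials = 6, spec = spec, seed = 9)
  expect_identical(unname(r1[, ]), unname(r2[, ]))

  # radius 0 is a no-op
  nop <- anneal_positions(sim$object, sim$probe, sim$stack, wrong,
                          radius_px = 0, trials = 4, spec = spec)
  expect_identical(unname(nop[, ]), unname(wrong[, ]))
})
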