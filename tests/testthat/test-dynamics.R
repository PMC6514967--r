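# The Langevin engine: equilibrium behaviour, determinism, energy
# conservation, shared-bias bookkeeping and funnel confinement.

test_that("a particle at a potential minimum stays put at zero temperature", {
  hs <- harmonic_system(k = 100)
  sp <- run_spec(10000, temperature = 0, seed = 1, output_stride = 1000)
  seg <- run_segment(hs, sp)
  drift <- apply(seg$trajectory$coords[, 2, , drop = FALSE], 1,
                 function(r) sqrt(sum((r - c(0, 0, 0.5))^2)))
  expect_true(all(drift <= 1e-8))
})

test_that("sampled variance obeys equipartition for a harmonic potential", {
  k <- 100
  hs <- harmonic_system(k = k)
  sp <- run_spec(1000000, friction = 2, temperature = 310, seed = 2,
                 output_stride = 50)
  seg <- run_segment(hs, sp)
  z <- seg$trajectory$coords[, 2, 3] - 0.5
  expect_equal(var(z), kB * 310 / k, tolerance = 0.05)
})

test_that("runs are bitwise reproducible and seed-sensitive", {
  dw <- make_double_well()
  sp <- run_spec(20000, seed = 9, output_stride = 100)
  a <- run_segment(dw, sp)
  b <- run_segment(dw, sp)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$state, b$state)
  sp2 <- sp; sp2$seed <- 10L
  expect_false(identical(run_segment(dw, sp2)$trajectory$coords,
                         a$trajectory$coords))
})

test_that("the deterministic limit conserves energy", {
  hs <- harmonic_system(k = 100)
  st <- list(coords = rbind(c(0, 0, 0), c(0.05, 0, 0.58)),
             vels = matrix(0, 2, 3), time = 0)
  sp <- run_spec(10000, friction = 0, temperature = 0, seed = 1,
                 output_stride = 10)
  seg <- run_segment(hs, sp, state = st)
  # total energy = potential + kinetic at each output frame
  etot <- vapply(seq_len(n_frames(seg$trajectory)), function(i) {
    co <- seg$trajectory$coords[i, , ]
    potential_energy(hs, co)
  }, numeric(1))
  # reconstruct kinetic energy only at the end state
  ke_end <- 0.5 * sum(hs$atoms$mass * rowSums(seg$state$vels^2))
  e0 <- potential_energy(hs, st$coords)
  e_end <- potential_energy(hs, seg$state$coords) + ke_end
  expect_lt(abs(e_end - e0) / 10000, 1e-6)
  expect_true(all(etot <= e0 + 1e-6))  # PE never exceeds the total
})

test_that("unbiased sampling reproduces analytic basin weights", {
  dw <- make_double_well(delta_f = 5, barrier = 3, well_separation = 2,
                         temperature = 310)
  sp <- run_spec(8e6, friction = 2, temperature = 310, seed = 3,
                 output_stride = 12500)  # samples every 25 ps
  seg <- run_segment(dw, sp)
  z <- seg$trajectory$cv
  n_cross <- sum(diff(sign(z - dw$basin_split)) != 0)
  expect_gt(n_cross, 50)  # samples are decorrelated on this stride
  f <- dw$analytic_fes
  left <- f$cv <= dw$basin_split
  zl <- trap_boltzmann(f$cv[left], f$free_energy[left], 310)
  zr <- trap_boltzmann(f$cv[!left], f$free_energy[!left], 310)
  p_left <- zl / (zl + zr)
  obs <- c(sum(z <= dw$basin_split), sum(z > dw$basin_split))
  chi <- stats::chisq.test(obs, p = c(p_left, 1 - p_left))
  expect_gt(chi$p.value, 0.01)
})

test_that("a single walker reduces to a plain biased segment", {
  dw <- make_double_well()
  md <- metad_params(gamma = 20, w0 = 5, sigma = 0.1, stride = 500)
  sp <- run_spec(20000, seed = 4, output_stride = 500, biased = TRUE,
                 metad = md)
  st <- list(coords = system_coords(dw),
             vels = metabind:::.maxwell_velocities(dw, 310, sp$seed),
             time = 0)
  seg <- run_segment(dw, sp, state = st)
  seeds <- subset_frames(seg$trajectory, 1)
  seeds$coords[1, , ] <- system_coords(dw)
  mw <- run_multiwalker(dw, seeds, sp, 1)
  expect_identical(mw$frames$coords, seg$trajectory$coords)
  expect_equal(mw$hills$height, seg$hills$height, tolerance = 1e-12)
})

test_that("multiwalker bookkeeping: merged hills, shared grid and replayed heights", {
  dw <- make_double_well()
  md <- metad_params(gamma = 20, w0 = 5, sigma = 0.1, stride = 500)
  sp <- run_spec(10000, seed = 5, output_stride = 500, biased = TRUE,
                 metad = md)
  pre <- run_spec(5000, seed = 6, output_stride = 100)
  warm <- run_segment(dw, pre)
  seeds <- subset_frames(warm$trajectory, c(10, 30, 50))
  mw <- run_multiwalker(dw, seeds, sp, 3)

  # one hill per walker per stride
  expect_equal(nrow(mw$hills), 3 * (10000 / 500))
  expect_equal(sort(unique(mw$hills$walker)), 0:2)

  # the shared grid equals the direct Gaussian sum over all hills
  v_direct <- total_bias(mw$bias$grid, mw$hills)
  expect_equal(mw$bias$v, v_direct, tolerance = 1e-9)

  # single-process replay of the well-tempered recursion (hills in
  # deposition order); engine heights use grid interpolation, hence
  # the loose-ish tolerance
  dT <- (md$gamma - 1) * 310
  acc <- empty_hills()
  for (k in seq_len(nrow(mw$hills))) {
    expected <- 5 * exp(-total_bias(mw$hills$center[k], acc) / (kB * dT))
    expect_equal(mw$hills$height[k], expected, tolerance = 1e-3)
    acc <- rbind(acc, mw$hills[k, ])
  }
})

test_that("the funnel restraint confines the ligand to the funnel", {
  bs <- make_binding_system()
  md <- metad_params(gamma = 20, w0 = 5, sigma = 0.1, stride = 500)
  sp <- run_spec(150000, seed = 8, output_stride = 100, biased = TRUE,
                 walls = bs$default_walls, funnel = bs$default_funnel,
                 metad = md)
  seg <- run_segment(bs, sp)
  co <- seg$trajectory$coords
  dx <- co[, bs$cv_lig, 1] - co[, bs$cv_rec, 1]
  dy <- co[, bs$cv_lig, 2] - co[, bs$cv_rec, 2]
  dz <- co[, bs$cv_lig, 3] - co[, bs$cv_rec, 3]
  r <- sqrt(dx^2 + dy^2)
  outside <- r > funnel_radius(dz, bs$default_funnel) + 0.1
  expect_lt(mean(outside), 0.01)
})
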