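# Synthetic-system generators: calibrated double wells, the planted
# binding landscape, and planted multi-mode ensembles.

test_that("double well reproduces the requested basin free-energy gap", {
  # symmetric case: equal Boltzmann weight in both basins
  dw0 <- make_double_well(delta_f = 0, barrier = 10)
  f <- dw0$analytic_fes
  zl <- trap_boltzmann(f$cv[f$cv <= 0], f$free_energy[f$cv <= 0], 310)
  zr <- trap_boltzmann(f$cv[f$cv >= 0], f$free_energy[f$cv >= 0], 310)
  expect_equal(zl / (zl + zr), 0.5, tolerance = 1e-6)

  # tilted case: basin population ratio exp(-dF/kBT) by the trapezoid
  # oracle, for several gaps and temperatures
  for (df in c(2, 10)) {
    for (temp in c(310, 400)) {
      dw <- make_double_well(delta_f = df, barrier = 15,
                             temperature = temp)
      f <- dw$analytic_fes
      left <- f$cv <= dw$basin_split
      zl <- trap_boltzmann(f$cv[left], f$free_energy[left], temp)
      zr <- trap_boltzmann(f$cv[!left], f$free_energy[!left], temp)
      expect_equal(zr / zl, exp(-df / (kB * temp)), tolerance = 1e-4)
      # quadrature-level agreement of the stated gap
      expect_lt(abs(-kB * temp * log(zr / zl) - df), 0.01)
    }
  }
})

test_that("double well rejects invalid geometry", {
  expect_error(make_double_well(barrier = -1), "barrier")
  expect_error(make_double_well(well_separation = 0), "separation")
})

test_that("binding system plants the bound pose as the global minimum", {
  bs <- make_binding_system(seed = 3)
  ref <- reference_coords(bs)
  e_ref <- potential_energy(bs, ref)
  expect_equal(e_ref, -bs$pocket_depth, tolerance = 1e-6)

  dec <- system_coords(bs)
  dec[bs$ligand_idx, ] <- bs$decoy_pose
  e_dec <- potential_energy(bs, dec)
  expect_gte(e_dec - e_ref,
             bs$pocket_depth - bs$decoy_depth - 0.5)

  # grid search over rigid placements (reference and flipped
  # orientation, 0.05 nm translation grid): nothing beats the pose
  flip <- diag(c(1, -1, -1))  # 180 degrees about x
  pose0 <- sweep(bs$reference_pose, 2, bs$reference_pose[1, ])
  best <- Inf
  for (orient in list(pose0, pose0 %*% flip)) {
    for (x in seq(-0.4, 0.4, by = 0.05)) {
      for (y in seq(-0.4, 0.4, by = 0.05)) {
        for (z in seq(0.2, 1.6, by = 0.05)) {
          co <- system_coords(bs)
          co[bs$ligand_idx, ] <- sweep(orient, 2, c(x, y, z), "+")
          e <- potential_energy(bs, co)
          if (e < best) best <- e
        }
      }
    }
  }
  expect_gte(best, e_ref - 1e-6)
})

test_that("binding system: ligand in the solvent has ~zero energy and the build is deterministic", {
  bs <- make_binding_system(seed = 5)
  expect_lt(abs(potential_energy(bs)), 1e-6)  # start pose is in solvent
  expect_identical(make_binding_system(seed = 5), bs)
  expect_false(identical(make_binding_system(seed = 6)$atoms, bs$atoms))
  expect_error(make_binding_system(pocket_depth = 5, decoy_depth = 10),
               "pocket_depth > decoy_depth")
})

test_that("binding system analytic FES has its minimum at the planted CV", {
  bs <- make_binding_system()
  f <- bs$analytic_fes
  expect_lt(abs(f$cv[which.min(f$free_energy)] - bs$reference_cv), 0.03)
})

test_that("planted ensembles realise the multinomial mode counts", {
  bs <- make_binding_system()
  fr <- c(0.7, 0.2, 0.05, 0.04, 0.01)
  poses <- lapply(seq_along(fr), function(i) {
    sweep(bs$reference_pose, 2, c(0.3 * (i - 1), 0, 0.1 * (i - 1)), "+")
  })
  modes <- Map(function(p, f) list(pose = p, fraction = f,
                                   noise_sd = 0.01), poses, fr)
  spec <- planted_ensemble_spec(modes, n_frames = 5000, seed = 99)
  ens <- sample_planted_ensemble(bs, spec)

  # independent RNG oracle with the same seed policy: the multinomial
  # draw is the first RNG consumption
  oracle_counts <- withr::with_seed(99, as.vector(rmultinom(1, 5000, fr)))
  expect_identical(attr(ens, "counts"), oracle_counts)
  expect_identical(as.vector(table(attr(ens, "mode")))[1:3],
                   oracle_counts[1:3])
})

test_that("planted ensemble recovers fractions within multinomial error", {
  bs <- make_binding_system()
  fr <- c(0.6, 0.3, 0.1)
  modes <- lapply(seq_along(fr), function(i) {
    list(pose = sweep(bs$reference_pose, 2, c(0.4 * (i - 1), 0, 0), "+"),
         fraction = fr[i], noise_sd = 0.005)
  })
  for (seed in 1:3) {
    spec <- planted_ensemble_spec(modes, n_frames = 5000, seed = seed)
    counts <- attr(sample_planted_ensemble(bs, spec), "counts")
    se <- sqrt(5000 * fr * (1 - fr))
    expect_true(all(abs(counts - 5000 * fr) <= 3 * se))
  }
})

test_that("degenerate ensembles behave as stated", {
  bs <- make_binding_system()
  one <- list(list(pose = bs$reference_pose, fraction = 1, noise_sd = 0))
  ens <- sample_planted_ensemble(
    bs, planted_ensemble_spec(one, n_frames = 10, seed = 1))
  for (k in 2:10) {
    expect_equal(ens$coords[k, , ], ens$coords[1, , ])
  }

  # rigid global motion leaves the internal geometry intact
  ens_rm <- sample_planted_ensemble(
    bs, planted_ensemble_spec(one, n_frames = 8, rigid_motion = TRUE,
                              seed = 2))
  fitted <- superpose_backbone(ens_rm, reference_frame = 1)
  for (k in 2:8) {
    expect_lt(ligand_rmsd(fitted$coords[k, , ], fitted$coords[1, , ],
                          bs$ligand_idx), 1e-6)
  }

  bad <- list(list(pose = bs$reference_pose, fraction = 0.9,
                   noise_sd = 0))
  expect_error(planted_ensemble_spec(bad, n_frames = 10), "sum to 1")
})

test_that("toy systems survive a YAML round trip", {
  bs <- make_binding_system(seed = 2)
  path <- tempfile(fileext = ".yaml")
  write_toy_system(bs, path)
  back <- read_toy_system(path)
  expect_equal(back$atoms$x, bs$atoms$x, tolerance = 1e-12)
  expect_equal(back$reference_pose, bs$reference_pose,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(potential_energy(back, reference_coords(back)),
               potential_energy(bs, reference_coords(bs)),
               tolerance = 1e-9)
  expect_equal(back$default_funnel, bs$default_funnel)
})
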