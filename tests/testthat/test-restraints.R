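# Binding CV, harmonic walls and the funnel restraint: printed-value
# checks, gradients against central differences, and symmetries.

test_that("binding CV is the z-component of the anchor->ligand displacement", {
  co <- rbind(c(0, 0, 1.0), c(0.3, -0.2, 1.46))
  expect_equal(binding_cv(co, 1, 2), 0.46)
  expect_equal(binding_cv(rbind(c(1, 2, 3), c(4, 5, 3)), 1, 2), 0)
  shifted <- sweep(co, 2, c(0.7, -1.2, 5.3), "+")
  expect_equal(binding_cv(shifted, 1, 2), binding_cv(co, 1, 2))
  expect_error(binding_cv(co, 1, 3), "out of range")
})

test_that("wall energies match hand evaluation of the harmonic form", {
  w <- wall_params(z_low = 0.4, z_up = 4.5, kappa = 1500)
  expect_equal(wall_bias(2.0, w), 0)
  expect_equal(wall_bias(0.3, w), 15)   # 1500 * 0.1^2
  expect_equal(wall_bias(4.6, w), 15)
  # continuity at both boundaries
  eps <- 1e-9
  expect_lt(abs(wall_bias(0.4 + eps, w) - wall_bias(0.4 - eps, w)), 1e-8)
  expect_lt(abs(wall_bias(4.5 + eps, w) - wall_bias(4.5 - eps, w)), 1e-8)
  expect_error(wall_params(z_low = 2, z_up = 1), "z_low < z_up")
})

test_that("wall gradient matches central differences at random points", {
  w <- wall_params(z_low = 0.3, z_up = 4.9, kappa = 1500)
  zs <- withr::with_seed(1, runif(100, -0.5, 5.5))
  for (z in zs) {
    num <- central_diff(function(s) wall_bias(s, w), z)
    ana <- wall_bias_grad(z, w)
    expect_lt(abs(ana - num), 1e-6 * max(1, abs(ana)))
  }
})

test_that("funnel radius has the printed midpoint and limits and is monotone", {
  fp <- funnel_params()  # printed GPCR parameters
  expect_equal(funnel_radius(fp$w, fp), fp$d / 2 + fp$r1)   # 1.6 nm
  expect_equal(funnel_radius(fp$w + 2, fp), 0.8, tolerance = 1e-6)
  expect_equal(funnel_radius(fp$w - 2, fp), 2.4, tolerance = 1e-6)
  # strict decrease over the resolvable transition region (the sigmoid
  # saturates to machine precision a few units of 1/m beyond w)
  grid <- seq(fp$w - 2, fp$w + 2, length.out = 1000)
  r <- funnel_radius(grid, fp)
  expect_true(all(diff(r) < 0))
  expect_true(all(r > fp$r1 & r < fp$d + fp$r1))
  wide <- funnel_radius(seq(-1, 6, length.out = 1000), fp)
  expect_true(all(wide >= fp$r1 & wide <= fp$d + fp$r1))
})

test_that("funnel bias has the printed plateau and sigmoid midpoint", {
  fp <- funnel_params()
  # far outside: the plateau h = 100 kJ/mol
  z <- 1.7
  R <- funnel_radius(z, fp)
  expect_equal(funnel_bias(R + 1, 0, z, fp), 100, tolerance = 1e-6)
  # on the funnel surface: h/2
  expect_equal(funnel_bias(R, 0, z, fp), 50)
  # well inside: zero
  expect_lt(funnel_bias(R - 1, 0, z, fp), 1e-6)
})

test_that("funnel bias is axially symmetric and has consistent gradients", {
  fp <- funnel_params()
  pts <- withr::with_seed(7, data.frame(r = runif(40, 0, 3),
                                        th = runif(40, 0, 2 * pi),
                                        z = runif(40, 0, 4.5)))
  base <- funnel_bias(pts$r, 0, pts$z, fp)
  rot <- funnel_bias(pts$r * cos(pts$th), pts$r * sin(pts$th), pts$z, fp)
  expect_equal(rot, base, tolerance = 1e-10)

  xyz <- withr::with_seed(8, matrix(runif(300, -2.5, 2.5), ncol = 3))
  xyz[, 3] <- xyz[, 3] + 2  # span the funnel transition region
  for (i in seq_len(nrow(xyz))) {
    p <- xyz[i, ]
    g <- funnel_bias_grad(p[1], p[2], p[3], fp)
    for (dim in 1:3) {
      f1 <- function(v) {
        q <- p; q[dim] <- v
        funnel_bias(q[1], q[2], q[3], fp)
      }
      num <- central_diff(f1, p[dim])
      expect_lt(abs(g[[dim]] - num), 1e-6 * max(1, abs(g[[dim]])))
    }
  }
})

test_that("restraints vanish inside the allowed funnel volume", {
  fp <- funnel_params()
  w <- wall_params(z_low = 0.3, z_up = 4.9)
  pts <- withr::with_seed(9, {
    z <- runif(200, 0.4, 4.8)
    rmax <- funnel_radius(z, fp) - 0.05
    r <- runif(200, 0, 1) * rmax
    th <- runif(200, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th), z)
  })
  e <- funnel_bias(pts[, 1], pts[, 2], pts[, 3], fp) +
    wall_bias(pts[, 3], w)
  expect_true(all(e <= 1e-3))
})

test_that("engine-side restraint forces agree with the analytic R gradients", {
  # the C++ kernel reimplements walls + funnel; cross-check via the
  # deterministic zero-temperature force response of a free particle
  bs <- make_binding_system()
  fp <- bs$default_funnel
  w <- bs$default_walls
  co <- system_coords(bs)
  d <- co[bs$cv_lig, ] - co[bs$cv_rec, ]
  eR <- restraint_energy(co, bs$cv_rec, bs$cv_lig, walls = w,
                         funnel = fp)
  expect_equal(eR, wall_bias(d[3], w) +
                 funnel_bias(d[1], d[2], d[3], fp))
})

test_that("the PLUMED stanza export reflects the parameters", {
  txt <- plumed_restraint_stanza(wall_params(0.3, 4.9),
                                 funnel_params(), cvname = "dz")
  expect_true(any(grepl("LOWER_WALLS .*AT=0.3", txt)))
  expect_true(any(grepl("UPPER_WALLS .*AT=4.9", txt)))
  expect_true(any(grepl("funnel", txt)))
})
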