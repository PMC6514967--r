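## Synthetic receptor-ligand systems with analytically known free
## energies and planted binding modes.  These provide ground truth for
## validating the metadynamics engine, the clustering stage and the
## refinement stage.

.toy_system <- function(name, atoms, terms, cv_rec, cv_lig,
                        backbone_idx, ligand_idx, reference_pose,
                        reference_cv, analytic_fes = NULL,
                        basin_split = NA_real_, temperature = 310,
                        default_walls = NULL, default_funnel = NULL) {
  .assert(length(cv_rec) == 1 && length(cv_lig) == 1,
          "toy_system: exactly one receptor and one ligand CV atom")
  .assert(nrow(reference_pose) == length(ligand_idx),
          "toy_system: reference_pose must match the ligand atom group")
  structure(list(name = name, atoms = atoms,
                 potential = list(terms = terms),
                 cv_rec = as.integer(cv_rec), cv_lig = as.integer(cv_lig),
                 backbone_idx = as.integer(backbone_idx),
                 ligand_idx = as.integer(ligand_idx),
                 reference_pose = reference_pose,
                 reference_cv = reference_cv,
                 analytic_fes = analytic_fes,
                 basin_split = basin_split,
                 temperature = temperature,
                 default_walls = default_walls,
                 default_funnel = default_funnel),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf(
    "toy_system '%s': %d atoms (%d backbone, %d ligand), T = %g K\n",
    x$name, nrow(x$atoms), length(x$backbone_idx), length(x$ligand_idx),
    x$temperature))
  if (!is.null(x$analytic_fes))
    cat(sprintf("  analytic FES on [%.2f, %.2f] nm; reference CV %.3f nm\n",
                min(x$analytic_fes$cv), max(x$analytic_fes$cv),
                x$reference_cv))
  invisible(x)
}

#' System coordinates of a toy system
#' @param system A `toy_system`.
#' @return Numeric n x 3 matrix (nm).
#' @export
system_coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

#' Potential energy of a configuration
#'
#' Evaluates the system potential (wells, bonds, repulsions; no
#' restraints, no metadynamics bias) for given coordinates.
#'
#' @param system A `toy_system`.
#' @param coords Coordinate matrix (n x 3, nm); defaults to the stored
#'   system coordinates.
#' @return Energy in kJ/mol.
#' @export
potential_energy <- function(system, coords = NULL) {
  if (is.null(coords)) coords <- system_coords(system)
  potential_energy_cpp(coords, system$potential$terms)
}

#' Free-energy difference between two basins by Boltzmann integration
#'
#' Trapezoid-rule integration of `exp(-F/kBT)` over the two sides of a
#' split point; returns `F(right basin) - F(left basin)`.
#'
#' @param cv Strictly increasing CV grid (nm).
#' @param free_energy Free energy on the grid (kJ/mol).
#' @param split CV value separating the basins.
#' @param temperature Temperature in K.
#' @return Free-energy difference in kJ/mol.
#' @export
basin_delta_f <- function(cv, free_energy, split, temperature) {
  beta <- 1 / (.kB * temperature)
  w <- exp(-beta * (free_energy - min(free_energy)))
  trap <- function(xs, ys) {
    if (length(xs) < 2) return(0)
    sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  }
  # both basins include the split sample so neither loses the boundary
  # sliver of the grid
  zl <- trap(cv[cv <= split], w[cv <= split])
  zr <- trap(cv[cv >= split], w[cv >= split])
  .assert(zl > 0 && zr > 0, "basin_delta_f: empty basin")
  -(log(zr) - log(zl)) / beta
}

## ---- 1D double well --------------------------------------------------------

#' One-dimensional double-well system with a known basin free-energy gap
#'
#' A single particle in the quartic potential
#' `U(z) = barrier * ((z^2 - a^2)/a^2)^2 + c * z` with minima near
#' `z = -a` and `z = +a` (`a = well_separation / 2`).  The linear tilt
#' `c` is calibrated by root finding so that the Boltzmann-integrated
#' free-energy difference between the two basins (split at the barrier
#' top) equals `delta_f` exactly at the stated temperature; for
#' `delta_f > 0` the low-z basin is the global minimum.
#'
#' The system carries its own analytic free-energy profile along the CV
#' (which here is simply the particle's z position relative to a frozen
#' anchor at the origin).
#'
#' @param delta_f Target basin free-energy difference (kJ/mol).
#' @param barrier Barrier height of the untilted well (kJ/mol, > 0).
#' @param well_separation Distance between the two minima (nm, > 0).
#' @param temperature Temperature (K).
#' @return A `toy_system`.
#' @export
make_double_well <- function(delta_f = 10, barrier = 15,
                             well_separation = 2, temperature = 310) {
  .assert(barrier > 0, "make_double_well: barrier must be positive")
  .assert(well_separation > 0,
          "make_double_well: well_separation must be positive")
  a <- well_separation / 2
  grid <- seq(-2.5 * a, 2.5 * a, length.out = 6001)
  u0 <- barrier * ((grid^2 - a^2) / a^2)^2

  delta_for_tilt <- function(cc) {
    u <- u0 + cc * grid
    inner <- grid > -a & grid < a
    split <- grid[inner][which.max(u[inner])]
    basin_delta_f(grid, u, split, temperature)
  }
  target <- abs(delta_f)
  if (target < 1e-12) {
    cc <- 0
  } else {
    cmax <- 2 * target / well_separation + 2
    cc <- stats::uniroot(function(c) delta_for_tilt(c) - target,
                         c(0, cmax), tol = 1e-12)$root
  }
  if (delta_f < 0) cc <- -cc

  u <- u0 + cc * grid
  inner <- grid > -a & grid < a
  split <- grid[inner][which.max(u[inner])]
  zmin <- grid[which.min(u)]

  atoms <- data.frame(
    name = c("ANC", "LIG"),
    group = c("receptor_backbone", "ligand_heavy"),
    mass = c(12, 14),
    x = c(0, 0), y = c(0, 0), z = c(0, -a),
    frozen = c(TRUE, FALSE))
  terms <- list(
    list(type = "quartic_z", atom = 2L,
         c4 = barrier / a^4, c3 = 0, c2 = -2 * barrier / a^2,
         c1 = cc, c0 = barrier),
    list(type = "harm_xy", atom = 2L, k = 50))

  .toy_system(
    name = sprintf("double_well_df%g", delta_f),
    atoms = atoms, terms = terms,
    cv_rec = 1L, cv_lig = 2L,
    backbone_idx = 1L, ligand_idx = 2L,
    reference_pose = matrix(c(0, 0, zmin), 1, 3),
    reference_cv = zmin,
    analytic_fes = data.frame(cv = grid, free_energy = u - min(u)),
    basin_split = split,
    temperature = temperature)
}

## ---- 3D pocket + channel binding system ------------------------------------

# rigid 4-bead ligand in its local frame: amine-N analogue at the
# origin, asymmetric carbon tail pointing along -z
.ligand_local <- function() {
  rbind(N  = c(0.00,  0.00,  0.00),
        C1 = c(0.00,  0.00, -0.15),
        C2 = c(0.13,  0.00, -0.28),
        C3 = c(-0.10, 0.09, -0.12))
}

#' Three-dimensional pocket-and-channel binding system
#'
#' A miniature binding landscape: a frozen pseudo-receptor scaffold (an
#' anchor bead at the origin plus two rings of backbone beads forming a
#' pocket around the z axis), a rigid four-bead ligand held together by
#' stiff bonds, a Gaussian binding well whose global minimum is the
#' planted reference pose inside the pocket (ligand nitrogen on the
#' axis, tail down), a shallower planted decoy well in the pocket
#' vestibule, and an open channel along +z to a flat "solvent" region.
#' Soft harmonic repulsions keep the ligand from passing through the
#' scaffold.
#'
#' At build time an approximate analytic free-energy profile along the
#' binding CV is computed by Boltzmann integration of the site
#' potential over the funnel-allowed transverse plane at each z (the
#' ligand orientation is treated adiabatically, i.e. the full binding
#' depth is attributed to the nitrogen site well).
#'
#' @param pocket_depth Depth of the binding well (kJ/mol).
#' @param decoy_depth Depth of the planted decoy well (kJ/mol), must be
#'   smaller than `pocket_depth`.
#' @param channel_length Length of the solvent channel above the pocket
#'   (nm).
#' @param seed Integer seed for the (deterministic) scaffold jitter.
#' @return A `toy_system` with `default_walls` and `default_funnel`
#'   attached.
#' @export
make_binding_system <- function(pocket_depth = 60, decoy_depth = 20,
                                channel_length = 3.5, seed = 1) {
  .assert(pocket_depth > decoy_depth && decoy_depth > 0,
          "make_binding_system: need pocket_depth > decoy_depth > 0")
  pocket <- c(0, 0, 0.5)
  decoy <- c(0, 0, 1.3)
  lig <- .ligand_local()

  ring <- function(nb, radius, zlev) {
    ang <- 2 * pi * (seq_len(nb) - 1) / nb
    cbind(radius * cos(ang), radius * sin(ang), zlev)
  }
  scaffold <- rbind(c(0, 0, 0), ring(6, 0.50, 0.10), ring(6, 0.55, 0.60))
  # small deterministic jitter breaks the scaffold symmetry (keeps the
  # backbone superposition well conditioned); the anchor stays at the origin
  jit <- withr::with_seed(seed, matrix(rnorm(nrow(scaffold) * 3, sd = 0.02),
                                       ncol = 3))
  jit[1, ] <- 0
  scaffold <- scaffold + jit

  nb <- nrow(scaffold)
  ref_pose <- sweep(lig, 2, pocket, "+")
  start_pose <- sweep(lig, 2, c(0, 0, 0.5 + channel_length - 0.4), "+")

  atoms <- data.frame(
    name = c("ANC", sprintf("B%02d", seq_len(nb - 1)),
             rownames(lig)),
    group = c(rep("receptor_backbone", nb), rep("ligand_heavy", 4)),
    mass = c(rep(12, nb), 14, 12, 12, 12),
    x = c(scaffold[, 1], start_pose[, 1]),
    y = c(scaffold[, 2], start_pose[, 2]),
    z = c(scaffold[, 3], start_pose[, 3]),
    frozen = c(rep(TRUE, nb), rep(FALSE, 4)))
  lig_idx <- nb + 1:4
  n_idx <- nb + 1L   # ligand CV atom (amine nitrogen analogue)

  terms <- list(
    # binding contacts: the nitrogen site plus two tail contacts that
    # fix the bound orientation; depths sum to pocket_depth and all
    # three are centred on the reference pose
    list(type = "gwell", atom = n_idx, center = pocket,
         depth = 0.50 * pocket_depth, width = 0.12),
    list(type = "gwell", atom = nb + 3L, center = ref_pose[3, ],
         depth = 0.30 * pocket_depth, width = 0.11),
    list(type = "gwell", atom = nb + 4L, center = ref_pose[4, ],
         depth = 0.20 * pocket_depth, width = 0.11),
    # planted metastable decoy in the vestibule
    list(type = "gwell", atom = n_idx, center = decoy,
         depth = decoy_depth, width = 0.12),
    # receptor body: only a narrow cavity (r < 0.35 nm) is open below
    # the pocket mouth at z = 0.9 nm
    list(type = "pocket_wall", atom = n_idx, r0 = 0.35, k = 500,
         z0 = 0.9, mz = 10),
    list(type = "pocket_wall", atom = nb + 3L, r0 = 0.35, k = 500,
         z0 = 0.9, mz = 10))
  # stiff bonds between all bead pairs make the ligand effectively rigid
  for (i in 1:3) for (j in (i + 1):4) {
    r0 <- sqrt(sum((lig[i, ] - lig[j, ])^2))
    terms <- c(terms, list(list(type = "bond", i = nb + i, j = nb + j,
                                r0 = r0, k = 40000)))
  }
  for (i in lig_idx) for (j in seq_len(nb)) {
    terms <- c(terms, list(list(type = "rep", i = i, j = j,
                                rcut = 0.25, k = 2000)))
  }

  walls <- wall_params(z_low = 0.1, z_up = 0.5 + channel_length,
                       kappa = 1500)
  # funnel sized to the toy scaffold: ~1 nm radius at the pocket mouth
  # narrowing to 0.4 nm in the solvent channel (same functional form as
  # the GPCR funnel, smaller geometry)
  funnel <- funnel_params(d = 0.6, r1 = 0.4, m = 10, w = 1.5)

  sys <- .toy_system(
    name = "binding_pocket_channel",
    atoms = atoms, terms = terms,
    cv_rec = 1L, cv_lig = n_idx,
    backbone_idx = seq_len(nb), ligand_idx = lig_idx,
    reference_pose = ref_pose, reference_cv = pocket[3],
    temperature = 310,
    default_walls = walls, default_funnel = funnel)
  sys$decoy_pose <- sweep(lig, 2, decoy, "+")
  sys$pocket_depth <- pocket_depth
  sys$decoy_depth <- decoy_depth
  sys$analytic_fes <- .binding_analytic_fes(pocket_depth, decoy_depth,
                                            pocket, decoy, walls, funnel,
                                            sys$temperature)
  sys
}

# transverse Boltzmann integration of the axial site wells inside the
# funnel: F(z) = -kT log Int_0^R(z) 2 pi r exp(-beta U(r, z)) dr
.binding_analytic_fes <- function(pocket_depth, decoy_depth, pocket,
                                  decoy, walls, funnel, temperature) {
  beta <- 1 / (.kB * temperature)
  zgrid <- seq(walls$z_low, walls$z_up, by = 0.01)
  f <- vapply(zgrid, function(z) {
    R <- funnel_radius(z, funnel)
    r <- seq(0, R, by = 0.005)
    d2p <- r^2 + (z - pocket[3])^2
    d2d <- r^2 + (z - decoy[3])^2
    gate <- .sigmoid(-10 * (z - 0.9))
    u <- -pocket_depth * exp(-d2p / (2 * 0.12^2)) -
      decoy_depth * exp(-d2d / (2 * 0.12^2)) +
      0.5 * 500 * gate * pmax(0, r - 0.35)^2
    integrand <- 2 * pi * r * exp(-beta * u)
    -log(sum(diff(r) * (head(integrand, -1) + tail(integrand, -1)) / 2)) /
      beta
  }, numeric(1))
  data.frame(cv = zgrid, free_energy = f - min(f))
}

## ---- planted conformational ensembles --------------------------------------

#' Specification of a planted multi-mode ensemble
#'
#' @param modes List of modes, each a list with elements `pose` (ligand
#'   coordinate matrix, nm), `fraction` (population fraction) and
#'   `noise_sd` (per-atom Gaussian positional noise, nm).
#' @param n_frames Number of frames to draw (>= number of modes).
#' @param backbone_jitter_sd Gaussian jitter of the backbone beads (nm).
#' @param rigid_motion Apply a random global rotation + translation to
#'   every frame.
#' @param seed Integer RNG seed.
#' @return An object of class `planted_ensemble_spec`.
#' @export
planted_ensemble_spec <- function(modes, n_frames,
                                  backbone_jitter_sd = 0,
                                  rigid_motion = FALSE, seed = 1) {
  fr <- vapply(modes, `[[`, numeric(1), "fraction")
  .assert(abs(sum(fr) - 1) <= 1e-9,
          "planted_ensemble_spec: population fractions must sum to 1")
  .assert(n_frames >= length(modes),
          "planted_ensemble_spec: n_frames must be >= number of modes")
  .assert(all(vapply(modes, `[[`, numeric(1), "noise_sd") >= 0),
          "planted_ensemble_spec: noise sds must be >= 0")
  .assert(backbone_jitter_sd >= 0,
          "planted_ensemble_spec: backbone_jitter_sd must be >= 0")
  structure(list(modes = modes, n_frames = as.integer(n_frames),
                 backbone_jitter_sd = backbone_jitter_sd,
                 rigid_motion = isTRUE(rigid_motion),
                 seed = as.integer(seed)),
            class = "planted_ensemble_spec")
}

# rotation matrix about a random axis by a random angle
.random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Sample a planted multi-mode ensemble
#'
#' Draws frames mode-by-mode according to the population fractions (a
#' single multinomial draw with the given seed, which is the first RNG
#' consumption), adds Gaussian positional noise per ligand atom and
#' optional backbone jitter, optionally applies a random global rigid
#' motion per frame, and computes the binding CV of every frame.
#'
#' @param system A `toy_system` whose ligand the mode poses conform to.
#' @param spec A [planted_ensemble_spec()].
#' @return A [frame_set()] with attribute `mode` holding the true
#'   per-frame mode index (the planted truth).
#' @export
sample_planted_ensemble <- function(system, spec) {
  .assert(inherits(spec, "planted_ensemble_spec"),
          "sample_planted_ensemble: spec must be a planted_ensemble_spec")
  nlig <- length(system$ligand_idx)
  for (m in spec$modes) {
    .assert(nrow(m$pose) == nlig,
            "sample_planted_ensemble: mode pose does not match the ligand")
  }
  base <- system_coords(system)
  nf <- spec$n_frames
  na <- nrow(base)
  fr <- vapply(spec$modes, `[[`, numeric(1), "fraction")

  withr::with_seed(spec$seed, {
    counts <- as.vector(rmultinom(1, nf, fr))
    assign_mode <- sample(rep(seq_along(spec$modes), counts))
    coords <- array(0, dim = c(nf, na, 3))
    for (k in seq_len(nf)) {
      fc <- base
      mode <- spec$modes[[assign_mode[k]]]
      fc[system$ligand_idx, ] <- mode$pose +
        matrix(rnorm(nlig * 3, sd = mode$noise_sd), nlig, 3)
      if (spec$backbone_jitter_sd > 0) {
        nbk <- length(system$backbone_idx)
        fc[system$backbone_idx, ] <- fc[system$backbone_idx, ] +
          matrix(rnorm(nbk * 3, sd = spec$backbone_jitter_sd), nbk, 3)
      }
      if (spec$rigid_motion) {
        R <- .random_rotation()
        tr <- runif(3, -0.5, 0.5)
        fc <- sweep(fc %*% t(R), 2, tr, "+")
      }
      coords[k, , ] <- fc
    }
  })

  out <- frame_set(coords,
                   backbone_idx = system$backbone_idx,
                   ligand_idx = system$ligand_idx,
                   cv_rec = system$cv_rec, cv_lig = system$cv_lig)
  attr(out, "mode") <- assign_mode
  attr(out, "counts") <- counts
  out
}
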