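## Langevin (BAOAB) dynamics of toy systems under the system potential
## plus walls, funnel and the history-dependent metadynamics bias.

#' Simulation run specification
#'
#' @param n_steps Number of integration steps (>= 1).
#' @param dt Time step (ps).  Default 0.002 (2 fs).
#' @param friction Langevin friction (ps^-1).
#' @param temperature Temperature (K).
#' @param seed Master RNG seed of the run.
#' @param output_stride Steps between trajectory/COLVAR records.
#' @param biased Whether metadynamics bias is deposited and felt.
#' @param walls Optional [wall_params()].
#' @param funnel Optional [funnel_params()].
#' @param metad Optional [metad_params()]; required when `biased`.
#' @return An object of class `run_spec`.
#' @export
run_spec <- function(n_steps, dt = 0.002, friction = 1,
                     temperature = 310, seed = 1, output_stride = 100,
                     biased = FALSE, walls = NULL, funnel = NULL,
                     metad = NULL) {
  .assert(dt > 0, "run_spec: dt must be > 0")
  .assert(n_steps >= 1, "run_spec: n_steps must be >= 1")
  if (biased) .assert(!is.null(metad), "run_spec: biased runs require metad")
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 friction = friction, temperature = temperature,
                 seed = as.integer(seed),
                 output_stride = as.integer(output_stride),
                 biased = isTRUE(biased), walls = walls, funnel = funnel,
                 metad = metad),
            class = "run_spec")
}

# deterministic sub-seed for (walker, round) derived from the master seed
.derive_seed <- function(master, walker, round) {
  ((master %% 100000) * 2654435 + walker * 97003 + round * 101) %%
    2147483647 + 1
}

# Maxwell-Boltzmann velocities (frozen atoms get zero)
.maxwell_velocities <- function(system, temperature, seed) {
  m <- system$atoms$mass
  v <- withr::with_seed(seed, matrix(rnorm(length(m) * 3), ncol = 3)) *
    sqrt(.kB * temperature / m)
  v[system$atoms$frozen, ] <- 0
  v
}

#' Fresh shared metadynamics bias state
#'
#' Bias potential and its CV-derivative on a uniform grid, plus the
#' global hill list; shared by all walkers of a run.
#'
#' @param grid_min,grid_max CV grid range (nm).
#' @param grid_step Grid spacing (nm), default 0.01.
#' @return An object of class `bias_state`.
#' @export
new_bias_state <- function(grid_min, grid_max, grid_step = 0.01) {
  grid <- seq(grid_min, grid_max, by = grid_step)
  structure(list(grid_min = grid_min, grid_step = grid_step,
                 grid = grid, v = numeric(length(grid)),
                 f = numeric(length(grid)), hills = empty_hills()),
            class = "bias_state")
}

# default CV grid range for the bias of a run
.bias_range <- function(system, spec) {
  if (!is.null(spec$walls)) {
    c(spec$walls$z_low - 0.5, spec$walls$z_up + 0.5)
  } else if (!is.null(system$analytic_fes)) {
    range(system$analytic_fes$cv)
  } else {
    cv0 <- binding_cv(system_coords(system), system$cv_rec, system$cv_lig)
    c(cv0 - 3, cv0 + 3)
  }
}

.hills_from_matrix <- function(mat) {
  if (nrow(mat) == 0) return(empty_hills())
  .as_hills(data.frame(time = mat[, 1], center = mat[, 2],
                       sigma = mat[, 3], height = mat[, 4],
                       walker = as.integer(mat[, 5])))
}

#' Run one dynamics segment
#'
#' BAOAB-discretised Langevin dynamics of a toy system under the system
#' potential, the CV walls, the funnel restraint and (for biased runs)
#' the well-tempered metadynamics bias, with in-run hill deposition.
#'
#' @param system A `toy_system`.
#' @param spec A [run_spec()].
#' @param state Optional initial state `list(coords, vels, time)`; by
#'   default the system coordinates with Maxwell-Boltzmann velocities
#'   drawn from the run seed.
#' @param bias Optional [new_bias_state()] carried over from earlier
#'   segments (biased runs); a fresh one is created if absent.
#' @param walker_id Walker id recorded with deposited hills and frames.
#' @return A list with `trajectory` (a [frame_set()]), `colvar` (data
#'   frame: time, cv, bias, energy), `hills` (hills deposited by this
#'   segment), `bias` (updated bias state) and `state` (final state).
#' @export
run_segment <- function(system, spec, state = NULL, bias = NULL,
                        walker_id = 0L) {
  coords <- if (is.null(state)) system_coords(system) else state$coords
  vels <- if (is.null(state)) {
    .maxwell_velocities(system, spec$temperature, spec$seed)
  } else state$vels
  t0 <- if (is.null(state)) 0 else state$time
  .assert(nrow(coords) == nrow(system$atoms),
          "run_segment: state inconsistent with system")

  metad_arg <- NULL
  if (spec$biased) {
    if (is.null(bias)) {
      rng <- .bias_range(system, spec)
      bias <- new_bias_state(rng[1], rng[2])
    }
    metad_arg <- list(w0 = spec$metad$w0, gamma = spec$metad$gamma,
                      sigma = spec$metad$sigma,
                      stride = spec$metad$stride,
                      grid_min = bias$grid_min,
                      grid_step = bias$grid_step,
                      step_offset = round(t0 / spec$dt),
                      walker_id = as.integer(walker_id),
                      bias_v = bias$v, bias_f = bias$f)
  }

  res <- ld_run_cpp(coords, vels, system$atoms$mass,
                    system$atoms$frozen, system$potential$terms,
                    system$cv_rec, system$cv_lig,
                    spec$walls, spec$funnel, metad_arg,
                    spec$dt, spec$friction, spec$temperature,
                    spec$n_steps, spec$output_stride, t0, spec$seed)

  nf <- res$n_frames
  na <- nrow(coords)
  traj_arr <- array(res$traj, dim = c(3, na, nf))  # filled [coord, atom, frame]
  traj <- aperm(traj_arr, c(3, 2, 1))
  trajectory <- frame_set(traj, cv = res$cv[seq_len(nf)],
                          time = res$time[seq_len(nf)],
                          walker = rep(as.integer(walker_id), nf),
                          backbone_idx = system$backbone_idx,
                          ligand_idx = system$ligand_idx,
                          cv_rec = system$cv_rec, cv_lig = system$cv_lig)
  hills <- .hills_from_matrix(res$hills)
  if (spec$biased) {
    bias$v <- res$bias_v
    bias$f <- res$bias_f
    bias$hills <- .as_hills(rbind(bias$hills, hills))
  }
  list(trajectory = trajectory,
       colvar = data.frame(time = res$time[seq_len(nf)],
                           cv = res$cv[seq_len(nf)],
                           bias = res$bias[seq_len(nf)],
                           energy = res$energy[seq_len(nf)]),
       hills = hills, bias = bias,
       state = list(coords = res$coords, vels = res$vels,
                    time = res$final_time))
}

#' Run shared-bias multiple-walker metadynamics
#'
#' Walkers advance in an interleaved schedule (one deposition stride per
#' walker per round) and deposit into, and feel, a single shared bias.
#' Every hill becomes visible to all walkers from the deposition event
#' onward.
#'
#' @param system A `toy_system`.
#' @param seeds A [frame_set()] of `n_walkers` starting structures
#'   (e.g. from [select_walker_seeds()]).
#' @param spec A [run_spec()] with `biased = TRUE`; `n_steps` is the
#'   per-walker step count.
#' @param n_walkers Number of walkers.
#' @return A list with `frames` (merged frame_set, walker-tagged),
#'   `hills` (merged, time-sorted), `bias` (final shared bias state) and
#'   `states` (final per-walker states).
#' @export
run_multiwalker <- function(system, seeds, spec, n_walkers) {
  .assert(spec$biased && !is.null(spec$metad),
          "run_multiwalker: spec must be biased with metad parameters")
  .assert(n_frames(seeds) == n_walkers,
          "run_multiwalker: need exactly one seed frame per walker")

  if (n_walkers == 1) {
    st <- list(coords = seeds$coords[1, , ],
               vels = .maxwell_velocities(system, spec$temperature,
                                          spec$seed),
               time = 0)
    seg <- run_segment(system, spec, state = st, walker_id = 0L)
    return(list(frames = seg$trajectory, hills = seg$hills,
                bias = seg$bias, states = list(seg$state)))
  }

  stride <- spec$metad$stride
  n_rounds <- ceiling(spec$n_steps / stride)
  rng <- .bias_range(system, spec)
  bias <- new_bias_state(rng[1], rng[2])

  states <- lapply(seq_len(n_walkers), function(w) {
    list(coords = seeds$coords[w, , ],
         vels = .maxwell_velocities(system, spec$temperature,
                                    .derive_seed(spec$seed, w, 0)),
         time = 0)
  })

  round_spec <- spec
  round_spec$n_steps <- as.integer(stride)
  traj_parts <- vector("list", n_rounds * n_walkers)
  k <- 0
  for (r in seq_len(n_rounds)) {
    for (w in seq_len(n_walkers)) {
      round_spec$seed <- .derive_seed(spec$seed, w, r)
      seg <- run_segment(system, round_spec, state = states[[w]],
                         bias = bias, walker_id = w - 1L)
      bias <- seg$bias
      states[[w]] <- seg$state
      k <- k + 1
      traj_parts[[k]] <- seg$trajectory
    }
  }
  frames <- do.call(bind_frames, traj_parts)
  hills <- bias$hills[order(bias$hills$time, bias$hills$walker), ]
  rownames(hills) <- NULL
  list(frames = frames, hills = .as_hills(hills), bias = bias,
       states = states)
}
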