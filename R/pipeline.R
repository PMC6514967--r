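## One-shot protocol orchestrator: initial pathway-sampling
## metadynamics -> walker seeding -> shared-bias multiple walkers ->
## free-energy profile and minimum -> frame extraction -> clustering ->
## unbiased refinement -> final report.

#' Pipeline configuration
#'
#' Bundles every stage parameter of the binding-mode protocol with the
#' published defaults: initial metadynamics with bias factor 50 and
#' 7 kJ/mol initial hills, multiple-walker metadynamics with bias
#' factor 20 and 5 kJ/mol hills (Gaussian width 0.1 nm in both), 32
#' walkers, a 0.3 nm (3 Angstrom) extraction window and five target
#' clusters.
#'
#' @param system A `toy_system`.
#' @param out_dir Output directory for stage files.
#' @param seed Master seed for all stages.
#' @param n_walkers Number of walkers (default 32).
#' @param initial_metad [metad_params()] of the initial pathway run.
#' @param walker_metad [metad_params()] of the multiple-walker run.
#' @param walls,funnel Restraints; default to the system's.
#' @param delta_cv Extraction window half-width (nm, default 0.3).
#' @param n_clusters Target cluster count (default 5).
#' @param initial_steps,walker_steps,refine_steps Step counts of the
#'   initial run, each walker, and each refinement run.
#' @param dt,friction,output_stride Integrator settings.
#' @param pocket_entry_cv CV value of the binding-pocket entry (nm),
#'   used by the escape guard.
#' @param escape_threshold Minimum fraction of initial-run frames that
#'   must lie below `pocket_entry_cv`; below it the upper wall is
#'   tightened to the pocket entry (default 0.2).
#' @param max_cluster_frames Cap on the number of extracted frames fed
#'   to clustering (deterministic thinning above it).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(system, out_dir = tempfile("metabind_run_"),
                            seed = 1, n_walkers = 32,
                            initial_metad = metad_params(
                              gamma = 50, w0 = 7, sigma = 0.1,
                              temperature = system$temperature),
                            walker_metad = metad_params(
                              gamma = 20, w0 = 5, sigma = 0.1,
                              temperature = system$temperature),
                            walls = system$default_walls,
                            funnel = system$default_funnel,
                            delta_cv = 0.3, n_clusters = 5,
                            initial_steps = 400000,
                            walker_steps = 150000,
                            refine_steps = 150000,
                            dt = 0.002, friction = 1,
                            output_stride = 250,
                            pocket_entry_cv = 1.5,
                            escape_threshold = 0.2,
                            max_cluster_frames = 4000) {
  structure(list(system = system, out_dir = out_dir, seed = seed,
                 n_walkers = n_walkers, initial_metad = initial_metad,
                 walker_metad = walker_metad, walls = walls,
                 funnel = funnel, delta_cv = delta_cv,
                 n_clusters = n_clusters,
                 initial_steps = as.integer(initial_steps),
                 walker_steps = as.integer(walker_steps),
                 refine_steps = as.integer(refine_steps),
                 dt = dt, friction = friction,
                 output_stride = as.integer(output_stride),
                 pocket_entry_cv = pocket_entry_cv,
                 escape_threshold = escape_threshold,
                 max_cluster_frames = as.integer(max_cluster_frames)),
            class = "pipeline_config")
}

#' Escape guard: tighten the upper CV wall if the pocket is undersampled
#'
#' If fewer than `escape_threshold` of the initial-run frames have a CV
#' below the pocket-entry value, the ligand is deemed to be escaping
#' into the solvent and the upper wall is lowered to the pocket entry.
#'
#' @param config A [pipeline_config()].
#' @param trajectory The initial-run [frame_set()].
#' @return A [wall_params()] object (possibly unchanged) with
#'   attributes `fired` (logical) and `fraction_inside`.
#' @export
escape_guard <- function(config, trajectory) {
  frac <- mean(trajectory$cv < config$pocket_entry_cv)
  fired <- frac < config$escape_threshold
  walls <- config$walls
  if (fired) {
    walls <- wall_params(z_low = walls$z_low,
                         z_up = config$pocket_entry_cv,
                         kappa = walls$kappa)
  }
  attr(walls, "fired") <- fired
  attr(walls, "fraction_inside") <- frac
  walls
}

#' Run the full binding-mode determination pipeline
#'
#' Executes: initial metadynamics along the binding path, the escape
#' guard (with a supplemental segment to cover the full path when the
#' wall is tightened), equidistant walker seeding, shared-bias
#' multiple-walker metadynamics, free-energy reconstruction and
#' minimum location, extraction of frames within the CV window,
#' backbone superposition and average-linkage clustering with
#' population ranking, unbiased refinement of every representative,
#' and the final convergence report.  All stage outputs and parameters
#' are written under `config$out_dir` and recorded in a JSON manifest.
#'
#' @param config A [pipeline_config()].
#' @param stop_after Optional stage name at which to stop: one of
#'   `"initial"`, `"seeds"`, `"multiwalker"`, `"fes"`, `"extract"`,
#'   `"cluster"`.
#' @return A list of stage results (`initial`, `walls`, `seeds`,
#'   `multiwalker`, `fes`, `extract`, `cluster`, `refine`, `report`),
#'   plus `manifest` (the manifest list) and `manifest_path`.
#' @export
run_pipeline <- function(config, stop_after = NULL) {
  sys <- config$system
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, out_dir = config$out_dir,
                   system = sys$name, stages = list())
  result <- list()
  path <- function(f) file.path(config$out_dir, f)
  done <- function(stage) {
    !is.null(stop_after) && identical(stop_after, stage)
  }

  ## --- stage 1: initial pathway metadynamics -------------------------------
  init_spec <- run_spec(config$initial_steps, dt = config$dt,
                        friction = config$friction,
                        temperature = sys$temperature,
                        seed = .derive_seed(config$seed, 0, 1),
                        output_stride = config$output_stride,
                        biased = TRUE, walls = config$walls,
                        funnel = config$funnel,
                        metad = config$initial_metad)
  init <- run_segment(sys, init_spec)
  write_hills(init$hills, path("HILLS.initial"),
              gamma = config$initial_metad$gamma)
  write_colvar(init$colvar, path("COLVAR.initial"))
  result$initial <- init
  manifest$stages$initial <- list(
    n_steps = config$initial_steps,
    gamma = config$initial_metad$gamma, w0 = config$initial_metad$w0,
    hills = path("HILLS.initial"), colvar = path("COLVAR.initial"),
    n_hills = nrow(init$hills))
  if (done("initial")) return(.finish_pipeline(result, manifest, config))

  ## --- stage 2: escape guard + seed pool -----------------------------------
  walls <- escape_guard(config, init$trajectory)
  pool <- init$trajectory
  if (isTRUE(attr(walls, "fired"))) {
    # tightened wall: resample the pocket region under the tight wall,
    # then supplement out-of-pocket conformations from the original
    # segment so the seed pool still spans the whole path
    entry_state <- list(coords = system_coords(sys),
                        vels = .maxwell_velocities(
                          sys, sys$temperature,
                          .derive_seed(config$seed, 0, 2)),
                        time = 0)
    entry_state$coords[sys$ligand_idx, ] <-
      sweep(sys$reference_pose, 2,
            c(0, 0, config$pocket_entry_cv - sys$reference_cv), "+")
    tight_spec <- init_spec
    tight_spec$walls <- walls
    tight_spec$seed <- .derive_seed(config$seed, 0, 3)
    tight <- run_segment(sys, tight_spec, state = entry_state)
    pool <- bind_frames(tight$trajectory, pool)
  }
  result$walls <- walls
  manifest$stages$escape_guard <- list(
    fired = isTRUE(attr(walls, "fired")),
    fraction_inside = attr(walls, "fraction_inside"),
    z_up = walls$z_up)

  seeds <- select_walker_seeds(pool, config$n_walkers)
  write_xyz(seeds, path("walker_seeds.xyz"))
  result$seeds <- seeds
  manifest$stages$seeds <- list(n = config$n_walkers,
                                file = path("walker_seeds.xyz"),
                                cv = as.numeric(seeds$cv))
  if (done("seeds")) return(.finish_pipeline(result, manifest, config))

  ## --- stage 3: multiple-walker metadynamics -------------------------------
  mw_spec <- run_spec(config$walker_steps, dt = config$dt,
                      friction = config$friction,
                      temperature = sys$temperature,
                      seed = .derive_seed(config$seed, 1, 1),
                      output_stride = config$output_stride,
                      biased = TRUE, walls = walls,
                      funnel = config$funnel,
                      metad = config$walker_metad)
  mw <- run_multiwalker(sys, seeds, mw_spec, config$n_walkers)
  write_hills(mw$hills, path("HILLS"),
              gamma = config$walker_metad$gamma)
  result$multiwalker <- mw
  manifest$stages$multiwalker <- list(
    n_walkers = config$n_walkers, steps_per_walker = config$walker_steps,
    gamma = config$walker_metad$gamma, w0 = config$walker_metad$w0,
    hills = path("HILLS"), n_hills = nrow(mw$hills),
    n_frames = n_frames(mw$frames))
  if (done("multiwalker")) return(.finish_pipeline(result, manifest, config))

  ## --- stage 4: free-energy profile and minimum ----------------------------
  fes <- reconstruct_fes(mw$hills, gamma = config$walker_metad$gamma)
  write_fes(fes, path("fes.dat"))
  result$fes <- fes
  manifest$stages$fes <- list(file = path("fes.dat"),
                              minimum_cv = fes$minimum_cv,
                              reference_cv = sys$reference_cv)
  if (done("fes")) return(.finish_pipeline(result, manifest, config))

  ## --- stage 5: extraction --------------------------------------------------
  ext <- extract_frames(mw$frames, fes$minimum_cv,
                        extraction_params(config$delta_cv))
  result$extract <- ext
  manifest$stages$extract <- list(delta_cv = config$delta_cv,
                                  fraction = ext$fraction,
                                  n_frames = n_frames(ext$frames))
  if (done("extract")) return(.finish_pipeline(result, manifest, config))

  ## --- stage 6: clustering ---------------------------------------------------
  cl_frames <- ext$frames
  if (n_frames(cl_frames) > config$max_cluster_frames) {
    keep <- round(seq(1, n_frames(cl_frames),
                      length.out = config$max_cluster_frames))
    cl_frames <- subset_frames(cl_frames, keep)
  }
  cl_frames <- superpose_backbone(cl_frames,
                                  reference_frame = system_coords(sys))
  clusters <- cluster_frames(cl_frames, n_clusters = config$n_clusters)
  ref_full <- system_coords(sys)
  ref_full[sys$ligand_idx, ] <- sys$reference_pose
  report <- report_clusters(clusters, cl_frames,
                            reference_coords = ref_full)
  write_cluster_assignments(clusters, cl_frames,
                            path("cluster_assignments.csv"))
  write.csv(report, path("cluster_report.csv"), row.names = FALSE)
  reps <- subset_frames(cl_frames, clusters$representatives)
  write_xyz(reps, path("cluster_representatives.xyz"))
  result$cluster <- clusters
  result$cluster_frames <- cl_frames
  result$cluster_report <- report
  manifest$stages$cluster <- list(
    n_clusters = clusters$n_clusters,
    populations = as.numeric(clusters$populations),
    assignments = path("cluster_assignments.csv"),
    report = path("cluster_report.csv"),
    representatives = path("cluster_representatives.xyz"))
  if (done("cluster")) return(.finish_pipeline(result, manifest, config))

  ## --- stage 7: unbiased refinement ----------------------------------------
  refine_spec <- run_spec(config$refine_steps, dt = config$dt,
                          friction = config$friction,
                          temperature = sys$temperature,
                          seed = 1,  # per-cluster seeds derived below
                          output_stride = config$output_stride,
                          biased = FALSE)
  outcomes <- lapply(seq_len(clusters$n_clusters), function(i) {
    rs <- refine_spec
    rs$seed <- .derive_seed(config$seed, 2, i)
    out <- refine_representative(
      sys, cl_frames$coords[clusters$representatives[i], , ], rs,
      cluster_id = i)
    write.csv(cbind(out$rmsd_series, cv = out$cv_series$cv),
              path(sprintf("refine_cluster%d.csv", i)),
              row.names = FALSE)
    out
  })
  rep_out <- convergence_report(outcomes)
  write.csv(rep_out$table, path("refinement_report.csv"),
            row.names = FALSE)
  result$refine <- outcomes
  result$report <- rep_out
  manifest$stages$refine <- list(
    n_steps = config$refine_steps,
    table = path("refinement_report.csv"),
    series = path("refine_cluster%d.csv"),
    classifications = rep_out$table$classification,
    success = rep_out$success, note = rep_out$note)

  .finish_pipeline(result, manifest, config)
}

.finish_pipeline <- function(result, manifest, config) {
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  result$manifest <- manifest
  result$manifest_path <- manifest_path
  result
}
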