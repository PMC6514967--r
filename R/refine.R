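## Unbiased refinement of cluster representatives with convergence
## diagnostics on the ligand-RMSD and binding-CV time series.

#' Classify a refinement run from its RMSD and CV time series
#'
#' Pure classification rule, applied to the final half of the run:
#' `converged_to_reference` if the mean ligand RMSD is at most
#' `rmsd_tol`; otherwise `dissociated` if the CV exceeds
#' `dissociation_cv` for more than half of the final-half frames;
#' otherwise `flexible` if the RMSD standard deviation exceeds
#' `flex_tol`; otherwise `alternative_stable`.
#'
#' @param rmsd_series Ligand RMSD time series (Angstrom).
#' @param cv_series Binding CV time series (nm), same length.
#' @param rmsd_tol Convergence threshold on the mean RMSD (Angstrom,
#'   default 2).
#' @param dissociation_cv CV value marking the funnel mouth /solvent
#'   (nm); frames beyond it count as unbound.
#' @param flex_tol Threshold on the RMSD standard deviation (Angstrom,
#'   default 1.5).
#' @return One of `"converged_to_reference"`, `"dissociated"`,
#'   `"flexible"`, `"alternative_stable"`.
#' @export
classify_refinement <- function(rmsd_series, cv_series, rmsd_tol = 2,
                                dissociation_cv = 2.8, flex_tol = 1.5) {
  .assert(length(rmsd_series) == length(cv_series) &&
          length(rmsd_series) >= 2,
          "classify_refinement: series must be congruent, length >= 2")
  half <- seq(floor(length(rmsd_series) / 2) + 1, length(rmsd_series))
  r <- rmsd_series[half]
  s <- cv_series[half]
  if (mean(r) <= rmsd_tol) return("converged_to_reference")
  if (mean(s > dissociation_cv) > 0.5) return("dissociated")
  if (stats::sd(r) > flex_tol) return("flexible")
  "alternative_stable"
}

#' Refine one cluster representative by unbiased dynamics
#'
#' Runs plain Langevin dynamics (no metadynamics bias) from the
#' representative structure, records the ligand heavy-atom RMSD to the
#' reference pose (after backbone superposition) and the binding CV as
#' functions of time, and classifies the outcome.
#'
#' @param system A `toy_system`.
#' @param representative_frame Full-system coordinate matrix (nm).
#' @param run A [run_spec()] with `biased = FALSE`.
#' @param cluster_id Identifier carried into the outcome.
#' @param reference_pose Ligand reference coordinates; defaults to the
#'   system's planted reference pose.
#' @param rmsd_tol,dissociation_cv,flex_tol Classification thresholds,
#'   see [classify_refinement()].  `dissociation_cv` defaults to the
#'   funnel inflection point `w` when the system has a default funnel.
#' @return An object of class `refinement_outcome` with the two series,
#'   the classification and a `converged` flag.
#' @export
refine_representative <- function(system, representative_frame, run,
                                  cluster_id = 1,
                                  reference_pose = system$reference_pose,
                                  rmsd_tol = 2,
                                  dissociation_cv = NULL,
                                  flex_tol = 1.5) {
  .assert(!isTRUE(run$biased),
          "refine_representative: refinement runs must be unbiased")
  if (is.null(dissociation_cv)) {
    dissociation_cv <- if (!is.null(system$default_funnel)) {
      system$default_funnel$w
    } else 2.8
  }
  st <- list(coords = representative_frame,
             vels = .maxwell_velocities(system, run$temperature,
                                        run$seed),
             time = 0)
  seg <- run_segment(system, run, state = st)
  traj <- seg$trajectory

  ref_full <- system_coords(system)
  ref_full[system$ligand_idx, ] <- reference_pose
  fitted <- superpose_backbone(traj, reference_frame = ref_full)
  rmsd <- vapply(seq_len(n_frames(fitted)), function(k) {
    ligand_rmsd(fitted$coords[k, , ], ref_full, system$ligand_idx)
  }, numeric(1))

  cls <- classify_refinement(rmsd, traj$cv, rmsd_tol = rmsd_tol,
                             dissociation_cv = dissociation_cv,
                             flex_tol = flex_tol)
  structure(list(cluster_id = cluster_id,
                 rmsd_series = data.frame(time = traj$time, rmsd = rmsd),
                 cv_series = data.frame(time = traj$time, cv = traj$cv),
                 classification = cls,
                 converged = cls == "converged_to_reference",
                 final_rmsd = rmsd[length(rmsd)],
                 final_cv = traj$cv[n_frames(traj)]),
            class = "refinement_outcome")
}

#' @export
print.refinement_outcome <- function(x, ...) {
  cat(sprintf(
    "refinement_outcome cluster %s: %s (final RMSD %.2f A, final CV %.3f nm)\n",
    x$cluster_id, x$classification, x$final_rmsd, x$final_cv))
  invisible(x)
}

#' Summarise refinement outcomes across clusters
#'
#' Tabulates the classification and final RMSD/CV per cluster and flags
#' whether the top-populated cluster converged to the reference binding
#' mode -- the protocol's success criterion.
#'
#' @param outcomes List of [refine_representative()] outcomes, ordered
#'   by descending cluster population (cluster 1 first).
#' @return A list with `table` (data frame), `success` (logical) and
#'   `note` (character).
#' @export
convergence_report <- function(outcomes) {
  .assert(length(outcomes) >= 1, "convergence_report: no outcomes")
  tab <- do.call(rbind, lapply(outcomes, function(o) {
    data.frame(cluster = o$cluster_id,
               classification = o$classification,
               final_rmsd = round(o$final_rmsd, 2),
               final_cv = round(o$final_cv, 3))
  }))
  top <- outcomes[[1]]
  success <- isTRUE(top$converged)
  note <- if (success) {
    "top-populated cluster converged to the reference binding mode"
  } else {
    sprintf("top-populated cluster did NOT converge (classified %s)",
            top$classification)
  }
  list(table = tab, success = success, note = note)
}
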