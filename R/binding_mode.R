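## Binding-mode identification: extract frames around the free-energy
## minimum, superpose on the receptor backbone, cluster on the unfitted
## ligand heavy-atom RMSD, rank clusters by population and report RMSDs
## to a reference pose.

#' Extraction parameters
#'
#' @param delta_cv Half-width of the CV window around the free-energy
#'   minimum (nm).  Default 0.3 nm (3 Angstrom).
#' @return An object of class `extraction_params`.
#' @export
extraction_params <- function(delta_cv = 0.3) {
  .assert(delta_cv > 0, "extraction_params: delta_cv must be > 0")
  structure(list(delta_cv = delta_cv), class = "extraction_params")
}

#' Extract frames within a CV window of the free-energy minimum
#'
#' Keeps exactly the frames with `|cv - minimum_cv| <= delta_cv`
#' (closed interval; boundary frames are included, with a 1e-9 nm guard
#' against floating-point noise at the window edge).
#'
#' @param frames A [frame_set()].
#' @param minimum_cv CV value of the free-energy minimum (nm).
#' @param params An [extraction_params()] object.
#' @return A list with `frames` (the selected `frame_set`) and
#'   `fraction` (percentage of input frames selected).
#' @export
extract_frames <- function(frames, minimum_cv,
                           params = extraction_params()) {
  .assert(n_frames(frames) > 0, "extract_frames: no frames")
  sel <- which(abs(frames$cv - minimum_cv) <= params$delta_cv + 1e-9)
  if (length(sel) == 0) {
    stop(sprintf(
      "extract_frames: no frames within %.3f nm of CV %.3f; increase delta_cv",
      params$delta_cv, minimum_cv), call. = FALSE)
  }
  list(frames = subset_frames(frames, sel),
       fraction = 100 * length(sel) / n_frames(frames))
}

#' Kabsch least-squares superposition
#'
#' Optimal rotation and translation mapping point set `P` onto `Q`
#' (n x 3 each) in the least-squares sense, via SVD of the covariance
#' with the usual reflection correction.
#'
#' @param P,Q Coordinate matrices (n x 3), n >= 3 non-collinear points.
#' @return List with rotation matrix `R` (3 x 3) and translation `t`
#'   such that `P %*% R + t` best matches `Q` (rows as points).
#' @export
kabsch <- function(P, Q) {
  .assert(nrow(P) == nrow(Q) && ncol(P) == 3 && ncol(Q) == 3,
          "kabsch: P and Q must be congruent n x 3 matrices")
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  sv <- svd(t(Pc) %*% Qc)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("kabsch: degenerate (collinear) point set", call. = FALSE)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = as.numeric(qc - pc %*% R))
}

#' Superpose all frames on the backbone of a reference frame
#'
#' Each frame is rigidly transformed by the least-squares (Kabsch)
#' rotation and translation that minimise the backbone RMSD to the
#' reference; ligand atoms are co-transformed.  This is the fit that
#' precedes the *unfitted* ligand RMSD used for clustering.
#'
#' @param frames A [frame_set()].
#' @param reference_frame Either the index of the reference frame
#'   (default 1) or an n_atoms x 3 coordinate matrix.
#' @return The superposed `frame_set`.
#' @export
superpose_backbone <- function(frames, reference_frame = 1) {
  bidx <- frames$backbone_idx
  .assert(length(bidx) >= 3,
          "superpose_backbone: need >= 3 backbone atoms")
  ref <- if (is.matrix(reference_frame)) {
    reference_frame
  } else {
    frames$coords[reference_frame, , ]
  }
  refb <- ref[bidx, , drop = FALSE]
  out <- frames$coords
  for (k in seq_len(n_frames(frames))) {
    fc <- frames$coords[k, , ]
    fit <- kabsch(fc[bidx, , drop = FALSE], refb)
    out[k, , ] <- sweep(fc %*% fit$R, 2, fit$t, "+")
  }
  res <- frames
  res$coords <- out
  res
}

#' Unfitted RMSD over an atom selection
#'
#' Plain coordinate RMSD over the selection, with no additional
#' superposition (the coordinates are used as positioned by any prior
#' backbone fit).  Reported in Angstrom.
#'
#' @param frame_a,frame_b Coordinate matrices (n_atoms x 3, nm).
#' @param atom_selection Indices of the atoms entering the RMSD.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(frame_a, frame_b, atom_selection) {
  .assert(nrow(frame_a) == nrow(frame_b),
          "ligand_rmsd: frames have different atom counts")
  .assert(all(atom_selection >= 1 & atom_selection <= nrow(frame_a)),
          "ligand_rmsd: selection out of range")
  d <- frame_a[atom_selection, , drop = FALSE] -
    frame_b[atom_selection, , drop = FALSE]
  10 * sqrt(mean(rowSums(d^2)))
}

#' Pocket atom selection around a reference ligand pose
#'
#' Backbone atoms with any position within `cutoff` of any reference
#' ligand atom (the toy analogue of the orthosteric-pocket residues
#' within 5 Angstrom of the reference ligand).
#'
#' @param frames A [frame_set()] (for the atom groups).
#' @param reference_coords Full-system reference coordinate matrix (nm).
#' @param cutoff Distance cutoff in nm (default 0.5 = 5 Angstrom).
#' @return Integer atom indices.
#' @export
pocket_selection <- function(frames, reference_coords, cutoff = 0.5) {
  lig <- reference_coords[frames$ligand_idx, , drop = FALSE]
  keep <- vapply(frames$backbone_idx, function(i) {
    d2 <- rowSums(sweep(lig, 2, reference_coords[i, ])^2)
    any(d2 <= cutoff^2)
  }, logical(1))
  frames$backbone_idx[keep]
}

#' Cluster frames by unfitted ligand RMSD
#'
#' Hierarchical agglomerative (bottom-up) clustering with average
#' linkage on the pairwise unfitted ligand heavy-atom RMSD matrix, cut
#' at `n_clusters`.  Clusters are sorted by population (descending) and
#' relabelled 1..k; the representative of each cluster is the member
#' with the minimal sum of RMSDs to all other members.
#'
#' Frames should already be backbone-superposed (see
#' [superpose_backbone()]).
#'
#' @param frames A [frame_set()].
#' @param n_clusters Target number of clusters (default 5).
#' @param reference_pose Optional ligand reference coordinates
#'   (n_ligand x 3, nm); per-cluster representative RMSDs to it are
#'   then reported.
#' @return An object of class `cluster_result` with per-frame `labels`,
#'   `populations` (percent, descending), `representatives` (frame
#'   indices), `rep_coords`, `linkage_log`, and `rmsd_to_reference`
#'   (when a reference was supplied).  `truncated` flags that fewer
#'   distinct conformations than `n_clusters` were available.
#' @export
cluster_frames <- function(frames, n_clusters = 5,
                           reference_pose = NULL) {
  nf <- n_frames(frames)
  .assert(n_clusters >= 1, "cluster_frames: n_clusters must be >= 1")
  if (nf < n_clusters) {
    stop(sprintf("cluster_frames: %d frames < %d clusters", nf,
                 n_clusters), call. = FALSE)
  }
  nlig <- length(frames$ligand_idx)
  X <- matrix(frames$coords[, frames$ligand_idx, , drop = FALSE],
              nrow = nf)
  # unfitted ligand RMSD in Angstrom == scaled Euclidean distance on the
  # flattened ligand coordinates
  d <- dist(X) * 10 / sqrt(nlig)

  n_distinct <- nrow(unique(round(X, 12)))
  k_eff <- min(n_clusters, n_distinct)
  truncated <- k_eff < n_clusters
  if (truncated) {
    warning(sprintf(
      "cluster_frames: only %d distinct conformations; returning %d clusters",
      n_distinct, k_eff))
  }

  hc <- hclust(d, method = "average")
  raw <- cutree(hc, k = k_eff)

  sizes <- table(raw)
  ord <- order(-as.numeric(sizes), as.numeric(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  labels <- relabel[raw]
  populations <- 100 * as.numeric(sizes[ord]) / nf

  dm <- as.matrix(d)
  representatives <- vapply(seq_len(k_eff), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    members[which.min(rowSums(dm[members, members, drop = FALSE]))]
  }, integer(1))

  res <- structure(list(labels = labels, populations = populations,
                        representatives = representatives,
                        rep_coords = frames$coords[representatives, , ,
                                                   drop = FALSE],
                        n_clusters = k_eff, truncated = truncated,
                        linkage_log = list(merge = hc$merge,
                                           height = hc$height,
                                           method = "average"),
                        rmsd_to_reference = NULL),
                   class = "cluster_result")
  if (!is.null(reference_pose)) {
    res$rmsd_to_reference <- vapply(seq_len(k_eff), function(cl) {
      rep_fr <- frames$coords[representatives[cl], , ]
      ref_full <- rep_fr
      ref_full[frames$ligand_idx, ] <- reference_pose
      ligand_rmsd(rep_fr, ref_full, frames$ligand_idx)
    }, numeric(1))
  }
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters%s\n", x$n_clusters,
              if (x$truncated) " (truncated)" else ""))
  for (i in seq_len(x$n_clusters)) {
    cat(sprintf("  cluster %d: %6.2f%%%s\n", i, x$populations[i],
                if (!is.null(x$rmsd_to_reference))
                  sprintf("  rep RMSD %.2f A", x$rmsd_to_reference[i])
                else ""))
  }
  invisible(x)
}

#' Tabulate clusters with populations and RMSDs to a reference
#'
#' Builds the per-cluster report: population percentage and, when a
#' reference structure is supplied, the representative's ligand RMSD
#' and pocket RMSD (both unfitted, in Angstrom, after the prior
#' backbone superposition).
#'
#' @param result A [cluster_frames()] result.
#' @param frames The (superposed) `frame_set` that was clustered.
#' @param reference_coords Optional full-system reference coordinate
#'   matrix (nm); RMSD columns are omitted when absent.
#' @param pocket_cutoff Pocket selection cutoff in nm (default 0.5).
#' @return A data frame with columns `cluster`, `population` and, with
#'   a reference, `ligand_rmsd` and `pocket_rmsd` (Angstrom, 2
#'   decimals).
#' @export
report_clusters <- function(result, frames, reference_coords = NULL,
                            pocket_cutoff = 0.5) {
  tab <- data.frame(cluster = seq_len(result$n_clusters),
                    population = round(result$populations, 2))
  if (!is.null(reference_coords)) {
    pocket <- pocket_selection(frames, reference_coords, pocket_cutoff)
    lig_rmsd <- numeric(result$n_clusters)
    poc_rmsd <- numeric(result$n_clusters)
    for (i in seq_len(result$n_clusters)) {
      rep_fr <- frames$coords[result$representatives[i], , ]
      lig_rmsd[i] <- ligand_rmsd(rep_fr, reference_coords,
                                 frames$ligand_idx)
      poc_rmsd[i] <- if (length(pocket) > 0) {
        ligand_rmsd(rep_fr, reference_coords, pocket)
      } else NA_real_
    }
    tab$ligand_rmsd <- round(lig_rmsd, 2)
    tab$pocket_rmsd <- round(poc_rmsd, 2)
  }
  tab
}

#' Write per-frame cluster assignments as CSV
#'
#' @param result A [cluster_frames()] result.
#' @param frames The clustered `frame_set`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_cluster_assignments <- function(result, frames, path) {
  df <- data.frame(frame = seq_len(n_frames(frames)),
                   walker = frames$walker, time = frames$time,
                   cv = frames$cv, cluster = result$labels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
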