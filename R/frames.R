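## Trajectory frame container: coordinates + CV + provenance per frame,
## with the atom groups needed downstream (backbone fit, ligand RMSD).

#' Construct a frame set
#'
#' A `frame_set` bundles trajectory frames (coordinates in nm), the
#' binding CV value, time stamp and walker id of each frame, and the
#' atom-group bookkeeping (backbone indices, ligand heavy-atom indices,
#' CV atom pair) needed by superposition, clustering and refinement.
#'
#' @param coords Numeric array `c(n_frames, n_atoms, 3)` in nm.
#' @param cv Numeric vector of CV values (nm), one per frame.  If `NULL`
#'   it is computed from the coordinates and the CV atom pair.
#' @param time Numeric vector of times (ps).
#' @param walker Integer vector of walker ids.
#' @param backbone_idx Indices of receptor backbone atoms.
#' @param ligand_idx Indices of ligand heavy atoms.
#' @param cv_rec,cv_lig Indices of the receptor and ligand CV atoms.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(coords, cv = NULL, time = NULL, walker = NULL,
                      backbone_idx, ligand_idx, cv_rec, cv_lig) {
  .assert(length(dim(coords)) == 3 && dim(coords)[3] == 3,
          "frame_set: coords must be an [n_frames, n_atoms, 3] array")
  nf <- dim(coords)[1]
  if (is.null(cv)) cv <- coords[, cv_lig, 3] - coords[, cv_rec, 3]
  if (is.null(time)) time <- seq_len(nf) - 1
  if (is.null(walker)) walker <- rep(0L, nf)
  .assert(all(is.finite(cv)), "frame_set: CV values must be finite")
  .assert(length(cv) == nf && length(time) == nf && length(walker) == nf,
          "frame_set: per-frame vectors must match the number of frames")
  structure(list(coords = coords, cv = cv, time = time,
                 walker = as.integer(walker),
                 backbone_idx = as.integer(backbone_idx),
                 ligand_idx = as.integer(ligand_idx),
                 cv_rec = as.integer(cv_rec), cv_lig = as.integer(cv_lig)),
            class = "frame_set")
}

#' Number of frames in a frame set
#' @param frames A `frame_set`.
#' @return Integer frame count.
#' @export
n_frames <- function(frames) dim(frames$coords)[1]

#' Subset a frame set by frame index
#' @param frames A `frame_set`.
#' @param idx Integer indices of the frames to keep.
#' @return A `frame_set` with the selected frames.
#' @export
subset_frames <- function(frames, idx) {
  frame_set(frames$coords[idx, , , drop = FALSE],
            cv = frames$cv[idx], time = frames$time[idx],
            walker = frames$walker[idx],
            backbone_idx = frames$backbone_idx,
            ligand_idx = frames$ligand_idx,
            cv_rec = frames$cv_rec, cv_lig = frames$cv_lig)
}

#' Concatenate frame sets
#' @param ... `frame_set` objects sharing the same atom layout.
#' @return A single merged `frame_set`.
#' @export
bind_frames <- function(...) {
  fs <- list(...)
  fs <- fs[!vapply(fs, is.null, logical(1))]
  .assert(length(fs) >= 1, "bind_frames: nothing to bind")
  na <- dim(fs[[1]]$coords)[2]
  .assert(all(vapply(fs, function(f) dim(f$coords)[2], numeric(1)) == na),
          "bind_frames: atom counts differ")
  coords <- do.call(abind3, lapply(fs, `[[`, "coords"))
  frame_set(coords,
            cv = unlist(lapply(fs, `[[`, "cv")),
            time = unlist(lapply(fs, `[[`, "time")),
            walker = unlist(lapply(fs, `[[`, "walker")),
            backbone_idx = fs[[1]]$backbone_idx,
            ligand_idx = fs[[1]]$ligand_idx,
            cv_rec = fs[[1]]$cv_rec, cv_lig = fs[[1]]$cv_lig)
}

# bind 3D arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  na <- dim(arrs[[1]])[2]
  tot <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, dim = c(tot, na, 3))
  at <- 1
  for (a in arrs) {
    n <- dim(a)[1]
    if (n > 0) out[at:(at + n - 1), , ] <- a
    at <- at + n
  }
  out
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf(
    "frame_set: %d frames, %d atoms (%d backbone, %d ligand), CV range [%.3f, %.3f] nm\n",
    n_frames(x), dim(x$coords)[2], length(x$backbone_idx),
    length(x$ligand_idx), min(x$cv), max(x$cv)))
  invisible(x)
}
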