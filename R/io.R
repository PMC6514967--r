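## Plain-text structure and trajectory formats: multi-frame XYZ,
## multi-model PDB (written here, readable by standard tools), and the
## YAML serialisation of toy systems.

#' Write frames as a multi-frame XYZ file
#'
#' Coordinates are written in Angstrom (the conventional XYZ unit);
#' the comment line carries time, CV and walker id.
#'
#' @param frames A [frame_set()].
#' @param path Output path.
#' @param names Atom names (recycled); default "C".
#' @return Invisibly, the path.
#' @export
write_xyz <- function(frames, path, names = "C") {
  na <- dim(frames$coords)[2]
  names <- rep_len(names, na)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(frames))) {
    writeLines(as.character(na), con)
    writeLines(sprintf("time=%.4f cv=%.6f walker=%d", frames$time[k],
                       frames$cv[k], frames$walker[k]), con)
    xyz <- frames$coords[k, , , drop = TRUE] * 10
    if (na == 1) xyz <- matrix(xyz, 1, 3)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", names,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file written by [write_xyz()]
#'
#' @param path File path.
#' @param backbone_idx,ligand_idx,cv_rec,cv_lig Atom-group bookkeeping
#'   to attach to the resulting [frame_set()].
#' @return A `frame_set` (coordinates converted back to nm).
#' @export
read_xyz <- function(path, backbone_idx, ligand_idx, cv_rec, cv_lig) {
  lines <- readLines(path)
  .assert(length(lines) >= 2, "read_xyz: empty file")
  na <- as.integer(lines[1])
  block <- na + 2
  nf <- length(lines) %/% block
  coords <- array(0, dim = c(nf, na, 3))
  time <- numeric(nf); walker <- integer(nf)
  for (k in seq_len(nf)) {
    off <- (k - 1) * block
    meta <- lines[off + 2]
    time[k] <- as.numeric(sub(".*time=([0-9.eE+-]+).*", "\\1", meta))
    walker[k] <- as.integer(sub(".*walker=([0-9]+).*", "\\1", meta))
    rows <- strsplit(trimws(lines[off + 2 + seq_len(na)]), "[ \t]+")
    coords[k, , ] <- t(vapply(rows, function(r) as.numeric(r[2:4]),
                              numeric(3))) / 10
  }
  frame_set(coords, time = time, walker = walker,
            backbone_idx = backbone_idx, ligand_idx = ligand_idx,
            cv_rec = cv_rec, cv_lig = cv_lig)
}

#' Write frames as a multi-model PDB file
#'
#' Minimal PDB writer for pseudo-atom systems: one MODEL per frame,
#' HETATM records, coordinates in Angstrom.
#'
#' @param frames A [frame_set()].
#' @param path Output path.
#' @param names Atom names (recycled).
#' @return Invisibly, the path.
#' @export
write_frames_pdb <- function(frames, path, names = "C") {
  na <- dim(frames$coords)[2]
  names <- rep_len(names, na)
  resn <- ifelse(seq_len(na) %in% frames$ligand_idx, "LIG", "REC")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(frames))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- frames$coords[k, , , drop = TRUE] * 10
    if (na == 1) xyz <- matrix(xyz, 1, 3)
    writeLines(sprintf(
      "HETATM%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(na), substr(names, 1, 4), resn,
      ifelse(resn == "LIG", 2L, 1L), xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- toy-system serialisation ---------------------------------------------

#' Serialise a toy system to a YAML file
#'
#' @param system A `toy_system`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_toy_system <- function(system, path) {
  doc <- list(
    name = system$name,
    temperature = system$temperature,
    cv_rec = system$cv_rec, cv_lig = system$cv_lig,
    backbone_idx = system$backbone_idx,
    ligand_idx = system$ligand_idx,
    reference_cv = system$reference_cv,
    basin_split = system$basin_split,
    atoms = lapply(seq_len(nrow(system$atoms)), function(i) {
      a <- system$atoms[i, ]
      list(name = a$name, group = a$group, mass = a$mass,
           x = a$x, y = a$y, z = a$z, frozen = a$frozen)
    }),
    terms = system$potential$terms,
    reference_pose = apply(system$reference_pose, 1, as.list,
                           simplify = FALSE),
    analytic_fes = if (!is.null(system$analytic_fes)) {
      list(cv = system$analytic_fes$cv,
           free_energy = system$analytic_fes$free_energy)
    },
    default_walls = if (!is.null(system$default_walls))
      unclass(system$default_walls),
    default_funnel = if (!is.null(system$default_funnel))
      unclass(system$default_funnel))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a toy system from a YAML file written by [write_toy_system()]
#'
#' @param path File path.
#' @return A `toy_system`.
#' @export
read_toy_system <- function(path) {
  doc <- yaml::read_yaml(path)
  atoms <- do.call(rbind, lapply(doc$atoms, function(a) {
    data.frame(name = a$name, group = a$group, mass = a$mass,
               x = a$x, y = a$y, z = a$z, frozen = a$frozen)
  }))
  ref <- do.call(rbind, lapply(doc$reference_pose,
                               function(p) unlist(p, use.names = FALSE)))
  fes <- if (!is.null(doc$analytic_fes)) {
    data.frame(cv = unlist(doc$analytic_fes$cv),
               free_energy = unlist(doc$analytic_fes$free_energy))
  }
  .toy_system(
    name = doc$name, atoms = atoms, terms = doc$terms,
    cv_rec = doc$cv_rec, cv_lig = doc$cv_lig,
    backbone_idx = unlist(doc$backbone_idx),
    ligand_idx = unlist(doc$ligand_idx),
    reference_pose = ref, reference_cv = doc$reference_cv,
    analytic_fes = fes,
    basin_split = if (is.null(doc$basin_split)) NA_real_
                  else doc$basin_split,
    temperature = doc$temperature,
    default_walls = if (!is.null(doc$default_walls))
      do.call(wall_params, doc$default_walls),
    default_funnel = if (!is.null(doc$default_funnel))
      do.call(funnel_params, doc$default_funnel))
}
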