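## Binding CV, harmonic CV walls and the sigmoidal funnel restraint,
## all with analytic gradients.  Energies in kJ/mol, lengths in nm.

#' Harmonic wall parameters for the binding CV
#'
#' Lower and upper harmonic walls restraining the binding collective
#' variable.  Outside the interval `(z_low, z_up)` the wall energy is
#' `kappa * (z - z_wall)^2` (note: no factor 1/2), inside it is zero.
#'
#' @param z_low Lower wall position (nm).
#' @param z_up Upper wall position (nm).
#' @param kappa Force constant (kJ mol^-1 nm^-2). Default 1500.
#' @return An object of class `wall_params`.
#' @export
wall_params <- function(z_low, z_up, kappa = 1500) {
  .assert(is.numeric(z_low) && is.numeric(z_up) && z_low < z_up,
          "wall_params: need z_low < z_up")
  .assert(kappa >= 0, "wall_params: kappa must be >= 0")
  structure(list(z_low = z_low, z_up = z_up, kappa = kappa),
            class = "wall_params")
}

#' Funnel restraint parameters
#'
#' Geometry and stiffness of the funnel-shaped restraint confining the
#' ligand's CV atom to the binding path.  The funnel radius is
#' `R(z) = d / (1 + exp(m * (z - w))) + r1` and the restraint energy is
#' `h * (1 - 1 / (1 + exp(lam * (r - R(z)))))` with `r = sqrt(x^2 + y^2)`
#' the transverse distance from the funnel axis.  The funnel axis is the
#' laboratory z axis centred on the receptor CV atom.
#'
#' Defaults are the published GPCR values: d = 1.6 nm, r1 = 0.8 nm,
#' m = 10 nm^-1, w = 2.8 nm, h = 100 kJ/mol, lam = 500 nm^-1.
#'
#' @param d Radius range of the sigmoidal part (nm).
#' @param r1 Limiting (narrow-end) radius at large z (nm).
#' @param m Steepness of the radius switch (nm^-1).
#' @param w Inflection point of the radius switch along z (nm).
#' @param h Plateau energy of the restraint (kJ mol^-1).
#' @param lam Steepness of the restraint switch (nm^-1).
#' @return An object of class `funnel_params`.
#' @export
funnel_params <- function(d = 1.6, r1 = 0.8, m = 10, w = 2.8,
                          h = 100, lam = 500) {
  .assert(d > 0 && r1 > 0 && m > 0 && h > 0 && lam > 0,
          "funnel_params: d, r1, m, h, lam must all be positive")
  structure(list(d = d, r1 = r1, m = m, w = w, h = h, lam = lam),
            class = "funnel_params")
}

#' Binding collective variable
#'
#' The z-component of the displacement from the receptor anchor atom
#' (the conserved-tryptophan C-alpha analogue) to the ligand's amine
#' nitrogen analogue: `z(ligand_atom) - z(receptor_atom)`.  Positive
#' values point toward the solvent side.
#'
#' @param coords Numeric matrix of per-atom coordinates (n x 3, nm).
#' @param receptor_atom Row index of the receptor CV atom.
#' @param ligand_atom Row index of the ligand CV atom.
#' @return CV value in nm.
#' @export
binding_cv <- function(coords, receptor_atom, ligand_atom) {
  n <- nrow(coords)
  .assert(receptor_atom >= 1 && receptor_atom <= n &&
          ligand_atom >= 1 && ligand_atom <= n,
          "binding_cv: atom index out of range")
  coords[ligand_atom, 3] - coords[receptor_atom, 3]
}

#' Harmonic wall energy along the CV
#'
#' @param z CV value(s) in nm (vectorised).
#' @param params A [wall_params()] object.
#' @return Wall energy in kJ/mol.
#' @export
wall_bias <- function(z, params) {
  lo <- pmin(z - params$z_low, 0)
  hi <- pmax(z - params$z_up, 0)
  params$kappa * (lo^2 + hi^2)
}

#' Gradient of the wall energy with respect to the CV
#'
#' @inheritParams wall_bias
#' @return dU/dz in kJ mol^-1 nm^-1.
#' @export
wall_bias_grad <- function(z, params) {
  lo <- pmin(z - params$z_low, 0)
  hi <- pmax(z - params$z_up, 0)
  2 * params$kappa * (lo + hi)
}

# numerically safe logistic
.sigmoid <- function(x) {
  out <- numeric(length(x))
  hi <- x > 40; lo <- x < -40; mid <- !hi & !lo
  out[hi] <- 1
  out[lo] <- 0
  out[mid] <- 1 / (1 + exp(-x[mid]))
  out
}

#' Funnel radius profile
#'
#' `R(z) = d / (1 + exp(m * (z - w))) + r1`: wide (d + r1) deep inside
#' the receptor at small z, narrowing to the limiting radius r1 in the
#' channel toward the solvent at large z.  Strictly decreasing in z.
#'
#' @param z Position(s) along the funnel axis (nm, vectorised).
#' @param params A [funnel_params()] object.
#' @return Funnel radius in nm.
#' @export
funnel_radius <- function(z, params) {
  params$d * .sigmoid(-params$m * (z - params$w)) + params$r1
}

#' Funnel restraint energy
#'
#' `h * (1 - 1 / (1 + exp(lam * (r - R(z)))))` with
#' `r = sqrt(x^2 + y^2)`.  Near zero inside the funnel, rising
#' sigmoidally to the plateau `h` outside it.
#'
#' @param x,y,z Components of the displacement from the receptor CV
#'   atom (funnel centre) to the ligand CV atom (nm, vectorised).
#' @param params A [funnel_params()] object.
#' @return Restraint energy in kJ/mol.
#' @export
funnel_bias <- function(x, y, z, params) {
  r <- sqrt(x^2 + y^2)
  params$h * (1 - .sigmoid(-params$lam * (r - funnel_radius(z, params))))
}

#' Gradient of the funnel restraint
#'
#' Analytic gradient of [funnel_bias()] with respect to the displacement
#' components.
#'
#' @inheritParams funnel_bias
#' @return A list with components `x`, `y`, `z` (kJ mol^-1 nm^-1).
#' @export
funnel_bias_grad <- function(x, y, z, params) {
  r <- sqrt(x^2 + y^2)
  a <- params$m * (z - params$w)
  E <- exp(pmin(pmax(a, -40), 40))
  dRdz <- ifelse(abs(a) > 40, 0, -params$d * params$m * E / (1 + E)^2)
  s <- .sigmoid(-params$lam * (r - funnel_radius(z, params)))
  dUdg <- params$h * params$lam * s * (1 - s)
  safe_r <- ifelse(r > 1e-10, r, 1)
  list(x = ifelse(r > 1e-10, dUdg * x / safe_r, 0),
       y = ifelse(r > 1e-10, dUdg * y / safe_r, 0),
       z = dUdg * (-dRdz))
}

#' Total restraint energy of a configuration
#'
#' Wall energy along the binding CV plus funnel energy on the
#' receptor-anchor-to-ligand displacement.
#'
#' @param coords Coordinate matrix (n x 3, nm).
#' @param receptor_atom,ligand_atom CV atom indices.
#' @param walls A [wall_params()] object or `NULL`.
#' @param funnel A [funnel_params()] object or `NULL`.
#' @return Energy in kJ/mol.
#' @export
restraint_energy <- function(coords, receptor_atom, ligand_atom,
                             walls = NULL, funnel = NULL) {
  d <- coords[ligand_atom, ] - coords[receptor_atom, ]
  e <- 0
  if (!is.null(walls)) e <- e + wall_bias(d[3], walls)
  if (!is.null(funnel)) e <- e + funnel_bias(d[1], d[2], d[3], funnel)
  e
}

#' Export restraints as a PLUMED-style input stanza
#'
#' Writes an equivalent PLUMED-dialect stanza for the CV, walls and
#' funnel as a documentation aid (the text is not executed by this
#' package).
#'
#' @param walls A [wall_params()] object or `NULL`.
#' @param funnel A [funnel_params()] object or `NULL`.
#' @param cvname Label used for the CV in the stanza.
#' @return Character vector of stanza lines (invisibly printable).
#' @export
plumed_restraint_stanza <- function(walls = NULL, funnel = NULL,
                                    cvname = "cv") {
  lines <- c(
    "# binding CV: z-component of the anchor->ligand-N distance",
    sprintf("%s: DISTANCE ATOMS=anchor,ligN COMPONENTS", cvname))
  if (!is.null(walls)) {
    lines <- c(lines,
      sprintf("LOWER_WALLS ARG=%s.z AT=%g KAPPA=%g EXP=2 LABEL=wall_lo",
              cvname, walls$z_low, walls$kappa),
      sprintf("UPPER_WALLS ARG=%s.z AT=%g KAPPA=%g EXP=2 LABEL=wall_up",
              cvname, walls$z_up, walls$kappa))
  }
  if (!is.null(funnel)) {
    lines <- c(lines,
      sprintf(paste0("# funnel: R(z) = %g/(1+exp(%g*(z-%g))) + %g ; ",
                     "U = %g*(1 - 1/(1+exp(%g*(r - R(z)))))"),
              funnel$d, funnel$m, funnel$w, funnel$r1,
              funnel$h, funnel$lam))
  }
  class(lines) <- "plumed_stanza"
  lines
}

#' @export
print.plumed_stanza <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
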