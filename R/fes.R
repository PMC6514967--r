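## Free-energy profile along the binding CV, reconstructed from the
## deposited hills with the well-tempered rescaling
## F(s) = -(gamma/(gamma-1)) V(s), global minimum shifted to zero.

#' Reconstruct the free-energy profile from deposited hills
#'
#' Sums all Gaussians on a uniform CV grid and applies the
#' well-tempered rescaling `F(s) = -(gamma/(gamma-1)) * V(s)`; the
#' profile is then shifted so that its global minimum is zero.
#'
#' @param hills A `hills` data frame (all walkers merged).
#' @param gamma Bias factor used in the run (> 1).
#' @param grid_min,grid_max CV grid range (nm); default auto-set to the
#'   hill range extended by 3 sigma.
#' @param grid_step Grid spacing (nm), default 0.01.
#' @return An object of class `fes_profile` with fields `grid`,
#'   `free_energy`, `minimum_cv`, `gamma_used` and logical `empty`
#'   (flat-profile flag for an empty hill list).
#' @export
reconstruct_fes <- function(hills, gamma, grid_min = NULL,
                            grid_max = NULL, grid_step = 0.01) {
  .assert(gamma > 1, "reconstruct_fes: gamma must be > 1")
  .assert(grid_step > 0, "reconstruct_fes: grid_step must be > 0")
  empty <- nrow(hills) == 0
  if (empty) {
    if (is.null(grid_min)) grid_min <- 0
    if (is.null(grid_max)) grid_max <- 1
    warning("reconstruct_fes: empty hill list, returning a flat profile")
    grid <- seq(grid_min, grid_max, by = grid_step)
    return(structure(list(grid = grid,
                          free_energy = numeric(length(grid)),
                          minimum_cv = NA_real_, gamma_used = gamma,
                          empty = TRUE),
                     class = "fes_profile"))
  }
  if (is.null(grid_min)) grid_min <- min(hills$center) - 3 * max(hills$sigma)
  if (is.null(grid_max)) grid_max <- max(hills$center) + 3 * max(hills$sigma)
  grid <- seq(grid_min, grid_max, by = grid_step)
  f <- -(gamma / (gamma - 1)) * total_bias(grid, hills)
  f <- f - min(f)
  prof <- structure(list(grid = grid, free_energy = f,
                         minimum_cv = NA_real_, gamma_used = gamma,
                         empty = FALSE),
                    class = "fes_profile")
  prof$minimum_cv <- locate_minimum(prof)
  prof
}

#' Locate the global free-energy minimum
#'
#' Finds the grid point of the global minimum (ties within 1e-9 broken
#' toward the smaller CV) and refines it by a parabolic fit through the
#' minimum and its two neighbours.
#'
#' @param profile An `fes_profile`.
#' @return Minimum CV position in nm.
#' @export
locate_minimum <- function(profile) {
  f <- profile$free_energy
  g <- profile$grid
  if (isTRUE(profile$empty) || diff(range(f)) < 1e-12)
    stop("locate_minimum: flat profile has no minimum", call. = FALSE)
  i <- which(f <= min(f) + 1e-9)[1]  # tie -> smaller CV
  if (i == 1 || i == length(f)) return(g[i])
  # parabola through (g[i-1], f[i-1]), (g[i], f[i]), (g[i+1], f[i+1])
  denom <- f[i - 1] - 2 * f[i] + f[i + 1]
  if (abs(denom) < 1e-14) return(g[i])
  h <- g[2] - g[1]
  g[i] + 0.5 * h * (f[i - 1] - f[i + 1]) / denom
}

#' @export
print.fes_profile <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("fes_profile: flat (no hills)\n")
  } else {
    cat(sprintf(
      "fes_profile: %d points on [%.2f, %.2f] nm, minimum at %.4f nm (gamma = %g)\n",
      length(x$grid), min(x$grid), max(x$grid), x$minimum_cv,
      x$gamma_used))
  }
  invisible(x)
}

#' Write a free-energy profile as a two-column text file
#'
#' @param profile An `fes_profile`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fes <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#cv free_energy", con)
  writeLines(sprintf("%.6f %.9f", profile$grid, profile$free_energy), con)
  invisible(path)
}

#' Read a free-energy profile written by [write_fes()]
#'
#' @param path File path.
#' @return An `fes_profile`.
#' @export
read_fes <- function(path) {
  tab <- read.table(path, comment.char = "#")
  prof <- structure(list(grid = tab[[1]], free_energy = tab[[2]],
                         minimum_cv = NA_real_, gamma_used = NA_real_,
                         empty = diff(range(tab[[2]])) < 1e-12),
                    class = "fes_profile")
  if (!prof$empty) prof$minimum_cv <- locate_minimum(prof)
  prof
}
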