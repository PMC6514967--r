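# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

kB <- 0.0083144621

# trapezoid-rule Boltzmann integral of exp(-beta*u) over (cv, u)
trap_boltzmann <- function(cv, u, temperature) {
  w <- exp(-u / (kB * temperature))
  sum(diff(cv) * (w[-length(w)] + w[-1]) / 2)
}

# brute-force Gaussian summation (double loop, no vectorised shortcut)
brute_total_bias <- function(s, hills) {
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    acc <- 0
    for (k in seq_len(nrow(hills))) {
      acc <- acc + hills$height[k] *
        exp(-(s[i] - hills$center[k])^2 / (2 * hills$sigma[k]^2))
    }
    out[i] <- acc
  }
  out
}

# central-difference gradient of a scalar function
central_diff <- function(f, x, h = 1e-7) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# exhaustive O(n^3) average-linkage agglomeration on a distance matrix;
# returns cluster labels at k clusters
brute_average_linkage <- function(dmat, k) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# do two labelings describe the same partition (up to renumbering)?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# minimal single-particle harmonic system built outside the generators
harmonic_system <- function(k = 100, temperature = 310) {
  atoms <- data.frame(
    name = c("ANC", "LIG"),
    group = c("receptor_backbone", "ligand_heavy"),
    mass = c(12, 14), x = c(0, 0), y = c(0, 0), z = c(0, 0.5),
    frozen = c(TRUE, FALSE))
  metabind:::.toy_system(
    name = "harmonic", atoms = atoms,
    terms = list(list(type = "harm", atom = 2L,
                      center = c(0, 0, 0.5), k = k)),
    cv_rec = 1L, cv_lig = 2L, backbone_idx = 1L, ligand_idx = 2L,
    reference_pose = matrix(c(0, 0, 0.5), 1, 3), reference_cv = 0.5,
    temperature = temperature)
}

# reference full-system coordinates of a binding system
reference_coords <- function(system) {
  co <- system_coords(system)
  co[system$ligand_idx, ] <- system$reference_pose
  co
}
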