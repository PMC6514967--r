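## Well-tempered hill deposition, shared-bias bookkeeping and
## PLUMED-dialect HILLS/COLVAR files.

#' Well-tempered metadynamics parameters
#'
#' @param gamma Bias factor (dimensionless, > 1).  The effective
#'   tempering temperature is `dT = (gamma - 1) * temperature`.
#' @param w0 Initial hill height (kJ mol^-1).
#' @param sigma Gaussian hill width along the CV (nm).
#' @param stride Integration steps between depositions (default 500,
#'   i.e. 1 ps at a 2 fs time step).
#' @param temperature Simulation temperature (K).
#' @return An object of class `metad_params`.
#' @export
metad_params <- function(gamma = 20, w0 = 5, sigma = 0.1, stride = 500,
                         temperature = 310) {
  .assert(gamma > 1, "metad_params: gamma must be > 1")
  .assert(w0 > 0, "metad_params: w0 must be > 0")
  .assert(sigma > 0, "metad_params: sigma must be > 0")
  .assert(stride >= 1, "metad_params: stride must be >= 1")
  structure(list(gamma = gamma, w0 = w0, sigma = sigma,
                 stride = as.integer(stride), temperature = temperature),
            class = "metad_params")
}

#' Empty hill list
#'
#' @return A zero-row `hills` data frame with columns `time`, `center`,
#'   `sigma`, `height`, `walker`.
#' @export
empty_hills <- function() {
  structure(data.frame(time = numeric(0), center = numeric(0),
                       sigma = numeric(0), height = numeric(0),
                       walker = integer(0)),
            class = c("hills", "data.frame"))
}

.as_hills <- function(df) {
  class(df) <- c("hills", "data.frame")
  df
}

#' Well-tempered hill height
#'
#' `W = w0 * exp(-V(s) / (kB * dT))` with `dT = (gamma - 1) * T`: the
#' height of the next hill decays exponentially with the bias already
#' accumulated at the deposition point.
#'
#' @param v_bias_here Current bias at the deposition point (kJ mol^-1,
#'   must be >= 0 since the bias is a sum of positive Gaussians).
#' @param params A [metad_params()] object.
#' @return Hill height in kJ mol^-1.
#' @export
hill_height <- function(v_bias_here, params) {
  .assert(all(v_bias_here >= 0),
          "hill_height: bias must be non-negative (sum of positive Gaussians)")
  dT <- (params$gamma - 1) * params$temperature
  params$w0 * exp(-v_bias_here / (.kB * dT))
}

#' Total metadynamics bias at CV value(s)
#'
#' Direct summation of all deposited Gaussians (from all walkers):
#' `V(s) = sum_k height_k * exp(-(s - center_k)^2 / (2 sigma_k^2))`.
#'
#' @param s CV value(s) in nm.
#' @param hills A `hills` data frame.
#' @return Bias in kJ mol^-1, one value per element of `s`.
#' @export
total_bias <- function(s, hills) {
  if (nrow(hills) == 0) return(numeric(length(s)) * 0 + 0)
  vapply(s, function(si) {
    sum(hills$height * exp(-(si - hills$center)^2 / (2 * hills$sigma^2)))
  }, numeric(1))
}

#' Deposit one well-tempered hill
#'
#' Appends a hill at the walker's current CV value with height scaled by
#' the bias already present there (shared across all walkers).
#'
#' @param state_cv Current CV value of the depositing walker (nm).
#' @param time Deposition time (ps).
#' @param walker_id Integer walker id.
#' @param hills Current global `hills` data frame.
#' @param params A [metad_params()] object.
#' @return The updated `hills` data frame; the new hill is the last row.
#' @export
deposit_hill <- function(state_cv, time, walker_id, hills, params) {
  h <- hill_height(total_bias(state_cv, hills), params)
  .as_hills(rbind(hills,
                  data.frame(time = time, center = state_cv,
                             sigma = params$sigma, height = h,
                             walker = as.integer(walker_id))))
}

#' Select equidistant walker seed frames along the CV
#'
#' Places `n` target CV values equally spaced between the observed CV
#' minimum and maximum and, for each target, selects the frame with the
#' nearest CV value (ties broken by earliest time).
#'
#' @param frames A [frame_set()] object.
#' @param n Number of walkers to seed (>= 2).
#' @return A `frame_set` of `n` selected frames, with attribute
#'   `target_cv` holding the target lattice.
#' @export
select_walker_seeds <- function(frames, n) {
  .assert(n >= 2, "select_walker_seeds: n must be >= 2")
  nf <- n_frames(frames)
  if (nf < n) {
    stop(sprintf(
      "select_walker_seeds: only %d frames available for %d walkers (deficit %d)",
      nf, n, n - nf), call. = FALSE)
  }
  targets <- seq(min(frames$cv), max(frames$cv), length.out = n)
  ord <- order(frames$time)  # earliest-time tie break
  idx <- vapply(targets, function(t) {
    d <- abs(frames$cv[ord] - t)
    ord[which.min(d)]  # which.min takes the first minimum -> earliest time
  }, integer(1))
  out <- subset_frames(frames, idx)
  attr(out, "target_cv") <- targets
  out
}

## ---- PLUMED-dialect files --------------------------------------------------

#' Write a PLUMED-dialect HILLS file
#'
#' Header `#! FIELDS time <cvname> sigma_<cvname> height biasf` followed
#' by whitespace-separated numeric rows.  With `per_walker = TRUE`, one
#' file per walker (`<path>.<walker>`) is written instead of a merged
#' file.
#'
#' @param hills A `hills` data frame.
#' @param path Output file path.
#' @param gamma Bias factor recorded in the `biasf` column.
#' @param cvname CV label used in the header.
#' @param per_walker Write one file per walker id.
#' @return Invisibly, the path(s) written.
#' @export
write_hills <- function(hills, path, gamma, cvname = "cv",
                        per_walker = FALSE) {
  write_one <- function(h, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("#! FIELDS time %s sigma_%s height biasf",
                       cvname, cvname), con)
    if (nrow(h) > 0) {
      rows <- sprintf("%.6f %.9f %.9f %.9f %.3f",
                      h$time, h$center, h$sigma, h$height, gamma)
      writeLines(rows, con)
    }
    p
  }
  if (per_walker) {
    ids <- sort(unique(hills$walker))
    paths <- vapply(ids, function(w) {
      write_one(hills[hills$walker == w, , drop = FALSE],
                sprintf("%s.%d", path, w))
    }, character(1))
    invisible(paths)
  } else {
    invisible(write_one(hills, path))
  }
}

#' Read PLUMED-dialect HILLS file(s)
#'
#' Accepts a merged file or several per-walker files; walker ids are
#' taken from the file order (0-based) when more than one path is given.
#'
#' @param paths Character vector of file paths.
#' @return A `hills` data frame.  The bias factor found in the `biasf`
#'   column is stored in attribute `gamma`.
#' @export
read_hills <- function(paths) {
  pieces <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    header <- readLines(p, n = 1)
    .assert(startsWith(header, "#! FIELDS"),
            sprintf("read_hills: %s has no '#! FIELDS' header", p))
    fields <- strsplit(sub("^#! FIELDS +", "", header), "[ \t]+")[[1]]
    tab <- read.table(p, comment.char = "#")
    names(tab) <- fields
    sig_col <- grep("^sigma_", fields, value = TRUE)[1]
    cv_col <- setdiff(fields, c("time", "height", "biasf", sig_col))[1]
    data.frame(time = tab$time, center = tab[[cv_col]],
               sigma = tab[[sig_col]], height = tab$height,
               walker = if (length(paths) > 1) i - 1L else 0L,
               biasf = if ("biasf" %in% fields) tab$biasf else NA_real_)
  })
  all <- do.call(rbind, pieces)
  gamma <- unique(all$biasf[is.finite(all$biasf)])
  out <- .as_hills(all[c("time", "center", "sigma", "height", "walker")])
  attr(out, "gamma") <- if (length(gamma) == 1) gamma else NA_real_
  out
}

#' Write a PLUMED-dialect COLVAR file
#'
#' @param colvar Data frame with columns `time`, `cv` and optionally
#'   further numeric columns (e.g. `bias`).
#' @param path Output file path.
#' @param cvname CV label used in the header.
#' @return Invisibly, the path.
#' @export
write_colvar <- function(colvar, path, cvname = "cv") {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- names(colvar)
  cols[cols == "cv"] <- cvname
  writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
  mat <- as.matrix(colvar)
  writeLines(apply(mat, 1, function(r) paste(sprintf("%.9g", r),
                                             collapse = " ")), con)
  invisible(path)
}

#' Read a PLUMED-dialect COLVAR file
#'
#' @param path File path.
#' @param cvname CV label expected in the header (renamed to `cv`).
#' @return Data frame with a `time` and a `cv` column (plus extras).
#' @export
read_colvar <- function(path, cvname = "cv") {
  header <- readLines(path, n = 1)
  .assert(startsWith(header, "#! FIELDS"),
          sprintf("read_colvar: %s has no '#! FIELDS' header", path))
  fields <- strsplit(sub("^#! FIELDS +", "", header), "[ \t]+")[[1]]
  tab <- read.table(path, comment.char = "#")
  names(tab) <- fields
  names(tab)[names(tab) == cvname] <- "cv"
  tab
}
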