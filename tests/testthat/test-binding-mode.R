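# Frame extraction, Kabsch superposition, unfitted ligand RMSD and
# average-linkage clustering with population ranking.

make_cv_frames <- function(cvs, system = make_binding_system()) {
  coords <- array(0, dim = c(length(cvs), nrow(system$atoms), 3))
  for (k in seq_along(cvs)) {
    co <- system_coords(system)
    co[system$cv_lig, 3] <- co[system$cv_rec, 3] + cvs[k]
    coords[k, , ] <- co
  }
  frame_set(coords, backbone_idx = system$backbone_idx,
            ligand_idx = system$ligand_idx, cv_rec = system$cv_rec,
            cv_lig = system$cv_lig)
}

test_that("extraction keeps exactly the frames inside the closed CV window", {
  fr <- make_cv_frames(seq(0.1, 1.0, by = 0.1))
  ext <- extract_frames(fr, 0.5, extraction_params(0.3))
  expect_equal(sort(ext$frames$cv), seq(0.2, 0.8, by = 0.1),
               tolerance = 1e-9)
  expect_equal(ext$fraction, 70)

  all_in <- extract_frames(make_cv_frames(rep(0.5, 20)), 0.5)
  expect_equal(all_in$fraction, 100)

  # brute-force filter oracle on 1e4 random CVs
  cvs <- withr::with_seed(41, runif(10000, 0, 4))
  fr2 <- make_cv_frames(cvs)
  ext2 <- extract_frames(fr2, 1.7, extraction_params(0.3))
  oracle <- cvs[abs(cvs - 1.7) <= 0.3]
  expect_identical(ext2$frames$cv, oracle)
  # idempotent
  again <- extract_frames(ext2$frames, 1.7, extraction_params(0.3))
  expect_equal(again$fraction, 100)

  expect_error(extract_frames(fr, 3.5, extraction_params(0.1)),
               "delta_cv")
})

test_that("Kabsch superposition recovers planted rigid motions", {
  bs <- make_binding_system()
  base <- reference_coords(bs)
  nb <- length(bs$backbone_idx)

  # identity
  fit0 <- kabsch(base[bs$backbone_idx, ], base[bs$backbone_idx, ])
  expect_equal(fit0$R, diag(3), tolerance = 1e-12)
  expect_equal(fit0$t, c(0, 0, 0), tolerance = 1e-12)

  # 90 degrees about z plus a translation
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- sweep(base %*% Rz, 2, c(1, -2, 0.5), "+")
  coords <- array(0, dim = c(2, nrow(base), 3))
  coords[1, , ] <- base
  coords[2, , ] <- moved
  fr <- frame_set(coords, backbone_idx = bs$backbone_idx,
                  ligand_idx = bs$ligand_idx, cv_rec = bs$cv_rec,
                  cv_lig = bs$cv_lig)
  fitted <- superpose_backbone(fr, reference_frame = 1)
  resid <- sqrt(mean((fitted$coords[2, bs$backbone_idx, ] -
                        base[bs$backbone_idx, ])^2))
  expect_lt(resid, 1e-9)
  # ligand co-transformed back onto the reference pose
  expect_lt(ligand_rmsd(fitted$coords[2, , ], base, bs$ligand_idx), 1e-8)

  # construct-then-recover on a 4-point asymmetric set
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.5, 0), c(0.2, 0.3, 2))
  th <- 0.7
  Rc <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
               3, 3)
  Q <- sweep(P %*% Rc, 2, c(0.3, -0.1, 0.9), "+")
  fit <- kabsch(P, Q)
  expect_equal(fit$R, Rc, tolerance = 1e-9)

  collinear <- cbind(seq_len(5), seq_len(5) * 2, seq_len(5) * -1)
  expect_error(kabsch(collinear, collinear), "collinear")
})

test_that("unfitted RMSD is a metric-like distance reported in Angstrom", {
  a <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE)
  expect_equal(ligand_rmsd(a, a, 1:2), 0)
  b <- a
  b[, 1] <- b[, 1] + 0.1  # both atoms displaced by 0.1 nm in x
  expect_equal(ligand_rmsd(a, b, 1:2), 1.0)
  # symmetry and positivity on random frames
  withr::with_seed(42, {
    for (i in 1:10) {
      p <- matrix(rnorm(12), 4, 3)
      q <- matrix(rnorm(12), 4, 3)
      expect_equal(ligand_rmsd(p, q, 1:4), ligand_rmsd(q, p, 1:4))
      expect_gt(ligand_rmsd(p, q, 1:4), 0)
    }
  })
  expect_error(ligand_rmsd(a, a, 1:3), "out of range")
})

test_that("clustering recovers planted populations and the dominant pose", {
  bs <- make_binding_system()
  fr <- c(0.7, 0.2, 0.05, 0.04, 0.01)
  flip <- diag(c(1, -1, -1))
  pose0 <- sweep(bs$reference_pose, 2, bs$reference_pose[1, ])
  poses <- list(
    bs$reference_pose,                                  # bound mode
    sweep(pose0 %*% flip, 2, c(0, 0, 0.5), "+"),        # reversed
    bs$decoy_pose,                                      # vestibule
    sweep(bs$reference_pose, 2, c(0, 0, 0.9), "+"),     # channel
    sweep(bs$reference_pose, 2, c(0.3, 0.3, 1.4), "+")) # off-path
  modes <- Map(function(p, f) list(pose = p, fraction = f,
                                   noise_sd = 0.02), poses, fr)
  spec <- planted_ensemble_spec(modes, n_frames = 5000,
                                backbone_jitter_sd = 0.01,
                                rigid_motion = TRUE, seed = 17)
  ens <- sample_planted_ensemble(bs, spec)
  fitted <- superpose_backbone(ens,
                               reference_frame = system_coords(bs))
  cl <- cluster_frames(fitted, n_clusters = 5)

  expect_equal(cl$n_clusters, 5)
  expect_equal(sum(cl$populations), 100, tolerance = 1e-6)
  expect_true(all(diff(cl$populations) <= 0))
  expect_true(all(abs(cl$populations - 100 * fr) <= 2))

  # the top representative matches the planted dominant pose (within
  # the planted per-atom noise and the jittered-backbone fit error)
  top_rep <- fitted$coords[cl$representatives[1], , ]
  expect_lt(ligand_rmsd(top_rep, reference_coords(bs), bs$ligand_idx),
            1.0)
  # each representative belongs to its own cluster
  expect_equal(cl$labels[cl$representatives], seq_len(5))
})

test_that("two noiseless modes split exactly and truncation warns", {
  bs <- make_binding_system()
  poses <- list(bs$reference_pose, bs$decoy_pose)
  modes <- Map(function(p, f) list(pose = p, fraction = f,
                                   noise_sd = 0), poses, c(0.8, 0.2))
  ens <- sample_planted_ensemble(
    bs, planted_ensemble_spec(modes, n_frames = 50, seed = 23))
  cl <- cluster_frames(ens, n_clusters = 2)
  expect_equal(cl$populations, c(80, 20), tolerance = 1e-9)
  truth <- attr(ens, "mode")
  expect_true(same_partition(cl$labels, truth))

  expect_warning(cl5 <- cluster_frames(ens, n_clusters = 5),
                 "distinct")
  expect_true(cl5$truncated)
  expect_equal(cl5$n_clusters, 2)
  expect_error(cluster_frames(subset_frames(ens, 1:3), n_clusters = 5),
               "frames")
})

test_that("average-linkage labels match an exhaustive reference implementation", {
  bs <- make_binding_system()
  mode <- list(list(pose = bs$reference_pose, fraction = 1,
                    noise_sd = 0.15))
  ens <- sample_planted_ensemble(
    bs, planted_ensemble_spec(mode, n_frames = 50, seed = 29))
  nlig <- length(bs$ligand_idx)
  X <- matrix(ens$coords[, bs$ligand_idx, ], nrow = 50)
  dmat <- as.matrix(dist(X) * 10 / sqrt(nlig))
  for (k in c(2, 3, 5)) {
    cl <- cluster_frames(ens, n_clusters = k)
    oracle <- brute_average_linkage(dmat, k)
    expect_true(same_partition(cl$labels, oracle))
  }
})

test_that("clustering is invariant to frame order", {
  bs <- make_binding_system()
  poses <- list(bs$reference_pose, bs$decoy_pose,
                sweep(bs$reference_pose, 2, c(0, 0.4, 0.8), "+"))
  modes <- Map(function(p, f) list(pose = p, fraction = f,
                                   noise_sd = 0.03), poses,
               c(0.5, 0.3, 0.2))
  ens <- sample_planted_ensemble(
    bs, planted_ensemble_spec(modes, n_frames = 120, seed = 31))
  cl <- cluster_frames(ens, n_clusters = 3)
  perm <- withr::with_seed(32, sample(120))
  cl_p <- cluster_frames(subset_frames(ens, perm), n_clusters = 3)
  expect_true(same_partition(cl$labels[perm], cl_p$labels))
  expect_equal(cl_p$populations, cl$populations, tolerance = 1e-9)
})

test_that("cluster reports rank the true binding mode first", {
  bs <- make_binding_system()
  fr <- c(0.7, 0.2, 0.1)
  poses <- list(bs$reference_pose, bs$decoy_pose,
                sweep(bs$reference_pose, 2, c(0.2, 0, 1.0), "+"))
  modes <- Map(function(p, f) list(pose = p, fraction = f,
                                   noise_sd = 0.02), poses, fr)
  ens <- sample_planted_ensemble(
    bs, planted_ensemble_spec(modes, n_frames = 600, seed = 37))
  fitted <- superpose_backbone(ens,
                               reference_frame = system_coords(bs))
  cl <- cluster_frames(fitted, n_clusters = 3)
  rep_tab <- report_clusters(cl, fitted,
                             reference_coords = reference_coords(bs))
  expect_named(rep_tab, c("cluster", "population", "ligand_rmsd",
                          "pocket_rmsd"))
  # the most populated cluster has the lowest RMSD to the reference
  expect_equal(which.min(rep_tab$ligand_rmsd), 1L)
  expect_lte(sum(rep_tab$population), 100 + 1e-6)

  # without a reference the RMSD columns are omitted
  bare <- report_clusters(cl, fitted)
  expect_named(bare, c("cluster", "population"))

  # assignments CSV round-trips
  f <- tempfile(fileext = ".csv")
  write_cluster_assignments(cl, fitted, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 600)
  expect_equal(tab$cluster, cl$labels)
})
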