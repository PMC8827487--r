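test_that("the 8-6 energy reproduces its analytic single-pair values", {
  xa <- matrix(c(0, 0, 0), 1)
  xb <- matrix(c(1, 0, 0), 1)
  # neutral pair with B = C = 0
  expect_equal(energy_maxdo_raw(xa, xb, 0, 0, 0, 0), 0)
  # B = C = 1 at r = 1: 1/1 - 1/1 = 0
  expect_equal(energy_maxdo_raw(xa, xb, 1, 1, 0, 0), 0)
  # pure charge term at r = 1: q q / (15 r^2) = 1/15
  expect_equal(energy_maxdo_raw(xa, xb, 0, 0, 1, 1), 1 / 15)
  # clash singularity
  expect_error(energy_maxdo_raw(xa, xa, 1, 1, 0, 0), "clash")
})

test_that("the 12-6 energy reproduces its analytic single-pair values", {
  xa <- matrix(c(0, 0, 0), 1)
  # sigma = 1 at r = 1: 1 - 1 = 0
  expect_equal(energy_iattract_raw(xa, matrix(c(1, 0, 0), 1), 1, 0, 0), 0)
  # LJ off, charges 1 at r = 2: 1 / (10 * 2)
  expect_equal(energy_iattract_raw(xa, matrix(c(2, 0, 0), 1), 0, 1, 1), 0.05)
})

test_that("both engine sums equal brute-force double loops with cutoff disabled", {
  set.seed(42)
  for (rep in 1:3) {
    xa <- matrix(runif(30, 0, 10), 10)
    xb <- matrix(runif(30, 12, 20), 10)
    B <- matrix(runif(100, 0, 5), 10)
    C <- matrix(runif(100, 0, 5), 10)
    sg <- matrix(runif(100, 0.5, 3), 10)
    qa <- sample(c(-1, 0, 1), 10, replace = TRUE)
    qb <- sample(c(-1, 0, 1), 10, replace = TRUE)
    expect_lt(abs(energy_maxdo_raw(xa, xb, B, C, qa, qb, cutoff = Inf) -
                    bf_energy_maxdo(xa, xb, B, C, qa, qb)), 1e-10)
    expect_lt(abs(energy_iattract_raw(xa, xb, sg, qa, qb, cutoff = Inf) -
                    bf_energy_iattract(xa, xb, sg, qa, qb)), 1e-10)
  }
})

test_that("pair energies are symmetric under receptor/ligand swap and rigid moves", {
  set.seed(7)
  a <- bead_protein("a", matrix(rnorm(18, sd = 3), 6), q = c(1, 0, -1, 0, 1, 0),
                    sigma = 2, eps = 0.5)
  b <- bead_protein("b", matrix(rnorm(15, sd = 3) + 8, 5), q = c(0, 1, 0, -1, 0),
                    sigma = 2.5, eps = 0.4)
  tf <- rigid_transform(rotation_about_axis(c(1, 1, 0), 0.4), c(1, -2, 0.5))
  for (fn in list(pair_energy_maxdo, pair_energy_iattract)) {
    e_ab <- fn(a, b, tf, cutoff = Inf)
    e_ba <- fn(b, a, invert_transform(tf), cutoff = Inf)
    expect_lt(abs(e_ab - e_ba), 1e-9)
    # common rigid transform of both proteins leaves the energy unchanged
    g <- rigid_transform(rotation_about_axis(c(0, 1, 2), 1.1), c(-3, 4, 9))
    a2 <- a; a2$beads[, c("x", "y", "z")] <- as.data.frame(apply_transform(cg_coords(a), g))
    e_moved <- fn(a2, b, compose_transforms(g, tf), cutoff = Inf)
    expect_lt(abs(e_ab - e_moved), 1e-9)
  }
})

test_that("with zero charges the energies vanish as the ligand moves to infinity", {
  a <- bead_protein("a", c(0, 0, 0), q = 0, sigma = 2, eps = 1)
  b <- bead_protein("b", c(0, 0, 0), q = 0, sigma = 2, eps = 1)
  far <- rigid_transform(translation = c(1e5, 0, 0))
  expect_lt(abs(pair_energy_maxdo(a, b, far, cutoff = Inf)), 1e-20)
  expect_lt(abs(pair_energy_iattract(a, b, far, cutoff = Inf)), 1e-20)
})

test_that("start poses respect the construction geometry", {
  cx <- make_toy_complex(fixture_spec(seed = 4, n_residues = 24, patch_size = 5), assert = FALSE)
  poses <- generate_start_poses(cx$a, cx$b, "surface-restrained",
                                n_positions = 1, n_rotations = 4)
  expect_length(poses, 4)
  # successive rotations differ by 90 degrees about the COM axis
  r01 <- poses[[2]]$rotation %*% t(poses[[1]]$rotation)
  ang <- acos(max(-1, min(1, (sum(diag(r01)) - 1) / 2)))
  expect_equal(ang, pi / 2, tolerance = 1e-9)
  # every start keeps the ligand COM on the receptor-COM -> position ray
  com_r <- colMeans(cg_coords(cx$a))
  com_l <- colMeans(cg_coords(cx$b))
  many <- generate_start_poses(cx$a, cx$b, "surface-restrained",
                               n_positions = 8, n_rotations = 3)
  for (tf in many) {
    u <- attr(tf, "direction")
    v <- as.numeric(tf$rotation %*% com_l) + tf$translation - com_r
    cosang <- sum(u * v) / sqrt(sum(v^2))
    expect_gt(cosang, 1 - 1e-9)
  }
})

test_that("a candidate mask restricts start positions to its region", {
  cx <- make_toy_complex(fixture_spec(seed = 4, n_residues = 40, patch_size = 6), assert = FALSE)
  a <- cx$a
  mask <- cg_coords(a)[, 3] > 0  # upper hemisphere residues only
  poses <- generate_start_poses(a, cx$b, "free", n_positions = 32, n_rotations = 1,
                                candidate_mask = mask)
  expect_gt(length(poses), 0)
  ca <- cg_coords(a)
  com_r <- colMeans(ca)
  for (tf in poses) {
    u <- attr(tf, "direction")
    ext <- max(sweep(ca, 2, com_r) %*% u)
    p <- com_r + u * ext
    nearest <- which.min(rowSums(sweep(ca, 2, p)^2))
    expect_true(mask[nearest])
  }
})

test_that("minimisation descends and finds the analytic two-bead optimum", {
  # d/dr (B r^-8 - C r^-6) = 0 at r* = sqrt(4B/3C); with B = C = 1, r* = sqrt(4/3)
  a <- unit_bc_protein("a", c(0, 0, 0))
  b <- unit_bc_protein("b", c(2, 0, 0))
  start <- rigid_transform()
  res <- minimize_pose(a, b, start, "maxdo", "surface-restrained", cutoff = Inf,
                       step_trans = 0.5, tol = 1e-12)
  e_start <- pair_energy_maxdo(a, b, start, cutoff = Inf)
  expect_lte(res$energy, e_start)
  r_opt <- sqrt(sum((apply_transform(cg_coords(b), res$transform) - cg_coords(a))^2))
  expect_equal(r_opt, sqrt(4 / 3), tolerance = 1e-2)
  # brute-force 1-D scan agrees on the location of the optimum
  rs <- seq(0.8, 3, by = 1e-4)
  expect_equal(rs[which.min(rs^-8 - rs^-6)], sqrt(4 / 3), tolerance = 1e-3)
  # starting at the optimum stays put
  at_opt <- rigid_transform(translation = c(sqrt(4 / 3) - 2, 0, 0))
  res2 <- minimize_pose(a, b, at_opt, "maxdo", "surface-restrained", cutoff = Inf)
  expect_equal(res2$energy, pair_energy_maxdo(a, b, at_opt, cutoff = Inf), tolerance = 1e-6)
})

test_that("minimisation never increases the energy on random starts", {
  cx <- make_toy_complex(fixture_spec(seed = 11, n_residues = 20, patch_size = 4), assert = FALSE)
  poses <- generate_start_poses(cx$a, cx$b, "surface-restrained", 4, 2)
  for (tf in poses) {
    e0 <- pair_energy_maxdo(cx$a, cx$b, tf)
    res <- minimize_pose(cx$a, cx$b, tf, "maxdo", "surface-restrained", max_sweeps = 8)
    expect_lte(res$energy, e0 + 1e-12)
  }
})

test_that("cross-docking enumerates ordered pairs and is seed-reproducible", {
  spec <- fixture_spec(seed = 6, n_proteins = 4, n_residues = 16, patch_size = 3)
  bench <- make_benchmark_set(spec, assert = FALSE)
  prot3 <- bench$proteins[1:3]
  settings <- dock_settings(n_positions = 3, n_rotations = 2, seed = 5, max_sweeps = 5)
  st <- cross_dock(prot3, settings)
  pairs <- dplyr::distinct(st$poses, receptor_id, ligand_id)
  expect_equal(nrow(pairs), 9)  # N^2 ordered pairs, self included
  st2 <- cross_dock(prot3, settings)
  expect_identical(st$poses$e_maxdo, st2$poses$e_maxdo)
  # free protocol mirrors the unordered pairs
  stf <- cross_dock(prot3, dock_settings(protocol = "free", n_positions = 2,
                                         n_rotations = 2, seed = 5, max_sweeps = 4))
  pf <- dplyr::distinct(stf$poses, receptor_id, ligand_id)
  expect_equal(nrow(pf), 9)
  ab <- stf$poses[stf$poses$receptor_id == names(prot3)[1] & stf$poses$ligand_id == names(prot3)[2], ]
  ba <- stf$poses[stf$poses$receptor_id == names(prot3)[2] & stf$poses$ligand_id == names(prot3)[1], ]
  expect_equal(ab$e_maxdo, ba$e_maxdo)
})

test_that("ordered-pair counts scale as N^2 with the surface-restrained protocol", {
  # 3 -> 9 checked above; the full-benchmark count follows the same square law
  for (n in c(2, 5)) {
    ids <- paste0("q", seq_len(n))
    expect_equal(nrow(expand.grid(ids, ids)), n^2)
  }
})

test_that("docked-interface annotation and external scores join correctly", {
  spec <- fixture_spec(seed = 6, n_proteins = 2, n_residues = 16, patch_size = 3)
  bench <- make_benchmark_set(spec, assert = FALSE)
  st <- cross_dock(bench$proteins, dock_settings(n_positions = 2, n_rotations = 2,
                                                 seed = 2, max_sweeps = 4))
  st <- docked_interfaces(st, 5)
  expect_true(all(c("di_receptor", "di_ligand") %in% names(st$poses)))
  # oracle: recompute one pose's interface by brute force
  k <- which.min(st$poses$e_maxdo)
  rec <- st$proteins[[st$poses$receptor_id[k]]]
  lig <- st$proteins[[st$poses$ligand_id[k]]]
  xl <- apply_transform(cg_coords(lig), st$poses$transform[[k]])
  bf <- bf_interface(cg_coords(rec), rec$beads$res_idx, xl, lig$beads$res_idx, 5)
  expect_equal(st$poses$di_receptor[[k]], bf$a)
  expect_equal(st$poses$di_ligand[[k]], bf$b)
  ext <- dplyr::mutate(st$poses[, c("receptor_id", "ligand_id", "pose_id")],
                       score = seq_len(nrow(st$poses)) * 1.5)
  st <- add_external_energy(st, ext)
  expect_equal(st$poses$e_external, seq_len(nrow(st$poses)) * 1.5)
})

test_that("a conformation store round-trips through its text layout", {
  spec <- fixture_spec(seed = 6, n_proteins = 2, n_residues = 14, patch_size = 3)
  bench <- make_benchmark_set(spec, assert = FALSE)
  st <- cross_dock(bench$proteins, dock_settings(n_positions = 2, n_rotations = 2,
                                                 seed = 3, max_sweeps = 4))
  st <- docked_interfaces(st, 5)
  dir <- withr::local_tempdir()
  write_store(st, dir)
  back <- read_store(dir)
  expect_equal(back$poses$e_maxdo, st$poses$e_maxdo)
  expect_equal(back$poses$di_receptor, st$poses$di_receptor)
  expect_equal(back$seed, st$seed)
  expect_equal(back$poses$transform[[3]]$rotation, st$poses$transform[[3]]$rotation,
               tolerance = 1e-12)
  expect_setequal(names(back$proteins), names(st$proteins))
})
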