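test_that("a tight alpha-helix cluster peaks in the cell containing (-60, -30)", {
  traj <- cluster_traj(1000, c(-60, -30), sd = 3, seed = 11)
  grid <- compute_rdp(traj, grid_dim = 32)
  peak <- which(grid$values == max(grid$values), arr.ind = TRUE)
  cell_w <- 360 / 32
  expect_equal(unname(peak[1, "row"]), floor((-60 + 180) / cell_w) + 1)
  expect_equal(unname(peak[1, "col"]), floor((-30 + 180) / cell_w) + 1)
  expect_true(all(grid$values >= 0))
})

test_that("grid values match an independently coded KDE oracle", {
  traj <- simulate_ensemble(ensemble_spec(n_residues = 3, n_frames = 50, seed = 2),
                            source_id = "oracle")
  grid <- compute_rdp(traj, grid_dim = 16)
  ctr <- grid_centers(16)
  eval_pts <- cbind(rep(ctr, times = 16), rep(ctr, each = 16))
  want <- brute_kde(cbind(traj$records$phi, traj$records$psi), eval_pts)
  expect_equal(as.vector(grid$values), want, tolerance = 1e-10)
})

test_that("Riemann mass of the 32x32 grid agrees with a 512x512 quadrature oracle", {
  traj <- simulate_ensemble(ensemble_spec(n_residues = 2, n_frames = 40, seed = 9),
                            source_id = "mass")
  grid <- compute_rdp(traj, grid_dim = 32)
  mass32 <- sum(grid$values) * (360 / 32)^2
  fine <- 512
  ctr <- grid_centers(fine)
  eval_pts <- cbind(rep(ctr, times = fine), rep(ctr, each = fine))
  oracle_mass <- sum(brute_kde(cbind(traj$records$phi, traj$records$psi),
                               eval_pts)) * (360 / fine)^2
  expect_lt(abs(mass32 - oracle_mass), 0.05)
  expect_gt(oracle_mass, 0.8)  # most kernel mass is in range
})

test_that("degenerate and undersized ensembles are rejected with guidance", {
  one <- dihedral_trajectory(0, "A", -60, -30)
  expect_error(compute_rdp(one), ">= 2")
  same <- dihedral_trajectory(c(0, 30, 60), c("A", "A", "A"),
                              rep(-60, 3), rep(-30, 3))
  expect_error(compute_rdp(same), "jitter|degenerate")
})

test_that("difference images are elementwise, antisymmetric, and zero on identity", {
  grids <- random_grids(2, 8, seed = 3)
  a <- grids[[1]]; b <- grids[[2]]
  expect_equal(rdp_difference_image(a, a), matrix(0, 8, 8))
  expect_equal(rdp_difference_image(a, b) + rdp_difference_image(b, a),
               matrix(0, 8, 8))
  expect_equal(rdp_difference_image(a, b), a$values - b$values)
  small <- random_grids(1, 4, seed = 4)[[1]]
  expect_error(rdp_difference_image(a, small), "mismatch")
})

test_that("shifting the sample moves the density peak by the matching cells", {
  base <- cluster_traj(800, c(-60, -30), sd = 5, seed = 21)
  cell_w <- 360 / 32
  shift <- 3 * cell_w
  shifted <- dihedral_trajectory(base$records$time, base$records$residue_tag,
                                 base$records$phi + shift,
                                 base$records$psi + shift,
                                 source_id = "shifted")
  p0 <- which(compute_rdp(base)$values == max(compute_rdp(base)$values),
              arr.ind = TRUE)
  p1 <- which(compute_rdp(shifted)$values == max(compute_rdp(shifted)$values),
              arr.ind = TRUE)
  expect_lte(abs(p1[1, "row"] - p0[1, "row"] - 3), 1)
  expect_lte(abs(p1[1, "col"] - p0[1, "col"] - 3), 1)
})

test_that("duplicating the sample leaves the density peak cell unchanged", {
  traj <- simulate_ensemble(ensemble_spec(n_residues = 2, n_frames = 60, seed = 5),
                            source_id = "dup")
  r <- traj$records
  ord <- order(rep(r$time, 2))
  doubled <- dihedral_trajectory(rep(r$time, 2)[ord], rep(r$residue_tag, 2)[ord],
                                 c(r$phi, r$phi)[ord], c(r$psi, r$psi)[ord],
                                 source_id = "doubled")
  a <- compute_rdp(traj)
  b <- compute_rdp(doubled)
  expect_equal(which(a$values == max(a$values), arr.ind = TRUE),
               which(b$values == max(b$values), arr.ind = TRUE))
})

test_that("grids round-trip through TSV and JSON in phi-slow row-major order", {
  grid <- compute_rdp(cluster_traj(200, c(-120, 130), sd = 8, seed = 6), 16)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(grid, f1)
  df <- read.delim(f1)
  expect_equal(nrow(df), 256)
  # phi is the slow axis: first 16 rows share the first phi center
  expect_equal(df$phi_center[1:16], rep(grid_centers(16)[1], 16))
  back <- read_grid_tsv(f1)
  expect_equal(back$values, grid$values, tolerance = 1e-12, ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".json")
  write_grid_json(grid, f2)
  back2 <- read_grid_json(f2)
  expect_equal(back2$values, grid$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back2$grid_dim, 16)
})

test_that("wrap mode moves seam-cluster mass across the boundary", {
  traj <- cluster_traj(500, c(176, 0), sd = 6, seed = 8)
  flat <- compute_rdp(traj, wrap = FALSE)
  wrapped <- compute_rdp(traj, wrap = TRUE)
  # density in the first phi row (near -180) only appears when wrapping
  expect_gt(sum(wrapped$values[1, ]), sum(flat$values[1, ]))
})
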