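test_that("an isotropic spherical shell is spherical by the ellipticity measure", {
  fr <- bead_frame(16 * fibonacci_shell(10000) + 20, "B", c(40, 40, 40))
  sh <- gyration_shape(fr)
  expect_lte(sh$E, 0.02)
  expect_equal(sh$lambda1, sh$lambda3, tolerance = 0.05)
  # random isotropic shell too
  set.seed(21)
  u <- matrix(rnorm(3 * 10000), ncol = 3)
  u <- 16 * u / sqrt(rowSums(u^2))
  sh2 <- gyration_shape(bead_frame(u + 20, "B", c(40, 40, 40)))
  expect_lte(sh2$E, 0.02)
})

test_that("beads on the x axis give the closed-form eigenstructure", {
  d <- 3
  pos <- rbind(c(d / 2, 0, 0), c(-d / 2, 0, 0),
               c(d / 2, 0, 0), c(-d / 2, 0, 0)) + 10
  sh <- gyration_shape(bead_frame(pos, "B", c(20, 20, 20)))
  expect_equal(sh$lambda1, d^2 / 4, tolerance = 1e-12)
  expect_equal(sh$lambda2, 0, tolerance = 1e-12)
  expect_equal(sh$E, 1, tolerance = 1e-12)
  expect_equal(sh$theta_V, 0, tolerance = 1e-9)
})

test_that("gyration tensor equals the explicit textbook sum", {
  set.seed(22)
  fr <- random_cloud(200, seed = 22)
  sh <- gyration_shape(fr)
  pos <- frame_positions(fr)
  com <- colMeans(pos)
  S <- matrix(0, 3, 3)
  for (i in seq_len(nrow(pos))) {          # deliberate O(N) loop oracle
    v <- pos[i, ] - com
    S <- S + tcrossprod(v)
  }
  S <- S / nrow(pos)
  lam <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  expect_equal(c(sh$lambda1, sh$lambda2, sh$lambda3), lam, tolerance = 1e-10)
})

test_that("E is rotation-invariant and eigenvalues are translation-invariant", {
  fr <- random_cloud(300, seed = 23)
  sh <- gyration_shape(fr)
  rot <- rotation_matrix_test(c(1, 2, 3), 0.9)
  fr_rot <- bead_frame(frame_positions(fr) %*% t(rot) + 30, fr$type,
                       box = c(100, 100, 100))
  sh_rot <- gyration_shape(fr_rot)
  expect_equal(sh_rot$E, sh$E, tolerance = 1e-9)
  expect_equal(c(sh_rot$lambda1, sh_rot$lambda2, sh_rot$lambda3),
               c(sh$lambda1, sh$lambda2, sh$lambda3), tolerance = 1e-9)
})

test_that("orientation angles locate a flow-aligned prolate shell", {
  set.seed(24)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  shell <- cbind(24 * u[, 1], 8 * u[, 2], 8 * u[, 3])
  sh <- gyration_shape(bead_frame(shell + 40, "B", c(80, 80, 80)))
  expect_lte(sh$theta_V, 2)            # major axis along x
  expect_gte(sh$phi_V, 88)             # in the x-y plane
  # rotate the major axis to y: theta_V -> 90
  rot <- rotation_matrix_test(c(0, 0, 1), pi / 2)
  sh2 <- gyration_shape(bead_frame(shell %*% t(rot) + 40, "B", c(80, 80, 80)))
  expect_gte(sh2$theta_V, 88)
})

test_that("reduced volume reproduces the worked values", {
  expect_equal(round(reduced_volume(9506, 3447)$nu, 2), 0.50)
  R <- 7.3
  expect_equal(reduced_volume((4 / 3) * pi * R^3, 4 * pi * R^2)$nu, 1,
               tolerance = 1e-12)
  expect_equal(reduced_volume(4188.8, 2513.3)$nu, 1 / 2^1.5,
               tolerance = 1e-3)
  expect_error(reduced_volume(-1, 10), "positive")
  # nu decreases as A grows at fixed V
  nus <- reduced_volume(rep(1000, 3), c(500, 700, 900))$nu
  expect_true(all(diff(nus) < 0))
})

test_that("voxel volume and co-area surface match a solid sphere", {
  # dense bead lattice filling radius R - rb so the dilated envelope is R
  R <- 10; rb <- 0.264
  g <- seq(-R, R, by = 0.35)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= (R - rb)^2, ]
  fr <- bead_frame(pts + 15, "B", c(30, 30, 30))
  va <- enclosed_volume_area(fr, bead_radius = rb)
  expect_equal(va$V, 4 / 3 * pi * R^3, tolerance = 0.05)
  expect_equal(va$A, 4 * pi * R^2, tolerance = 0.05)
  expect_true(va$closed)
  # halving the voxel reduces the volume error
  va2 <- enclosed_volume_area(fr, voxel = 0.25, bead_radius = rb)
  expect_lt(abs(va2$V - 4 / 3 * pi * R^3), abs(va$V - 4 / 3 * pi * R^3) + 1e-9)
})

test_that("hollow vesicle volume includes the enclosed solvent core", {
  ves <- make_vesicle(morphology_spec(outer_radius = 16, thickness = 5,
                                      n_chains = 3871, seed = 2))
  va <- enclosed_volume_area(ves$frame)
  # outer bead centres sit at 16 nm; the outer envelope of their spheres
  # is at 16 + bead_radius
  truth <- 4 / 3 * pi * (16 + 0.264)^3
  expect_equal(va$V, truth, tolerance = 0.05)
  expect_equal(va$A, 4 * pi * (16 + 0.264)^2, tolerance = 0.05)
  expect_true(va$closed)
  expect_equal(va$nu, 1, tolerance = 0.02)
})

test_that("an open structure triggers the topology warning and falls back", {
  # hemisphere bowl: flood fill reaches the inside
  set.seed(25)
  u <- matrix(rnorm(3 * 4000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u <- u[u[, 3] > 0.2, ]
  shell <- 8 * u
  fr <- bead_frame(shell + 12, "B", c(24, 24, 24))
  expect_warning(va <- enclosed_volume_area(fr), "open structure")
  expect_false(va$closed)
  expect_lt(va$V, 4 / 3 * pi * 8^3 / 2)
})
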