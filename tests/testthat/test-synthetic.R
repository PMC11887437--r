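test_that("fixed seed gives bit-identical output; seeds vary the layout", {
  a <- make_vesicle(morphology_spec(n_chains = 100, outer_radius = 8,
                                    thickness = 4, seed = 5))
  b <- make_vesicle(morphology_spec(n_chains = 100, outer_radius = 8,
                                    thickness = 4, seed = 5))
  expect_identical(frame_positions(a$frame), frame_positions(b$frame))
  c_ <- make_vesicle(morphology_spec(n_chains = 100, outer_radius = 8,
                                     thickness = 4, seed = 6))
  expect_false(identical(frame_positions(a$frame), frame_positions(c_$frame)))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(make_vesicle(morphology_spec(n_chains = 50,
                                                      outer_radius = 8,
                                                      thickness = 4)))
  expect_identical(runif(1), before)
})

test_that("spec validation rejects infeasible morphologies", {
  expect_error(morphology_spec(thickness = 1.5), "below 2 nm")
  expect_error(morphology_spec(thickness = 17, outer_radius = 8), "thickness")
  expect_error(morphology_spec(stretched_fraction = 1.2), "\\[0, 1\\]")
  expect_error(morphology_spec(n_chains = 0), "positive")
  # chain count beyond the surface capacity at the minimum spacing
  expect_error(make_vesicle(morphology_spec(outer_radius = 4, thickness = 2.5,
                                            n_chains = 5000)),
               "packing error")
  expect_error(make_vesicle(morphology_spec("fragments", n_chains = 10,
                                            fragment_chains = c(4, 4))),
               "sum")
})

test_that("the membrane is a single aggregate with interfaces in the right order", {
  ves <- make_vesicle(morphology_spec(outer_radius = 10, thickness = 5,
                                      n_chains = 1200, seed = 3))
  cl <- find_clusters(ves$frame, ves$topology)
  expect_gte(largest_cluster_fraction(cl), 0.99)
  # radial span of the membrane: [outer_radius - thickness, outer_radius]
  pos <- frame_positions(ves$frame, copolymer_beads(ves$frame))
  r <- sqrt(rowSums(sweep(pos, 2, colMeans(pos))^2))
  expect_equal(max(r), 10, tolerance = 0.02)
  expect_equal(min(r), 5, tolerance = 0.1)
})

test_that("stretched fraction is realised exactly in the placed population", {
  for (frac in c(0, 0.25, 1)) {
    ves <- make_vesicle(morphology_spec(outer_radius = 10, thickness = 4,
                                        n_chains = 400,
                                        stretched_fraction = frac, seed = 4))
    qq <- end_to_end(ves$frame, ves$topology)
    n_ext <- sum(qq$Q > 5)
    expect_equal(n_ext, round(frac * 400))
  }
})

test_that("ellipticity series is AR(1) with the prescribed correlation time", {
  sp <- series_spec(mean = 0.05, correlation_time = 6, noise_sd = 0.01,
                    dt = 0.05, n_steps = 50000, seed = 3)
  s <- make_ellipticity_series(sp)
  expect_equal(nrow(s), 50000)
  expect_equal(diff(s$time)[1], 0.05)
  expect_equal(mean(s$value), 0.05, tolerance = 0.02)
  expect_equal(sd(s$value), 0.01, tolerance = 0.1)
  rho1 <- acf(s$value, lag.max = 1, plot = FALSE)$acf[2, 1, 1]
  expect_equal(rho1, exp(-0.05 / 6), tolerance = 0.005)
  # degenerate noise: constant series
  s0 <- make_ellipticity_series(series_spec(noise_sd = 0, n_steps = 500))
  expect_true(all(s0$value == s0$value[1]))
  # undersampling warning
  expect_warning(make_ellipticity_series(series_spec(correlation_time = 0.01,
                                                     dt = 0.05,
                                                     n_steps = 200)),
                 "undersampled")
  # two seeds: different paths, compatible fitted tau
  s1 <- make_ellipticity_series(series_spec(seed = 21))
  s2 <- make_ellipticity_series(series_spec(seed = 22))
  expect_false(identical(s1$value, s2$value))
  t1 <- acf_relaxation_time(s1)$tau
  t2 <- acf_relaxation_time(s2)$tau
  expect_lt(abs(t1 - 6) / 6, 0.3)
  expect_lt(abs(t2 - 6) / 6, 0.3)
})

test_that("rupture trajectory splits exactly when strain exceeds the threshold", {
  spec <- morphology_spec(outer_radius = 10, thickness = 5, n_chains = 800,
                          seed = 11)
  traj <- make_rupture_trajectory(spec, rupture_strain = 6, strain_rate = 1,
                                  n_frames = 10, dt = 1)
  expect_length(traj$frames, 10)
  counts <- vapply(traj$frames, nrow, integer(1))
  expect_true(all(counts == counts[1]))   # constant bead count
  times <- vapply(traj$frames, frame_time, numeric(1))
  expect_equal(times, 0:9)
  fr7 <- traj$frames[[8]]                  # t = 7, gamma = 7 > 6
  cl7 <- find_clusters(fr7, traj$topology)
  expect_lt(largest_cluster_fraction(cl7), 0.9)
  expect_gte(length(cluster_sizes(cl7)), 2)
  fr6 <- traj$frames[[7]]                  # t = 6, gamma = 6, not ruptured
  expect_gte(largest_cluster_fraction(find_clusters(fr6, traj$topology)), 0.9)
  expect_error(make_rupture_trajectory(spec, 6, 1, n_frames = 2), "3 frames")
  expect_error(make_rupture_trajectory(spec, -1, 1, n_frames = 5), "positive")
})

test_that("no-rupture trajectory stays one aggregate in every frame", {
  spec <- morphology_spec(outer_radius = 9, thickness = 5, n_chains = 600,
                          seed = 12)
  traj <- make_rupture_trajectory(spec, rupture_strain = 100, strain_rate = 1,
                                  n_frames = 5, dt = 1)
  fracs <- vapply(traj$frames, function(fr) {
    largest_cluster_fraction(find_clusters(fr, traj$topology))
  }, numeric(1))
  expect_true(all(fracs >= 0.9))
})

test_that("solvent lattice fills core and exterior at the stated density", {
  ves <- make_vesicle(morphology_spec(outer_radius = 8, thickness = 4,
                                      n_chains = 300, core_solvated = TRUE,
                                      box = rep(20, 3), seed = 13))
  fr <- ves$frame
  w <- which(fr$type == "W")
  expect_gt(length(w), 0)
  pos <- frame_positions(fr, w)
  r <- sqrt(rowSums(sweep(pos, 2, rep(10, 3))^2))
  expect_true(all(r < 8 - 4))          # solvent confined to the core
  core_vol <- 4 / 3 * pi * 3.5^3       # radius 8 - 4 - 0.5 margin
  expect_equal(length(w) / core_vol, 8.4, tolerance = 0.15)
})
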