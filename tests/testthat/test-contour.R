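test_that("uniform spherical shell gives flat thickness and density profiles", {
  ves <- make_vesicle(morphology_spec(outer_radius = 16, thickness = 5,
                                      n_chains = 3871, seed = 8))
  cp <- contour_profiles(ves$frame, ves$topology)
  expect_equal(nrow(cp), 72)
  expect_true(all(abs(cp$thickness - 5) <= 0.4))
  rel <- cp$bead_density / mean(cp$bead_density)
  expect_true(all(abs(rel - 1) <= 0.1))
  expect_length(attr(cp, "gaps"), 0)
})

test_that("bin density times arc length sums to the total bead count", {
  for (seed in c(8, 9)) {
    ves <- make_vesicle(morphology_spec(outer_radius = 10, thickness = 4,
                                        n_chains = 800, seed = seed))
    cp <- contour_profiles(ves$frame, ves$topology)
    total <- sum(cp$bead_density * cp$arc_len, na.rm = TRUE)
    expect_equal(total, length(copolymer_beads(ves$frame)), tolerance = 0.01)
  }
})

test_that("profiles rotate with the body frame", {
  ves <- make_vesicle(morphology_spec("ellipsoid", semi_axes = c(14, 7, 7),
                                      thickness = 4, n_chains = 800,
                                      seed = 10))
  cp1 <- suppressWarnings(contour_profiles(ves$frame, ves$topology,
                                           n_bins = 36))
  rot <- rotation_matrix_test(c(0, 0, 1), 0.17)
  pos_rot <- frame_positions(ves$frame) %*% t(rot)
  fr_rot <- bead_frame(pos_rot + 40, ves$frame$type, box = rep(120, 3))
  cp2 <- suppressWarnings(contour_profiles(fr_rot, ves$topology,
                                           n_bins = 36))
  expect_equal(cp2$thickness, cp1$thickness, tolerance = 0.05)
  expect_equal(cp2$bead_density, cp1$bead_density, tolerance = 0.05)
})

test_that("dumbbell thickness shows two end maxima and a mid-contour minimum", {
  hfun <- function(psi) 2.2 + (5 - 2.2) * abs(cos(psi))^1.5
  ves <- make_vesicle(morphology_spec("dumbbell", thickness = hfun,
                                      n_chains = 2000, end_radius = 8,
                                      centre_sep = 12, neck_radius = 3,
                                      seed = 5))
  cp <- suppressWarnings(contour_profiles(ves$frame, ves$topology,
                                          n_bins = 24))
  th <- cp$thickness
  ang <- cp$angle_deg
  # ends of the major axis sit a quarter-contour from the origin bin
  end1 <- abs(((ang - 90) + 180) %% 360 - 180) <= 30
  end2 <- abs(((ang - 270) + 180) %% 360 - 180) <= 30
  mid <- !(end1 | end2)
  expect_gt(max(th[end1], na.rm = TRUE), 4)
  expect_gt(max(th[end2], na.rm = TRUE), 4)
  expect_lt(min(th[mid], na.rm = TRUE), 3)
})

test_that("stretched chains confined to the neck raise mid-contour extension", {
  hfun <- function(psi) 2.5 + (5 - 2.5) * abs(cos(psi))^1.5
  ves <- make_vesicle(morphology_spec("dumbbell", thickness = hfun,
                                      n_chains = 2000, end_radius = 8,
                                      centre_sep = 10, neck_radius = 3.5,
                                      stretched_fraction = 0.15,
                                      stretched_region = "neck", seed = 7))
  cp <- suppressWarnings(contour_profiles(ves$frame, ves$topology,
                                          n_bins = 24))
  ang <- cp$angle_deg
  end_bins <- abs(((ang - 90) + 180) %% 360 - 180) <= 30 |
    abs(((ang - 270) + 180) %% 360 - 180) <= 30
  expect_gt(max(cp$Qbar_s[!end_bins], na.rm = TRUE),
            max(cp$Qbar_s[end_bins], na.rm = TRUE))
  # brute-force chain-to-bin assignment oracle
  sh <- gyration_shape(ves$frame)
  axes <- attr(sh, "axes"); com <- attr(sh, "com")
  e1 <- axes[, 1] * sign(axes[which.max(abs(axes[, 1])), 1])
  e2 <- axes[, 2] * sign(axes[which.max(abs(axes[, 2])), 2])
  pos <- frame_positions(ves$frame)
  qq <- end_to_end(ves$frame, ves$topology)
  width <- 2 * pi / 24
  got_bins <- rep(NA_real_, 24)
  for (b in 1:24) {
    qs <- c()
    for (ch in unique(ves$topology$chain)) {
      beads <- ves$topology$bead[ves$topology$chain == ch]
      cc <- colMeans(pos[beads, , drop = FALSE]) - com
      angc <- atan2(sum(cc * e2), sum(cc * e1))
      rel <- (angc - pi / 2 + width / 2) %% (2 * pi)
      if (min(floor(rel / width), 23) + 1 == b) qs <- c(qs, qq$Q[qq$chain == ch])
    }
    if (length(qs)) got_bins[b] <- mean(qs)
  }
  expect_equal(cp$Qbar_s, got_bins, tolerance = 1e-9)
})

test_that("an interrupted outline flags empty bins", {
  # crescent: ring of chains with one side removed
  set.seed(36)
  n <- 300
  th <- runif(n, 0.25 * pi, 1.75 * pi)
  starts <- cbind(8 * cos(th), 8 * sin(th), runif(n, -1, 1))
  vecs <- matrix(rep(c(0, 0, 0.95), n), n, 3, byrow = TRUE)
  obj <- chains_frame(starts, vecs, box = 40)
  expect_warning(cp <- contour_profiles(obj$frame, obj$topology),
                 "empty contour bin")
  expect_gt(length(attr(cp, "gaps")), 0)
  expect_true(all(is.na(cp$thickness[attr(cp, "gaps")])))
})
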