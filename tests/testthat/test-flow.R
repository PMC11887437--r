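test_that("flow context keeps the Wi and strain bookkeeping exact", {
  fc <- flow_context(shear_rate = 2, tau = 6)
  expect_equal(fc$Wi, 12)
  expect_equal(fc$strain(3), 6)
  expect_error(flow_context(-1, 6), "nonnegative")
  expect_error(flow_context(1, 0), "positive")
})

test_that("exact exponential autocorrelation values recover tau precisely", {
  lag_time <- seq(0, 15, by = 0.05)
  y <- exp(-lag_time / 6)
  ft <- vesishear:::fit_exp_acf(lag_time, y, n_obs = 50000)
  expect_equal(ft$tau, 6, tolerance = 1e-6)
})

test_that("AR(1) series recover the prescribed relaxation time", {
  taus <- vapply(1:10, function(s) {
    ser <- make_ellipticity_series(series_spec(correlation_time = 6,
                                               dt = 0.05, n_steps = 50000,
                                               seed = s))
    acf_relaxation_time(ser)$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 6) / 6, 0.1)     # ensemble estimate
  expect_true(all(abs(taus - 6) / 6 < 0.3))   # per-seed sampling noise
})

test_that("degenerate series are flagged", {
  expect_error(acf_relaxation_time(scalar_series(1:200 * 0.1, rep(1, 200))),
               "zero-variance")
  expect_error(acf_relaxation_time(scalar_series(1:50 * 0.1, rnorm(50))),
               "too short")
  set.seed(42)
  wn <- scalar_series((1:5000) * 0.05, rnorm(5000))
  expect_warning(ft <- acf_relaxation_time(wn), "unresolved")
  expect_lt(ft$tau, 0.05)
  expect_false(ft$resolved)
})

test_that("rupture detection applies threshold and persistence", {
  # two chains: together (fraction 1) or apart (fraction 0.5)
  make_pair <- function(apart, t) {
    gap <- if (apart) 30 else 0.2
    obj <- chains_frame(rbind(c(0, 0, 0), c(gap, 0.2, 0)),
                        rbind(c(8.93, 0, 0), c(8.93, 0, 0)))
    fr <- obj$frame
    attr(fr, "time") <- t
    fr
  }
  topo <- chain_topology(2)
  # transient one-frame dip then recovery: no rupture
  frames <- list(make_pair(FALSE, 0), make_pair(TRUE, 1), make_pair(FALSE, 2),
                 make_pair(FALSE, 3), make_pair(FALSE, 4))
  det <- detect_rupture(frames, topo)
  expect_false(det$ruptured)
  # persistent split from t = 2: rupture at 2
  frames2 <- list(make_pair(FALSE, 0), make_pair(FALSE, 1), make_pair(TRUE, 2),
                  make_pair(TRUE, 3), make_pair(TRUE, 4))
  det2 <- detect_rupture(frames2, topo)
  expect_true(det2$ruptured)
  expect_equal(det2$time, 2)
  # intact trajectory: none
  frames3 <- lapply(0:3, function(t) make_pair(FALSE, t))
  expect_false(detect_rupture(frames3, topo)$ruptured)
  expect_error(detect_rupture(frames3[1:2], topo, persistence = 3),
               "persistence")
})

test_that("constructed rupture trajectory is detected at the built time", {
  spec <- morphology_spec(outer_radius = 9, thickness = 5, n_chains = 600,
                          seed = 11)
  traj <- make_rupture_trajectory(spec, rupture_strain = 6, strain_rate = 1,
                                  n_frames = 10, dt = 1)
  det <- detect_rupture(traj$frames, traj$topology)
  expect_true(det$ruptured)
  expect_equal(det$time, 7)
  fc <- flow_context(shear_rate = 1, tau = 6)
  cs <- critical_strain(det, fc)
  expect_equal(cs$gamma_c, 7)
})

test_that("critical strain is the strain at rupture, or absent", {
  fc <- flow_context(shear_rate = 2, tau = 6)
  expect_equal(critical_strain(3, fc)$gamma_c, 6)
  none <- tibble::tibble(ruptured = FALSE, time = NA_real_)
  expect_true(is.na(critical_strain(none, fc)$gamma_c))
})

test_that("the critical-strain law is recovered exactly from noiseless points", {
  wi <- c(10.2, 12, 15, 18, 24, 30)
  gc <- 8.52 + (62 - 8.52) * exp(-0.548 * (wi - 10.2))
  fit <- fit_critical_strain(data.frame(Wi = wi, gamma_c = gc))
  expect_equal(fit$alpha, 0.548, tolerance = 1e-4)
  expect_equal(fit$gamma_inf, 8.52, tolerance = 1e-4)
  expect_equal(fit$Wi_star, 10.2)
  expect_equal(fit$gamma_star, 62)
  # anchored: the curve passes exactly through (Wi*, gamma*)
  expect_equal(predict(fit, data.frame(Wi = 10.2)), 62, tolerance = 1e-9)
  # predictions decrease with Wi under the fitted law
  grid <- data.frame(Wi = seq(10.2, 30, length.out = 50))
  expect_true(all(diff(predict(fit, grid)) < 0))
})

test_that("noisy replicates recover the law parameters in aggregate", {
  wi <- c(10.2, 12, 15, 18, 24, 30)
  gc0 <- 8.52 + (62 - 8.52) * exp(-0.548 * (wi - 10.2))
  set.seed(7)
  ests <- t(replicate(100, {
    f <- fit_critical_strain(data.frame(Wi = wi, gamma_c = gc0 + rnorm(6)))
    c(alpha = f$alpha, gamma_inf = f$gamma_inf)
  }))
  expect_lt(abs(mean(ests[, "alpha"]) - 0.548) / 0.548, 0.2)
  expect_lt(abs(mean(ests[, "gamma_inf"]) - 8.52) / 8.52, 0.1)
})

test_that("misspecified and insufficient inputs are rejected", {
  up <- data.frame(Wi = c(10, 12, 15, 20), gamma_c = c(10, 20, 30, 45))
  expect_warning(fit_critical_strain(up), "misspecification")
  expect_error(fit_critical_strain(data.frame(Wi = c(1, 2, 3),
                                              gamma_c = c(3, 2, 1))),
               "insufficient")
  expect_error(fit_critical_strain(data.frame(Wi = c(1, 1, 2, 3),
                                              gamma_c = c(4, 3, 2, 1))),
               "distinct")
})

test_that("tidy and glance summarise the rupture fit", {
  wi <- c(10.2, 12, 15, 18, 24, 30)
  gc <- 8.52 + (62 - 8.52) * exp(-0.548 * (wi - 10.2))
  fit <- fit_critical_strain(data.frame(Wi = wi, gamma_c = gc + 0.1))
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "gamma_inf", "Wi_star", "gamma_star"))
  expect_true(all(td$fixed == c(FALSE, FALSE, TRUE, TRUE)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 6)
  expect_gte(gl$rss, 0)
})
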