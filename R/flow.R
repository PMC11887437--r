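#' Flow context: shear rate, relaxation time, Weissenberg number, strain
#'
#' Bookkeeping for homogeneous shear: the Weissenberg number is
#' `Wi = shear_rate * tau` (the ratio of the shape-fluctuation relaxation
#' time to the inverse shear rate) and the accumulated strain is
#' `gamma(t) = shear_rate * t`.
#'
#' @param shear_rate Shear rate in 1/ns (>= 0).
#' @param tau Equilibrium shape-fluctuation relaxation time in ns (> 0).
#' @return A `flow_context` list with elements `shear_rate`, `tau`, `Wi`
#'   and a function `strain(t)`.
#' @examples
#' fc <- flow_context(shear_rate = 2, tau = 6)
#' fc$Wi          # 12
#' fc$strain(3)   # 6
#' @export
flow_context <- function(shear_rate, tau) {
  if (shear_rate < 0) stop("`shear_rate` must be nonnegative", call. = FALSE)
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  structure(list(
    shear_rate = shear_rate, tau = tau, Wi = shear_rate * tau,
    strain = function(t) shear_rate * t
  ), class = "flow_context")
}

#' Relaxation time from the ellipticity autocorrelation function
#'
#' Computes the mean-subtracted, normalised autocorrelation function of a
#' stationary scalar series and fits a single exponential
#' `exp(-lag / tau)` by least squares with `ACF(0)` fixed to 1. The fit
#' uses lags up to the first lag at which the ACF drops below `fit_floor`
#' (default 0.1), restricting it to the resolvable exponential regime; if
#' the ACF never drops below the floor, all lags are used with a warning.
#'
#' @param series A [scalar_series()] (or a data frame with `time` and
#'   `value` columns, uniformly sampled).
#' @param fit_floor ACF level that ends the fitting window (default 0.1).
#' @return Tibble with columns `tau` (ns), `tau_se` (standard error, ns),
#'   `n_lags` (lags used) and `resolved` (`FALSE` when the fitted tau is
#'   below the sampling interval). The ACF itself is in attribute `acf`
#'   (tibble `lag_time`, `acf`).
#' @examples
#' s <- make_ellipticity_series(series_spec(n_steps = 5000, seed = 1))
#' acf_relaxation_time(s)$tau
#' @export
acf_relaxation_time <- function(series, fit_floor = 0.1) {
  x <- series$value
  times <- series$time
  if (length(x) < 100) stop("series too short: need >= 100 samples", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance (constant) series", call. = FALSE)
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stop("series must be uniformly sampled", call. = FALSE)
  }
  dt <- dts[1]
  lag_max <- min(length(x) - 1L, max(10L, floor(length(x) / 5)))
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  below <- which(ac < fit_floor)
  if (length(below)) {
    n_lags <- max(below[1] - 1L, 3L)
  } else {
    warning("ACF never drops below fit_floor; fitting over all lags",
            call. = FALSE)
    n_lags <- lag_max
  }
  lag_time <- (0:n_lags) * dt
  y <- ac[1:(n_lags + 1L)]
  ft <- fit_exp_acf(lag_time, y, n_obs = length(x))
  tau <- ft$tau
  tau_se <- ft$tau_se
  resolved <- tau >= dt
  if (!resolved) {
    warning(sprintf("fitted tau (%.3g ns) is below the sampling interval: unresolved",
                    tau), call. = FALSE)
  }
  out <- tibble::tibble(tau = tau, tau_se = tau_se, n_lags = n_lags,
                        resolved = resolved)
  attr(out, "acf") <- tibble::tibble(lag_time = (0:lag_max) * dt, acf = ac)
  out
}

# Fit exp(-lag/tau) to autocorrelation values with ACF(0) = 1 fixed.
# Iteratively reweighted least squares: weights are the inverse Bartlett
# variance of the sample ACF of an AR(1) process at the current tau, so
# long noisy lags do not dominate. Exact exponential input is recovered
# to solver precision.
fit_exp_acf <- function(lag_time, y, n_obs) {
  dt <- lag_time[2] - lag_time[1]
  start_tau <- {
    pos <- y > 0.05
    if (sum(pos) > 2) {
      fitl <- stats::lm(log(y[pos]) ~ 0 + lag_time[pos])
      max(dt / 10, -1 / stats::coef(fitl)[1])
    } else dt
  }
  tau <- start_tau
  fit <- NULL
  for (it in 1:3) {
    rho <- exp(-dt / max(tau, dt / 100))
    k <- seq_along(y) - 1L
    r2k <- rho^(2 * k)
    v <- ((1 - r2k) * (1 + rho^2) / (1 - rho^2) - 2 * k * r2k) / n_obs
    v[1] <- if (any(v > 0)) min(v[v > 0]) else 1 / n_obs
    w <- 1 / pmax(v, 1e-12)
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ exp(-lag_time / tau), start = list(tau = tau),
                   weights = w,
                   control = stats::nls.control(warnOnly = TRUE))
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) break
    tau <- stats::coef(fit)[["tau"]]
  }
  if (is.null(fit)) {
    opt <- stats::optimize(function(tau) sum((y - exp(-lag_time / tau))^2),
                           interval = c(dt / 100, max(lag_time) * 10))
    return(list(tau = opt$minimum, tau_se = NA_real_))
  }
  list(
    tau = tau,
    tau_se = tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                      error = function(e) NA_real_)
  )
}

#' Detect vesicle rupture along a trajectory
#'
#' The vesicle counts as ruptured at the first frame where the
#' largest-cluster chain fraction drops below `fraction_threshold` and
#' stays below it for `persistence` consecutive frames (so a one-frame
#' transient neck-thinning dip is not labelled rupture).
#'
#' @param frames List of [bead_frame()] objects in time order.
#' @param topology A [chain_topology()].
#' @param cutoff Clustering cutoff in nm (default 0.5).
#' @param fraction_threshold Largest-cluster chain fraction below which a
#'   frame counts as broken (default 0.9).
#' @param persistence Consecutive broken frames required (default 3); the
#'   trailing frames of the trajectory may satisfy it by running out.
#' @param periodic Passed to [find_clusters()].
#' @return Tibble with columns `ruptured` (logical), `time` (ns, `NA` if
#'   intact) and attribute `fractions` (per-frame tibble `time`,
#'   `fraction`, `n_clusters`).
#' @export
detect_rupture <- function(frames, topology, cutoff = 0.5,
                           fraction_threshold = 0.9, persistence = 3,
                           periodic = FALSE) {
  if (length(frames) < persistence) {
    stop("need at least `persistence` frames", call. = FALSE)
  }
  per <- purrr::map_dfr(frames, function(fr) {
    cl <- find_clusters(fr, topology, cutoff = cutoff, periodic = periodic)
    tibble::tibble(
      time = frame_time(fr),
      fraction = largest_cluster_fraction(cl),
      n_clusters = length(cluster_sizes(cl))
    )
  })
  broken <- per$fraction < fraction_threshold
  rupture_time <- NA_real_
  n <- length(broken)
  for (i in seq_len(n)) {
    if (!broken[i]) next
    window <- broken[i:min(n, i + persistence - 1L)]
    if (all(window)) { rupture_time <- per$time[i]; break }
  }
  out <- tibble::tibble(ruptured = !is.na(rupture_time), time = rupture_time)
  attr(out, "fractions") <- per
  out
}

#' Critical strain of a rupture event
#'
#' `gamma_c = shear_rate * t_rupture`; `NA` when no rupture was detected
#' (for Weissenberg numbers below the rupture threshold the vesicle
#' tank-treads indefinitely).
#'
#' @param rupture Result of [detect_rupture()] (or a rupture time in ns).
#' @param context A [flow_context()].
#' @return Tibble with columns `Wi`, `gamma_c`, `time`.
#' @export
critical_strain <- function(rupture, context) {
  stopifnot(inherits(context, "flow_context"))
  t_r <- if (is.data.frame(rupture)) rupture$time[1] else as.numeric(rupture)
  tibble::tibble(
    Wi = context$Wi,
    gamma_c = if (is.na(t_r)) NA_real_ else context$strain(t_r),
    time = t_r
  )
}

#' Fit the critical-strain-versus-Weissenberg-number law
#'
#' Fits `gamma_c(Wi) = gamma_inf + (gamma_star - gamma_inf) *
#' exp(-alpha * (Wi - Wi_star))` to observed rupture points. `Wi_star` and
#' `gamma_star` are anchored to the smallest-Wi rupturing point (the
#' rupture threshold), so the curve passes through it exactly; `alpha` and
#' `gamma_inf` are estimated by least squares. A fit with `alpha <= 0`
#' (critical strain increasing with Wi) is rejected as misspecified.
#'
#' @param points Data frame with columns `Wi` and `gamma_c` (rupturing
#'   runs only, >= 4 distinct points).
#' @return A `rupture_fit` object; see [tidy.rupture_fit()] and
#'   [glance.rupture_fit()].
#' @examples
#' wi <- c(10.2, 12, 15, 18, 24, 30)
#' gc <- 8.52 + (62 - 8.52) * exp(-0.548 * (wi - 10.2))
#' fit <- fit_critical_strain(data.frame(Wi = wi, gamma_c = gc))
#' tidy(fit)
#' @export
fit_critical_strain <- function(points) {
  pts <- tibble::as_tibble(points)[, c("Wi", "gamma_c")]
  pts <- pts[stats::complete.cases(pts), ]
  if (nrow(pts) < 4L) {
    stop("insufficient data: need >= 4 rupture points", call. = FALSE)
  }
  if (anyDuplicated(pts$Wi)) {
    stop("`Wi` values must be distinct", call. = FALSE)
  }
  pts <- pts[order(pts$Wi), ]
  Wi_star <- pts$Wi[1]
  gamma_star <- pts$gamma_c[1]
  dWi <- pts$Wi - Wi_star
  y <- pts$gamma_c
  model <- function(alpha, gamma_inf) {
    gamma_inf + (gamma_star - gamma_inf) * exp(-alpha * dWi)
  }
  fit <- NULL
  last_err <- NULL
  for (a0 in c(0.5, 0.05, -0.5, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ gamma_inf + (gamma_star - gamma_inf) * exp(-alpha * dWi),
        start = list(alpha = a0, gamma_inf = max(1e-3, min(y) * 0.9)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("fit error: ", last_err, call. = FALSE)
  }
  co <- stats::coef(fit)
  alpha <- co[["alpha"]]; gamma_inf <- co[["gamma_inf"]]
  if (alpha <= 0) {
    warning("model misspecification: fitted alpha <= 0 ",
            "(critical strain not decreasing in Wi)", call. = FALSE)
  }
  resid <- y - model(alpha, gamma_inf)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(alpha = NA_real_, gamma_inf = NA_real_))
  structure(list(
    alpha = alpha, gamma_inf = gamma_inf,
    Wi_star = Wi_star, gamma_star = gamma_star,
    residuals = resid, points = pts, se = se, fit = fit
  ), class = "rupture_fit")
}

#' @export
print.rupture_fit <- function(x, ...) {
  cat("Critical-strain law: gamma_c = gamma_inf + (gamma* - gamma_inf)",
      "exp(-alpha (Wi - Wi*))\n")
  cat(sprintf("  alpha     = %.4g\n  gamma_inf = %.4g\n", x$alpha, x$gamma_inf))
  cat(sprintf("  anchored at Wi* = %.4g, gamma* = %.4g (%d points)\n",
              x$Wi_star, x$gamma_star, nrow(x$points)))
  invisible(x)
}

#' Tidy a fitted critical-strain law
#'
#' @param x A `rupture_fit` from [fit_critical_strain()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`,
#'   `fixed` (TRUE for the anchored threshold point).
#' @export
tidy.rupture_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "gamma_inf", "Wi_star", "gamma_star"),
    estimate = c(x$alpha, x$gamma_inf, x$Wi_star, x$gamma_star),
    std.error = c(unname(x$se["alpha"]), unname(x$se["gamma_inf"]),
                  NA_real_, NA_real_),
    fixed = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' @rdname tidy.rupture_fit
#' @return `glance`: a one-row tibble with `sigma` (residual standard
#'   deviation), `rss`, `nobs`.
#' @export
glance.rupture_fit <- function(x, ...) {
  n <- length(x$residuals)
  tibble::tibble(
    sigma = sqrt(sum(x$residuals^2) / max(1, n - 2)),
    rss = sum(x$residuals^2),
    nobs = n
  )
}

#' Predict from a fitted critical-strain law
#'
#' @param object A `rupture_fit`.
#' @param newdata Data frame with a `Wi` column (default: the fitted
#'   points).
#' @param ... Unused.
#' @return Numeric vector of predicted critical strains.
#' @export
predict.rupture_fit <- function(object, newdata = NULL, ...) {
  Wi <- if (is.null(newdata)) object$points$Wi else newdata$Wi
  object$gamma_inf + (object$gamma_star - object$gamma_inf) *
    exp(-object$alpha * (Wi - object$Wi_star))
}
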