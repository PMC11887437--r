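#' Specify a synthetic vesicle morphology
#'
#' Parameter bundle for [make_vesicle()] and [make_rupture_trajectory()].
#' Defaults describe the equilibrium system the analysis targets: a
#' spherical bilayer vesicle of 16 nm outer radius with a 5 nm wall
#' (an ~11 nm water core) built from 3871 BAB triblock chains in hairpin
#' configuration.
#'
#' @param geometry `"sphere"`, `"ellipsoid"`, `"dumbbell"` or
#'   `"fragments"`.
#' @param outer_radius Outer radius in nm (sphere, and fragment scale).
#' @param semi_axes Length-3 outer semi-axes in nm (ellipsoid).
#' @param thickness Membrane thickness in nm: a single number or a
#'   function of the polar angle from the +x axis (radians) returning nm,
#'   for contour-varying membranes.
#' @param n_chains Number of 20-bead B5-A10-B5 chains (default 3871).
#' @param stretched_fraction Fraction of chains placed as quasilinear
#'   chains spanning the membrane tangentially instead of hairpins.
#' @param stretched_region `"anywhere"` (default) or `"neck"`: restrict
#'   stretched chains to the mid-contour band (|cos psi| < 0.35).
#' @param core_solvated Fill the enclosed core with solvent beads on a
#'   cubic lattice.
#' @param exterior_solvated Also fill the box outside the vesicle.
#' @param solvent_density Lattice solvent density in beads/nm^3
#'   (default 8.4).
#' @param end_radius,centre_sep,neck_radius Dumbbell parameters (nm): the
#'   radius of the two spherical ends, the half-separation of their
#'   centres, and the waist radius of the catenoid-like neck bridging
#'   them.
#' @param fragment_chains Integer vector of chains per fragment
#'   (geometry `"fragments"`); must sum to `n_chains`.
#' @param fragment_gap Surface-to-surface gap between fragments in nm
#'   (default 5).
#' @param box Length-3 box edge lengths in nm; sized to the structure plus
#'   a margin when `NULL`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `morphology_spec` list.
#' @export
morphology_spec <- function(geometry = c("sphere", "ellipsoid", "dumbbell",
                                         "fragments"),
                            outer_radius = 16, semi_axes = NULL,
                            thickness = 5, n_chains = 3871,
                            stretched_fraction = 0,
                            stretched_region = c("anywhere", "neck"),
                            core_solvated = FALSE, exterior_solvated = FALSE,
                            solvent_density = 8.4,
                            end_radius = 8, centre_sep = 12, neck_radius = 2.5,
                            fragment_chains = NULL, fragment_gap = 5,
                            box = NULL, seed = 1) {
  geometry <- match.arg(geometry)
  stretched_region <- match.arg(stretched_region)
  if (n_chains < 1) stop("`n_chains` must be positive", call. = FALSE)
  if (stretched_fraction < 0 || stretched_fraction > 1) {
    stop("`stretched_fraction` must lie in [0, 1]", call. = FALSE)
  }
  h_fun <- if (is.function(thickness)) thickness else function(psi) {
    rep(thickness, length(psi))
  }
  psi_probe <- seq(0, pi, length.out = 33)
  h_probe <- h_fun(psi_probe)
  # local radius scale along the contour, per geometry
  r_local <- switch(geometry,
    sphere = rep(outer_radius, 33),
    ellipsoid = {
      ax <- semi_axes %||% rep(outer_radius, 3)
      bc <- sqrt((ax[2]^2 + ax[3]^2) / 2)
      1 / sqrt((cos(psi_probe) / ax[1])^2 + (sin(psi_probe) / bc)^2)
    },
    dumbbell = end_radius + (neck_radius - end_radius) *
      sin(psi_probe)^2,   # ends ~ end_radius, waist ~ neck_radius
    fragments = rep(Inf, 33)
  )
  if (geometry != "fragments" && any(h_probe >= 2 * r_local)) {
    stop("membrane thickness must be smaller than the local radius",
         call. = FALSE)
  }
  if (any(h_probe < 2)) {
    stop("membrane thickness below 2 nm cannot hold a hairpin leaflet",
         call. = FALSE)
  }
  structure(list(
    geometry = geometry, outer_radius = outer_radius, semi_axes = semi_axes,
    thickness = h_fun, n_chains = as.integer(n_chains),
    stretched_fraction = stretched_fraction,
    stretched_region = stretched_region,
    core_solvated = core_solvated, exterior_solvated = exterior_solvated,
    solvent_density = solvent_density,
    end_radius = end_radius, centre_sep = centre_sep,
    neck_radius = neck_radius,
    fragment_chains = fragment_chains, fragment_gap = fragment_gap,
    box = box, seed = as.integer(seed)
  ), class = "morphology_spec")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# geometric constants of the coarse-grained chain model
bond_len <- function() 0.47        # bead spacing, nm
arm_gap <- function() 0.47         # hairpin arm separation, nm
arm_stagger <- function() 0.87     # longitudinal arm offset -> Q ~ 1 nm

#' Generate a bead-resolution vesicle
#'
#' Builds a synthetic snapshot with the statistical structure the analysis
#' stages assume. Chain anchors run along an equal-area spiral over the
#' outer surface, leaflets alternating slot by slot, so that the deep arm
#' ends of consecutive outer/inner hairpins meet at mid-membrane and the
#' whole membrane is one connected aggregate under the 0.5 nm clustering
#' cutoff. Each hairpin stands normal to the local surface: the two
#' hydrophobic arms fold side by side (0.47 nm apart, 0.47 nm bead
#' spacing, a 0.87 nm longitudinal stagger, giving an end-to-end distance
#' of ~1 nm), with the hydrophilic loop at the inner or outer interface.
#' A `stretched_fraction` of chains is instead laid out as quasilinear
#' 20-bead chains spanning the membrane tangentially (~8.9 nm long).
#' Hairpin arms are compressed radially where the local leaflet
#' (half-membrane) is thinner than their natural span. Optionally the
#' core (and exterior) is filled with solvent beads on a cubic lattice.
#'
#' @param spec A [morphology_spec()].
#' @return List with elements `frame` (a [bead_frame()]) and `topology`
#'   (a [chain_topology()]).
#' @examples
#' ves <- make_vesicle(morphology_spec(n_chains = 500, seed = 7))
#' nrow(ves$frame)   # 10000 beads
#' @export
make_vesicle <- function(spec) {
  stopifnot(inherits(spec, "morphology_spec"))
  with_seed(spec$seed, build_vesicle(spec))
}

build_vesicle <- function(spec) {
  if (spec$geometry == "fragments") return(build_fragments(spec))
  surf <- surface_model(spec)
  n <- spec$n_chains
  # packing feasibility: spiral rows closer than the 0.5 nm minimum
  # spacing mean the chain count exceeds the surface capacity
  row_gap <- surf$area / (n * spiral_step())
  if (row_gap < 0.5) {
    stop(sprintf(
      "packing error: %d chains exceed surface capacity (row gap %.2f nm < 0.5 nm)",
      n, row_gap
    ), call. = FALSE)
  }
  anchors <- anchor_spiral(surf, n)
  h <- spec$thickness(anchors$psi)
  stretched <- pick_stretched(spec, anchors, n)
  leaflet <- rep(c("outer", "inner"), length.out = n)
  pos <- matrix(0, nrow = 20L * n, ncol = 3)
  for (i in seq_len(n)) {
    p_out <- anchors$points[i, ]
    nrm <- anchors$normals[i, ]
    v <- anchors$tangents[i, ]
    rows <- ((i - 1L) * 20L + 1L):(i * 20L)
    if (stretched[i]) {
      centre <- p_out - (h[i] / 2) * nrm
      pos[rows, ] <- stretched_chain(centre, v)
    } else if (leaflet[i] == "outer") {
      pos[rows, ] <- hairpin_chain(p_out, -nrm, v, h[i] / 2)
    } else {
      p_in <- p_out - h[i] * nrm
      pos[rows, ] <- hairpin_chain(p_in, nrm, v, h[i] / 2)
    }
  }
  topo <- chain_topology(n)
  types <- rep(chain_bead_pattern(), n)
  extent <- max(abs(pos)) + 4
  box <- spec$box %||% rep(2 * extent, 3)
  centre <- box / 2
  pos <- sweep(pos, 2, centre, `+`)
  if (spec$core_solvated || spec$exterior_solvated) {
    sol <- solvent_lattice(spec, surf, box, centre)
    pos <- rbind(pos, sol)
    types <- c(types, rep("W", nrow(sol)))
  }
  list(frame = bead_frame(pos, types, box, time = 0), topology = topo)
}

pick_stretched <- function(spec, anchors, n) {
  k <- round(spec$stretched_fraction * n)
  stretched <- rep(FALSE, n)
  if (k == 0) return(stretched)
  cand <- if (spec$stretched_region == "neck") {
    # mid-contour band: by axial position for waisted shapes, by polar
    # angle otherwise
    if (spec$geometry == "dumbbell") {
      which(abs(anchors$points[, 1]) < 0.75 * spec$centre_sep)
    } else {
      which(abs(cos(anchors$psi)) < 0.35)
    }
  } else {
    seq_len(n)
  }
  if (length(cand) < k) {
    stop("packing error: not enough chains in the stretched region", call. = FALSE)
  }
  stretched[sample(cand, k)] <- TRUE
  stretched
}

# Hairpin: loop apex at `apex` (the interface), arms running into the
# membrane along unit vector `u`; arm 2 is offset 0.47 nm tangentially and
# reaches to just short of mid-membrane so that opposing leaflets meet
# there (the longitudinal stagger also sets the ~1 nm end-to-end
# distance). Beads 1..10 = arm 1 (deep B end to loop), 11..20 = arm 2
# (loop to deep B end).
hairpin_chain <- function(apex, u, v, leaflet_depth) {
  d_arm <- max(0.3, min(9 * bond_len() / 2,
                        leaflet_depth - arm_stagger() - 0.05))
  # arm 2 ends 0.05 nm short of mid-membrane, capped so its bead spacing
  # stays below the clustering cutoff
  d_arm2 <- max(d_arm + 0.3, min(leaflet_depth - 0.05, 9 * 0.495))
  arm1 <- t(vapply(1:10, function(j) apex + (10 - j) / 9 * d_arm * u,
                   numeric(3)))
  arm2 <- t(vapply(11:20, function(j) {
    apex + (j - 11) / 9 * d_arm2 * u + arm_gap() * v
  }, numeric(3)))
  rbind(arm1, arm2)
}

stretched_chain <- function(centre, v) {
  offs <- (seq_len(20) - 10.5) * bond_len()
  centre_mat <- matrix(centre, nrow = 20, ncol = 3, byrow = TRUE)
  centre_mat + outer(offs, v)
}

# --- surface models. Each model describes a star-shaped outer surface
# (about the origin, symmetric enough about the x axis for the anchor
# spiral): radius_profile(theta) gives the outer radius along a direction
# at polar angle theta from +x (azimuth 0); radius_at(dirs) the same for
# arbitrary unit directions; normal_at(points) outward unit normals.

surface_model <- function(spec) {
  switch(spec$geometry,
    sphere = surf_sphere(spec$outer_radius),
    ellipsoid = surf_ellipsoid(spec$semi_axes %||%
                                 rep(spec$outer_radius, 3)),
    dumbbell = surf_dumbbell(spec$end_radius, spec$centre_sep,
                             spec$neck_radius),
    stop("no surface model for geometry ", spec$geometry, call. = FALSE)
  )
}

spiral_step <- function() 0.42     # anchor spacing along the spiral, nm

# Anchors along an equal-area spiral around the +x axis: polar angles from
# the cumulative-area inverse CDF of the surface of revolution, azimuth
# advancing by ~spiral_step of arc per anchor (random phase). Consecutive
# anchors are near neighbours on the surface, which makes the assembled
# membrane one connected aggregate under the 0.5 nm cutoff: the deep arm
# ends of consecutive outer/inner-leaflet hairpins meet at mid-membrane.
anchor_spiral <- function(surf, n, step = spiral_step()) {
  mx <- surf$meridian$x          # meridian polyline, +x tip to -x tip
  mr <- surf$meridian$rho
  dxs <- diff(mx); drs <- diff(mr)
  ds <- sqrt(dxs^2 + drs^2)
  rho_mid <- (mr[-1] + mr[-length(mr)]) / 2
  dA <- 2 * pi * rho_mid * ds
  cdf <- c(0, cumsum(dA))
  arc <- c(0, cumsum(ds))
  t_i <- (seq_len(n) - 0.5) / n * cdf[length(cdf)]
  s_i <- stats::approx(cdf, arc, xout = t_i, ties = "ordered")$y
  x_i <- stats::approx(arc, mx, xout = s_i)$y
  rho_i <- pmax(stats::approx(arc, mr, xout = s_i)$y, 1e-6)
  # meridian tangent (at segment midpoints) -> outward normal of the
  # surface of revolution: N = (d rho / ds, -d x / ds)
  arc_mid <- (arc[-1] + arc[-length(arc)]) / 2
  tx <- stats::approx(arc_mid, dxs / ds, xout = s_i, rule = 2)$y
  tr <- stats::approx(arc_mid, drs / ds, xout = s_i, rule = 2)$y
  nn <- sqrt(tx^2 + tr^2)
  n_x <- tr / nn; n_rho <- -tx / nn
  phi <- stats::runif(1, 0, 2 * pi) + cumsum(step / pmax(rho_i, step / 2))
  points <- cbind(x_i, rho_i * cos(phi), rho_i * sin(phi))
  normals <- cbind(n_x, n_rho * cos(phi), n_rho * sin(phi))
  # azimuthal unit vector: the spiral's local direction of travel
  tangents <- cbind(0, -sin(phi), cos(phi))
  psi <- acos(pmin(1, pmax(-1, x_i / sqrt(x_i^2 + rho_i^2))))
  list(points = points, normals = normals, tangents = tangents, psi = psi)
}

surf_sphere <- function(R) {
  th <- seq(0, pi, length.out = 2048)
  list(
    area = 4 * pi * R^2,
    meridian = list(x = R * cos(th), rho = R * sin(th)),
    radius_profile = function(theta) rep(R, length(theta)),
    radius_at = function(dirs) rep(R, nrow(dirs)),
    normal_at = function(points) points / sqrt(rowSums(points^2))
  )
}

surf_ellipsoid <- function(axes) {
  a <- axes[1]; b <- axes[2]; c_ <- axes[3]
  # Knud Thomsen approximation for the area (p = 1.6075)
  p <- 1.6075
  area <- 4 * pi * ((a^p * b^p + a^p * c_^p + b^p * c_^p) / 3)^(1 / p)
  th <- seq(0, pi, length.out = 2048)
  bc_m <- sqrt((b^2 + c_^2) / 2)
  list(
    area = area,
    meridian = list(x = a * cos(th), rho = bc_m * sin(th)),
    radius_profile = function(theta) {
      bc <- sqrt((b^2 + c_^2) / 2)   # mean transverse axis for the spiral
      1 / sqrt((cos(theta) / a)^2 + (sin(theta) / bc)^2)
    },
    radius_at = function(dirs) {
      1 / sqrt((dirs[, 1] / a)^2 + (dirs[, 2] / b)^2 + (dirs[, 3] / c_)^2)
    },
    normal_at = function(points) {
      nrm <- cbind(points[, 1] / a^2, points[, 2] / b^2, points[, 3] / c_^2)
      nrm / sqrt(rowSums(nrm^2))
    }
  )
}

# Dumbbell: two spheres of radius `a` centred at (+/-c, 0, 0) bridged by a
# catenoid-like neck rho(x) = r_n cosh(x / lambda) with rho(+/-c) = a;
# star-shaped about the origin for sensible parameters.
surf_dumbbell <- function(a, c_, r_n) {
  lambda <- c_ / acosh(a / r_n)
  raw_profile <- function(x) {
    s1 <- ifelse(abs(x - c_) <= a, sqrt(pmax(0, a^2 - (x - c_)^2)), 0)
    s2 <- ifelse(abs(x + c_) <= a, sqrt(pmax(0, a^2 - (x + c_)^2)), 0)
    nk <- ifelse(abs(x) <= c_, r_n * cosh(pmin(abs(x), c_) / lambda), 0)
    pmax(s1, s2, nk)
  }
  x_max <- c_ + a
  xg <- seq(-x_max, x_max, length.out = 2048)
  dx <- xg[2] - xg[1]
  # Gaussian-smooth the union profile (sigma ~0.7 nm): the sphere/neck
  # junction would otherwise be a crease where surface normals jump and
  # the two leaflet shells lose contact
  half <- ceiling(3 * 0.7 / dx)
  kern <- stats::dnorm(seq(-half, half) * dx, sd = 0.7)
  kern <- kern / sum(kern)
  rho_pad <- c(rep(0, half), raw_profile(xg), rep(0, half))
  rho_s <- pmax(stats::filter(rho_pad, kern, sides = 2)[(half + 1):(half + length(xg))],
                0.05)
  pfun <- stats::splinefun(xg, rho_s, method = "natural")
  profile_x <- function(x) {
    pmax(pfun(pmin(pmax(x, -x_max), x_max)), 0.05)
  }
  dprofile_x <- function(x) {
    pfun(pmin(pmax(x, -x_max), x_max), deriv = 1)
  }
  radius_profile <- function(theta) {
    ct <- cos(theta); st <- sin(theta)
    lo <- rep(0, length(theta)); hi <- rep(x_max + 0.5, length(theta))
    for (k in 1:48) {       # the origin is inside; outer crossing is unique
      mid <- (lo + hi) / 2
      x <- mid * ct; y <- mid * st
      ins <- abs(x) < x_max & y < profile_x(x)
      lo <- ifelse(ins, mid, lo)
      hi <- ifelse(ins, hi, mid)
    }
    (lo + hi) / 2
  }
  drho <- dprofile_x(xg)
  area <- sum(2 * pi * rho_s * sqrt(1 + drho^2)) * dx
  list(
    area = area,
    meridian = list(x = rev(xg), rho = rev(as.numeric(rho_s))),
    radius_profile = radius_profile,
    radius_at = function(dirs) {
      radius_profile(acos(pmin(1, pmax(-1, dirs[, 1]))))
    },
    normal_at = function(points) {
      dr <- dprofile_x(points[, 1])
      rho_p <- pmax(sqrt(points[, 2]^2 + points[, 3]^2), 1e-9)
      nr <- 1 / sqrt(1 + dr^2)
      cbind(-dr * nr, nr * points[, 2] / rho_p, nr * points[, 3] / rho_p)
    }
  )
}

build_fragments <- function(spec) {
  counts <- spec$fragment_chains %||%
    stop("geometry 'fragments' needs `fragment_chains`", call. = FALSE)
  counts <- as.integer(counts)
  if (sum(counts) != spec$n_chains) {
    stop("`fragment_chains` must sum to `n_chains`", call. = FALSE)
  }
  # fragment radius scaled so surface area tracks chain count
  ref_area_per_chain <- 4 * pi * spec$outer_radius^2 / spec$n_chains
  radii <- sqrt(counts * ref_area_per_chain / (4 * pi))
  h <- spec$thickness(0)
  radii <- pmax(radii, h / 2 + 1.5)
  centres_x <- cumsum(c(0, radii[-1] + radii[-length(radii)] +
                          spec$fragment_gap))
  pieces <- vector("list", length(counts))
  for (k in seq_along(counts)) {
    sub <- morphology_spec(
      geometry = "sphere", outer_radius = radii[k],
      thickness = min(h, 2 * radii[k] - 2.2),
      n_chains = counts[k], stretched_fraction = 0,
      seed = spec$seed + k
    )
    pieces[[k]] <- build_vesicle(sub)
  }
  # assemble: recentre each fragment on its x offset
  pos <- list(); types <- list()
  for (k in seq_along(pieces)) {
    fr <- pieces[[k]]$frame
    p <- frame_positions(fr)
    p <- sweep(p, 2, centre_of_mass(p))
    p[, 1] <- p[, 1] + centres_x[k]
    pos[[k]] <- p
    types[[k]] <- fr$type
  }
  pos <- do.call(rbind, pos)
  types <- unlist(types)
  extent <- apply(pos, 2, function(v) diff(range(v)))
  box <- spec$box %||% (extent + 10)
  pos <- sweep(pos, 2, apply(pos, 2, min) - 5, `-`)
  list(frame = bead_frame(pos, types, box, time = 0),
       topology = chain_topology(sum(counts)))
}

solvent_lattice <- function(spec, surf, box, centre) {
  spacing <- spec$solvent_density^(-1 / 3)
  gx <- seq(spacing / 2, box[1] - spacing / 2, by = spacing)
  gy <- seq(spacing / 2, box[2] - spacing / 2, by = spacing)
  gz <- seq(spacing / 2, box[3] - spacing / 2, by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  rel <- sweep(pts, 2, centre)
  r <- sqrt(rowSums(rel^2))
  r[r < 1e-9] <- 1e-9
  dirs <- rel / r
  r_out <- surf$radius_at(dirs)
  psi <- acos(pmin(1, pmax(-1, dirs[, 1])))
  h <- spec$thickness(psi)
  keep <- rep(FALSE, nrow(pts))
  if (spec$core_solvated) keep <- keep | (r < r_out - h - 0.5)
  if (spec$exterior_solvated) keep <- keep | (r > r_out + 0.5)
  pts[keep, , drop = FALSE]
}

#' Specify a synthetic ellipticity time series
#'
#' @param mean Stationary mean of the series (dimensionless).
#' @param correlation_time Exponential correlation time in ns.
#' @param noise_sd Stationary standard deviation.
#' @param dt Sampling interval in ns.
#' @param n_steps Number of samples.
#' @param seed Integer seed.
#' @return A `series_spec` list.
#' @export
series_spec <- function(mean = 0.05, correlation_time = 6, noise_sd = 0.01,
                        dt = 0.05, n_steps = 50000, seed = 1) {
  if (correlation_time <= 0) stop("`correlation_time` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  structure(list(
    mean = mean, correlation_time = correlation_time, noise_sd = noise_sd,
    dt = dt, n_steps = as.integer(n_steps), seed = as.integer(seed)
  ), class = "series_spec")
}

#' Generate a stationary ellipticity fluctuation series
#'
#' First-order autoregressive (AR(1), the discretised Ornstein-Uhlenbeck)
#' series whose population autocorrelation is
#' `exp(-lag * dt / correlation_time)`, emulating the equilibrium shape
#' fluctuations whose relaxation time defines the Weissenberg number. The
#' first sample is drawn from the stationary distribution.
#'
#' @param spec A [series_spec()].
#' @return A [scalar_series()] labelled `"E"`.
#' @examples
#' s <- make_ellipticity_series(series_spec(n_steps = 2000, seed = 2))
#' acf_relaxation_time(s)$tau
#' @export
make_ellipticity_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  if (spec$dt >= spec$correlation_time) {
    warning("dt >= correlation_time: the ACF is undersampled", call. = FALSE)
  }
  with_seed(spec$seed, {
    phi <- exp(-spec$dt / spec$correlation_time)
    n <- spec$n_steps
    x <- numeric(n)
    if (spec$noise_sd == 0) {
      x[] <- spec$mean
    } else {
      innov_sd <- spec$noise_sd * sqrt(1 - phi^2)
      x[1] <- spec$mean + stats::rnorm(1, 0, spec$noise_sd)
      eps <- stats::rnorm(n - 1, 0, innov_sd)
      for (t in 2:n) x[t] <- spec$mean + phi * (x[t - 1] - spec$mean) + eps[t - 1]
    }
    scalar_series((seq_len(n) - 1L) * spec$dt, x, label = "E")
  })
}

#' Generate a rupture trajectory
#'
#' Frame sequence that interpolates sphere, ellipsoid and dumbbell shapes
#' with a thinning midsection as the strain `gamma = strain_rate * t`
#' grows, then splits the structure into two disjoint aggregates
#' (separated by more than the 0.5 nm clustering cutoff) at the first
#' frame whose strain strictly exceeds `rupture_strain`. Bead count and
#' topology are constant across frames; no solvent is added.
#'
#' @param spec A [morphology_spec()] describing the intact (spherical)
#'   vesicle; `outer_radius`, `thickness` and `n_chains` are used.
#' @param rupture_strain Strain at which the vesicle breaks (> 0).
#' @param strain_rate Shear rate in 1/ns.
#' @param n_frames Number of frames (>= 3).
#' @param dt Frame spacing in ns (default 1).
#' @return List with `frames` (list of [bead_frame()]) and `topology`.
#' @export
make_rupture_trajectory <- function(spec, rupture_strain, strain_rate,
                                    n_frames, dt = 1) {
  stopifnot(inherits(spec, "morphology_spec"))
  if (rupture_strain <= 0) stop("`rupture_strain` must be positive", call. = FALSE)
  if (n_frames < 3) stop("need at least 3 frames", call. = FALSE)
  R <- spec$outer_radius
  h0 <- spec$thickness(0)[1]
  frames <- vector("list", n_frames)
  topo <- chain_topology(spec$n_chains)
  for (k in seq_len(n_frames)) {
    t_k <- (k - 1) * dt
    gamma <- strain_rate * t_k
    p <- min(gamma / rupture_strain, 1)
    fspec <- if (gamma > rupture_strain) {
      half <- spec$n_chains %/% 2L
      morphology_spec(
        geometry = "fragments", outer_radius = R, thickness = h0,
        n_chains = spec$n_chains,
        fragment_chains = c(spec$n_chains - half, half),
        fragment_gap = 4, seed = spec$seed + k
      )
    } else if (p < 0.45) {
      q <- p / 0.45
      stretch <- 1 + 1.2 * q
      morphology_spec(
        geometry = "ellipsoid",
        semi_axes = c(R * stretch, R / sqrt(stretch), R / sqrt(stretch)),
        thickness = h0, n_chains = spec$n_chains, seed = spec$seed + k
      )
    } else {
      q <- (p - 0.45) / 0.55
      h_neck <- max(2.05, h0 * (1 - 0.7 * q))
      h_fun <- local({
        hn <- h_neck; he <- h0
        function(psi) hn + (he - hn) * abs(cos(psi))^1.5
      })
      morphology_spec(
        geometry = "dumbbell", end_radius = 0.75 * R,
        centre_sep = R * (0.8 + 0.8 * q),
        neck_radius = max(2.2, R / 3 * (1 - 0.8 * q)),
        thickness = h_fun, n_chains = spec$n_chains,
        stretched_fraction = min(0.15, 0.05 + 0.1 * q),
        stretched_region = "neck", seed = spec$seed + k
      )
    }
    ves <- make_vesicle(fspec)
    fr <- ves$frame
    attr(fr, "time") <- t_k
    frames[[k]] <- fr
  }
  list(frames = frames, topology = topo)
}
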