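#' Gyration-tensor shape and orientation descriptors
#'
#' The gyration tensor is the mean outer product of the centre-of-mass
#' centred bead positions. Its eigenvalues `lambda1 >= lambda2 >= lambda3`
#' (nm^2) and principal axes give the ellipticity
#' `E = (lambda1 - lambda3) / (lambda1 + lambda3)` (0 for a sphere, toward
#' 1 for elongated or planar shapes) and the flow-orientation angles of the
#' major axis: `theta_V` is the angle between the x-y-plane projection of
#' the `lambda1` eigenvector and the x (flow) axis; `phi_V` the angle
#' between its x-z-plane projection and the z axis. Both are folded to
#' \[0, 90\] degrees because eigenvectors carry no sign.
#'
#' @param frame A [bead_frame()].
#' @param member_indices Bead indices to analyse (default: all copolymer
#'   beads). The structure must be whole (unwrapped).
#' @return A `shape_descriptor`: one-row tibble with columns `lambda1`,
#'   `lambda2`, `lambda3`, `rg` (radius of gyration, nm), `E`, `theta_V`,
#'   `phi_V`; principal axes (columns, descending eigenvalue) in attribute
#'   `axes`, centre of mass in attribute `com`.
#' @examples
#' sph <- 16 * fibonacci_shell(2000)
#' gyration_shape(bead_frame(sph, "B", box = c(40, 40, 40)))$E   # ~0
#' @export
gyration_shape <- function(frame, member_indices = copolymer_beads(frame)) {
  pos <- frame_positions(frame, member_indices)
  if (nrow(pos) < 4L) stop("need at least 4 beads for a shape", call. = FALSE)
  com <- centre_of_mass(pos)
  cen <- sweep(pos, 2, com)
  if (max(abs(cen)) < 1e-12) {
    stop("degenerate geometry: all beads coincident", call. = FALSE)
  }
  S <- crossprod(cen) / nrow(cen)          # mean outer product, nm^2
  eig <- eigen(S, symmetric = TRUE)        # eigenvalues descending
  lam <- pmax(eig$values, 0)
  v1 <- eig$vectors[, 1]
  E <- (lam[1] - lam[3]) / (lam[1] + lam[3])
  theta_V <- if (abs(v1[1]) < 1e-15 && abs(v1[2]) < 1e-15) NA_real_ else
    fold_angle_90(atan2(v1[2], v1[1]) * 180 / pi)
  phi_V <- if (abs(v1[1]) < 1e-15 && abs(v1[3]) < 1e-15) NA_real_ else
    fold_angle_90(atan2(v1[1], v1[3]) * 180 / pi)
  out <- tibble::tibble(
    lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
    rg = sqrt(sum(lam)), E = E, theta_V = theta_V, phi_V = phi_V
  )
  attr(out, "axes") <- eig$vectors
  attr(out, "com") <- com
  class(out) <- c("shape_descriptor", class(out))
  out
}

#' Quasi-uniform unit-sphere point set
#'
#' Deterministic golden-spiral lattice on the unit sphere; multiply by a
#' radius to get an isotropic shell. Exported because shell fixtures are
#' useful for validating shape descriptors.
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_shell <- function(n) fibonacci_sphere(n)

#' Enclosed volume and outer surface area of an aggregate
#'
#' Voxelises the member beads (a voxel is occupied when its centre lies
#' within `bead_radius + voxel/2` of a bead centre), seals sub-probe pores
#' by morphological closing with a ball of radius `closing_radius` voxels,
#' identifies the exterior by flood fill from the box boundary, and reports
#' `V` as the volume of all non-exterior voxels (membrane plus enclosed
#' solvent core) and `A` as the area of the exterior-facing surface,
#' evaluated as the gradient-magnitude integral of a Gaussian-smoothed
#' solid indicator (the co-area formula, which is free of the staircase
#' bias of raw voxel-face counting).
#'
#' If the structure is open (the flood fill reaches the centre of mass of
#' the member beads) a topology warning is raised and `V` falls back to the
#' volume of the occupied voxels only.
#'
#' @param frame A [bead_frame()].
#' @param member_indices Bead indices of one connected aggregate.
#' @param voxel Voxel edge length in nm (default 0.5).
#' @param bead_radius Bead hard-sphere radius in nm (default 0.264, half a
#'   regular coarse-grained bead diameter).
#' @param closing_radius Closing-ball radius in voxels (default 2).
#' @return Tibble with columns `V` (nm^3), `A` (nm^2), `nu` (reduced
#'   volume, see [reduced_volume()]) and `closed` (logical).
#' @export
enclosed_volume_area <- function(frame, member_indices = copolymer_beads(frame),
                                 voxel = 0.5, bead_radius = 0.264,
                                 closing_radius = 2L) {
  pos <- frame_positions(frame, member_indices)
  pad <- bead_radius + voxel * (closing_radius + 4)
  lo <- apply(pos, 2, min) - pad
  hi <- apply(pos, 2, max) + pad
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / voxel)))
  occ <- voxelise(pos, lo, voxel, dims, bead_radius + voxel / 2)
  closed <- close_mask(occ, closing_radius)
  exterior <- flood_exterior(!closed)
  solid <- !exterior
  # openness check: does the exterior reach the bead centroid?
  com <- centre_of_mass(pos)
  ci <- pmin(dims, pmax(1L, as.integer(floor((com - lo) / voxel)) + 1L))
  is_closed <- !exterior[ci[1], ci[2], ci[3]]
  if (!is_closed) {
    warning("open structure: flood fill reached the interior; ",
            "V is the occupied-voxel volume only", call. = FALSE)
    V <- sum(occ) * voxel^3
    A <- surface_area_coarea(occ, voxel)
  } else {
    V <- sum(solid) * voxel^3
    A <- surface_area_coarea(solid, voxel)
  }
  tibble::tibble(V = V, A = A, nu = reduced_volume(V, A)$nu, closed = is_closed)
}

# Occupancy grid: voxel centres within `radius` of any bead centre.
voxelise <- function(pos, lo, voxel, dims, radius) {
  occ <- array(FALSE, dims)
  rv <- ceiling(radius / voxel)
  off <- as.matrix(expand.grid(dx = -rv:rv, dy = -rv:rv, dz = -rv:rv))
  grid_idx <- floor(sweep(pos, 2, lo) / voxel) + 1L
  for (k in seq_len(nrow(off))) {
    cand <- sweep(grid_idx, 2, off[k, ], `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
          cand[, 2] >= 1 & cand[, 2] <= dims[2] &
          cand[, 3] >= 1 & cand[, 3] <= dims[3]
    if (!any(ok)) next
    ci <- cand[ok, , drop = FALSE]
    centres <- sweep((ci - 0.5) * voxel, 2, lo, `+`)
    d2 <- rowSums((centres - pos[ok, , drop = FALSE])^2)
    hit <- d2 <= radius^2
    if (any(hit)) occ[ci[hit, , drop = FALSE]] <- TRUE
  }
  occ
}

# Binary dilation by a ball of radius r voxels (shift-and-OR over the ball).
dilate_ball <- function(mask, r) {
  if (r < 1L) return(mask)
  dims <- dim(mask)
  out <- mask
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= r^2 + 1e-9, ]
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  for (k in seq_len(nrow(off))) {
    out <- out | shift_mask(mask, c(off$dx[k], off$dy[k], off$dz[k]))
  }
  out
}

close_mask <- function(mask, r) {
  if (r < 1L) return(mask)
  d <- dilate_ball(mask, r)
  !dilate_ball(!d, r)     # erosion = complement-dilate-complement
}

shift_mask <- function(mask, s) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (s[k] >= 0) {
      dst[[k]] <- (1 + s[k]):dims[k]; src[[k]] <- 1:(dims[k] - s[k])
    } else {
      dst[[k]] <- 1:(dims[k] + s[k]); src[[k]] <- (1 - s[k]):dims[k]
    }
    if (abs(s[k]) >= dims[k]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

# Flood fill of `open` voxels (TRUE = passable) from all box faces;
# 6-connected breadth-first frontier expansion on linear indices.
flood_exterior <- function(open) {
  dims <- dim(open)
  n <- prod(dims)
  sx <- 1L; sy <- dims[1]; sz <- dims[1] * dims[2]
  idx <- array(seq_len(n), dims)
  seeds <- unique(c(
    idx[c(1, dims[1]), , ], idx[, c(1, dims[2]), ], idx[, , c(1, dims[3])]
  ))
  visited <- logical(n)
  frontier <- seeds[open[seeds]]
  visited[frontier] <- TRUE
  ix <- ((seq_len(n) - 1L) %% dims[1]) + 1L
  iy <- (((seq_len(n) - 1L) %/% dims[1]) %% dims[2]) + 1L
  iz <- ((seq_len(n) - 1L) %/% (dims[1] * dims[2])) + 1L
  while (length(frontier)) {
    nb <- c(
      frontier[ix[frontier] > 1L] - sx,
      frontier[ix[frontier] < dims[1]] + sx,
      frontier[iy[frontier] > 1L] - sy,
      frontier[iy[frontier] < dims[2]] + sy,
      frontier[iz[frontier] > 1L] - sz,
      frontier[iz[frontier] < dims[3]] + sz
    )
    nb <- unique(nb[!visited[nb] & open[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  array(visited, dims)
}

# Surface area of a binary mask via the co-area formula: smooth the
# indicator with a separable Gaussian and integrate |grad|.
surface_area_coarea <- function(mask, voxel, sigma_vox = 1.2) {
  u <- array(as.numeric(mask), dim(mask))
  half <- max(2L, ceiling(3 * sigma_vox))
  kx <- stats::dnorm(-half:half, sd = sigma_vox)
  kx <- kx / sum(kx)
  u <- convolve_axis(u, kx, 1)
  u <- convolve_axis(u, kx, 2)
  u <- convolve_axis(u, kx, 3)
  d <- dim(u)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (u[3:d[1], , ] - u[1:(d[1] - 2), , ]) / (2 * voxel)
  gy[, 2:(d[2] - 1), ] <- (u[, 3:d[2], ] - u[, 1:(d[2] - 2), ]) / (2 * voxel)
  gz[, , 2:(d[3] - 1)] <- (u[, , 3:d[3]] - u[, , 1:(d[3] - 2)]) / (2 * voxel)
  sum(sqrt(gx^2 + gy^2 + gz^2)) * voxel^3
}

convolve_axis <- function(u, kernel, axis) {
  half <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(u))
  for (j in seq_along(kernel)) {
    s <- integer(3); s[axis] <- j - 1L - half
    out <- out + kernel[j] * shift_array(u, s)
  }
  out
}

shift_array <- function(u, s) {
  dims <- dim(u)
  out <- array(0, dims)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (abs(s[k]) >= dims[k]) return(out)
    if (s[k] >= 0) {
      dst[[k]] <- (1 + s[k]):dims[k]; src[[k]] <- 1:(dims[k] - s[k])
    } else {
      dst[[k]] <- 1:(dims[k] + s[k]); src[[k]] <- (1 - s[k]):dims[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- u[src[[1]], src[[2]], src[[3]]]
  out
}

#' Reduced (effective) volume of a vesicle
#'
#' `nu = 3 V / (4 pi R^3)` with `R = sqrt(A / (4 pi))`, the radius of the
#' sphere having the vesicle's surface area. `nu = 1` for a sphere and
#' decreases as the shape deviates from sphericity at fixed volume.
#'
#' @param V Enclosed volume in nm^3.
#' @param A Surface area in nm^2.
#' @return Tibble with columns `V`, `A`, `R` (nm) and `nu`.
#' @examples
#' reduced_volume(9506, 3447)$nu   # ~0.50
#' @export
reduced_volume <- function(V, A) {
  if (any(V <= 0) || any(A <= 0)) {
    stop("`V` and `A` must be positive", call. = FALSE)
  }
  R <- sqrt(A / (4 * pi))
  tibble::tibble(V = V, A = A, R = R, nu = 3 * V / (4 * pi * R^3))
}
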