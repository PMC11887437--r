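#' Contour-resolved bilayer profiles
#'
#' Parameterises the vesicle outline by the contour distance `s` and
#' reports, along it, the bilayer thickness, the linear bead density and
#' the mean chain extension. Beads are projected onto the principal
#' (`lambda1`-`lambda2`) plane of the gyration tensor and binned by angle
#' about the centre of mass; the origin bin is centred on the `+lambda2`
#' direction (the midplane of the upper portion of the bilayer) and `s`
#' increases counterclockwise. Per bin: thickness is the spread between the
#' 2.5th and 97.5th percentile of the in-plane radial bead distances (the
#' bilayer's inner and outer envelopes, robust to outlier beads); the bead
#' density is the copolymer bead count divided by the bin's arc length
#' along the mid-radius polyline; `Qbar_s` is the mean end-to-end distance
#' of chains whose centre of mass falls in the bin. The structure must be
#' star-shaped about its centre of mass in the principal plane (one
#' cluster, no periphery overhangs).
#'
#' The thickness envelope is evaluated in a slab of half-width `slab_half`
#' about the principal plane (an equatorial cross-section), so that the
#' in-plane radial distance approximates the true distance from the
#' contour; the bead density counts every member bead in the angular
#' wedge, so that density times arc length sums to the total bead count.
#'
#' @param frame A [bead_frame()].
#' @param topology A [chain_topology()].
#' @param member_indices Copolymer bead indices of the aggregate (default:
#'   all copolymer beads).
#' @param n_bins Number of angular bins (default 72, i.e. 5 degrees).
#' @param slab_half Half-width (nm) of the cross-sectional slab used for
#'   the thickness envelope (default 2).
#' @return A `contour_profile` tibble with columns `s` (arc length at the
#'   bin centre, nm), `angle_deg`, `thickness` (nm), `bead_density`
#'   (beads/nm), `Qbar_s` (nm), `n_beads`, `arc_len`; empty bins (a
#'   ruptured outline) carry `NA` profiles and are flagged in attribute
#'   `gaps`.
#' @export
contour_profiles <- function(frame, topology,
                             member_indices = copolymer_beads(frame),
                             n_bins = 72, slab_half = 2) {
  if (n_bins < 4L) stop("need at least 4 angular bins", call. = FALSE)
  shape <- gyration_shape(frame, member_indices)
  axes <- attr(shape, "axes")
  com <- attr(shape, "com")
  e1 <- fix_sign(axes[, 1])   # +x of the principal frame (major axis)
  e2 <- fix_sign(axes[, 2])   # +y, the "top" where s = 0
  e3 <- fix_sign(axes[, 3])   # out-of-plane
  pos <- frame_positions(frame, member_indices)
  cen <- sweep(pos, 2, com)
  u <- cen %*% cbind(e1, e2)               # in-plane coordinates
  w <- as.numeric(cen %*% e3)              # out-of-plane coordinate
  r <- sqrt(rowSums(u^2))
  ang <- atan2(u[, 2], u[, 1])             # counterclockwise from +e1
  # origin bin centred on +e2 (angle pi/2), increasing counterclockwise
  width <- 2 * pi / n_bins
  rel <- (ang - pi / 2 + width / 2) %% (2 * pi)
  bin <- pmin(floor(rel / width), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  in_slab <- abs(w) <= slab_half
  qlo <- qhi <- rep(NA_real_, n_bins)
  for (b in which(counts > 0L)) {
    sel <- bin == b & in_slab
    if (!any(sel)) next
    rb <- r[sel]
    # keep only the outermost contiguous radial band: wedges along the
    # major axis of a waisted shape also sweep past near-axis membrane
    # that is not part of the local bilayer
    rbin <- floor(rb / 0.5)
    occ <- sort(unique(rbin), decreasing = TRUE)
    run_end <- which(c(-diff(occ), 2) > 1L)[1]
    rb <- rb[rbin >= occ[run_end]]
    qs <- stats::quantile(rb, c(0.025, 0.975), names = FALSE)
    qlo[b] <- qs[1]; qhi[b] <- qs[2]
  }
  mid_r <- (qlo + qhi) / 2
  # arc length along the mid-radius polyline between bin-centre points
  centre_ang <- pi / 2 + (seq_len(n_bins) - 1L) * width
  mr <- mid_r
  if (anyNA(mr) && !all(is.na(mr))) {
    # interpolate across gaps for the polyline only
    ok <- which(!is.na(mr))
    mr <- stats::approx(centre_ang[ok], mr[ok], xout = centre_ang,
                        rule = 2)$y
  }
  px <- mr * cos(centre_ang); py <- mr * sin(centre_ang)
  seg <- sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2)  # bin b -> b+1
  arc_len <- (c(seg[n_bins], seg[-n_bins]) + seg) / 2       # centred on bin
  s <- cumsum(c(0, seg[-n_bins]))
  # chain assignment by chain COM
  chain_com <- chain_coms(frame, topology)
  ccen <- sweep(chain_com, 2, com)
  cu <- ccen %*% cbind(e1, e2)
  cang <- atan2(cu[, 2], cu[, 1])
  crel <- (cang - pi / 2 + width / 2) %% (2 * pi)
  cbin <- pmin(floor(crel / width), n_bins - 1L) + 1L
  qq <- end_to_end(frame, topology)
  qbar_s <- rep(NA_real_, n_bins)
  agg <- tapply(qq$Q, cbin, mean)
  qbar_s[as.integer(names(agg))] <- as.numeric(agg)
  out <- tibble::tibble(
    s = s,
    angle_deg = (centre_ang - pi / 2) * 180 / pi,
    thickness = qhi - qlo,
    bead_density = ifelse(counts > 0, counts / arc_len, NA_real_),
    Qbar_s = qbar_s,
    n_beads = counts,
    arc_len = arc_len
  )
  gaps <- which(counts == 0L)
  if (length(gaps)) {
    warning(sprintf("%d empty contour bin(s): outline has gaps", length(gaps)),
            call. = FALSE)
  }
  attr(out, "gaps") <- gaps
  attr(out, "com") <- com
  attr(out, "axes") <- cbind(e1, e2)
  class(out) <- c("contour_profile", class(out))
  out
}

# deterministic eigenvector sign: largest-magnitude component positive
fix_sign <- function(v) {
  k <- which.max(abs(v))
  if (v[k] < 0) -v else v
}

chain_coms <- function(frame, topology) {
  pos <- frame_positions(frame)
  idx <- matrix(topology$bead, nrow = 20)
  t(apply(idx, 2, function(i) colMeans(pos[i, , drop = FALSE])))
}
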