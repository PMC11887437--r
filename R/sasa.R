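#' Solvent-accessible surface area by the rolling-probe construction
#'
#' Shrake-Rupley-style numerical SASA: each bead carries a quasi-uniform
#' set of test points on its expanded sphere of radius
#' `bead_radius + probe_radius`; a point is exposed when it lies outside
#' every other bead's expanded sphere, and the area is the summed exposed
#' fraction times `4 pi (bead_radius + probe_radius)^2`. This is the area
#' swept by the centre of a spherical probe sliding along the periphery of
#' the bead assembly, a proxy for the polymer-solvent interfacial area.
#'
#' @param frame A [bead_frame()].
#' @param member_indices Bead indices of the aggregate (default: all
#'   copolymer beads).
#' @param probe_radius Probe (solvent bead) radius in nm, default 0.264.
#' @param bead_radius Bead radius in nm, default 0.264; all beads share one
#'   radius unless `radii` is given.
#' @param n_points Test points per bead (default 960); at least 32.
#' @param radii Optional per-bead radii (same length as `member_indices`),
#'   overriding `bead_radius`.
#' @return Tibble with columns `area` (nm^2), `probe_radius`, `bead_radius`,
#'   `n_points`.
#' @examples
#' fr <- bead_frame(matrix(c(5, 5, 5), 1), "B", box = c(10, 10, 10))
#' sasa(fr, 1)$area   # 4*pi*0.528^2
#' @export
sasa <- function(frame, member_indices = copolymer_beads(frame),
                 probe_radius = 0.264, bead_radius = 0.264,
                 n_points = 960, radii = NULL) {
  if (!length(member_indices)) stop("member set is empty", call. = FALSE)
  if (n_points < 32) stop("resolution error: n_points must be >= 32", call. = FALSE)
  pos <- frame_positions(frame, member_indices)
  n <- nrow(pos)
  R <- (radii %||% rep(bead_radius, n)) + probe_radius
  if (length(R) != n) stop("`radii` must match `member_indices`", call. = FALSE)
  sphere <- fibonacci_sphere(n_points)
  # neighbour pairs via the clustering cell list at the maximal reach
  reach <- 2 * max(R)
  nb_pairs <- neighbour_pairs(pos, reach + 1e-9, box = NULL)
  buried <- matrix(0L, n, n_points)
  if (nrow(nb_pairs)) {
    # a test point u on bead i's expanded sphere is buried by bead j iff
    # u . (p_j - p_i) > (R_i^2 + |d|^2 - R_j^2) / (2 R_i); evaluate all
    # (point, pair) combinations as one matrix product per chunk
    owners <- c(nb_pairs[, 1], nb_pairs[, 2])
    others <- c(nb_pairs[, 2], nb_pairs[, 1])
    d <- pos[others, , drop = FALSE] - pos[owners, , drop = FALSE]
    cth <- (R[owners]^2 + rowSums(d^2) - R[others]^2) / (2 * R[owners])
    m <- length(owners)
    chunk <- max(1L, 50000L)
    for (lo in seq(1L, m, by = chunk)) {
      hi <- min(lo + chunk - 1L, m)
      sel <- lo:hi
      proj <- sphere %*% t(d[sel, , drop = FALSE])      # n_points x m'
      hit <- t(proj > rep(cth[sel], each = n_points))   # m' x n_points
      counts <- rowsum(hit * 1L, owners[sel])
      ids <- as.integer(rownames(counts))
      buried[ids, ] <- buried[ids, , drop = FALSE] + counts
    }
  }
  exposed <- rowSums(buried == 0L) / n_points
  tibble::tibble(
    area = sum(exposed * 4 * pi * R^2),
    probe_radius = probe_radius,
    bead_radius = if (is.null(radii)) bead_radius else NA_real_,
    n_points = n_points
  )
}
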