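#' Centre-of-mass pair correlation function of a cluster
#'
#' Measures how the density of `B`, `A` or `W` beads varies with distance
#' `r` from the (unweighted) centre of mass of a cluster. For each radial
#' shell `[r, r + dr)` of volume `V(r) = (4/3) * pi * ((r + dr)^3 - r^3)`,
#' the shell density `<rho(r)>` is the bead count divided by `V(r)`;
#' `g(r) = <rho(r)> / rho` with the mean density
#' `rho = 3 * N_m / (4 * pi * r_max^3)`, where `N_m` is the number of beads
#' of the species counted and `r_max` the distance of the farthest such
#' bead from the centre. Shells are half-open: a bead at the inner boundary
#' is included, one at the outer boundary belongs to the next shell; the
#' farthest bead (at exactly `r_max`) lands in the final shell so that the
#' shell counts always sum to `N_m`.
#'
#' The cluster must be whole (unwrapped) before calling: no periodic
#' imaging is applied.
#'
#' @param frame A [bead_frame()].
#' @param member_indices Bead indices defining the cluster; the centre of
#'   mass is taken over these beads (all beads weighted equally).
#' @param species Bead species to profile (subset of `"B"`, `"A"`, `"W"`);
#'   each species gets its own `N_m`, `r_max` and normalisation. Solvent
#'   `WF` beads are counted with `W`.
#' @param dr Shell width in nm (default 0.1).
#' @return A `radial_profile` tibble with columns `r` (shell inner radius,
#'   nm), `species`, `count`, `g`; attributes `dr`, `com` and per-species
#'   `n_beads` and `r_max`.
#' @examples
#' fr <- bead_frame(rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0)) + 5,
#'                  "B", box = c(10, 10, 10))
#' gr <- pair_correlation(fr, member_indices = 1:4, species = "B")
#' gr$g[gr$r == 1.0]   # ~3.02
#' @export
pair_correlation <- function(frame, member_indices = copolymer_beads(frame),
                             species = c("B", "A", "W"), dr = 0.1) {
  if (!length(member_indices)) stop("member set is empty", call. = FALSE)
  if (dr <= 0) stop("`dr` must be positive", call. = FALSE)
  species <- match.arg(species, c("B", "A", "W"), several.ok = TRUE)
  com <- centre_of_mass(frame_positions(frame, member_indices))
  res <- list(); n_beads <- c(); r_maxs <- c()
  for (sp in species) {
    sel <- if (sp == "W") frame$type %in% c("W", "WF") else frame$type == sp
    idx <- which(sel)
    if (!length(idx)) next
    pos <- frame_positions(frame, idx)
    d <- sqrt(rowSums(sweep(pos, 2, com)^2))
    r_max <- max(d)
    if (r_max < dr * 1e-9) {
      stop("degenerate geometry: all beads at the centre of mass", call. = FALSE)
    }
    n_shell <- floor(r_max / dr) + 1L
    shell <- pmin(floor(d / dr), n_shell - 1L)  # farthest bead -> final shell
    counts <- tabulate(shell + 1L, nbins = n_shell)
    r_in <- (seq_len(n_shell) - 1L) * dr
    vol <- (4 / 3) * pi * ((r_in + dr)^3 - r_in^3)
    rho <- 3 * length(idx) / (4 * pi * r_max^3)
    res[[sp]] <- tibble::tibble(
      r = r_in, species = sp, count = counts, g = (counts / vol) / rho
    )
    n_beads[sp] <- length(idx)
    r_maxs[sp] <- r_max
  }
  if (!length(res)) stop("no beads of the requested species present", call. = FALSE)
  out <- dplyr::bind_rows(res)
  attr(out, "dr") <- dr
  attr(out, "com") <- com
  attr(out, "n_beads") <- n_beads
  attr(out, "r_max") <- r_maxs
  class(out) <- c("radial_profile", class(out))
  out
}
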