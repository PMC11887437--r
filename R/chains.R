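#' Per-chain end-to-end distances
#'
#' `Q` is the Euclidean distance between the first and last bead of each
#' 20-bead chain. Chains must be whole (unwrapped): a bond longer than
#' `max_bond` is taken as evidence of periodic wrapping and raises an
#' error.
#'
#' @param frame A [bead_frame()].
#' @param topology A [chain_topology()].
#' @param chains Optional chain ids to restrict to (default: all).
#' @param max_bond Maximum plausible bond length in nm (default 1.5).
#' @return Tibble with columns `chain`, `Q` (nm) and attribute `Qbar`
#'   (arithmetic mean of `Q` over the selected chains).
#' @examples
#' ves <- make_vesicle(morphology_spec(n_chains = 200, seed = 1))
#' qq <- end_to_end(ves$frame, ves$topology)
#' mean(qq$Q)
#' @export
end_to_end <- function(frame, topology, chains = NULL, max_bond = 1.5) {
  topo <- topology
  if (!is.null(chains)) topo <- topo[topo$chain %in% chains, ]
  if (!nrow(topo)) stop("no chains selected", call. = FALSE)
  pos <- frame_positions(frame)
  idx <- matrix(topo$bead, nrow = 20)       # one column per chain
  bond_vec <- pos[idx[-1, ], , drop = FALSE] - pos[idx[-20, ], , drop = FALSE]
  bl2 <- rowSums(bond_vec^2)
  if (any(bl2 > max_bond^2)) {
    stop(sprintf(
      "unwrap error: %d bond(s) exceed %.2f nm; chains appear wrapped across the box",
      sum(bl2 > max_bond^2), max_bond
    ), call. = FALSE)
  }
  ee <- pos[idx[20, ], , drop = FALSE] - pos[idx[1, ], , drop = FALSE]
  out <- tibble::tibble(
    chain = unique(topo$chain),
    Q = sqrt(rowSums(ee^2))
  )
  attr(out, "Qbar") <- mean(out$Q)
  out
}

#' Configurational (information) entropy of the chain-stretch distribution
#'
#' Bins the per-chain end-to-end distances `Q` on a fixed-origin grid
#' (origin 0, width `bin_width`) and returns the Shannon entropy
#' `H = -sum(p * log(p))` over the occupied bins, in nats. `H` is 0 for a
#' point mass and `log(k)` for `k` equally occupied bins; broadening of
#' `p(Q)` (e.g. the hairpin-to-stretched bimodality that precedes rupture)
#' raises `H`. Entropies are only comparable between identical bin grids.
#'
#' @param Q Numeric vector of end-to-end distances in nm (or the tibble
#'   returned by [end_to_end()]).
#' @param bin_width Bin width in nm (default 0.25).
#' @return Tibble with columns `H` (nats), `n_bins` (occupied bins) and
#'   `n_chains`.
#' @examples
#' chain_entropy(rep(c(1, 2, 3, 4), 25))$H   # log(4)
#' @export
chain_entropy <- function(Q, bin_width = 0.25) {
  if (is.data.frame(Q)) Q <- Q$Q
  Q <- Q[is.finite(Q)]
  if (length(Q) < 2L) stop("need at least 2 chains for an entropy", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  bins <- floor(Q / bin_width)
  p <- as.numeric(table(bins)) / length(Q)
  tibble::tibble(
    H = -sum(p * log(p)),
    n_bins = length(p),
    n_chains = length(Q)
  )
}

#' Probability distribution of `Q` on the entropy grid
#'
#' Normalised histogram of per-chain end-to-end distances on the same
#' fixed-origin grid used by [chain_entropy()].
#'
#' @inheritParams chain_entropy
#' @return Tibble with columns `Q_lo` (bin lower edge, nm), `Q_mid`, `p`.
#' @export
q_pdf <- function(Q, bin_width = 0.25) {
  if (is.data.frame(Q)) Q <- Q$Q
  Q <- Q[is.finite(Q)]
  bins <- floor(Q / bin_width)
  tab <- table(bins)
  lo <- as.numeric(names(tab)) * bin_width
  tibble::tibble(Q_lo = lo, Q_mid = lo + bin_width / 2,
                 p = as.numeric(tab) / length(Q))
}

#' Chain orientation distribution in the flow plane
#'
#' For each chain, the end-to-end vector is projected onto the x-y (flow-
#' gradient) plane and the angle `theta_c` to the x (flow) axis is folded
#' to \[0, 90\] degrees (chain end labelling is arbitrary). Chains whose
#' end-to-end vector has a zero x-y projection are skipped and counted.
#'
#' @param frame A [bead_frame()].
#' @param topology A [chain_topology()].
#' @param bin_deg Angular bin width in degrees (default 5).
#' @param chains Optional chain ids to restrict to.
#' @return Tibble with columns `theta_lo`, `theta_mid` (degrees), `p`
#'   (normalised over chains with a defined angle); attributes `theta_c`
#'   (per-chain angles) and `n_skipped`.
#' @export
orientation_pdf <- function(frame, topology, bin_deg = 5, chains = NULL) {
  topo <- topology
  if (!is.null(chains)) topo <- topo[topo$chain %in% chains, ]
  pos <- frame_positions(frame)
  idx <- matrix(topo$bead, nrow = 20)
  ee <- pos[idx[20, ], , drop = FALSE] - pos[idx[1, ], , drop = FALSE]
  proj <- sqrt(ee[, 1]^2 + ee[, 2]^2)
  ok <- proj > 1e-12
  theta <- fold_angle_90(atan2(ee[ok, 2], ee[ok, 1]) * 180 / pi)
  n_bins <- ceiling(90 / bin_deg)
  bin <- pmin(floor(theta / bin_deg), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  lo <- (seq_len(n_bins) - 1L) * bin_deg
  out <- tibble::tibble(theta_lo = lo, theta_mid = lo + bin_deg / 2,
                        p = counts / sum(counts))
  attr(out, "theta_c") <- theta
  attr(out, "n_skipped") <- sum(!ok)
  out
}
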