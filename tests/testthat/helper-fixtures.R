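# Shared fixture builders and independent oracles.

# random bead cloud in a box
random_cloud <- function(n, box = 10, seed = 1, type = "B") {
  set.seed(seed)
  bead_frame(matrix(stats::runif(3 * n, 0, box), ncol = 3), type,
             box = rep(box, 3))
}

# O(N^2) connected-components clustering oracle: full distance matrix,
# strict cutoff, graph search via igraph on the brute-force edge list
cluster_oracle <- function(frame, cutoff = 0.5, periodic = FALSE) {
  idx <- copolymer_beads(frame)
  pos <- frame_positions(frame, idx)
  n <- nrow(pos)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(pos[, k], pos[, k], `-`)
    if (periodic) {
      bl <- frame_box(frame)[k]
      dk <- dk - bl * round(dk / bl)
    }
    d2 <- d2 + dk^2
  }
  adj <- d2 < cutoff^2
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# canonical form of a partition for comparison
partition_key <- function(labels) {
  match(labels, unique(labels))
}

# naive per-bead histogram oracle for the COM pair correlation
gr_oracle <- function(frame, member_indices, species, dr = 0.1) {
  com <- colMeans(frame_positions(frame, member_indices))
  sel <- if (species == "W") frame$type %in% c("W", "WF") else
    frame$type == species
  pos <- frame_positions(frame, which(sel))
  d <- sqrt(rowSums(sweep(pos, 2, com)^2))
  r_max <- max(d)
  n_shell <- floor(r_max / dr) + 1
  counts <- integer(n_shell)
  for (di in d) {
    s <- floor(di / dr) + 1
    if (s > n_shell) s <- n_shell      # farthest bead into final shell
    counts[s] <- counts[s] + 1
  }
  r_in <- (seq_len(n_shell) - 1) * dr
  vol <- (4 / 3) * pi * ((r_in + dr)^3 - r_in^3)
  rho <- 3 * length(d) / (4 * pi * r_max^3)
  list(r = r_in, g = (counts / vol) / rho, counts = counts)
}

# Monte-Carlo gyration-tensor oracle for an ellipsoidal membrane shell:
# area-uniform surface sampling (rejection method), offset inward
# uniformly through the membrane thickness
mc_ellipsoid_shell_E <- function(axes, h, n = 200000, seed = 42) {
  set.seed(seed)
  a <- axes[1]; b <- axes[2]; c_ <- axes[3]
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < n) {
    m <- 2 * (n - nrow(pts)) + 64
    u <- matrix(stats::rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    w <- sqrt((u[, 1] * b * c_)^2 + (u[, 2] * a * c_)^2 + (u[, 3] * a * b)^2)
    keep <- stats::runif(m) < w / max(a * b, a * c_, b * c_)
    pts <- rbind(pts, cbind(a * u[keep, 1], b * u[keep, 2], c_ * u[keep, 3]))
  }
  pts <- pts[1:n, ]
  nrm <- cbind(pts[, 1] / a^2, pts[, 2] / b^2, pts[, 3] / c_^2)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  q <- pts - nrm * stats::runif(n, 0, h)
  cen <- sweep(q, 2, colMeans(q))
  lam <- sort(eigen(crossprod(cen) / n, symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  (lam[1] - lam[3]) / (lam[1] + lam[3])
}

# a small equilibrium vesicle shared across tests
small_vesicle <- function(n_chains = 600, seed = 1) {
  make_vesicle(morphology_spec(outer_radius = 8, thickness = 4,
                               n_chains = n_chains, seed = seed))
}

# synthetic frame whose chains have prescribed end-to-end vectors:
# bead 1 at `starts`, beads interpolated toward `starts + vecs`
chains_frame <- function(starts, vecs, box = 200) {
  n <- nrow(starts)
  t_frac <- (seq_len(20) - 1) / 19
  pos <- matrix(0, 20 * n, 3)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * 20 + 1):(i * 20)
    pos[rows, ] <- matrix(starts[i, ], 20, 3, byrow = TRUE) +
      outer(t_frac, vecs[i, ])
  }
  list(frame = bead_frame(pos + box / 2, rep(chain_bead_pattern_test(), n),
                          box = rep(box, 3)),
       topology = chain_topology(n))
}

chain_bead_pattern_test <- function() {
  c(rep("B", 5), rep("A", 10), rep("B", 5))
}

# Rodrigues rotation matrix (independent of the package internals)
rotation_matrix_test <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
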