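#' Identify copolymer aggregates by cutoff-distance clustering
#'
#' Two copolymer beads belong to the same aggregate when their
#' centre-to-centre separation is strictly less than the cutoff distance
#' (default 0.5 nm, the non-bonded interaction range of the coarse-grained
#' model); aggregates are the connected components of the resulting contact
#' graph. Solvent beads are never clustered. A pair at exactly the cutoff is
#' not bonded.
#'
#' @param frame A [bead_frame()].
#' @param topology Optional [chain_topology()]; enables the per-cluster
#'   chain counts (a chain belongs to the cluster holding the majority of
#'   its beads, ties broken toward the larger cluster).
#' @param cutoff Contact distance in nm (default 0.5).
#' @param periodic Apply the minimum-image convention across the box.
#' @return A `cluster_set`: tibble with one row per copolymer bead, columns
#'   `bead` (frame index) and `cluster` (id, 1 = largest by bead count),
#'   with attributes `sizes` (beads per cluster, descending),
#'   `chain_sizes` (chains per cluster, if a topology was given) and
#'   `cutoff`.
#' @examples
#' fr <- bead_frame(cbind(c(0, 0.4, 2), 0, 0), "B", box = c(10, 10, 10))
#' cl <- find_clusters(fr)
#' cluster_sizes(cl)   # 2, 1
#' @export
find_clusters <- function(frame, topology = NULL, cutoff = 0.5,
                          periodic = FALSE) {
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  members <- copolymer_beads(frame)
  if (!length(members)) stop("frame contains no copolymer beads", call. = FALSE)
  pos <- frame_positions(frame, members)
  box <- if (periodic) frame_box(frame) else NULL
  edges <- neighbour_pairs(pos, cutoff, box)
  g <- igraph::make_empty_graph(n = length(members), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # relabel so cluster 1 is the largest by bead count
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  labels <- relabel[comp$membership]
  sizes <- as.integer(sort(comp$csize, decreasing = TRUE))
  out <- tibble::tibble(bead = members, cluster = labels)
  attr(out, "sizes") <- sizes
  attr(out, "cutoff") <- cutoff
  if (!is.null(topology)) {
    attr(out, "chain_sizes") <- chain_cluster_sizes(out, topology, sizes)
  }
  class(out) <- c("cluster_set", class(out))
  out
}

# Candidate contact pairs via a cell list of edge >= cutoff; O(N) for
# bounded local density. Returns a 2-column matrix of member-local indices.
neighbour_pairs <- function(pos, cutoff, box = NULL) {
  n <- nrow(pos)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  if (!is.null(box)) {
    pos <- sweep(pos, 2, box, function(x, b) x %% b)
    ncell <- pmax(1L, as.integer(floor(box / cutoff)))
    cell_len <- box / ncell
  } else {
    lo <- apply(pos, 2, min)
    pos <- sweep(pos, 2, lo, `-`)
    span <- apply(pos, 2, max) + 1e-9
    ncell <- pmax(1L, as.integer(floor(span / cutoff)))
    cell_len <- span / ncell + 1e-12
  }
  ix <- pmin(ncell[1] - 1L, as.integer(pos[, 1] %/% cell_len[1]))
  iy <- pmin(ncell[2] - 1L, as.integer(pos[, 2] %/% cell_len[2]))
  iz <- pmin(ncell[3] - 1L, as.integer(pos[, 3] %/% cell_len[3]))
  cell_id <- 1L + ix + ncell[1] * (iy + ncell[2] * iz)
  by_cell <- split(seq_len(n), cell_id)
  occupied <- as.integer(names(by_cell))
  occ_ix <- (occupied - 1L) %% ncell[1]
  occ_iy <- ((occupied - 1L) %/% ncell[1]) %% ncell[2]
  occ_iz <- (occupied - 1L) %/% (ncell[1] * ncell[2])
  # half-shell of offsets: each unordered cell pair visited once
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  code <- offsets$dx + 3 * offsets$dy + 9 * offsets$dz
  offsets <- offsets[code >= 0, ]
  cell_index <- match(seq_len(prod(ncell)), occupied)
  pieces <- list()
  for (k in seq_len(nrow(offsets))) {
    jx <- occ_ix + offsets$dx[k]
    jy <- occ_iy + offsets$dy[k]
    jz <- occ_iz + offsets$dz[k]
    if (!is.null(box)) {
      jx <- jx %% ncell[1]; jy <- jy %% ncell[2]; jz <- jz %% ncell[3]
      ok <- rep(TRUE, length(jx))
    } else {
      ok <- jx >= 0 & jx < ncell[1] & jy >= 0 & jy < ncell[2] &
            jz >= 0 & jz < ncell[3]
    }
    if (!any(ok)) next
    tgt <- 1L + jx[ok] + ncell[1] * (jy[ok] + ncell[2] * jz[ok])
    src_cells <- which(ok)
    tgt_pos <- cell_index[tgt]
    has <- !is.na(tgt_pos)
    if (!any(has)) next
    src_cells <- src_cells[has]; tgt_pos <- tgt_pos[has]
    a <- unlist(mapply(function(s, t) {
      ai <- by_cell[[s]]; bi <- by_cell[[t]]
      rep(ai, each = length(bi))
    }, src_cells, tgt_pos, SIMPLIFY = FALSE), use.names = FALSE)
    b <- unlist(mapply(function(s, t) {
      ai <- by_cell[[s]]; bi <- by_cell[[t]]
      rep(bi, times = length(ai))
    }, src_cells, tgt_pos, SIMPLIFY = FALSE), use.names = FALSE)
    same_cell <- offsets$dx[k] == 0 && offsets$dy[k] == 0 && offsets$dz[k] == 0
    keep <- if (same_cell) a < b else a != b
    if (any(keep)) pieces[[length(pieces) + 1L]] <- cbind(a[keep], b[keep])
  }
  if (!length(pieces)) return(matrix(integer(0), ncol = 2))
  cand <- do.call(rbind, pieces)
  d <- pos[cand[, 1], , drop = FALSE] - pos[cand[, 2], , drop = FALSE]
  if (!is.null(box)) d <- sweep_min_image(d, box)
  keep <- rowSums(d * d) < cutoff^2        # strict inequality at the cutoff
  cand[keep, , drop = FALSE]
}

sweep_min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- min_image(d[, k], box[k])
  d
}

# chains per cluster: majority bead membership, ties toward larger cluster
chain_cluster_sizes <- function(clusters, topology, sizes) {
  lab <- clusters$cluster[match(topology$bead, clusters$bead)]
  assign <- vapply(split(lab, topology$chain), function(l) {
    l <- l[!is.na(l)]
    if (!length(l)) return(NA_integer_)
    tab <- table(l)
    best <- names(tab)[tab == max(tab)]
    # cluster ids are ordered by descending size, so min id = largest cluster
    min(as.integer(best))
  }, integer(1))
  counts <- integer(length(sizes))
  tab <- table(assign)
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' @rdname find_clusters
#' @param clusters A `cluster_set`.
#' @export
cluster_sizes <- function(clusters) attr(clusters, "sizes")

#' @rdname find_clusters
#' @export
cluster_chain_sizes <- function(clusters) attr(clusters, "chain_sizes")

#' Fraction of chains in the largest aggregate
#'
#' The rupture-detection order parameter: the number of chains assigned to
#' the largest cluster divided by the total chain count.
#'
#' @param clusters A `cluster_set` from [find_clusters()] (computed with a
#'   topology, or pass `topology` here).
#' @param topology A [chain_topology()], required if the cluster set carries
#'   no chain counts.
#' @return A fraction in \[0, 1\].
#' @export
largest_cluster_fraction <- function(clusters, topology = NULL) {
  cs <- cluster_chain_sizes(clusters)
  if (is.null(cs)) {
    if (is.null(topology)) {
      stop("cluster set has no chain counts; supply `topology`", call. = FALSE)
    }
    cs <- chain_cluster_sizes(clusters, topology, cluster_sizes(clusters))
  }
  cs[1] / sum(cs)
}
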