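#' Bead species recognised by the data model
#'
#' `B` is the hydrophobic butadiene monomer, `A` the hydrophilic ethylene
#' oxide monomer, `W` a solvent bead and `WF` an antifreeze solvent bead.
#' Copolymer beads are the `B` and `A` species; solvent is `W`/`WF`.
#'
#' @format Character vector of length four.
#' @export
bead_types <- c("B", "A", "W", "WF")

#' Construct a single-snapshot bead frame
#'
#' A bead frame is a tibble with one row per bead and columns `bead`
#' (integer index), `x`, `y`, `z` (coordinates in nm) and `type` (one of
#' [bead_types]). The orthorhombic box edge lengths (nm) and the snapshot
#' time (ns) travel as attributes `box` and `time`.
#'
#' @param positions Numeric matrix (n x 3) or data frame with columns
#'   `x`, `y`, `z`, coordinates in nm.
#' @param types Character vector of bead species, recycled if length 1.
#' @param box Numeric length-3 vector of box edge lengths in nm.
#' @param time Snapshot time in ns.
#' @return A `bead_frame` tibble.
#' @examples
#' fr <- bead_frame(matrix(rnorm(30), ncol = 3), "B", box = c(10, 10, 10))
#' frame_box(fr)
#' @export
bead_frame <- function(positions, types, box, time = 0) {
  if (is.data.frame(positions)) {
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  if (n == 0L) stop("bead frame must contain at least one bead", call. = FALSE)
  if (!all(is.finite(positions))) {
    stop("bead positions must be finite", call. = FALSE)
  }
  if (length(types) == 1L) types <- rep(types, n)
  if (length(types) != n) {
    stop("`types` must have one entry per bead", call. = FALSE)
  }
  types <- as.character(types)
  bad <- setdiff(unique(types), bead_types)
  if (length(bad) > 0L) {
    stop("unknown bead type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("`box` must be three positive edge lengths (nm)", call. = FALSE)
  }
  out <- tibble::tibble(
    bead = seq_len(n),
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    type = types
  )
  attr(out, "box") <- box
  attr(out, "time") <- as.numeric(time)
  class(out) <- c("bead_frame", class(out))
  out
}

#' @rdname bead_frame
#' @param frame A `bead_frame`.
#' @export
frame_box <- function(frame) attr(frame, "box")

#' @rdname bead_frame
#' @export
frame_time <- function(frame) attr(frame, "time")

#' Positions of a bead frame as a numeric matrix
#'
#' @param frame A `bead_frame`.
#' @param beads Optional integer vector of bead indices to extract.
#' @return n x 3 numeric matrix in nm.
#' @export
frame_positions <- function(frame, beads = NULL) {
  m <- cbind(x = frame$x, y = frame$y, z = frame$z)
  if (!is.null(beads)) m <- m[beads, , drop = FALSE]
  m
}

#' @export
print.bead_frame <- function(x, ...) {
  box <- frame_box(x)
  cat(sprintf(
    "# bead_frame: %d beads, box %.3f x %.3f x %.3f nm, t = %g ns\n",
    nrow(x), box[1], box[2], box[3], frame_time(x)
  ))
  NextMethod()
}

#' Indices of copolymer (non-solvent) beads
#'
#' @param frame A `bead_frame`.
#' @return Integer vector of bead indices whose type is `B` or `A`.
#' @export
copolymer_beads <- function(frame) {
  which(frame$type %in% c("B", "A"))
}

#' Construct a chain topology for 20-bead BAB triblock chains
#'
#' Each chain is a PB5-PEO10-PB5 triblock: beads 1-5 hydrophobic (`B`),
#' 6-15 hydrophilic (`A`), 16-20 hydrophobic (`B`). The topology is a tibble
#' with columns `chain` (chain id), `bead` (bead index into the frame) and
#' `type`, 20 rows per chain in intra-chain order.
#'
#' @param chains List of length-20 integer vectors (bead indices per chain),
#'   or a single integer `n_chains` to lay out chains contiguously starting
#'   at bead 1.
#' @return A `chain_topology` tibble.
#' @examples
#' topo <- chain_topology(2)
#' n_chains(topo)
#' @export
chain_topology <- function(chains) {
  if (is.numeric(chains) && length(chains) == 1L) {
    nc <- as.integer(chains)
    if (nc < 1L) stop("need at least one chain", call. = FALSE)
    chains <- lapply(seq_len(nc), function(i) ((i - 1L) * 20L + 1L):(i * 20L))
  }
  if (!length(chains)) stop("need at least one chain", call. = FALSE)
  lens <- lengths(chains)
  if (any(lens != 20L)) {
    stop("every chain must have exactly 20 beads", call. = FALSE)
  }
  idx <- unlist(chains, use.names = FALSE)
  if (anyDuplicated(idx)) {
    stop("chain bead lists must be disjoint", call. = FALSE)
  }
  out <- tibble::tibble(
    chain = rep(seq_along(chains), each = 20L),
    bead = as.integer(idx),
    type = rep(chain_bead_pattern(), length(chains))
  )
  class(out) <- c("chain_topology", class(out))
  out
}

chain_bead_pattern <- function() {
  c(rep("B", 5), rep("A", 10), rep("B", 5))
}

#' @rdname chain_topology
#' @param topology A `chain_topology`.
#' @export
n_chains <- function(topology) length(unique(topology$chain))

#' Check a frame against a chain topology
#'
#' Verifies that every bead index listed in the topology exists in the frame
#' and that bead types match the B5-A10-B5 pattern.
#'
#' @param frame A `bead_frame`.
#' @param topology A `chain_topology`.
#' @return Invisibly `TRUE`; stops with a topology error otherwise.
#' @export
validate_topology <- function(frame, topology) {
  if (max(topology$bead) > nrow(frame)) {
    stop(sprintf(
      "topology error: topology references bead %d but frame has %d beads",
      max(topology$bead), nrow(frame)
    ), call. = FALSE)
  }
  ft <- frame$type[topology$bead]
  if (!all(ft == topology$type)) {
    bad <- which(ft != topology$type)[1]
    stop(sprintf(
      "topology error: bead %d has frame type %s but topology type %s",
      topology$bead[bad], ft[bad], topology$type[bad]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a labelled scalar time series
#'
#' Tibble with columns `time` (ns, strictly increasing) and `value`;
#' the label travels as attribute `label`.
#'
#' @param times Numeric vector of times in ns, strictly increasing.
#' @param values Numeric vector, same length as `times`.
#' @param label Short name of the quantity (e.g. `"E"`, `"H"`, `"SASA"`).
#' @return A `scalar_series` tibble.
#' @export
scalar_series <- function(times, values, label = "value") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time = times, value = values)
  attr(out, "label") <- label
  class(out) <- c("scalar_series", class(out))
  out
}
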