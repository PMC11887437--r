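#' Read a bead trajectory from a CG-MD text format
#'
#' Supported dialects: GROMACS `.gro` (possibly multi-frame, coordinates in
#' nm, box from the final vector line), LAMMPS text dump (`ITEM:` blocks,
#' coordinates in Angstrom by default, scaled `xs ys zs` coordinates
#' unscaled by the box) and XYZ (Angstrom by default). Coordinates are
#' always returned in nm. Boxes must be orthorhombic; triclinic input is
#' rejected. No periodic wrapping is applied on read.
#'
#' @param path Path to the trajectory file.
#' @param format One of `"gro"`, `"lammps-dump"`, `"xyz"`. Guessed from the
#'   file extension when `NULL`.
#' @param topology Optional [chain_topology()]; if given, the bead count of
#'   every frame is checked against it.
#' @param units Length unit of the file for `lammps-dump` and `xyz`:
#'   `"angstrom"` (default) or `"nm"`. GRO is always nm.
#' @param timestep For LAMMPS dumps, the time in ns represented by one unit
#'   of the `TIMESTEP` record (default 1: times are reported in raw step
#'   units unless the MD timestep is supplied).
#' @param type_map Named vector mapping on-file species labels to
#'   [bead_types] (used for numeric LAMMPS type ids); by default labels
#'   `1:4` map to `B`, `A`, `W`, `WF` and literal type strings pass through.
#' @return List of [bead_frame()] objects in time order.
#' @examples
#' fr <- bead_frame(matrix(runif(60, 1, 9), ncol = 3),
#'                  rep(c("B", "A"), 10), box = c(10, 10, 10))
#' f <- tempfile(fileext = ".gro")
#' write_frame(fr, f)
#' traj <- read_trajectory(f)
#' length(traj)
#' @export
read_trajectory <- function(path, format = NULL, topology = NULL,
                            units = "angstrom", timestep = 1,
                            type_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("gro", "lammps-dump", "xyz"))
  lines <- readLines(path, warn = FALSE)
  # trailing whitespace / blank terminal lines are tolerated
  lines <- sub("[ \t\r]+$", "", lines)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  frames <- switch(format,
    "gro" = parse_gro(lines),
    "lammps-dump" = parse_lammps_dump(lines, units, timestep, type_map),
    "xyz" = parse_xyz(lines, units)
  )
  counts <- vapply(frames, nrow, integer(1))
  if (length(unique(counts)) > 1L) {
    stop("bead count varies across frames: ", paste(unique(counts), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(topology)) {
    want <- max(topology$bead)
    if (counts[1] < want) {
      stop(sprintf(
        "topology error: file has %d beads but topology references bead %d",
        counts[1], want
      ), call. = FALSE)
    }
    validate_topology(frames[[1]], topology)
  }
  times <- vapply(frames, frame_time, numeric(1))
  frames[order(times)]
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "gro" = "gro",
    "xyz" = "xyz",
    "dump" = "lammps-dump",
    "lammpstrj" = "lammps-dump",
    stop("cannot guess trajectory format from extension: ", ext, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_num <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v))) {
    stop(sprintf("parse error at line %d: bad %s field", lineno, what),
         call. = FALSE)
  }
  v
}

parse_gro <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    if (i + 1L > length(lines)) {
      stop(sprintf("parse error at line %d: truncated GRO frame", i), call. = FALSE)
    }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("parse error at line %d: bad atom count", i + 1L), call. = FALSE)
    }
    if (i + 1L + nat + 1L > length(lines)) {
      stop(sprintf("parse error at line %d: GRO frame shorter than atom count", i),
           call. = FALSE)
    }
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    # fixed columns: resid(1-5) resname(6-10) name(11-15) nr(16-20) x y z %8.3f
    types <- trimws(substr(atom_lines, 11, 15))
    xs <- parse_num(substr(atom_lines, 21, 28), i + 2L, "x coordinate")
    ys <- parse_num(substr(atom_lines, 29, 36), i + 2L, "y coordinate")
    zs <- parse_num(substr(atom_lines, 37, 44), i + 2L, "z coordinate")
    box_line <- i + 2L + nat
    box_fields <- strsplit(trimws(lines[box_line]), "[ \t]+")[[1]]
    box <- parse_num(box_fields, box_line, "box")
    if (length(box) > 3L && any(abs(box[-(1:3)]) > 1e-9)) {
      stop(sprintf("parse error at line %d: triclinic boxes are not supported",
                   box_line), call. = FALSE)
    }
    time <- 0
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
    frames[[length(frames) + 1L]] <-
      bead_frame(cbind(xs, ys, zs), types, box[1:3], time)
    i <- box_line + 1L
  }
  if (!length(frames)) stop("no frames found in GRO file", call. = FALSE)
  frames
}

parse_xyz <- function(lines, units = "angstrom") {
  scale <- if (units == "nm") 1 else 0.1
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop(sprintf("parse error at line %d: bad atom count", i), call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop(sprintf("parse error at line %d: XYZ frame shorter than atom count", i),
           call. = FALSE)
    }
    comment <- lines[i + 1L]
    time <- 0
    tm <- regmatches(comment, regexpr("time=\\s*[-0-9.eE+]+", comment))
    if (length(tm)) time <- as.numeric(sub("time=\\s*", "", tm))
    box <- c(NA_real_, NA_real_, NA_real_)
    bm <- regmatches(comment,
                     regexpr("box=\\s*[-0-9.eE+]+,[-0-9.eE+]+,[-0-9.eE+]+", comment))
    if (length(bm)) {
      box <- as.numeric(strsplit(sub("box=\\s*", "", bm), ",")[[1]]) * scale
    }
    fields <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 4L)) {
      bad <- which(nf < 4L)[1]
      stop(sprintf("parse error at line %d: expected 'type x y z'", i + 1L + bad),
           call. = FALSE)
    }
    types <- vapply(fields, `[[`, character(1), 1L)
    pos <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3))) * scale
    if (any(is.na(pos))) {
      stop(sprintf("parse error near line %d: non-numeric coordinate", i + 2L),
           call. = FALSE)
    }
    if (any(is.na(box))) {
      # no box recorded: tight bounding box with a 1 nm pad
      box <- apply(pos, 2, function(v) diff(range(v))) + 2
    }
    frames[[length(frames) + 1L]] <- bead_frame(pos, types, box, time)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in XYZ file", call. = FALSE)
  frames
}

default_type_map <- c("1" = "B", "2" = "A", "3" = "W", "4" = "WF",
                      "B" = "B", "A" = "A", "W" = "W", "WF" = "WF")

parse_lammps_dump <- function(lines, units = "angstrom", timestep = 1,
                              type_map = NULL) {
  scale <- if (units == "nm") 1 else 0.1
  type_map <- type_map %||% default_type_map
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^ITEM: TIMESTEP", lines[i])) {
      stop(sprintf("parse error at line %d: expected 'ITEM: TIMESTEP'", i),
           call. = FALSE)
    }
    step <- parse_num(trimws(lines[i + 1L]), i + 1L, "timestep")
    if (!grepl("^ITEM: NUMBER OF ATOMS", lines[i + 2L])) {
      stop(sprintf("parse error at line %d: expected 'ITEM: NUMBER OF ATOMS'", i + 2L),
           call. = FALSE)
    }
    nat <- as.integer(parse_num(trimws(lines[i + 3L]), i + 3L, "atom count"))
    if (!grepl("^ITEM: BOX BOUNDS", lines[i + 4L])) {
      stop(sprintf("parse error at line %d: expected 'ITEM: BOX BOUNDS'", i + 4L),
           call. = FALSE)
    }
    if (grepl("xy|xz|yz", lines[i + 4L])) {
      stop(sprintf("parse error at line %d: triclinic boxes are not supported", i + 4L),
           call. = FALSE)
    }
    bounds <- t(vapply(1:3, function(k) {
      parse_num(strsplit(trimws(lines[i + 4L + k]), "[ \t]+")[[1]][1:2],
                i + 4L + k, "box bound")
    }, numeric(2)))
    lo <- bounds[, 1] * scale
    box <- (bounds[, 2] - bounds[, 1]) * scale
    hdr <- i + 8L
    if (!grepl("^ITEM: ATOMS", lines[hdr])) {
      stop(sprintf("parse error at line %d: expected 'ITEM: ATOMS'", hdr),
           call. = FALSE)
    }
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[hdr]), "[ \t]+")[[1]]
    scaled <- all(c("xs", "ys", "zs") %in% cols)
    xyz_cols <- if (scaled) c("xs", "ys", "zs") else c("x", "y", "z")
    need <- c("id", "type", xyz_cols)
    if (!all(need %in% cols)) {
      stop(sprintf("parse error at line %d: dump must provide columns %s",
                   hdr, paste(need, collapse = " ")), call. = FALSE)
    }
    if (hdr + nat > length(lines)) {
      stop(sprintf("parse error at line %d: dump frame shorter than atom count", hdr),
           call. = FALSE)
    }
    fields <- strsplit(trimws(lines[(hdr + 1L):(hdr + nat)]), "[ \t]+")
    if (any(lengths(fields) < length(cols))) {
      bad <- which(lengths(fields) < length(cols))[1]
      stop(sprintf("parse error at line %d: too few fields", hdr + bad),
           call. = FALSE)
    }
    tab <- t(vapply(fields, function(f) f[seq_along(cols)], character(length(cols))))
    colnames(tab) <- cols
    ids <- as.integer(tab[, "id"])
    ord <- order(ids)
    raw_type <- tab[ord, "type"]
    types <- unname(type_map[raw_type])
    if (any(is.na(types))) {
      stop("unknown LAMMPS type label(s): ",
           paste(unique(raw_type[is.na(types)]), collapse = ", "), call. = FALSE)
    }
    pos <- apply(tab[, xyz_cols, drop = FALSE], 2, as.numeric)[ord, , drop = FALSE]
    if (scaled) {
      pos <- sweep(pos, 2, box, `*`)      # fractional -> nm, origin at 0
    } else {
      pos <- sweep(pos * scale, 2, lo, `-`)
    }
    frames[[length(frames) + 1L]] <- bead_frame(pos, types, box, step * timestep)
    i <- hdr + nat + 1L
  }
  if (!length(frames)) stop("no frames found in LAMMPS dump", call. = FALSE)
  frames
}

#' Write a bead frame to disk
#'
#' GRO is written with nm coordinates at three decimals; XYZ and LAMMPS dump
#' are written in Angstrom. Reading back a written frame reproduces
#' coordinates to the format precision (5e-4 nm for GRO).
#'
#' @param frame A [bead_frame()].
#' @param path Output path.
#' @param format One of `"gro"`, `"xyz"`, `"lammps-dump"`; guessed from the
#'   extension when `NULL`.
#' @param append Append to an existing file (multi-frame trajectories).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, format = NULL, append = FALSE) {
  if (!inherits(frame, "bead_frame")) stop("`frame` must be a bead_frame", call. = FALSE)
  if (nrow(frame) == 0L) stop("cannot write an empty frame", call. = FALSE)
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("gro", "lammps-dump", "xyz"))
  box <- frame_box(frame)
  time <- frame_time(frame)
  lines <- switch(format,
    "gro" = {
      n <- nrow(frame)
      atom <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                      rep(1L, n), "VES", frame$type,
                      seq_len(n) %% 100000L, frame$x, frame$y, frame$z)
      c(sprintf("vesishear frame t= %.6f", time),
        sprintf("%5d", n), atom,
        sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
    },
    "xyz" = {
      c(sprintf("%d", nrow(frame)),
        sprintf("time= %.6f box= %.4f,%.4f,%.4f",
                time, box[1] * 10, box[2] * 10, box[3] * 10),
        sprintf("%-2s %12.4f %12.4f %12.4f",
                frame$type, frame$x * 10, frame$y * 10, frame$z * 10))
    },
    "lammps-dump" = {
      inv_map <- c(B = 1L, A = 2L, W = 3L, WF = 4L)
      c("ITEM: TIMESTEP", sprintf("%d", round(time)),
        "ITEM: NUMBER OF ATOMS", sprintf("%d", nrow(frame)),
        "ITEM: BOX BOUNDS pp pp pp",
        sprintf("%.6f %.6f", 0, box[1] * 10),
        sprintf("%.6f %.6f", 0, box[2] * 10),
        sprintf("%.6f %.6f", 0, box[3] * 10),
        "ITEM: ATOMS id type x y z",
        sprintf("%d %d %.4f %.4f %.4f", frame$bead, inv_map[frame$type],
                frame$x * 10, frame$y * 10, frame$z * 10))
    }
  )
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write a chain-topology sidecar table
#'
#' The sidecar is a TSV with columns `chain`, `bead`, `type`, 20 rows per
#' chain in intra-chain order.
#'
#' @param path Path to the TSV file.
#' @return [read_topology()]: a [chain_topology()] tibble.
#' @export
read_topology <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chain", "bead", "type") %in% names(tab))) {
    stop("topology TSV needs columns chain, bead, type", call. = FALSE)
  }
  grp <- factor(tab$chain, levels = unique(tab$chain))
  tab <- tab[order(grp), ]
  chains <- split(tab$bead, factor(tab$chain, levels = unique(tab$chain)))
  topo <- chain_topology(unname(chains))
  if (!all(tab$type == topo$type)) {
    stop("topology TSV types do not follow the B5-A10-B5 pattern", call. = FALSE)
  }
  topo
}

#' @rdname read_topology
#' @param topology A [chain_topology()].
#' @export
write_topology <- function(topology, path) {
  utils::write.table(as.data.frame(topology[, c("chain", "bead", "type")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
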