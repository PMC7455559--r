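#' Atomic structure container
#'
#' A `jl_structure` holds an ordered atom table plus an optional orthorhombic
#' box.  Atom order is stable across read/write round-trips, which the
#' trajectory and pairing machinery rely on.
#'
#' @param atoms A data frame with columns `atom_name`, `element`,
#'   `residue_name`, `residue_id`, `chain_id`, `x`, `y`, `z`, `is_hetero`.
#'   Coordinates are in Angstrom.
#' @param box Optional length-3 numeric vector, box edge lengths in Angstrom.
#' @return An object of class `jl_structure`.
#' @export
jl_structure <- function(atoms, box = NULL) {
  atoms <- as_tibble(atoms)
  needed <- c("atom_name", "element", "residue_name", "residue_id",
              "chain_id", "x", "y", "z", "is_hetero")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!nzchar(atoms$element))) {
    abort("every atom must carry a non-empty element symbol")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("atom positions must be finite")
  }
  if (!is.null(box)) {
    stopifnot(is.numeric(box), length(box) == 3, all(box > 0))
  }
  structure(list(atoms = atoms[, needed], box = box), class = "jl_structure")
}

#' @export
print.jl_structure <- function(x, ...) {
  cat(sprintf("<jl_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain_id", "residue_id")])),
              paste(unique(x$atoms$chain_id), collapse = " ")))
  if (!is.null(x$box)) {
    cat(sprintf("  box: %.1f x %.1f x %.1f A\n", x$box[1], x$box[2], x$box[3]))
  }
  invisible(x)
}

#' @export
as_tibble.jl_structure <- function(x, ...) x$atoms

#' Coordinates of a structure as a matrix
#'
#' @param x A [jl_structure] or `jl_trajectory`.
#' @param frame For trajectories, which frame to extract.
#' @return An n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(x, frame = 1L) {
  if (inherits(x, "jl_structure")) {
    return(unname(as.matrix(x$atoms[, c("x", "y", "z")])))
  }
  if (inherits(x, "jl_trajectory")) {
    return(x$frames[[frame]])
  }
  if (is.matrix(x) && ncol(x) == 3) return(x)
  abort("coords() expects a jl_structure, jl_trajectory, or n x 3 matrix")
}

#' Replace the coordinates of a structure
#' @param x A [jl_structure].
#' @param xyz n x 3 matrix.
#' @return The modified structure.
#' @export
set_coords <- function(x, xyz) {
  stopifnot(inherits(x, "jl_structure"), nrow(xyz) == nrow(x$atoms))
  x$atoms$x <- xyz[, 1]
  x$atoms$y <- xyz[, 2]
  x$atoms$z <- xyz[, 3]
  x
}

guess_element <- function(atom_name) {
  # PDB columns 13-16; two-letter elements are left-justified in 13-14.
  nm <- gsub("[0-9' ]", "", atom_name)
  first <- toupper(substr(nm, 1, 1))
  ifelse(first %in% c("C", "N", "O", "P", "S", "H"), first,
         ifelse(nzchar(nm), substr(nm, 1, 2), "X"))
}

#' Read an atomic structure from a PDB file
#'
#' ATOM and HETATM records are both retained, in file order, with
#' `is_hetero` set.  Multi-model files are refused: use [read_trajectory()]
#' for those.
#'
#' @param path Path to a PDB file.
#' @param format Only `"pdb"` is supported.
#' @return A [jl_structure].
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  head_lines <- readLines(path, warn = FALSE)
  if (any(grepl("^MODEL", head_lines))) {
    abort(paste0(path, " contains MODEL/ENDMDL records; ",
                 "use read_trajectory() for multi-frame files"))
  }
  bad <- grep("^(ATOM|HETATM)", head_lines)
  for (i in bad) {
    ln <- head_lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54)))))) {
      abort(sprintf("malformed coordinate record at line %d of %s", i, path))
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  pdb_to_structure(pdb)
}

pdb_to_structure <- function(pdb) {
  a <- pdb$atom
  elem <- a$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- guess_element(a$elety[blank])
  chain <- a$chain
  chain[is.na(chain)] <- " "
  jl_structure(tibble(
    atom_name = a$elety,
    element = trimws(elem),
    residue_name = a$resid,
    residue_id = a$resno,
    chain_id = chain,
    x = a$x, y = a$y, z = a$z,
    is_hetero = a$type == "HETATM"
  ))
}

#' Write a structure to a PDB file
#'
#' @param x A [jl_structure].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "jl_structure"))
  writeLines(pdb_lines(x$atoms, coords(x)), path)
  invisible(path)
}

pdb_lines <- function(atoms, xyz, model = NULL) {
  rec <- ifelse(atoms$is_hetero, "HETATM", "ATOM  ")
  name <- vapply(atoms$atom_name, function(n) {
    # standard PDB alignment: 1-3 char names start in column 14
    if (nchar(n) >= 4) substr(n, 1, 4) else sprintf(" %-3s", n)
  }, character(1))
  lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec,
                   (seq_len(nrow(atoms)) - 1L) %% 99999L + 1L,
                   name,
                   substr(atoms$residue_name, 1, 3),
                   substr(atoms$chain_id, 1, 1),
                   atoms$residue_id %% 10000L,
                   xyz[, 1], xyz[, 2], xyz[, 3],
                   1, 0,
                   atoms$element)
  if (!is.null(model)) {
    lines <- c(sprintf("MODEL     %4d", model), lines, "ENDMDL")
  }
  lines
}

#' Trajectory container
#'
#' @param topology A [jl_structure] providing atom identities.
#' @param frames List of n_atoms x 3 coordinate matrices (Angstrom).
#' @param dt_ns Time per frame in nanoseconds (default 0.1).
#' @return An object of class `jl_trajectory`.
#' @export
jl_trajectory <- function(topology, frames, dt_ns = 0.1) {
  stopifnot(inherits(topology, "jl_structure"), is.list(frames),
            length(frames) >= 1)
  if (!is.numeric(dt_ns) || length(dt_ns) != 1 || dt_ns <= 0) {
    abort("dt_ns must be a single positive number")
  }
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3 || nrow(f) != n) {
      abort(sprintf("frame %d has %s atoms; topology has %d",
                    i, if (is.matrix(f)) nrow(f) else "?", n))
    }
  }
  structure(list(topology = topology, frames = frames, dt_ns = dt_ns),
            class = "jl_trajectory")
}

#' @export
print.jl_trajectory <- function(x, ...) {
  cat(sprintf("<jl_trajectory> %d frames x %d atoms, dt = %g ns (%.1f ns total)\n",
              length(x$frames), nrow(x$topology$atoms), x$dt_ns,
              length(x$frames) * x$dt_ns))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [jl_trajectory].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Read a coordinate trajectory
#'
#' Multi-model PDB is the canonical interchange format; DCD is accepted via
#' bio3d when a topology is supplied.  Frames are returned in stored order.
#'
#' @param path Path to a multi-model PDB or DCD file.
#' @param format `"pdb"` or `"dcd"` (guessed from the extension by default).
#' @param topology Optional [jl_structure]; required for DCD, otherwise
#'   taken from the first model.
#' @param dt_ns Time per frame in ns; defaults to 0.1.
#' @return A [jl_trajectory].
#' @export
read_trajectory <- function(path, format = NULL, topology = NULL,
                            dt_ns = 0.1) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(format)) {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  format <- match.arg(format, c("pdb", "dcd"))
  if (format == "dcd") {
    if (is.null(topology)) abort("DCD trajectories require a topology")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    frames <- lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    })
    n <- nrow(topology$atoms)
    for (i in seq_along(frames)) {
      if (nrow(frames[[i]]) != n) {
        abort(sprintf("frame %d has %d atoms; topology has %d",
                      i, nrow(frames[[i]]), n))
      }
    }
    return(jl_trajectory(topology, frames, dt_ns))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- topology %||% pdb_to_structure(pdb)
  n <- nrow(topo$atoms)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != n) {
      abort(sprintf("frame %d has %d atoms; topology has %d",
                    i, nrow(frames[[i]]), n))
    }
  }
  jl_trajectory(topo, frames, dt_ns)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A [jl_trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "jl_trajectory"))
  atoms <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    writeLines(pdb_lines(atoms, traj$frames[[i]], model = i), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atom indices from a structure
#'
#' Tidy-style helper: the expression is evaluated in the atom table, so
#' `select_atoms(s, element != "H" & !is_hetero)` works like a
#' [dplyr::filter()] predicate but returns integer indices.
#'
#' @param x A [jl_structure].
#' @param expr Logical predicate on the atom columns.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(x, expr) {
  stopifnot(inherits(x, "jl_structure"))
  keep <- rlang::eval_tidy(rlang::enquo(expr), data = x$atoms)
  which(keep)
}

resolve_selection <- function(x, selection) {
  n <- nrow(x$atoms)
  if (is.logical(selection)) {
    stopifnot(length(selection) == n)
    return(which(selection))
  }
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.function(selection)) {
    keep <- selection(x$atoms)
    if (is.logical(keep)) return(which(keep))
    return(as.integer(keep))
  }
  abort("selection must be a logical mask, integer indices, or a function")
}
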