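WATER_RESNAMES <- c("HOH", "WAT", "TIP3")

#' Construct a molecular structure object
#'
#' A `structure3d` holds an ordered atom table for a single conformation.
#' All coordinates are in Angstrom. Atom order is significant and preserved
#' by every operation in the package.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `residue_name`,
#'   `chain_id`, `residue_seq`, `x`, `y`, `z`, `element` (and optionally
#'   `altloc`, `occupancy`).
#' @param title optional title string.
#' @param water_names residue names recognized as water.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, title = "", water_names = WATER_RESNAMES) {
  required <- c("serial", "atom_name", "residue_name", "chain_id",
                "residue_seq", "x", "y", "z", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  atoms$is_water <- atoms$residue_name %in% water_names
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name, atoms$altloc)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom, altloc) in atom table: ",
         key[anyDuplicated(key)])
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain_id", "residue_seq")])),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Coordinates of a structure as an N x 3 matrix
#' @param x a `structure3d`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(x) {
  UseMethod("coords")
}

#' @export
coords.structure3d <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param x a `structure3d`.
#' @param value N x 3 numeric matrix.
#' @return modified structure.
#' @export
set_coords <- function(x, value) {
  stopifnot(inherits(x, "structure3d"), is.matrix(value),
            nrow(value) == nrow(x$atoms), ncol(value) == 3L)
  x$atoms$x <- value[, 1L]
  x$atoms$y <- value[, 2L]
  x$atoms$z <- value[, 3L]
  x
}

#' Atom roster (atom table without coordinates)
#' @param x a `structure3d` or `frame_source`.
#' @return data.frame describing the atoms.
#' @export
roster <- function(x) {
  if (inherits(x, "frame_source")) return(x$roster)
  x$atoms[, setdiff(names(x$atoms), c("x", "y", "z"))]
}

## ---- PDB v3 fixed-column parsing --------------------------------------

parse_pdb_atom_lines <- function(lines, lineno) {
  substr_trim <- function(s, a, b) trimws(substr(s, a, b))
  n <- length(lines)
  serial <- suppressWarnings(as.integer(substr_trim(lines, 7, 11)))
  x <- suppressWarnings(as.numeric(substr_trim(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr_trim(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr_trim(lines, 47, 54)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad) > 0L) {
    stop(sprintf("malformed PDB coordinate record at line %d: '%s'",
                 lineno[bad[1L]], lines[bad[1L]]))
  }
  occ <- suppressWarnings(as.numeric(substr_trim(lines, 55, 60)))
  occ[!is.finite(occ)] <- 1
  data.frame(
    serial = ifelse(is.na(serial), seq_len(n), serial),
    atom_name = substr_trim(lines, 13, 16),
    altloc = substr_trim(lines, 17, 17),
    residue_name = substr_trim(lines, 18, 20),
    chain_id = substr_trim(lines, 22, 22),
    residue_seq = suppressWarnings(as.integer(substr_trim(lines, 23, 26))),
    x = x, y = y, z = z,
    occupancy = occ,
    element = substr_trim(lines, 77, 78),
    stringsAsFactors = FALSE
  )
}

resolve_altlocs <- function(atoms) {
  if (all(atoms$altloc %in% c("", "A"))) {
    atoms$altloc <- ""
    return(atoms)
  }
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name)
  keep <- logical(nrow(atoms))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
    } else {
      # highest occupancy wins; ties resolved to the first listed
      best <- idx[which.max(atoms$occupancy[idx])]
      keep[best] <- TRUE
    }
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- ""
  atoms
}

infer_element <- function(atoms) {
  blank <- atoms$element == ""
  if (any(blank)) {
    nm <- atoms$atom_name[blank]
    first <- sub("^[0-9]*", "", nm)
    atoms$element[blank] <- substr(first, 1, 1)
  }
  atoms
}

#' Read a structure from a PDB file
#'
#' Parses ATOM and HETATM records (PDB v3 fixed columns). Alternate locations
#' are resolved to the highest-occupancy copy (ties go to the first listed).
#' Water residues (HOH/WAT/TIP3) are flagged. For multi-model files only the
#' first model is returned; use [read_frames()] for trajectories.
#'
#' @param path path to a PDB file.
#' @return a [structure3d()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PDB file: ", path)
  rec <- substr(lines, 1, 6)
  endmdl <- which(trimws(rec) == "ENDMDL")
  last <- if (length(endmdl) > 0L) endmdl[1L] else length(lines)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  sel <- sel[sel <= last]
  if (length(sel) == 0L) stop("no ATOM/HETATM records in ", path)
  atoms <- parse_pdb_atom_lines(lines[sel], sel)
  atoms <- resolve_altlocs(atoms)
  atoms <- infer_element(atoms)
  title <- trimws(sub("^TITLE ", "", lines[trimws(rec) == "TITLE"][1]))
  if (is.na(title) || length(title) == 0L) title <- ""
  structure3d(atoms, title = title)
}

format_pdb_atom_lines <- function(atoms) {
  name4 <- vapply(atoms$atom_name, function(nm) {
    # PDB v3: atom names of <4 chars start in column 14 unless 2-char element
    if (nchar(nm) >= 4L) nm else sprintf(" %-3s", nm)
  }, character(1))
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, name4, "", atoms$residue_name,
          atoms$chain_id, atoms$residue_seq,
          atoms$x, atoms$y, atoms$z, atoms$occupancy, 0, atoms$element)
}

#' Write a structure to a PDB file
#' @param x a `structure3d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "structure3d"))
  lines <- c(if (nzchar(x$title)) paste("TITLE ", x$title),
             format_pdb_atom_lines(x$atoms), "END")
  writeLines(lines, path)
  invisible(path)
}

## ---- FrameSource -------------------------------------------------------

#' Construct a trajectory frame source
#'
#' A `frame_source` couples one atom roster with an `N x 3 x n_frames`
#' coordinate array. Every frame shares the roster; [get_frame()] is
#' reproducible (two reads of the same index are identical).
#'
#' @param roster atom table (as from [roster()]), without coordinates.
#' @param coords_array numeric array of dimension `c(n_atoms, 3, n_frames)`.
#' @param frame_interval time between saved frames, ps (metadata).
#' @return object of class `frame_source`.
#' @export
frame_source <- function(roster, coords_array, frame_interval = 200) {
  stopifnot(is.array(coords_array), length(dim(coords_array)) == 3L)
  if (dim(coords_array)[1L] != nrow(roster) || dim(coords_array)[2L] != 3L) {
    stop("coords_array must be n_atoms x 3 x n_frames matching the roster")
  }
  if (dim(coords_array)[3L] < 1L) stop("a frame source needs >= 1 frame")
  if (!all(is.finite(coords_array))) stop("non-finite coordinates in frames")
  rownames(roster) <- NULL
  structure(list(roster = roster, coords = coords_array,
                 n_frames = dim(coords_array)[3L],
                 frame_interval = frame_interval),
            class = "frame_source")
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("<frame_source> %d frames x %d atoms (dt = %g ps)\n",
              x$n_frames, nrow(x$roster), x$frame_interval))
  invisible(x)
}

#' Number of frames in a frame source
#' @param x a `frame_source`.
#' @export
n_frames <- function(x) x$n_frames

#' Extract one frame's coordinates
#' @param x a `frame_source`.
#' @param i frame index (1-based).
#' @return N x 3 coordinate matrix.
#' @export
get_frame <- function(x, i) {
  stopifnot(inherits(x, "frame_source"))
  if (i < 1L || i > x$n_frames) stop("frame index out of range: ", i)
  m <- x$coords[, , i]
  dim(m) <- c(nrow(x$roster), 3L)
  m
}

#' Materialize one frame as a structure
#' @param x a `frame_source`.
#' @param i frame index.
#' @return a [structure3d()].
#' @export
frame_structure <- function(x, i) {
  m <- get_frame(x, i)
  atoms <- x$roster
  atoms$x <- m[, 1L]; atoms$y <- m[, 2L]; atoms$z <- m[, 3L]
  structure3d(atoms)
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame. The atom roster is taken from
#' the first model; any later model whose atoms differ in count or identity
#' is an error naming the offending model. A file without MODEL records is
#' read as a single-frame trajectory.
#'
#' @param path path to a multi-model PDB file.
#' @param format only `"pdb"` is supported.
#' @param frame_interval time per frame, ps (metadata).
#' @return a [frame_source()].
#' @export
read_frames <- function(path, format = "pdb", frame_interval = 200) {
  if (!identical(format, "pdb")) {
    stop("unsupported trajectory format: ", format,
         " (multi-model PDB is the supported interchange format)")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  starts <- which(rec == "MODEL")
  is_atom <- rec %in% c("ATOM", "HETATM")
  if (length(starts) == 0L) {
    if (!any(is_atom)) stop("no models and no atoms in ", path)
    s <- read_pdb(path)
    arr <- array(coords(s), dim = c(nrow(s$atoms), 3L, 1L))
    return(frame_source(roster(s), arr, frame_interval))
  }
  ends <- which(rec == "ENDMDL")
  if (length(ends) != length(starts)) {
    stop("unbalanced MODEL/ENDMDL records in ", path)
  }
  ref_atoms <- NULL
  arr <- NULL
  for (m in seq_along(starts)) {
    idx <- which(is_atom & seq_along(lines) > starts[m] &
                   seq_along(lines) < ends[m])
    atoms <- parse_pdb_atom_lines(lines[idx], idx)
    if (m == 1L) {
      atoms <- resolve_altlocs(atoms)
      atoms <- infer_element(atoms)
      ref_atoms <- atoms
      arr <- array(NA_real_, dim = c(nrow(atoms), 3L, length(starts)))
      arr[, , 1L] <- as.matrix(atoms[, c("x", "y", "z")])
    } else {
      if (nrow(atoms) != nrow(ref_atoms)) {
        stop(sprintf("model %d has %d atoms but model 1 has %d", m,
                     nrow(atoms), nrow(ref_atoms)))
      }
      same <- all(atoms$atom_name == ref_atoms$atom_name) &&
        all(atoms$residue_seq == ref_atoms$residue_seq) &&
        all(atoms$chain_id == ref_atoms$chain_id)
      if (!same) stop(sprintf("model %d atom roster differs from model 1", m))
      arr[, , m] <- as.matrix(atoms[, c("x", "y", "z")])
    }
  }
  ref <- ref_atoms[, setdiff(names(ref_atoms), c("x", "y", "z"))]
  ref$is_water <- ref$residue_name %in% WATER_RESNAMES
  frame_source(ref, arr, frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#' @param x a `frame_source`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path) {
  stopifnot(inherits(x, "frame_source"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(x$n_frames)) {
    s <- frame_structure(x, i)
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(format_pdb_atom_lines(s$atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
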