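BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Resolve an atom selection against a roster
#'
#' The selection grammar is a conjunction of clauses joined by `" and "`:
#'
#' * `resid 110-118` or `resid 114` or `resid 110-112,114` — author residue
#'   numbers (ranges and comma lists);
#' * `name CA` or `name N,CA,C,O` — PDB v3 atom names;
#' * `chain A` — chain identifier;
#' * `element O` — element symbol;
#' * `backbone` / `backbone-heavy` — the four heavy backbone atoms
#'   N, CA, C, O;
#' * `water` / `protein` — water residues (HOH/WAT/TIP3) or everything else.
#'
#' Resolution is deterministic (indices follow roster order) and total: a
#' clause that names a residue or atom absent from the roster is an error
#' listing what was not found, never a silent skip. An empty final
#' intersection is also an error.
#'
#' @param spec selection string.
#' @param roster atom roster (from [roster()]) or a `structure3d` /
#'   `frame_source`, which is coerced.
#' @return integer vector of atom indices (roster order), with the spec
#'   attached as attribute `"spec"`.
#' @export
resolve_selection <- function(spec, roster) {
  if (inherits(roster, "structure3d") || inherits(roster, "frame_source")) {
    roster <- roster(roster)
  }
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec))
  clauses <- trimws(strsplit(spec, "\\s+and\\s+")[[1]])
  keep <- rep(TRUE, nrow(roster))
  for (cl in clauses) {
    if (cl == "backbone" || cl == "backbone-heavy") {
      keep <- keep & roster$atom_name %in% BACKBONE_ATOMS
    } else if (cl == "water") {
      keep <- keep & roster$is_water
    } else if (cl == "protein") {
      keep <- keep & !roster$is_water
    } else if (grepl("^resid\\s+", cl)) {
      wanted <- parse_resid_list(sub("^resid\\s+", "", cl))
      missing <- setdiff(wanted, roster$residue_seq[keep])
      if (length(missing) > 0L) {
        stop(sprintf("selection '%s': residue(s) not found: %s", spec,
                     paste(missing, collapse = ", ")))
      }
      keep <- keep & roster$residue_seq %in% wanted
    } else if (grepl("^name\\s+", cl)) {
      wanted <- trimws(strsplit(sub("^name\\s+", "", cl), ",")[[1]])
      missing <- setdiff(wanted, roster$atom_name[keep])
      if (length(missing) > 0L) {
        stop(sprintf("selection '%s': atom name(s) not found: %s", spec,
                     paste(missing, collapse = ", ")))
      }
      keep <- keep & roster$atom_name %in% wanted
    } else if (grepl("^chain\\s+", cl)) {
      wanted <- trimws(strsplit(sub("^chain\\s+", "", cl), ",")[[1]])
      missing <- setdiff(wanted, roster$chain_id[keep])
      if (length(missing) > 0L) {
        stop(sprintf("selection '%s': chain(s) not found: %s", spec,
                     paste(missing, collapse = ", ")))
      }
      keep <- keep & roster$chain_id %in% wanted
    } else if (grepl("^element\\s+", cl)) {
      wanted <- trimws(strsplit(sub("^element\\s+", "", cl), ",")[[1]])
      keep <- keep & roster$element %in% wanted
    } else {
      stop("unparseable selection clause: '", cl, "'")
    }
  }
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop(sprintf("selection '%s' matched no atoms", spec))
  }
  structure(idx, spec = spec)
}

parse_resid_list <- function(txt) {
  parts <- trimws(strsplit(txt, ",")[[1]])
  out <- integer(0)
  for (p in parts) {
    if (grepl("^-?[0-9]+\\s*-\\s*-?[0-9]+$", p) && grepl("[0-9]-", p)) {
      m <- regmatches(p, regexec("^(-?[0-9]+)\\s*-\\s*(-?[0-9]+)$", p))[[1]]
      out <- c(out, as.integer(m[2]):as.integer(m[3]))
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop("unparseable residue token: '", p, "'")
    }
  }
  unique(out)
}

#' Coordinates of exactly one atom
#'
#' Convenience wrapper used by the pairwise metrics: resolves `spec` and
#' errors unless it names exactly one atom.
#'
#' @param frame a `structure3d`.
#' @param spec selection string, e.g. `"resid 114 and name OH"`.
#' @return length-3 numeric vector.
#' @export
atom_coord <- function(frame, spec) {
  idx <- resolve_selection(spec, frame)
  if (length(idx) != 1L) {
    stop(sprintf("selection '%s' must name exactly one atom (matched %d)",
                 spec, length(idx)))
  }
  as.numeric(coords(frame)[idx, ])
}

## ---- Ballesteros-Weinstein mapping ------------------------------------

#' Ballesteros-Weinstein residue code map
#'
#' Maps author residue numbers to generic class-A GPCR codes (e.g. 103 ->
#' "3.49", 114 -> "34.53"). The mapping must be injective per chain.
#'
#' @param residue_seq integer vector of author residue numbers.
#' @param bw_code character vector of BW codes, same length.
#' @param chain_id chain the map applies to (default "A").
#' @return object of class `bw_map`.
#' @export
bw_map <- function(residue_seq, bw_code, chain_id = "A") {
  stopifnot(length(residue_seq) == length(bw_code))
  if (anyDuplicated(residue_seq) || anyDuplicated(bw_code)) {
    stop("BW map must be injective: duplicated residue number or code")
  }
  structure(list(residue_seq = as.integer(residue_seq),
                 bw_code = as.character(bw_code),
                 chain_id = chain_id),
            class = "bw_map")
}

#' Translate BW codes to author residue numbers
#' @param map a [bw_map()].
#' @param code character vector of BW codes.
#' @return integer vector of residue numbers.
#' @export
bw_to_resid <- function(map, code) {
  stopifnot(inherits(map, "bw_map"))
  i <- match(code, map$bw_code)
  if (anyNA(i)) {
    stop("BW code(s) not in map: ", paste(code[is.na(i)], collapse = ", "))
  }
  map$residue_seq[i]
}

#' Translate author residue numbers to BW codes
#' @param map a [bw_map()].
#' @param residue_seq integer vector of residue numbers.
#' @return character vector of BW codes.
#' @export
resid_to_bw <- function(map, residue_seq) {
  stopifnot(inherits(map, "bw_map"))
  i <- match(as.integer(residue_seq), map$residue_seq)
  if (anyNA(i)) {
    stop("residue(s) not in BW map: ",
         paste(residue_seq[is.na(i)], collapse = ", "))
  }
  map$bw_code[i]
}
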