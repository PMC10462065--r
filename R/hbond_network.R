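#' Geometric hydrogen-bond criteria
#'
#' The defaults are the standard geometric criterion used by contact-analysis
#' tools: donor-acceptor heavy-atom distance <= 3.5 Angstrom and, when
#' explicit hydrogens are present, a D-H...A angle >= 110 degrees. Crystal
#' structures and heavy-atom trajectories use `heavy_only = TRUE`, where the
#' distance test alone applies.
#'
#' @param da_cutoff maximum donor-acceptor distance, Angstrom.
#' @param dha_min_angle minimum D-H...A angle, degrees.
#' @param heavy_only if `TRUE`, ignore hydrogens and use the distance test.
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(da_cutoff = 3.5, dha_min_angle = 110,
                           heavy_only = FALSE) {
  stopifnot(da_cutoff > 0, dha_min_angle >= 0, dha_min_angle <= 180)
  structure(list(da_cutoff = da_cutoff, dha_min_angle = dha_min_angle,
                 heavy_only = heavy_only), class = "hbond_criteria")
}

# hydrogens within this distance of a heavy atom are treated as bonded to it
H_ATTACH_CUTOFF <- 1.25

attached_hydrogens <- function(frame_coords, roster, donor_idx) {
  h_idx <- which(roster$element == "H")
  if (length(h_idx) == 0L) return(integer(0))
  same_res <- roster$chain_id[h_idx] == roster$chain_id[donor_idx] &
    roster$residue_seq[h_idx] == roster$residue_seq[donor_idx]
  h_idx <- h_idx[same_res]
  if (length(h_idx) == 0L) return(integer(0))
  d <- sqrt(colSums((t(frame_coords[h_idx, , drop = FALSE]) -
                       frame_coords[donor_idx, ])^2))
  h_idx[d <= H_ATTACH_CUTOFF]
}

vec_angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

#' Detect hydrogen bonds between donor and acceptor selections
#'
#' Reports every donor-acceptor atom pair (donor != acceptor) whose
#' heavy-atom distance is within `criteria$da_cutoff` and, unless running in
#' heavy-only mode, for which some hydrogen attached to the donor satisfies
#' the D-H...A angle criterion. Each qualifying pair is reported once per
#' frame regardless of how many hydrogens realize it.
#'
#' @param frame a `structure3d`.
#' @param donors_spec,acceptors_spec selection strings for candidate donor
#'   and acceptor heavy atoms (N/O chemistry is the caller's choice of
#'   selection; see [default_polar_spec()]).
#' @param criteria an [hbond_criteria()].
#' @return data.frame with columns `donor_idx`, `acceptor_idx`, `donor`,
#'   `acceptor`, `da_distance`, `dha_angle` (NA in heavy-only mode).
#' @export
detect_hbonds <- function(frame, donors_spec, acceptors_spec,
                          criteria = hbond_criteria()) {
  ros <- roster(frame)
  xyz <- coords(frame)
  di <- resolve_selection(donors_spec, ros)
  ai <- resolve_selection(acceptors_spec, ros)
  if (!criteria$heavy_only) {
    has_h <- vapply(di, function(i)
      length(attached_hydrogens(xyz, ros, i)) > 0L, logical(1))
    if (any(!has_h)) {
      stop("donor(s) without attached hydrogens (e.g. ",
           atom_label(ros, di[!has_h][1L]),
           "); re-run with heavy_only = TRUE for heavy-atom structures")
    }
  }
  out <- list()
  dmat <- outer_dist(xyz[di, , drop = FALSE], xyz[ai, , drop = FALSE])
  hits <- which(dmat <= criteria$da_cutoff, arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    d_idx <- di[hits[k, 1L]]
    a_idx <- ai[hits[k, 2L]]
    if (d_idx == a_idx) next
    angle <- NA_real_
    if (!criteria$heavy_only) {
      hs <- attached_hydrogens(xyz, ros, d_idx)
      angs <- vapply(hs, function(h)
        vec_angle_deg(xyz[d_idx, ] - xyz[h, ], xyz[a_idx, ] - xyz[h, ]),
        numeric(1))
      if (!any(angs >= criteria$dha_min_angle)) next
      angle <- max(angs)
    }
    out[[length(out) + 1L]] <- data.frame(
      donor_idx = d_idx, acceptor_idx = a_idx,
      donor = atom_label(ros, d_idx), acceptor = atom_label(ros, a_idx),
      da_distance = dmat[hits[k, 1L], hits[k, 2L]], dha_angle = angle,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(donor_idx = integer(0), acceptor_idx = integer(0),
                      donor = character(0), acceptor = character(0),
                      da_distance = numeric(0), dha_angle = numeric(0)))
  }
  do.call(rbind, out)
}

outer_dist <- function(a, b) {
  # pairwise Euclidean distances between rows of a and rows of b
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

atom_label <- function(ros, i) {
  sprintf("%s%d:%s", ros$residue_name[i], ros$residue_seq[i], ros$atom_name[i])
}

#' Default polar-atom selection for hydrogen-bond chemistry
#'
#' Nitrogen and oxygen atoms act as both donors (when carrying a hydrogen,
#' or always in heavy-only mode) and acceptors. Shipped as a selection
#' string so callers can replace the chemistry without touching code.
#'
#' @return a selection string.
#' @export
default_polar_spec <- function() "element N,O"

#' Detect water-mediated hydrogen-bond bridges
#'
#' A bridge is reported for every water residue whose water oxygen forms a
#' hydrogen bond (either polarity) with some atom of `partner_a_spec` and
#' some atom of `partner_b_spec` in the same frame. One bridge per water
#' residue per frame; the first qualifying partner atoms are recorded.
#'
#' @param frame a `structure3d` containing water residues.
#' @param partner_a_spec,partner_b_spec selections for the two bridged
#'   partners (polar atoms).
#' @param criteria an [hbond_criteria()]; bridges use the distance test on
#'   the water oxygen (water hydrogen geometry is rarely meaningful in
#'   heavy-atom trajectories), so `heavy_only` is implied here.
#' @return data.frame with columns `water_chain`, `water_resid`,
#'   `partner_a`, `partner_b`.
#' @export
detect_water_bridges <- function(frame, partner_a_spec, partner_b_spec,
                                 criteria = hbond_criteria()) {
  ros <- roster(frame)
  xyz <- coords(frame)
  w_o <- which(ros$is_water & ros$element == "O")
  if (length(w_o) == 0L) {
    warning("no water oxygens in roster; returning zero bridges")
    return(data.frame(water_chain = character(0), water_resid = integer(0),
                      partner_a = character(0), partner_b = character(0)))
  }
  pa <- resolve_selection(partner_a_spec, ros)
  pb <- resolve_selection(partner_b_spec, ros)
  da <- outer_dist(xyz[w_o, , drop = FALSE], xyz[pa, , drop = FALSE])
  db <- outer_dist(xyz[w_o, , drop = FALSE], xyz[pb, , drop = FALSE])
  out <- list()
  for (k in seq_along(w_o)) {
    ja <- which(da[k, ] <= criteria$da_cutoff & pa != w_o[k])
    jb <- which(db[k, ] <= criteria$da_cutoff & pb != w_o[k])
    # the two bridged partners must be distinct atoms
    ok <- length(ja) > 0L && length(jb) > 0L &&
      !(length(ja) == 1L && length(jb) == 1L && pa[ja] == pb[jb])
    if (!ok) next
    # pick the first pair of distinct partner atoms
    pair <- NULL
    for (a_ in ja) {
      bset <- jb[pb[jb] != pa[a_]]
      if (length(bset) > 0L) { pair <- c(pa[a_], pb[bset[1L]]); break }
    }
    if (is.null(pair)) next
    out[[length(out) + 1L]] <- data.frame(
      water_chain = ros$chain_id[w_o[k]],
      water_resid = ros$residue_seq[w_o[k]],
      partner_a = atom_label(ros, pair[1L]),
      partner_b = atom_label(ros, pair[2L]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(water_chain = character(0), water_resid = integer(0),
                      partner_a = character(0), partner_b = character(0)))
  }
  do.call(rbind, out)
}

#' Fraction-of-frames interaction frequency across replicas
#'
#' For each named atom pair, counts a frame as positive when a direct
#' hydrogen bond (either polarity) or a water-mediated bridge between the
#' two selections is present, divides by the number of counted frames per
#' replica, and summarizes across replicas as mean and 68% confidence
#' half-width (standard error of the replica means).
#'
#' @param replicas list of [frame_source()] objects.
#' @param pair_specs named list; each element is `list(a = <spec>, b =
#'   <spec>)`. Names become row labels.
#' @param criteria an [hbond_criteria()].
#' @param frame_masks optional list (one logical vector per replica) marking
#'   frames to count, e.g. "folded ICL2 only". Replicas left with zero
#'   counted frames are excluded with a warning.
#' @param include_water if `TRUE` (default) water bridges count.
#' @return data.frame (class `frequency_table`) with one row per pair:
#'   `pair`, `mean`, `ci68`, `n_replicas`; per-replica fractions are in
#'   `attr(, "per_replica")`.
#' @export
interaction_frequency <- function(replicas, pair_specs,
                                  criteria = hbond_criteria(heavy_only = TRUE),
                                  frame_masks = NULL, include_water = TRUE) {
  stopifnot(length(replicas) >= 1L, length(pair_specs) >= 1L)
  if (is.null(names(pair_specs))) {
    names(pair_specs) <- vapply(pair_specs, function(p)
      paste(p$a, "--", p$b), character(1))
  }
  frac <- matrix(NA_real_, nrow = length(pair_specs), ncol = length(replicas),
                 dimnames = list(names(pair_specs), NULL))
  for (r in seq_along(replicas)) {
    fs <- replicas[[r]]
    mask <- if (is.null(frame_masks)) rep(TRUE, fs$n_frames) else frame_masks[[r]]
    if (length(mask) != fs$n_frames) {
      stop("frame mask length does not match frame count in replica ", r)
    }
    counted <- which(mask)
    if (length(counted) == 0L) {
      warning("replica ", r, " has zero counted frames; excluded")
      next
    }
    hits <- matrix(0L, nrow = length(pair_specs), ncol = length(counted))
    for (ci in seq_along(counted)) {
      fr <- frame_structure(fs, counted[ci])
      for (p in seq_along(pair_specs)) {
        ps <- pair_specs[[p]]
        direct <- pair_hbond_present(fr, ps$a, ps$b, criteria)
        bridged <- FALSE
        if (!direct && include_water && any(fs$roster$is_water)) {
          bridged <- nrow(detect_water_bridges(fr, ps$a, ps$b, criteria)) > 0L
        }
        hits[p, ci] <- as.integer(direct || bridged)
      }
    }
    frac[, r] <- rowMeans(hits)
  }
  used <- colSums(!is.na(frac)) > 0
  if (!any(used)) stop("all replicas excluded: no counted frames anywhere")
  frac <- frac[, used, drop = FALSE]
  out <- data.frame(
    pair = rownames(frac),
    mean = rowMeans(frac),
    ci68 = apply(frac, 1L, sem),
    n_replicas = ncol(frac),
    stringsAsFactors = FALSE)
  attr(out, "per_replica") <- frac
  class(out) <- c("frequency_table", "data.frame")
  out
}

pair_hbond_present <- function(frame, spec_a, spec_b, criteria) {
  ros <- roster(frame); xyz <- coords(frame)
  ia <- resolve_selection(spec_a, ros)
  ib <- resolve_selection(spec_b, ros)
  d <- outer_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  same <- outer(ia, ib, "==")
  within <- d <= criteria$da_cutoff & !same
  if (criteria$heavy_only) return(any(within))
  # with hydrogens, require the angle test with either atom as donor
  hit <- which(within, arr.ind = TRUE)
  for (k in seq_len(nrow(hit))) {
    a_idx <- ia[hit[k, 1L]]; b_idx <- ib[hit[k, 2L]]
    for (dn in list(c(a_idx, b_idx), c(b_idx, a_idx))) {
      hs <- attached_hydrogens(xyz, ros, dn[1L])
      if (length(hs) == 0L) next
      angs <- vapply(hs, function(h)
        vec_angle_deg(xyz[dn[1L], ] - xyz[h, ], xyz[dn[2L], ] - xyz[h, ]),
        numeric(1))
      if (any(angs >= criteria$dha_min_angle)) return(TRUE)
    }
  }
  FALSE
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1L) return(0)
  stats::sd(x) / sqrt(length(x))
}
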