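#' Vertical shift of TM5 relative to TM4
#'
#' Projects the C-alpha of a TM5 residue (default 190) onto the line through
#' the C-alpha atoms of two TM4 residues (default 130 and 141) and reports
#' the signed position of the projection along the 130 -> 141 unit vector,
#' minus the same quantity in `ref_zero`. With the TM4 axis pointing toward
#' the extracellular side, positive values mean an upward (extracellular)
#' shift of TM5; the reference structure reads 0 by convention.
#'
#' @param frame a `structure3d`.
#' @param ref_zero reference `structure3d` that defines the zero point.
#' @param tm5_resid TM5 residue whose C-alpha is projected (default 190).
#' @param tm4_resids the two TM4 residues defining the axis (default
#'   `c(130, 141)`).
#' @param chain chain id holding these residues (default "A").
#' @return signed shift in Angstrom.
#' @export
tm5_vertical_shift <- function(frame, ref_zero, tm5_resid = 190,
                               tm4_resids = c(130, 141), chain = "A") {
  proj <- function(s) {
    a <- atom_coord(s, sprintf("chain %s and resid %d and name CA", chain, tm4_resids[1]))
    b <- atom_coord(s, sprintf("chain %s and resid %d and name CA", chain, tm4_resids[2]))
    p <- atom_coord(s, sprintf("chain %s and resid %d and name CA", chain, tm5_resid))
    u <- b - a
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) stop("zero-length TM4 axis (residues ",
                        tm4_resids[1], "-", tm4_resids[2], ")")
    sum((p - a) * u) / nu
  }
  proj(frame) - proj(ref_zero)
}

#' Distance between two named atoms
#'
#' Plain Euclidean distance; invariant to any rigid motion of the frame.
#'
#' @param frame a `structure3d`.
#' @param spec_a,spec_b selection strings each resolving to exactly one atom.
#' @return distance in Angstrom.
#' @export
pair_distance <- function(frame, spec_a, spec_b) {
  a <- atom_coord(frame, spec_a)
  b <- atom_coord(frame, spec_b)
  sqrt(sum((a - b)^2))
}

#' Rotation angle of the ICL2 helix about its axis
#'
#' On a frame already aligned to the reference on the TM1-4 fit set (so the
#' ICL2 helical axis lies approximately along x), draws the vector from the
#' L112 side-chain CG atom to the Y114 side-chain OH atom, projects it onto
#' the reference (y, z) plane and measures the unit-circle angle
#' `atan2(v_z, v_y)` in degrees. The raw angle is returned; subtract the
#' reference structure's raw angle to get the displayed-trace convention in
#' which the starting crystal structure reads 0.
#'
#' @param aligned_frame a `structure3d`, pre-aligned on TM1-4.
#' @param oh_spec,cg_spec selections for the two vector endpoints.
#' @param min_proj minimum in-plane length (Angstrom) below which the angle
#'   is flagged unreliable (vector nearly parallel to the helical axis).
#' @return list with `raw` (degrees in (-180, 180]) and `reliable` (logical).
#' @export
icl2_rotation_angle <- function(aligned_frame,
                                oh_spec = "resid 114 and name OH",
                                cg_spec = "resid 112 and name CG",
                                min_proj = 0.1) {
  oh <- atom_coord(aligned_frame, oh_spec)
  cg <- atom_coord(aligned_frame, cg_spec)
  v <- oh - cg
  plane_len <- sqrt(v[2]^2 + v[3]^2)
  ang <- atan2(v[3], v[2]) * 180 / pi
  list(raw = ang, reliable = plane_len >= min_proj)
}

#' Locally superposed backbone RMSD of the ICL2 segment
#'
#' RMSD over the heavy backbone atoms (N, CA, C, O) of `residue_range`,
#' computed after superposing that selection itself onto the reference
#' (local alignment, as used by the helicity rule).
#'
#' @param frame,ref `structure3d` objects sharing the segment's atoms.
#' @param residue_range two integers, inclusive (default `c(110, 118)`).
#' @param chain chain id (default "A").
#' @return RMSD in Angstrom.
#' @export
icl2_backbone_rmsd <- function(frame, ref, residue_range = c(110, 118),
                               chain = "A") {
  spec <- sprintf("chain %s and resid %d-%d and backbone",
                  chain, residue_range[1], residue_range[2])
  ia <- resolve_selection(spec, frame)
  ib <- resolve_selection(spec, ref)
  n_expect <- 4L * (residue_range[2] - residue_range[1] + 1L)
  if (length(ia) != n_expect || length(ib) != n_expect) {
    stop(sprintf("incomplete backbone for residues %d-%d (expected %d atoms, got %d/%d)",
                 residue_range[1], residue_range[2], n_expect,
                 length(ia), length(ib)))
  }
  rmsd(coords(frame)[ia, , drop = FALSE], coords(ref)[ib, , drop = FALSE],
       superpose = TRUE)
}

#' Multi-RMSD collective variable on ICL2 residues 111-118
#'
#' The biased-sampling reaction coordinate: locally superposed RMSD of the
#' heavy backbone atoms of residues 111-118 against the reference.
#'
#' @inheritParams icl2_backbone_rmsd
#' @return RMSD in Angstrom.
#' @export
multi_rmsd_cv <- function(frame, ref, chain = "A") {
  icl2_backbone_rmsd(frame, ref, residue_range = c(111, 118), chain = chain)
}

#' Displacement of the G-alpha helix 5 relative to the receptor
#'
#' Aligns the frame on the receptor fit set (TM1-4, not on G-alpha), then
#' reports the unsuperposed RMSD of the G-alpha C-alpha range (default
#' 519-530) against the reference.
#'
#' @param complex_frame `structure3d` containing receptor and G-alpha chains.
#' @param ref reference `structure3d` (typically the starting frame).
#' @param fit_spec receptor fit selection (TM1-4 C-alpha set).
#' @param g_alpha_range C-alpha residue range on the G-alpha chain.
#' @param g_chain chain id of the G-alpha subunit.
#' @return displacement RMSD in Angstrom.
#' @export
helix5_displacement <- function(complex_frame, ref, fit_spec,
                                g_alpha_range = c(519, 530), g_chain = "B") {
  g_spec <- sprintf("chain %s and resid %d-%d and name CA",
                    g_chain, g_alpha_range[1], g_alpha_range[2])
  fit_idx <- resolve_selection(fit_spec, complex_frame)
  fit_ref <- resolve_selection(fit_spec, ref)
  g_idx <- resolve_selection(g_spec, complex_frame)
  g_ref <- resolve_selection(g_spec, ref)
  if (length(g_idx) != length(g_ref)) {
    stop("G-alpha range resolves to different sizes on frame and reference")
  }
  fit <- kabsch(coords(complex_frame)[fit_idx, , drop = FALSE],
                coords(ref)[fit_ref, , drop = FALSE])
  moved <- apply_alignment(coords(complex_frame)[g_idx, , drop = FALSE], fit)
  rmsd(moved, coords(ref)[g_ref, , drop = FALSE], superpose = FALSE)
}

#' End-to-end distance of the G-alpha beta6-alpha5 loop
#'
#' Distance between the C-alpha atoms of two loop residues (default 504 and
#' 508), a measure of G-protein internal conformation.
#'
#' @param frame a `structure3d`.
#' @param resids the two residue numbers (default `c(504, 508)`).
#' @param chain chain id of the G-alpha subunit.
#' @return distance in Angstrom.
#' @export
loop_end_to_end <- function(frame, resids = c(504, 508), chain = "B") {
  pair_distance(frame,
                sprintf("chain %s and resid %d and name CA", chain, resids[1]),
                sprintf("chain %s and resid %d and name CA", chain, resids[2]))
}
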