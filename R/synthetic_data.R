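## Ideal peptide backbone geometry (Engh-Huber-like values, Angstrom/degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_N_H  <- 1.010
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5
ANGLE_C_N_H  <- 119.0

#' Place an atom from internal coordinates (natural extension reference frame)
#'
#' Returns the position D with bond length |CD|, bond angle B-C-D and
#' torsion A-B-C-D (same sign convention as [dihedral_angle()]).
#'
#' @param a,b,c length-3 positions of the three reference atoms.
#' @param bond bond length C-D, Angstrom.
#' @param angle bond angle B-C-D, degrees.
#' @param torsion dihedral A-B-C-D, degrees.
#' @return length-3 position of D.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # sign flip keeps parity with dihedral_angle()
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal peptide backbone with prescribed torsions
#'
#' Constructs N, CA, C, O (and optionally amide H) atoms for `n_res`
#' residues from ideal bond lengths and angles and the given phi/psi
#' torsions (omega fixed at 180). The default (-57, -47) is the canonical
#' alpha-helix, whose interior i,i+4 N...O distances fall below 3.5
#' Angstrom. Deterministic: identical inputs give bit-identical
#' coordinates.
#'
#' @param n_res number of residues (>= 4).
#' @param phi,psi backbone torsions in degrees; scalars are recycled,
#'   vectors give per-residue values (phi[1] and psi[n_res] shape the
#'   termini).
#' @param start_resid author number of the first residue.
#' @param chain chain id.
#' @param residue_names residue names (recycled; default "ALA").
#' @param with_h if `TRUE`, add amide hydrogens (residues 2..n).
#' @return a [structure3d()].
#' @export
make_ideal_helix <- function(n_res, phi = -57, psi = -47, start_resid = 1,
                             chain = "A", residue_names = "ALA",
                             with_h = FALSE) {
  if (n_res < 4L) stop("a helix needs >= 4 residues, got ", n_res)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  residue_names <- rep_len(residue_names, n_res)
  N <- CA <- C <- O <- H <- matrix(NA_real_, n_res, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  C[1L, ] <- CA[1L, ] + BOND_CA_C * c(cos(pi - th), sin(pi - th), 0)
  for (i in seq_len(n_res)) {
    if (i < n_res) {
      N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                                BOND_C_N, ANGLE_CA_C_N, psi[i])
      CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                                 BOND_N_CA, ANGLE_C_N_CA, 180)
      C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                                BOND_CA_C, ANGLE_N_CA_C, phi[i + 1L])
      if (with_h) {
        # amide H: in the peptide plane, cis to the previous CA (trans to O)
        H[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                                  BOND_N_H, ANGLE_C_N_H, 0)
      }
    }
    # carbonyl O anti to the next amide N (torsion psi + 180)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANGLE_CA_C_O, psi[i] + 180)
  }
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    res <- start_resid + i - 1L
    add <- function(name, pos, element) {
      serial <<- serial + 1L
      data.frame(serial = serial, atom_name = name,
                 residue_name = residue_names[i], chain_id = chain,
                 residue_seq = res, x = pos[1], y = pos[2], z = pos[3],
                 element = element, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add("N", N[i, ], "N")
    if (with_h && i > 1L) rows[[length(rows) + 1L]] <- add("H", H[i, ], "H")
    rows[[length(rows) + 1L]] <- add("CA", CA[i, ], "C")
    rows[[length(rows) + 1L]] <- add("C", C[i, ], "C")
    rows[[length(rows) + 1L]] <- add("O", O[i, ], "O")
  }
  structure3d(do.call(rbind, rows), title = "ideal backbone")
}

## ---- receptor-like scaffold -------------------------------------------

#' Specification for the synthetic receptor scaffold
#'
#' @param n_waters number of water molecules (oxygen-only), default 3.
#' @param with_galpha include the G-alpha fragment chain (C-alpha 500-530).
#' @param with_hydrogens build amide hydrogens on the ICL2 strand.
#' @return list of class `scaffold_spec`.
#' @export
scaffold_spec <- function(n_waters = 3, with_galpha = TRUE,
                          with_hydrogens = FALSE) {
  stopifnot(n_waters >= 0)
  structure(list(n_waters = n_waters, with_galpha = with_galpha,
                 with_hydrogens = with_hydrogens), class = "scaffold_spec")
}

# (y, z) center of the ICL2 helical axis and side-chain pseudo-atom radii
ICL2_AXIS_YZ <- c(4, -16)
R_OH <- 8   # Y114:OH circle radius about the axis
R_CG <- 2   # L112:CG circle radius
# geometry used to pin T39:CB so that d crosses 13 A between 80 and 40 deg
D_THETA_PR <- 80
D_THETA_NR <- 40
D_AT_PR <- 9

#' Build the synthetic receptor scaffold
#'
#' A single-conformation stand-in for a class-A GPCR carrying every atom the
#' metrics name: C-alpha anchors for TM1-6 (residues 10-244), T39 CB/OG1 on
#' TM2, an ICL2 strand (residues 108-120) built as an ideal alpha-helix and
#' mounted with its helical axis exactly along x (residues 110-118 are the
#' mobile loop; 108-109 and 119-120 are fixed TM3/TM4 stubs), side-chain
#' pseudo-atoms Y114:OH and L112:CG placed on circles about the axis so the
#' raw rotation angle of the base scaffold is exactly 0 degrees, an optional
#' G-alpha C-alpha fragment (chain B, residues 500-530) and water oxygens.
#' T39:CB is positioned so the Y114-TM2 distance is 9 Angstrom at a +80
#' degree rotation and crosses the 13 Angstrom threshold by -40 degrees,
#' exercising both classifier branches.
#'
#' Attributes: `icl2_axis` (list with `point`, `dir`), `icl2_resids`,
#' `fit_spec` (the TM1-4 C-alpha fit selection), `bridge_partners` (default
#' water-bridge partner selections).
#'
#' @param spec a [scaffold_spec()].
#' @return a [structure3d()].
#' @export
make_scaffold <- function(spec = scaffold_spec()) {
  stopifnot(inherits(spec, "scaffold_spec"))
  y0 <- ICL2_AXIS_YZ[1]; z0 <- ICL2_AXIS_YZ[2]

  ## ICL2 strand 108-120, mounted axis-along-x through (y0, z0)
  icl2_names <- c("ALA", "ALA", "ILE", "SER", "LEU", "ALA", "TYR", "LEU",
                  "ALA", "ILE", "PHE", "ALA", "ALA")
  helix <- make_ideal_helix(13L, start_resid = 108, chain = "A",
                            residue_names = icl2_names,
                            with_h = spec$with_hydrogens)
  hx <- coords(helix)
  ca_idx <- which(helix$atoms$atom_name == "CA")
  ca <- hx[ca_idx, , drop = FALSE]
  ctr <- colMeans(ca)
  ax <- prcomp(ca, center = TRUE)$rotation[, 1L]
  if (sum(ax * (ca[nrow(ca), ] - ca[1L, ])) < 0) ax <- -ax
  R <- rotation_between(ax, c(1, 0, 0))
  hx <- sweep(hx, 2L, ctr) %*% t(R)
  hx <- sweep(hx, 2L, c(0, y0, z0), "+")
  helix <- set_coords(helix, hx)

  atoms <- helix$atoms[, c("serial", "atom_name", "residue_name", "chain_id",
                           "residue_seq", "x", "y", "z", "element")]
  x_oh <- atoms$x[atoms$residue_seq == 114 & atoms$atom_name == "CA"]
  x_cg <- atoms$x[atoms$residue_seq == 112 & atoms$atom_name == "CA"]

  add_atom <- function(df, name, resname, resid, chain, pos, element) {
    rbind(df, data.frame(serial = 0L, atom_name = name,
                         residue_name = resname, chain_id = chain,
                         residue_seq = resid, x = pos[1], y = pos[2],
                         z = pos[3], element = element,
                         stringsAsFactors = FALSE))
  }
  ## side-chain pseudo-atoms on circles about the axis, base angle 0 (+y)
  atoms <- add_atom(atoms, "CG", "LEU", 112, "A",
                    c(x_cg, y0 + R_CG, z0), "C")
  atoms <- add_atom(atoms, "OH", "TYR", 114, "A",
                    c(x_oh, y0 + R_OH, z0), "O")

  ## TM C-alpha anchors (membrane normal = z, extracellular = +z)
  anchors <- list(
    list(10, c(14, -2, -8)),  list(15, c(14, -2, 0)), list(20, c(14, -2, 8)),
    list(35, c(7, -9, -6)),   list(36, c(7, -9, -2)), list(43, c(7, -9, 6)),
    list(83, c(10, 5, 12)),   list(103, c(8, 4, -9)), list(104, c(8, 4, -11)),
    list(105, c(8.3, 4.3, -13)),
    list(122, c(0, 12, -14)), list(126, c(0, 12, -9)),
    list(130, c(0, 12, -4)),  list(141, c(0, 12, 12.5)),
    list(184, c(-6, 10, 12)), list(190, c(-5, 9, 4)), list(208, c(-4, 8, -12)),
    list(222, c(-2, -6, -12)), list(244, c(-4, -8, 12)))
  for (a in anchors) {
    atoms <- add_atom(atoms, "CA", "ALA", a[[1]], "A", a[[2]], "C")
  }

  ## T39 on TM2: CB pinned by the d-metric geometry, CA and OG1 nearby
  e <- function(th) c(cos(th * pi / 180), sin(th * pi / 180))
  oh_pr <- c(y0, z0) + R_OH * e(D_THETA_PR)
  oh_nr <- c(y0, z0) + R_OH * e(D_THETA_NR)
  u <- (oh_pr - oh_nr) / sqrt(sum((oh_pr - oh_nr)^2))
  cb_yz <- oh_pr + D_AT_PR * u
  atoms <- add_atom(atoms, "CA", "THR", 39, "A",
                    c(x_oh - 0.8, cb_yz[1] - 1.2, cb_yz[2] - 0.5), "C")
  atoms <- add_atom(atoms, "CB", "THR", 39, "A",
                    c(x_oh, cb_yz[1], cb_yz[2]), "C")
  atoms <- add_atom(atoms, "OG1", "THR", 39, "A",
                    c(x_oh + 0.9, cb_yz[1] + 0.9, cb_yz[2] + 0.9), "O")

  ## G-alpha fragment: chain B, C-alpha 500-530
  if (spec$with_galpha) {
    for (i in 500:512) {
      atoms <- add_atom(atoms, "CA", "GLY", i, "B",
                        c(-12, -9 + 1.5 * (i - 500), -30), "C")
    }
    for (i in 513:530) {
      atoms <- add_atom(atoms, "CA", "GLY", i, "B",
                        c(-12, 10, -30 + 1.2 * (i - 513)), "C")
    }
  }

  ## waters, parked far from everything
  if (spec$n_waters > 0L) {
    for (k in seq_len(spec$n_waters)) {
      atoms <- add_atom(atoms, "O", "HOH", 900L + k, "W",
                        c(40 + 4 * k, 40, 40), "O")
    }
  }

  atoms$serial <- seq_len(nrow(atoms))
  out <- structure3d(atoms, title = "synthetic receptor scaffold")
  attr(out, "icl2_axis") <- list(point = c(0, y0, z0), dir = c(1, 0, 0))
  attr(out, "icl2_resids") <- 110:118
  attr(out, "fit_spec") <- paste0(
    "chain A and resid 10,15,20,35,36,43,83,103,104,105,122,126,130,141",
    " and name CA")
  attr(out, "bridge_partners") <- c("chain A and resid 111 and name O",
                                    "chain A and resid 114 and name O")
  out
}

rotation_between <- function(from, to) {
  # proper rotation taking unit vector `from` to unit vector `to`
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- cross3(from, to)
  s <- sqrt(sum(v^2)); cth <- sum(from * to)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular axis
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- cross3(from, p); v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

#' Default TM1-4 fit selection of a scaffold
#' @param scaffold a structure from [make_scaffold()].
#' @return selection string.
#' @export
scaffold_fit_spec <- function(scaffold) {
  fs <- attr(scaffold, "fit_spec")
  if (is.null(fs)) stop("not a scaffold: no fit_spec attribute")
  fs
}

## ---- trajectory simulation --------------------------------------------

#' Specification for synthetic two-state trajectories
#'
#' The generator emulates the phenomenology the analysis assumes: an ICL2
#' helix switching between two rotational states about its helical axis
#' (defaults +80 and +40 degrees raw, i.e. a -40 degree rotation out of the
#' PR window), per-frame Markov switching, isotropic Gaussian coordinate
#' noise, optional unfolding episodes (randomized-torsion ICL2), optional
#' planted water bridges, and optional rigid offsets of TM5 or the G-alpha
#' fragment.
#'
#' @param n_frames frames per replica (>= 1).
#' @param n_replicas number of independent replicas.
#' @param theta_pr raw rotation angle of the PR state, degrees (default 80,
#'   the center of the printed PR window).
#' @param theta_nr raw angle of the NR state (default `theta_pr - 40`).
#' @param p_pr_to_nr,p_nr_to_pr per-frame switch probabilities.
#' @param start_state `"PR"`, `"NR"` or `"stationary"` (draw the initial
#'   state from the chain's stationary distribution).
#' @param noise_sigma isotropic Gaussian noise SD per coordinate, Angstrom.
#' @param unfold_frames frames with randomized-torsion (non-helical) ICL2:
#'   an integer vector of frame indices (applied to every replica) or a
#'   fraction in (0, 1) sampled per replica.
#' @param bridge_frames frames with a planted water bridge: indices or a
#'   fraction, as above.
#' @param bridge_partners length-2 selection strings for the bridge
#'   partners (defaults to the scaffold's).
#' @param tm5_shift rigid displacement of the TM5 C-alpha 190 along the
#'   TM4 axis, Angstrom.
#' @param galpha_shift length-3 rigid translation of the G-alpha chain.
#' @param frame_interval ps per frame (metadata; default 200).
#' @param seed mandatory RNG seed; all stochastic output is a pure function
#'   of (spec, seed).
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames, n_replicas = 1, theta_pr = 80,
                            theta_nr = theta_pr - 40,
                            p_pr_to_nr = 0.02, p_nr_to_pr = 0.02,
                            start_state = "PR", noise_sigma = 0,
                            unfold_frames = NULL, bridge_frames = NULL,
                            bridge_partners = NULL, tm5_shift = 0,
                            galpha_shift = c(0, 0, 0),
                            frame_interval = 200, seed) {
  if (missing(seed)) stop("a seed is mandatory for any stochastic output")
  stopifnot(n_frames >= 1, n_replicas >= 1,
            p_pr_to_nr >= 0, p_pr_to_nr <= 1,
            p_nr_to_pr >= 0, p_nr_to_pr <= 1,
            noise_sigma >= 0,
            start_state %in% c("PR", "NR", "stationary"))
  structure(list(n_frames = as.integer(n_frames),
                 n_replicas = as.integer(n_replicas),
                 theta_pr = theta_pr, theta_nr = theta_nr,
                 p_pr_to_nr = p_pr_to_nr, p_nr_to_pr = p_nr_to_pr,
                 start_state = start_state, noise_sigma = noise_sigma,
                 unfold_frames = unfold_frames,
                 bridge_frames = bridge_frames,
                 bridge_partners = bridge_partners,
                 tm5_shift = tm5_shift, galpha_shift = galpha_shift,
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "trajectory_spec")
}

resolve_schedule <- function(x, n_frames) {
  if (is.null(x)) return(integer(0))
  if (length(x) == 1L && x > 0 && x < 1) {
    return(sort(sample.int(n_frames, round(x * n_frames))))
  }
  x <- as.integer(x)
  if (any(x < 1L | x > n_frames)) stop("schedule frame index out of range")
  sort(unique(x))
}

#' Simulate multi-replica two-state trajectories with ground truth
#'
#' Per frame, the ICL2 residues (110-118, side-chain pseudo-atoms included)
#' are rigidly rotated about the scaffold's helical axis to the current
#' state's angle; unfold frames instead substitute a randomized-torsion
#' conformer (redrawn until its locally superposed backbone RMSD to the
#' helical reference exceeds 2.5 Angstrom, so unfolded frames are
#' unambiguous by construction); bridge frames park the first water oxygen
#' midway between the partner atoms; finally isotropic Gaussian noise is
#' added to every atom. Identical (spec, scaffold) give bit-identical
#' output.
#'
#' @param spec a [trajectory_spec()].
#' @param scaffold a structure from [make_scaffold()].
#' @return list with `replicas` (list of [frame_source()]) and `truth`
#'   (data.frame: `replica`, `frame`, `state` in PR/NR/UNFOLDED, `theta`).
#' @export
simulate_trajectory <- function(spec, scaffold = make_scaffold()) {
  stopifnot(inherits(spec, "trajectory_spec"))
  axis <- attr(scaffold, "icl2_axis")
  if (is.null(axis)) stop("scaffold lacks icl2_axis attribute")
  ros <- roster(scaffold)
  base <- coords(scaffold)

  ## constant offsets
  if (spec$tm5_shift != 0) {
    i190 <- which(ros$chain_id == "A" & ros$residue_seq == 190 &
                    ros$atom_name == "CA")
    base[i190, ] <- base[i190, ] + spec$tm5_shift * c(0, 0, 1)
  }
  if (any(spec$galpha_shift != 0)) {
    ib <- which(ros$chain_id == "B")
    if (length(ib) == 0L) stop("galpha_shift set but scaffold has no chain B")
    base[ib, ] <- sweep(base[ib, , drop = FALSE], 2L, spec$galpha_shift, "+")
  }

  icl2_resids <- attr(scaffold, "icl2_resids")
  mob <- which(ros$chain_id == "A" & ros$residue_seq %in% icl2_resids)
  rel <- sweep(base[mob, , drop = FALSE], 2L, axis$point)
  rotated_icl2 <- function(theta) {
    th <- theta * pi / 180
    out <- rel
    out[, 2L] <- rel[, 2L] * cos(th) - rel[, 3L] * sin(th)
    out[, 3L] <- rel[, 2L] * sin(th) + rel[, 3L] * cos(th)
    sweep(out, 2L, axis$point, "+")
  }
  icl2_pr <- rotated_icl2(spec$theta_pr)
  icl2_nr <- rotated_icl2(spec$theta_nr)

  partners <- spec$bridge_partners
  if (is.null(partners)) partners <- attr(scaffold, "bridge_partners")
  pa_i <- pb_i <- NA_integer_
  w1_i <- which(ros$is_water & ros$element == "O")[1L]
  if (!is.null(partners)) {
    pa_i <- resolve_selection(partners[1], ros)[1L]
    pb_i <- resolve_selection(partners[2], ros)[1L]
  }

  ## helical ICL2 backbone (base orientation) for the unfold redraw check
  bb_mask <- ros$chain_id[mob] == "A" &
    ros$atom_name[mob] %in% BACKBONE_ATOMS
  helical_bb <- base[mob, , drop = FALSE][bb_mask, , drop = FALSE]

  set.seed(spec$seed)
  p_stat_pr <- if (spec$p_pr_to_nr + spec$p_nr_to_pr > 0) {
    spec$p_nr_to_pr / (spec$p_pr_to_nr + spec$p_nr_to_pr)
  } else 0.5

  replicas <- vector("list", spec$n_replicas)
  truth <- vector("list", spec$n_replicas)
  for (r in seq_len(spec$n_replicas)) {
    nf <- spec$n_frames
    state <- character(nf)
    s <- switch(spec$start_state,
                PR = "PR", NR = "NR",
                stationary = if (stats::runif(1) < p_stat_pr) "PR" else "NR")
    for (i in seq_len(nf)) {
      state[i] <- s
      p_switch <- if (s == "PR") spec$p_pr_to_nr else spec$p_nr_to_pr
      if (stats::runif(1) < p_switch) s <- if (s == "PR") "NR" else "PR"
    }
    unfold <- resolve_schedule(spec$unfold_frames, nf)
    bridge <- resolve_schedule(spec$bridge_frames, nf)

    arr <- array(base, dim = c(nrow(base), 3L, nf))
    theta <- ifelse(state == "PR", spec$theta_pr, spec$theta_nr)
    for (i in seq_len(nf)) {
      arr[mob, , i] <- if (state[i] == "PR") icl2_pr else icl2_nr
    }
    for (i in unfold) {
      arr[mob, , i] <- random_unfolded_icl2(helical_bb, base[mob, , drop = FALSE],
                                            bb_mask, ros[mob, , drop = FALSE])
      state[i] <- "UNFOLDED"
      theta[i] <- NA_real_
    }
    for (i in bridge) {
      if (is.na(w1_i)) stop("bridge schedule set but scaffold has no water")
      mid <- (arr[pa_i, , i] + arr[pb_i, , i]) / 2
      arr[w1_i, , i] <- mid + c(0, 0, 0.3)
    }
    if (spec$noise_sigma > 0) {
      arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sigma)
    }
    replicas[[r]] <- frame_source(ros, arr, spec$frame_interval)
    truth[[r]] <- data.frame(replica = r, frame = seq_len(nf),
                             state = state, theta = theta,
                             stringsAsFactors = FALSE)
  }
  list(replicas = replicas, truth = do.call(rbind, truth))
}

random_unfolded_icl2 <- function(helical_bb, base_icl2, bb_mask, icl2_ros) {
  # randomized-torsion 9-residue conformer, best-fit mounted on the helical
  # segment; redrawn until clearly non-helical (local RMSD > 2.5 A)
  for (try in 1:50) {
    conf <- make_ideal_helix(9L, phi = stats::runif(9, -180, 180),
                             psi = stats::runif(9, -180, 180),
                             start_resid = 110, chain = "A")
    cb <- coords(conf)
    bb <- cb[conf$atoms$atom_name %in% BACKBONE_ATOMS, , drop = FALSE]
    fit <- kabsch(bb, helical_bb)
    if (fit$rmsd <= 2.5) next
    placed_bb <- apply_alignment(bb, fit)
    out <- base_icl2
    out[bb_mask, ] <- placed_bb
    # side-chain pseudo-atoms ride on their residue's CA
    for (nm in list(c(112, "CG"), c(114, "OH"))) {
      j <- which(icl2_ros$residue_seq == as.integer(nm[1]) &
                   icl2_ros$atom_name == nm[2])
      ca <- which(icl2_ros$residue_seq == as.integer(nm[1]) &
                    icl2_ros$atom_name == "CA")
      if (length(j) == 1L && length(ca) == 1L) {
        out[j, ] <- out[ca, ] + c(0, 1.4, 0)
      }
    }
    return(out)
  }
  stop("failed to draw a non-helical conformer in 50 tries")
}

#' Fetch a crystal structure from the PDB (network convenience)
#'
#' Downloads a PDB entry and reads it with [read_pdb()]. Requires network
#' access; never used by the test suite.
#'
#' @param id 4-character PDB id, e.g. "5TZY".
#' @param dest_dir cache directory.
#' @return a [structure3d()].
#' @export
fetch_crystal_fixture <- function(id, dest_dir = tempdir()) {
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", id)) stop("invalid PDB id: ", id)
  dest <- file.path(dest_dir, paste0(toupper(id), ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
    ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      if (file.exists(dest)) unlink(dest)
      stop("could not download PDB entry ", id, " (network unavailable?)")
    }
  }
  read_pdb(dest)
}
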