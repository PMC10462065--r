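#' Default classifier thresholds
#'
#' Every printed threshold of the rotational-state rule in one editable
#' list: the helicity criteria (at least `min_hbonds` i,i+4 backbone
#' hydrogen bonds, or locally superposed backbone RMSD below `rmsd_cutoff`)
#' and the PR window on the raw ICL2 angle `a` (degrees) and the Y114-TM2
#' distance `d` (Angstrom): PR iff helical, `a_lo < a < a_hi`, and
#' `d_lo_intercept + d_lo_slope * a < d < d_hi`. A helical frame failing
#' the PR window is NR; a non-helical frame is NONHELICAL. The lower
#' distance bound `195 - 20 a` is implemented exactly as printed even
#' though it is vacuous over the stated angle window.
#'
#' @param a_lo,a_hi raw-angle window bounds, degrees (45, 120).
#' @param d_hi upper distance bound, Angstrom (13).
#' @param d_lo_intercept,d_lo_slope lower distance bound `intercept +
#'   slope * a` (195, -20).
#' @param rmsd_cutoff helicity RMSD cutoff, Angstrom (2).
#' @param min_hbonds minimum i,i+4 backbone hydrogen bonds (3).
#' @param icl2_range ICL2 residue range (110-118).
#' @return named list of thresholds.
#' @export
state_thresholds <- function(a_lo = 45, a_hi = 120, d_hi = 13,
                             d_lo_intercept = 195, d_lo_slope = -20,
                             rmsd_cutoff = 2, min_hbonds = 3,
                             icl2_range = c(110, 118)) {
  list(a_lo = a_lo, a_hi = a_hi, d_hi = d_hi,
       d_lo_intercept = d_lo_intercept, d_lo_slope = d_lo_slope,
       rmsd_cutoff = rmsd_cutoff, min_hbonds = min_hbonds,
       icl2_range = icl2_range)
}

#' Count i,i+4 backbone hydrogen bonds within the ICL2 segment
#'
#' For each residue pair (i, i+4) inside `residue_range`, tests the
#' backbone amide nitrogen of residue i+4 against the backbone carbonyl
#' oxygen of residue i under the hydrogen-bond criteria. In heavy-only
#' mode the N...O distance test alone is used.
#'
#' @param frame a `structure3d`.
#' @param residue_range inclusive ICL2 range (default `c(110, 118)`).
#' @param criteria an [hbond_criteria()].
#' @param chain chain id (default "A").
#' @return integer count of satisfied (i, i+4) pairs.
#' @export
count_i4_hbonds <- function(frame, residue_range = c(110, 118),
                            criteria = hbond_criteria(heavy_only = TRUE),
                            chain = "A") {
  ros <- roster(frame); xyz <- coords(frame)
  resids <- residue_range[1]:residue_range[2]
  n <- 0L
  for (i in resids) {
    j <- i + 4L
    if (!(j %in% resids)) next
    oi <- which(ros$chain_id == chain & ros$residue_seq == i &
                  ros$atom_name == "O")
    nj <- which(ros$chain_id == chain & ros$residue_seq == j &
                  ros$atom_name == "N")
    if (length(oi) != 1L || length(nj) != 1L) {
      stop(sprintf("missing backbone atom for i,i+4 pair %d-%d", i, j))
    }
    d <- sqrt(sum((xyz[oi, ] - xyz[nj, ])^2))
    if (d > criteria$da_cutoff) next
    if (!criteria$heavy_only) {
      hs <- attached_hydrogens(xyz, ros, nj)
      if (length(hs) == 0L) {
        stop("donor N of residue ", j, " has no attached hydrogen; ",
             "use heavy_only criteria")
      }
      angs <- vapply(hs, function(h)
        vec_angle_deg(xyz[nj, ] - xyz[h, ], xyz[oi, ] - xyz[h, ]), numeric(1))
      if (!any(angs >= criteria$dha_min_angle)) next
    }
    n <- n + 1L
  }
  n
}

#' Is the ICL2 segment helical in this frame?
#'
#' The two-branch helicity rule: helical iff at least `min_hbonds` i,i+4
#' backbone hydrogen bonds are present within the segment, OR the locally
#' superposed backbone RMSD against the reference is strictly below
#' `rmsd_cutoff` Angstrom.
#'
#' @param frame,ref `structure3d` objects.
#' @param thresholds a [state_thresholds()] list.
#' @param criteria hydrogen-bond criteria for the i,i+4 test.
#' @param chain chain id.
#' @return logical.
#' @export
classify_helicity <- function(frame, ref, thresholds = state_thresholds(),
                              criteria = hbond_criteria(heavy_only = TRUE),
                              chain = "A") {
  r <- icl2_backbone_rmsd(frame, ref, thresholds$icl2_range, chain = chain)
  if (r < thresholds$rmsd_cutoff) return(TRUE)
  count_i4_hbonds(frame, thresholds$icl2_range, criteria, chain) >=
    thresholds$min_hbonds
}

#' Assign the rotational state label of one frame
#'
#' Vectorized over `a`, `d`, `helical`. PR requires a helical segment, the
#' raw angle inside the printed window, and the distance inside the printed
#' bounds (all inequalities strict as printed); a helical frame that is not
#' PR is NR; otherwise NONHELICAL.
#'
#' @param a raw ICL2 angle, degrees.
#' @param d Y114-TM2 distance, Angstrom.
#' @param helical logical.
#' @param thresholds a [state_thresholds()] list.
#' @return character vector with values in `c("PR", "NR", "NONHELICAL")`.
#' @export
classify_state <- function(a, d, helical, thresholds = state_thresholds()) {
  stopifnot(length(a) == length(d), length(d) == length(helical))
  pr <- helical &
    a > thresholds$a_lo & a < thresholds$a_hi &
    d > thresholds$d_lo_intercept + thresholds$d_lo_slope * a &
    d < thresholds$d_hi
  out <- ifelse(helical, ifelse(pr, "PR", "NR"), "NONHELICAL")
  out[!helical] <- "NONHELICAL"
  out
}

#' Per-frame state trace of a trajectory
#'
#' The composed per-frame pipeline: align each frame on the TM1-4 fit set,
#' measure the raw and reference-offset ICL2 rotation angle, the Y114-TM2
#' distance, the locally superposed ICL2 backbone RMSD and i,i+4
#' hydrogen-bond count, then apply the helicity rule and the state
#' thresholds.
#'
#' @param frames a [frame_source()].
#' @param ref reference `structure3d` (starting frame / crystal structure).
#' @param fit_spec TM1-4 fit selection string.
#' @param thresholds a [state_thresholds()] list.
#' @param criteria hydrogen-bond criteria for the helicity test.
#' @param oh_spec,cg_spec angle vector endpoints (Y114:OH, L112:CG).
#' @param d_specs length-2 character vector: the two atoms of the distance
#'   metric (Y114:OH, T39:CB).
#' @param chain receptor chain id.
#' @return data.frame with one row per frame: `frame`, `angle_raw`,
#'   `angle_offset` (raw minus the reference structure's raw angle),
#'   `angle_reliable`, `d`, `icl2_rmsd`, `n_i4_hbonds`, `helical`, `state`.
#' @export
state_trace <- function(frames, ref, fit_spec,
                        thresholds = state_thresholds(),
                        criteria = hbond_criteria(heavy_only = TRUE),
                        oh_spec = "resid 114 and name OH",
                        cg_spec = "resid 112 and name CG",
                        d_specs = c("resid 114 and name OH",
                                    "resid 39 and name CB"),
                        chain = "A") {
  stopifnot(inherits(frames, "frame_source"))
  nf <- frames$n_frames
  if (nf < 1L) stop("empty frame source")
  ros <- frames$roster
  # fail fast: resolve every selection once, before frame 1
  fit_idx <- resolve_selection(fit_spec, ros)
  fit_ref <- coords(ref)[resolve_selection(fit_spec, ref), , drop = FALSE]
  one <- function(spec, r) {
    i <- resolve_selection(spec, r)
    if (length(i) != 1L) stop("selection '", spec, "' must name one atom")
    i
  }
  oh_i <- one(oh_spec, ros); cg_i <- one(cg_spec, ros)
  d1_i <- one(d_specs[1], ros); d2_i <- one(d_specs[2], ros)
  rng <- thresholds$icl2_range
  bb_spec <- sprintf("chain %s and resid %d-%d and backbone",
                     chain, rng[1], rng[2])
  bb_idx <- resolve_selection(bb_spec, ros)
  bb_ref <- coords(ref)[resolve_selection(bb_spec, ref), , drop = FALSE]
  n_expect <- 4L * (rng[2] - rng[1] + 1L)
  if (length(bb_idx) != n_expect || nrow(bb_ref) != n_expect) {
    stop("incomplete ICL2 backbone for residues ", rng[1], "-", rng[2])
  }
  # i,i+4 donor/acceptor backbone atom indices, resolved once
  i4 <- lapply(rng[1]:(rng[2] - 4L), function(i) {
    oi <- which(ros$chain_id == chain & ros$residue_seq == i &
                  ros$atom_name == "O")
    nj <- which(ros$chain_id == chain & ros$residue_seq == i + 4L &
                  ros$atom_name == "N")
    if (length(oi) != 1L || length(nj) != 1L) {
      stop(sprintf("missing backbone atom for i,i+4 pair %d-%d", i, i + 4L))
    }
    c(oi, nj)
  })
  ref_angle <- icl2_rotation_angle(ref, oh_spec, cg_spec)$raw

  angle_raw <- numeric(nf); reliable <- logical(nf)
  d <- numeric(nf); icl2_r <- numeric(nf); nhb <- rep(NA_integer_, nf)
  helical <- logical(nf)
  for (i in seq_len(nf)) {
    fr <- frames$coords[, , i]
    fit <- tryCatch(kabsch(fr[fit_idx, , drop = FALSE], fit_ref),
                    error = function(e)
                      stop(sprintf("frame %d: %s", i, conditionMessage(e))))
    # the OH-CG difference vector only needs the rotation part
    v <- as.numeric((fr[oh_i, ] - fr[cg_i, ]) %*% fit$rotation)
    angle_raw[i] <- atan2(v[3], v[2]) * 180 / pi
    reliable[i] <- sqrt(v[2]^2 + v[3]^2) >= 0.1
    d[i] <- sqrt(sum((fr[d1_i, ] - fr[d2_i, ])^2))
    icl2_r[i] <- rmsd(fr[bb_idx, , drop = FALSE], bb_ref, superpose = TRUE)
    if (icl2_r[i] < thresholds$rmsd_cutoff) {
      helical[i] <- TRUE  # RMSD branch decides; h-bond count not needed
    } else {
      cnt <- 0L
      for (p in i4) {
        if (sqrt(sum((fr[p[1L], ] - fr[p[2L], ])^2)) <= criteria$da_cutoff) {
          cnt <- cnt + 1L
        }
      }
      if (!criteria$heavy_only) {
        # exact hydrogen-aware count for frames not settled by the RMSD branch
        cnt <- count_i4_hbonds(frame_structure(frames, i), rng, criteria, chain)
      }
      nhb[i] <- cnt
      helical[i] <- cnt >= thresholds$min_hbonds
    }
  }
  data.frame(frame = seq_len(nf), angle_raw = angle_raw,
             angle_offset = wrap_angle(angle_raw - ref_angle),
             angle_reliable = reliable, d = d, icl2_rmsd = icl2_r,
             n_i4_hbonds = nhb, helical = helical,
             state = classify_state(angle_raw, d, helical, thresholds),
             stringsAsFactors = FALSE)
}

wrap_angle <- function(a) {
  ((a + 180) %% 360) - 180
}

#' Cross-replica state occupancy summary
#'
#' Per-replica fractions of frames labelled PR and NR (denominator is all
#' frames, so NONHELICAL time counts against both), with cross-replica mean
#' and 68% confidence half-width (standard error of the replica means).
#'
#' @param replica_labels list of character vectors of per-frame labels.
#' @return list of class `occupancy_summary` with `per_replica_pr`,
#'   `per_replica_nr`, `mean_pr`, `ci68_pr`, `mean_nr`, `ci68_nr`,
#'   `n_frames_per_replica`.
#' @export
occupancy <- function(replica_labels) {
  stopifnot(length(replica_labels) >= 1L)
  if (any(vapply(replica_labels, length, integer(1)) == 0L)) {
    stop("empty replica label sequence")
  }
  fpr <- vapply(replica_labels, function(l) mean(l == "PR"), numeric(1))
  fnr <- vapply(replica_labels, function(l) mean(l == "NR"), numeric(1))
  structure(list(per_replica_pr = fpr, per_replica_nr = fnr,
                 mean_pr = mean(fpr), ci68_pr = sem(fpr),
                 mean_nr = mean(fnr), ci68_nr = sem(fnr),
                 n_frames_per_replica = vapply(replica_labels, length,
                                               integer(1))),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf("PR: %.3f +/- %.3f   NR: %.3f +/- %.3f   (%d replicas, 68%% CI)\n",
              x$mean_pr, x$ci68_pr, x$mean_nr, x$ci68_nr,
              length(x$per_replica_pr)))
  invisible(x)
}

#' Re-label a state trace under different thresholds
#'
#' Recomputes helicity and state labels from the columns of a
#' [state_trace()] table under new thresholds, without re-measuring the
#' geometry. Used for threshold-robustness analyses. Rows whose i,i+4
#' hydrogen-bond count was skipped (the RMSD branch decided) but whose RMSD
#' no longer clears the new cutoff have their count recomputed from
#' `frames` if given, else are treated as failing the hydrogen-bond branch.
#'
#' @param trace data.frame from [state_trace()].
#' @param thresholds a [state_thresholds()] list.
#' @param frames optional [frame_source()] the trace came from.
#' @param criteria hydrogen-bond criteria for any recomputed counts.
#' @param chain chain id.
#' @return character vector of state labels.
#' @export
relabel_trace <- function(trace, thresholds, frames = NULL,
                          criteria = hbond_criteria(heavy_only = TRUE),
                          chain = "A") {
  nhb <- trace$n_i4_hbonds
  need <- is.na(nhb) & trace$icl2_rmsd >= thresholds$rmsd_cutoff
  if (any(need)) {
    if (is.null(frames)) {
      nhb[need] <- 0L
    } else {
      nhb[need] <- vapply(which(need), function(i)
        count_i4_hbonds(frame_structure(frames, trace$frame[i]),
                        thresholds$icl2_range, criteria, chain), integer(1))
    }
  }
  helical <- trace$icl2_rmsd < thresholds$rmsd_cutoff |
    (!is.na(nhb) & nhb >= thresholds$min_hbonds)
  classify_state(trace$angle_raw, trace$d, helical, thresholds)
}
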