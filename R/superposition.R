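#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `mobile %*% R + t` to `reference` (row-vector convention). The sign of the
#' smallest singular value is corrected so that `det(R) = +1` always, i.e.
#' reflections are never returned.
#'
#' @param mobile n x 3 matrix of points to move.
#' @param reference n x 3 matrix of target points (same n).
#' @return list of class `alignment_result` with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be n x 3 matrices of equal size")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs >= 3 points, got ", n)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  Mc <- sweep(mobile, 2L, cm); Rc <- sweep(reference, 2L, cr)
  H <- crossprod(Mc, Rc)
  s <- svd(H)
  # rank < 2 (all points collinear) leaves the rotation under-determined
  if (s$d[2L] < 1e-8 * max(s$d[1L], 1e-12)) {
    stop("degenerate (collinear) point configuration: rotation undetermined")
  }
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  moved <- Mc %*% R
  rmsd_val <- sqrt(sum((moved - Rc)^2) / n)
  t_vec <- as.numeric(cr - cm %*% R)
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd_val),
            class = "alignment_result")
}

#' Apply an alignment to coordinates
#' @param coords n x 3 matrix.
#' @param fit an `alignment_result` from [kabsch()].
#' @return transformed n x 3 matrix.
#' @export
apply_alignment <- function(coords, fit) {
  stopifnot(inherits(fit, "alignment_result"))
  sweep(as.matrix(coords) %*% fit$rotation, 2L, fit$translation, "+")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param coords_a,coords_b n x 3 matrices (same n, corresponding rows).
#' @param superpose if `TRUE`, the optimal Kabsch superposition is applied
#'   first and the minimized RMSD returned; if `FALSE`, the plain RMSD of
#'   the coordinates as given.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b, superpose = FALSE) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) {
    stop("coordinate sets differ in size: ", nrow(coords_a), " vs ",
         nrow(coords_b))
  }
  if (superpose) {
    return(kabsch(coords_a, coords_b)$rmsd)
  }
  sqrt(sum((coords_a - coords_b)^2) / nrow(coords_a))
}

#' Align every frame of a trajectory to a reference structure
#'
#' Each frame is rigid-body transformed by the Kabsch fit computed on
#' `fit_spec` (resolved independently on the trajectory roster and on the
#' reference), the alignment step that precedes every frame metric.
#'
#' @param frames a [frame_source()].
#' @param fit_spec selection string for the fit atoms (e.g. the TM1-4
#'   C-alpha set).
#' @param reference a [structure3d()]; defaults to the first frame, the
#'   usual "starting frame" convention.
#' @return a new [frame_source()] with transformed coordinates.
#' @export
align_frames <- function(frames, fit_spec, reference = NULL) {
  stopifnot(inherits(frames, "frame_source"))
  if (is.null(reference)) reference <- frame_structure(frames, 1L)
  idx_m <- resolve_selection(fit_spec, frames$roster)
  idx_r <- resolve_selection(fit_spec, reference)
  if (length(idx_m) != length(idx_r)) {
    stop("fit selection resolves to different sizes on trajectory and reference")
  }
  ref_fit <- coords(reference)[idx_r, , drop = FALSE]
  out <- frames$coords
  for (i in seq_len(frames$n_frames)) {
    fr <- frames$coords[, , i]
    fit <- tryCatch(kabsch(fr[idx_m, , drop = FALSE], ref_fit),
                    error = function(e) {
                      stop(sprintf("frame %d: %s", i, conditionMessage(e)))
                    })
    out[, , i] <- apply_alignment(fr, fit)
  }
  frame_source(frames$roster, out, frames$frame_interval)
}
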