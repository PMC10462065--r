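#' Torsion angle defined by four points
#'
#' Standard signed dihedral: the angle between the planes (p1, p2, p3) and
#' (p2, p3, p4), in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 numeric vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone phi/psi dihedral matrix for a residue window
#'
#' Extracts phi(C[i-1], N, CA, C) and psi(N, CA, C, N[i+1]) for every
#' residue of the window, one row per frame, columns named `phi_<resid>` /
#' `psi_<resid>`. A dihedral whose flanking atom is absent from the roster
#' (chain termini) is dropped with a message; dropped columns are recorded
#' in `attr(, "dropped")`.
#'
#' @param frames a [frame_source()].
#' @param residue_window integer vector of residue numbers (e.g. `109:119`),
#'   or a character vector of Ballesteros-Weinstein codes resolved through
#'   `bw` (the convention in which such windows are usually stated).
#' @param bw optional [bw_map()] used when `residue_window` is character;
#'   the window then spans `bw_to_resid(bw, residue_window[1])` to
#'   `bw_to_resid(bw, residue_window[2])`.
#' @param chain chain id (default "A").
#' @return numeric matrix (frames x dihedrals), degrees in (-180, 180].
#' @export
compute_dihedrals <- function(frames, residue_window, bw = NULL,
                              chain = "A") {
  stopifnot(inherits(frames, "frame_source"))
  if (is.character(residue_window)) {
    if (is.null(bw)) stop("a bw_map is required to resolve BW codes")
    ends <- bw_to_resid(bw, residue_window)
    residue_window <- min(ends):max(ends)
  }
  ros <- frames$roster
  find <- function(resid, name) {
    i <- which(ros$chain_id == chain & ros$residue_seq == resid &
                 ros$atom_name == name)
    if (length(i) == 1L) i else NA_integer_
  }
  cols <- list(); dropped <- character(0)
  for (r in residue_window) {
    quad <- c(find(r - 1L, "C"), find(r, "N"), find(r, "CA"), find(r, "C"))
    if (anyNA(quad)) dropped <- c(dropped, sprintf("phi_%d", r))
    else cols[[sprintf("phi_%d", r)]] <- quad
    quad <- c(find(r, "N"), find(r, "CA"), find(r, "C"), find(r + 1L, "N"))
    if (anyNA(quad)) dropped <- c(dropped, sprintf("psi_%d", r))
    else cols[[sprintf("psi_%d", r)]] <- quad
  }
  if (length(cols) == 0L) stop("no computable dihedrals in window")
  if (length(dropped) > 0L) {
    message("dropped dihedral(s) with missing flanking atoms: ",
            paste(dropped, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = frames$n_frames, ncol = length(cols),
                dimnames = list(NULL, names(cols)))
  for (i in seq_len(frames$n_frames)) {
    fr <- frames$coords[, , i]
    out[i, ] <- vapply(cols, function(q)
      dihedral_angle(fr[q[1L], ], fr[q[2L], ], fr[q[3L], ], fr[q[4L], ]),
      numeric(1))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Principal component analysis of a dihedral matrix
#'
#' Mean-centered PCA (covariance form, no column scaling) of the masked
#' rows, via singular value decomposition. Dihedrals enter as raw degrees
#' by default; `embed = "sincos"` expands each angle column into its sine
#' and cosine to avoid wraparound artifacts near +/-180 degrees.
#'
#' @param mat frames x dihedrals matrix from [compute_dihedrals()].
#' @param mask optional logical vector selecting rows (e.g. helical frames
#'   only); at least 2 rows must survive.
#' @param embed `"degrees"` (default) or `"sincos"`.
#' @return object of class `pca_model`: `mean`, `components` (orthonormal
#'   rows, one per PC), `variance` (per-PC variances), `explained_variance`
#'   (fractions, non-increasing), `embed`.
#' @export
fit_pca <- function(mat, mask = NULL, embed = c("degrees", "sincos")) {
  embed <- match.arg(embed)
  mat <- as.matrix(mat)
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(mat))
    mat <- mat[mask, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("PCA needs >= 2 (masked) rows, got ", nrow(mat))
  if (ncol(mat) < 1L) stop("PCA needs >= 1 column")
  X <- embed_dihedrals(mat, embed)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- svd(Xc)
  var_pc <- s$d^2 / (nrow(X) - 1L)
  structure(list(mean = mu, components = t(s$v),
                 variance = var_pc,
                 explained_variance = var_pc / sum(var_pc),
                 embed = embed),
            class = "pca_model")
}

embed_dihedrals <- function(mat, embed) {
  if (embed == "degrees") return(mat)
  rad <- mat * pi / 180
  out <- cbind(sin(rad), cos(rad))
  colnames(out) <- c(paste0("sin_", colnames(mat)),
                     paste0("cos_", colnames(mat)))
  out
}

#' Project frames onto a fitted PCA model
#'
#' Centers the (embedded) rows with the model mean and dots them with the
#' component vectors.
#'
#' @param model a `pca_model` from [fit_pca()].
#' @param mat frames x dihedrals matrix with the columns the model was fit
#'   on.
#' @param n_components number of leading components to return scores for
#'   (default: all).
#' @return frames x n_components score matrix.
#' @export
project_pca <- function(model, mat, n_components = NULL) {
  stopifnot(inherits(model, "pca_model"))
  mat <- as.matrix(mat)
  if (nrow(mat) == 0L) stop("empty matrix: nothing to project")
  X <- embed_dihedrals(mat, model$embed)
  if (ncol(X) != length(model$mean)) {
    stop("column count (", ncol(X), ") does not match model dimension (",
         length(model$mean), ")")
  }
  if (is.null(n_components)) n_components <- nrow(model$components)
  sc <- sweep(X, 2L, model$mean) %*%
    t(model$components[seq_len(n_components), , drop = FALSE])
  colnames(sc) <- paste0("PC", seq_len(n_components))
  sc
}

#' Reconstruct (embedded) data from PCA scores
#' @param model a `pca_model`.
#' @param scores matrix of scores (frames x k).
#' @return reconstructed data in the embedded space.
#' @export
reconstruct_pca <- function(model, scores) {
  stopifnot(inherits(model, "pca_model"))
  k <- ncol(scores)
  sweep(scores %*% model$components[seq_len(k), , drop = FALSE],
        2L, model$mean, "+")
}
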