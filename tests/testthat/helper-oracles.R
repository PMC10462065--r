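# Independent oracles kept deliberately separate from the package code paths.

# Horn's quaternion eigen-method for optimal rigid superposition: builds the
# 4x4 key matrix from the cross-covariance and takes its top eigenvector.
quaternion_superpose <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  S <- t(A) %*% B
  Sxx <- S[1,1]; Sxy <- S[1,2]; Sxz <- S[1,3]
  Syx <- S[2,1]; Syy <- S[2,2]; Syz <- S[2,3]
  Szx <- S[3,1]; Szy <- S[3,2]; Szz <- S[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  moved <- A %*% t(R)
  list(rotation = R, rmsd = sqrt(sum((moved - B)^2) / nrow(A)))
}

# All-pairs brute-force hydrogen-bond enumeration with explicit loops.
brute_hbonds <- function(frame, donors_spec, acceptors_spec, criteria) {
  ros <- roster(frame); xyz <- coords(frame)
  di <- resolve_selection(donors_spec, ros)
  ai <- resolve_selection(acceptors_spec, ros)
  hits <- list()
  for (d in di) for (a in ai) {
    if (d == a) next
    dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
    if (dist > criteria$da_cutoff) next
    if (!criteria$heavy_only) {
      h_idx <- which(ros$element == "H" &
                       ros$chain_id == ros$chain_id[d] &
                       ros$residue_seq == ros$residue_seq[d])
      h_idx <- h_idx[vapply(h_idx, function(h)
        sqrt(sum((xyz[h, ] - xyz[d, ])^2)) <= 1.25, logical(1))]
      ok <- FALSE
      for (h in h_idx) {
        v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
        ang <- acos(min(max(sum(v1*v2)/sqrt(sum(v1^2)*sum(v2^2)), -1), 1)) *
          180 / pi
        if (ang >= criteria$dha_min_angle) ok <- TRUE
      }
      if (!ok) next
    }
    hits[[length(hits) + 1L]] <- c(d, a)
  }
  if (length(hits) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# random proper rotation (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(coords, R, t) {
  sweep(coords %*% t(R), 2, t, "+")
}

rigid_structure <- function(s, R, t) {
  set_coords(s, apply_rigid(coords(s), R, t))
}
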