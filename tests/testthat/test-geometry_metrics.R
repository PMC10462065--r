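test_that("tm5_vertical_shift follows its projection contract", {
  sc <- test_scaffold
  expect_equal(tm5_vertical_shift(sc, sc), 0)

  # +2 A along the 130->141 unit axis reads +2.0 exactly
  ros <- roster(sc)
  axis_u <- c(0, 0, 1)  # 130 -> 141 in the scaffold points extracellular
  i190 <- which(ros$chain_id == "A" & ros$residue_seq == 190 &
                  ros$atom_name == "CA")
  xyz <- coords(sc); xyz[i190, ] <- xyz[i190, ] + 2 * axis_u
  expect_equal(tm5_vertical_shift(set_coords(sc, xyz), sc), 2, tolerance = 1e-12)

  # linear along the axis, insensitive perpendicular to it
  set.seed(2)
  for (k in 1:10) {
    s <- runif(1, -4, 4)
    perp <- c(rnorm(2), 0)[c(1, 2, 3)]; perp[3] <- 0
    xyz <- coords(sc); xyz[i190, ] <- xyz[i190, ] + s * axis_u + perp
    expect_equal(tm5_vertical_shift(set_coords(sc, xyz), sc), s,
                 tolerance = 1e-9)
  }
  expect_error(tm5_vertical_shift(sc, sc, tm5_resid = 999), "999")
})

test_that("pair_distance is exact and rigid-motion invariant", {
  atoms <- data.frame(serial = 1:2, atom_name = c("CA", "CA"),
                      residue_name = "GLY", chain_id = "A",
                      residue_seq = 1:2,
                      x = c(0, 3), y = c(0, 4), z = c(0, 0),
                      element = "C", stringsAsFactors = FALSE)
  s <- structure3d(atoms)
  expect_equal(pair_distance(s, "resid 1", "resid 2"), 5)
  s2 <- set_coords(s, matrix(c(1, 1, 1, 1, 1, 1), 2, 3, byrow = TRUE))
  expect_equal(pair_distance(s2, "resid 1", "resid 2"), 0)
  set.seed(4)
  for (k in 1:20) {
    sr <- rigid_structure(test_scaffold, random_rotation(), rnorm(3, sd = 10))
    expect_equal(
      pair_distance(sr, "resid 114 and name OH", "resid 39 and name CB"),
      pair_distance(test_scaffold, "resid 114 and name OH",
                    "resid 39 and name CB"),
      tolerance = 1e-9)
  }
})

test_that("icl2_rotation_angle is equivariant under rotations about x", {
  sc <- test_scaffold
  expect_equal(icl2_rotation_angle(sc)$raw, 0, tolerance = 1e-9)
  base <- coords(sc)
  for (phi in c(-170, -40, -5, 30, 80, 179)) {
    th <- phi * pi / 180
    Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
                 3, 3, byrow = TRUE)
    rot <- set_coords(sc, base %*% t(Rx))
    expect_equal(icl2_rotation_angle(rot)$raw, phi, tolerance = 1e-6)
  }
  # vector nearly parallel to the helical axis is flagged unreliable
  ros <- roster(sc)
  oh <- which(ros$residue_seq == 114 & ros$atom_name == "OH")
  cg <- which(ros$residue_seq == 112 & ros$atom_name == "CG")
  xyz <- base; xyz[oh, ] <- xyz[cg, ] + c(5, 0.01, 0)
  expect_false(icl2_rotation_angle(set_coords(sc, xyz))$reliable)
})

test_that("icl2_backbone_rmsd and the multi-RMSD CV obey their contracts", {
  sc <- test_scaffold
  expect_equal(icl2_backbone_rmsd(sc, sc), 0, tolerance = 1e-9)
  expect_equal(multi_rmsd_cv(sc, sc), 0, tolerance = 1e-9)

  # definitional equality with superposed rmsd on the same selection
  spec <- trajectory_spec(n_frames = 3, unfold_frames = 2, noise_sigma = 0.2,
                          seed = 13)
  fr <- frame_structure(simulate_trajectory(spec, sc)$replicas[[1]], 2)
  sel <- "chain A and resid 110-118 and backbone"
  expect_equal(icl2_backbone_rmsd(fr, sc),
               rmsd(coords(fr)[resolve_selection(sel, fr), ],
                    coords(sc)[resolve_selection(sel, sc), ],
                    superpose = TRUE))
  expect_gt(icl2_backbone_rmsd(fr, sc), 2)

  # independent brute-force recomputation of the CV
  sel2 <- "chain A and resid 111-118 and backbone"
  a <- coords(fr)[resolve_selection(sel2, fr), ]
  b <- coords(sc)[resolve_selection(sel2, sc), ]
  oracle <- quaternion_superpose(a, b)$rmsd
  expect_equal(multi_rmsd_cv(fr, sc), oracle, tolerance = 1e-9)

  expect_error(icl2_backbone_rmsd(sc, sc, residue_range = c(100, 118)), "100")
})

test_that("the CV stays inside the sampled range on generator output", {
  spec <- trajectory_spec(n_frames = 40, noise_sigma = 0.3,
                          unfold_frames = 0.2, p_pr_to_nr = 0.2,
                          p_nr_to_pr = 0.2, seed = 21)
  sim <- simulate_trajectory(spec, test_scaffold)
  cv <- vapply(seq_len(40), function(i)
    multi_rmsd_cv(frame_structure(sim$replicas[[1]], i), test_scaffold),
    numeric(1))
  expect_true(all(cv >= 0 & cv <= 5.5))
})

test_that("helix5_displacement measures G-alpha motion after receptor fit", {
  sc <- test_scaffold
  expect_equal(helix5_displacement(sc, sc, test_fit), 0, tolerance = 1e-9)

  # rigid 5 A translation of G-alpha with the receptor fixed reads 5.0
  ros <- roster(sc)
  ib <- which(ros$chain_id == "B")
  xyz <- coords(sc)
  xyz[ib, ] <- sweep(xyz[ib, ], 2, c(3, 4, 0) / 5 * 5, "+")
  expect_equal(helix5_displacement(set_coords(sc, xyz), sc, test_fit), 5,
               tolerance = 1e-9)

  # whole-complex rigid motion vanishes after alignment
  set.seed(6)
  sr <- rigid_structure(sc, random_rotation(), rnorm(3, sd = 10))
  expect_equal(helix5_displacement(sr, sc, test_fit), 0, tolerance = 1e-6)
})

test_that("loop_end_to_end inherits the pair-distance contract", {
  expect_equal(loop_end_to_end(test_scaffold), 6, tolerance = 1e-9)
  sc_no_g <- make_scaffold(scaffold_spec(with_galpha = FALSE))
  expect_error(loop_end_to_end(sc_no_g), "B")
  expect_error(helix5_displacement(sc_no_g, sc_no_g, test_fit), "B")
})

test_that("distance metrics are invariant to rigid motion before alignment", {
  set.seed(8)
  spec <- trajectory_spec(n_frames = 2, noise_sigma = 0.3, seed = 3)
  fs <- simulate_trajectory(spec, test_scaffold)$replicas[[1]]
  fr <- frame_structure(fs, 1)
  sr <- rigid_structure(fr, random_rotation(), rnorm(3, sd = 12))
  expect_equal(icl2_backbone_rmsd(sr, test_scaffold),
               icl2_backbone_rmsd(fr, test_scaffold), tolerance = 1e-9)
  expect_equal(helix5_displacement(sr, test_scaffold, test_fit),
               helix5_displacement(fr, test_scaffold, test_fit),
               tolerance = 1e-6)
  expect_equal(tm5_vertical_shift(sr, test_scaffold),
               tm5_vertical_shift(fr, test_scaffold), tolerance = 1e-9)
})
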