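make_hb_structure <- function(xyz, elements, names = NULL, resids = NULL) {
  n <- nrow(xyz)
  if (is.null(names)) names <- paste0(elements, seq_len(n))
  if (is.null(resids)) resids <- seq_len(n)
  structure3d(data.frame(
    serial = seq_len(n), atom_name = names, residue_name = "UNK",
    chain_id = "A", residue_seq = resids,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = elements, stringsAsFactors = FALSE))
}

test_that("constructed donor-H-acceptor geometries classify correctly", {
  # N donor, H on the N->O line, O acceptor at 2.8 A: detected, angle 180
  s <- make_hb_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0)),
                         c("N", "H", "O"),
                         names = c("N", "H", "O"), resids = c(1, 1, 2))
  hb <- detect_hbonds(s, "element N", "element O", hbond_criteria())
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$da_distance, 2.8)
  expect_equal(hb$dha_angle, 180, tolerance = 1e-6)

  # beyond the 3.5 A cutoff: not detected
  s2 <- make_hb_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(3.6, 0, 0)),
                          c("N", "H", "O"),
                          names = c("N", "H", "O"), resids = c(1, 1, 2))
  expect_equal(nrow(detect_hbonds(s2, "element N", "element O",
                                  hbond_criteria())), 0L)

  # angle below 110 degrees fails even inside the distance cutoff
  s3 <- make_hb_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2.5, 0)),
                          c("N", "H", "O"),
                          names = c("N", "H", "O"), resids = c(1, 1, 2))
  expect_equal(nrow(detect_hbonds(s3, "element N", "element O",
                                  hbond_criteria())), 0L)
  expect_equal(nrow(detect_hbonds(s3, "element N", "element O",
                                  hbond_criteria(heavy_only = TRUE))), 1L)

  # donor without hydrogens in hydrogen-aware mode is a contract error
  s4 <- make_hb_structure(rbind(c(0, 0, 0), c(2.8, 0, 0)), c("N", "O"))
  expect_error(detect_hbonds(s4, "element N", "element O", hbond_criteria()),
               "heavy_only")
})

test_that("detection matches the all-pairs brute-force oracle on 200 random configurations", {
  set.seed(17)
  for (k in 1:100) {
    s <- random_polar_structure(sample(4:10, 1))
    cr <- hbond_criteria(heavy_only = TRUE)
    got <- detect_hbonds(s, "element N,O", "element N,O", cr)
    want <- brute_hbonds(s, "element N,O", "element N,O", cr)
    got_set <- sort(paste(got$donor_idx, got$acceptor_idx))
    want_set <- if (nrow(want)) sort(paste(want[, 1], want[, 2])) else character(0)
    expect_identical(got_set, want_set)
  }
  for (k in 1:100) {
    s <- random_polar_structure(sample(4:8, 1), with_h = TRUE)
    cr <- hbond_criteria()
    got <- detect_hbonds(s, "element N,O", "element N,O", cr)
    want <- brute_hbonds(s, "element N,O", "element N,O", cr)
    got_set <- sort(paste(got$donor_idx, got$acceptor_idx))
    want_set <- if (nrow(want)) sort(paste(want[, 1], want[, 2])) else character(0)
    expect_identical(got_set, want_set)
  }
})

test_that("detection is invariant to rigid motion", {
  set.seed(23)
  s <- random_polar_structure(8)
  cr <- hbond_criteria(heavy_only = TRUE)
  base <- detect_hbonds(s, "element N,O", "element N,O", cr)
  for (k in 1:10) {
    sr <- rigid_structure(s, random_rotation(), rnorm(3, sd = 10))
    moved <- detect_hbonds(sr, "element N,O", "element N,O", cr)
    expect_identical(paste(moved$donor_idx, moved$acceptor_idx),
                     paste(base$donor_idx, base$acceptor_idx))
  }
})

test_that("water bridges require both partners in the same frame", {
  # water O equidistant (2.8 A) from both partners: exactly one bridge
  w <- make_hb_structure(rbind(c(0, 0, 0), c(5.6, 0, 0), c(2.8, 0, 0)),
                         c("O", "O", "O"),
                         names = c("O1", "O2", "O"), resids = c(1, 2, 900))
  w$atoms$residue_name[3] <- "HOH"
  w <- structure3d(w$atoms)
  cr <- hbond_criteria(heavy_only = TRUE)
  br <- detect_water_bridges(w, "resid 1", "resid 2", cr)
  expect_equal(nrow(br), 1L)
  expect_equal(br$water_resid, 900L)

  # within range of one partner only: no bridge
  w2 <- w; xyz <- coords(w2); xyz[3, 1] <- 1.0
  w2 <- set_coords(w2, xyz)
  expect_equal(nrow(detect_water_bridges(w2, "resid 1", "resid 2", cr)), 0L)

  # no waters at all: empty result plus a warning
  dry <- make_hb_structure(rbind(c(0, 0, 0), c(5, 0, 0)), c("O", "O"))
  expect_warning(out <- detect_water_bridges(dry, "resid 1", "resid 2", cr),
                 "no water")
  expect_equal(nrow(out), 0L)
})

test_that("planted bridge schedules are recovered exactly", {
  sched <- c(2, 5, 6, 9)
  spec <- trajectory_spec(n_frames = 10, p_pr_to_nr = 0, p_nr_to_pr = 0,
                          bridge_frames = sched, seed = 31)
  sim <- simulate_trajectory(spec, test_scaffold)
  partners <- attr(test_scaffold, "bridge_partners")
  cr <- hbond_criteria(heavy_only = TRUE)
  found <- vapply(1:10, function(i)
    nrow(detect_water_bridges(frame_structure(sim$replicas[[1]], i),
                              partners[1], partners[2], cr)) > 0, logical(1))
  expect_identical(which(found), as.integer(sched))
})

test_that("interaction frequencies follow the per-frame presence contract", {
  partners <- attr(test_scaffold, "bridge_partners")
  pairs <- list(bridge = list(a = partners[1], b = partners[2]))
  cr <- hbond_criteria(heavy_only = TRUE)

  # planted every frame in every replica: mean 1, zero CI
  spec <- trajectory_spec(n_frames = 8, n_replicas = 3, p_pr_to_nr = 0,
                          p_nr_to_pr = 0, bridge_frames = 1:8, seed = 5)
  sim <- simulate_trajectory(spec, test_scaffold)
  ft <- interaction_frequency(sim$replicas, pairs, cr)
  expect_equal(ft$mean, 1)
  expect_equal(ft$ci68, 0)

  # planted in exactly half the frames: 0.5
  spec2 <- trajectory_spec(n_frames = 8, n_replicas = 3, p_pr_to_nr = 0,
                           p_nr_to_pr = 0, bridge_frames = c(1, 3, 5, 7),
                           seed = 5)
  sim2 <- simulate_trajectory(spec2, test_scaffold)
  ft2 <- interaction_frequency(sim2$replicas, pairs, cr)
  expect_equal(ft2$mean, 0.5)

  # a mask that excludes all positive frames gives 0
  masks <- rep(list(rep(c(FALSE, TRUE), 4)), 3)
  ft3 <- interaction_frequency(sim2$replicas, pairs, cr, frame_masks = masks)
  expect_equal(ft3$mean, 0)

  # frequencies always in [0, 1]; direct-only never exceeds direct-or-water
  pr <- attr(ft2, "per_replica")
  expect_true(all(pr >= 0 & pr <= 1))
  ft_nw <- interaction_frequency(sim2$replicas, pairs, cr,
                                 include_water = FALSE)
  expect_true(all(ft_nw$mean <= ft2$mean))

  # all replicas excluded is an error
  empty_masks <- rep(list(rep(FALSE, 8)), 3)
  expect_error(
    suppressWarnings(interaction_frequency(sim2$replicas, pairs, cr,
                                           frame_masks = empty_masks)),
    "all replicas")
})
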