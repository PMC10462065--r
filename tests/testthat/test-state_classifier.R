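test_that("the two-branch helicity rule fires on either branch", {
  helix_h <- make_ideal_helix(9, start_resid = 110, with_h = TRUE)

  # RMSD branch: the reference itself is trivially helical
  expect_true(classify_helicity(helix_h, helix_h))

  # hydrogen-bond branch: reference is an extended conformer, so the RMSD
  # branch fails, yet the ideal helix carries >= 4 i,i+4 bonds
  expect_gt(icl2_backbone_rmsd(helix_h, extended_icl2), 2)
  expect_gte(count_i4_hbonds(helix_h, criteria = hbond_criteria()), 4L)
  expect_true(classify_helicity(helix_h, extended_icl2,
                                criteria = hbond_criteria()))

  # extended conformer against the helical reference: neither branch
  expect_equal(count_i4_hbonds(extended_icl2), 0L)
  expect_false(classify_helicity(extended_icl2, helix_h))
})

test_that("the RMSD cutoff is strict at the measured value", {
  helix <- make_ideal_helix(9, start_resid = 110)
  r <- icl2_backbone_rmsd(extended_icl2, helix)
  # cutoff equal to the measured RMSD: r < r is FALSE, so not helical
  expect_false(classify_helicity(extended_icl2, helix,
                                 state_thresholds(rmsd_cutoff = r)))
  # infinitesimally above: helical
  expect_true(classify_helicity(extended_icl2, helix,
                                state_thresholds(rmsd_cutoff = r + 1e-9)))
})

test_that("classify_state reproduces the printed threshold arithmetic", {
  expect_equal(classify_state(80, 10, TRUE), "PR")
  expect_equal(classify_state(80, 14, TRUE), "NR")   # fails d < 13
  expect_equal(classify_state(80, 10, FALSE), "NONHELICAL")
  # strict boundaries, as printed
  expect_equal(classify_state(45, 10, TRUE), "NR")
  expect_equal(classify_state(120, 10, TRUE), "NR")
  expect_equal(classify_state(80, 13, TRUE), "NR")
  # the lower bound 195 - 20a is vacuous over (45, 120) but implemented:
  # an angle below the window where it would bind still classifies NR
  # through the angle test, and a tiny d passes the bound when a = 80
  expect_equal(classify_state(80, 1e-6, TRUE), "PR")
  # vectorized and total
  expect_equal(classify_state(c(80, 80, 0), c(10, 14, 10),
                              c(TRUE, TRUE, FALSE)),
               c("PR", "NR", "NONHELICAL"))
})

test_that("classification is piecewise constant between thresholds", {
  set.seed(19)
  for (k in 1:50) {
    a <- runif(1, -170, 170); d <- runif(1, 2, 20)
    base <- classify_state(a, d, TRUE)
    # perturbations too small to cross any printed threshold
    da <- min(abs(a - 45), abs(a - 120)) / 3
    dd <- abs(d - 13) / 3
    expect_equal(classify_state(a + sign(runif(1) - 0.5) * da,
                                d + sign(runif(1) - 0.5) * dd, TRUE), base)
  }
})

test_that("the helicity rule is monotone in the hydrogen-bond count", {
  # with RMSD fixed above the cutoff, raising the count can only go
  # non-helical -> helical, never the reverse
  thr <- state_thresholds()
  helical_at <- function(cnt) cnt >= thr$min_hbonds
  for (cnt in 0:4) {
    if (helical_at(cnt)) expect_true(helical_at(cnt + 1L))
  }
})

test_that("occupancy summarizes replica fractions with a SEM-based 68% CI", {
  occ <- occupancy(rep(list(rep("PR", 10)), 5))
  expect_equal(occ$mean_pr, 1)
  expect_equal(occ$ci68_pr, 0)
  expect_equal(occ$mean_nr, 0)

  two <- occupancy(list(c(rep("PR", 4), rep("NR", 6)),
                        c(rep("PR", 6), rep("NR", 4))))
  expect_equal(two$mean_pr, 0.5)
  expect_equal(two$ci68_pr, 0.1)  # SEM of 0.4 and 0.6
  expect_equal(two$per_replica_pr + two$per_replica_nr, c(1, 1))

  expect_error(occupancy(list(character(0))), "empty")
})

test_that("state_trace labels follow the generator schedule in lock-step", {
  # zero-noise PR trajectory: every label PR, angle constant
  spec <- trajectory_spec(n_frames = 6, p_pr_to_nr = 0, p_nr_to_pr = 0,
                          seed = 2)
  tr <- state_trace(simulate_trajectory(spec, test_scaffold)$replicas[[1]],
                    test_scaffold, test_fit)
  expect_true(all(tr$state == "PR"))
  expect_equal(tr$angle_raw, rep(80, 6), tolerance = 1e-9)
  expect_equal(tr$angle_offset, tr$angle_raw)  # reference raw angle is 0

  # switch probabilities of 1 alternate deterministically
  spec2 <- trajectory_spec(n_frames = 6, p_pr_to_nr = 1, p_nr_to_pr = 1,
                           seed = 2)
  sim2 <- simulate_trajectory(spec2, test_scaffold)
  tr2 <- state_trace(sim2$replicas[[1]], test_scaffold, test_fit)
  expect_equal(tr2$state, rep(c("PR", "NR"), 3))
  expect_equal(tr2$state, sim2$truth$state)

  # unreliable-angle flag propagates; trace has one row per frame
  expect_equal(nrow(tr2), 6L)
  expect_true(all(tr2$angle_reliable))
})

test_that("relabel_trace reproduces the original labels at the original thresholds", {
  spec <- trajectory_spec(n_frames = 30, noise_sigma = 0.3, p_pr_to_nr = 0.2,
                          p_nr_to_pr = 0.2, unfold_frames = 0.2, seed = 27)
  fs <- simulate_trajectory(spec, test_scaffold)$replicas[[1]]
  tr <- state_trace(fs, test_scaffold, test_fit)
  expect_equal(relabel_trace(tr, state_thresholds(), fs), tr$state)
})
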