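test_that("a minimal single-record PDB parses field by field", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_s3_class(s, "structure3d")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$atom_name, "CA")
  expect_equal(s$atoms$residue_seq, 1L)
  expect_equal(s$atoms$chain_id, "A")
  expect_equal(unname(coords(s)[1, ]), c(11.104, 6.134, -6.504))
  expect_false(s$atoms$is_water)
})

test_that("read_pdb errors are informative", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_pdb(f), "empty")
  writeLines(c("ATOM      1  CA  ALA A   1      xx.xxx   6.134  -6.504"), f)
  expect_error(read_pdb(f), "line 1")
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "no such file")
})

test_that("altlocs resolve to highest occupancy, ties to first listed", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$atom_name == "CA"], 1.0)  # occupancy 0.60
  expect_equal(s$atoms$x[s$atoms$atom_name == "CB"], 2.0)  # tie -> first
})

test_that("write_pdb/read_pdb round-trips the scaffold field by field", {
  f <- withr::local_tempfile(fileext = ".pdb")
  # quantize to the PDB's 3-decimal coordinate precision first
  sc <- test_scaffold
  sc <- set_coords(sc, round(coords(sc), 3))
  write_pdb(sc, f)
  back <- read_pdb(f)
  for (col in c("atom_name", "residue_name", "chain_id", "residue_seq",
                "element", "is_water")) {
    expect_equal(back$atoms[[col]], sc$atoms[[col]], info = col)
  }
  expect_equal(coords(back), coords(sc), ignore_attr = TRUE)
  expect_true(any(back$atoms$is_water))
})

test_that("multi-model trajectories read, error and round-trip correctly", {
  # 3 models of the same atoms -> 3 frames
  f <- withr::local_tempfile(fileext = ".pdb")
  model <- function(i, drop_atom = FALSE) {
    lines <- c(
      sprintf("ATOM      1  N   ALA A   1       %.3f   0.000   0.000  1.00  0.00           N", i + 0.5),
      "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C")
    if (drop_atom) lines <- lines[1]
    c(sprintf("MODEL %8d", i), lines, "ENDMDL")
  }
  writeLines(c(model(1), model(2), model(3), "END"), f)
  fs <- read_frames(f)
  expect_equal(n_frames(fs), 3L)
  expect_equal(get_frame(fs, 2)[1, 1], 2.5)
  expect_identical(get_frame(fs, 2), get_frame(fs, 2))

  writeLines(c(model(1), model(2, drop_atom = TRUE), "END"), f)
  expect_error(read_frames(f), "model 2")

  writeLines("END", f)
  expect_error(read_frames(f), "no models")

  # generator output round-trips through the multi-model writer exactly
  # (coordinates pre-quantized to the format's 3-decimal precision)
  spec <- trajectory_spec(n_frames = 20, noise_sigma = 0.3, seed = 42)
  sim <- simulate_trajectory(spec, test_scaffold)
  fs0 <- sim$replicas[[1]]
  fs0 <- frame_source(fs0$roster, round(fs0$coords, 3), fs0$frame_interval)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_frames(fs0, f2)
  back <- read_frames(f2)
  expect_equal(n_frames(back), 20L)
  expect_identical(back$coords, fs0$coords)
  expect_equal(back$roster$atom_name, fs0$roster$atom_name)
})

test_that("selection resolution is deterministic, ordered and total", {
  h <- make_ideal_helix(9, start_resid = 110)
  idx <- resolve_selection("resid 110-118 and backbone", h)
  expect_length(idx, 36L)  # N, CA, C, O per residue
  expect_identical(as.integer(idx), sort(as.integer(idx)))  # roster order
  expect_identical(resolve_selection("resid 110-118 and backbone-heavy", h),
                   idx, ignore_attr = TRUE)

  # hand-enumerated oracle on the fixture: backbone-heavy of 111-118
  ros <- roster(h)
  oracle <- which(ros$residue_seq %in% 111:118 &
                    ros$atom_name %in% c("N", "CA", "C", "O"))
  expect_equal(as.integer(resolve_selection("resid 111-118 and backbone-heavy", h)),
               oracle)

  expect_error(resolve_selection("resid 114 and name OH", h), "OH")
  expect_error(resolve_selection("resid 300", h), "300")
  expect_error(resolve_selection("bogus clause", h), "unparseable")
  # comma lists and single residues
  expect_length(resolve_selection("resid 110,112 and name CA", h), 2L)
})

test_that("BW code mapping is injective and bidirectional", {
  m <- bw_map(c(103, 109, 114), c("3.49", "3.55", "34.53"))
  expect_equal(bw_to_resid(m, "34.53"), 114L)
  expect_equal(resid_to_bw(m, 103), "3.49")
  expect_error(bw_to_resid(m, "9.99"), "9.99")
  expect_error(bw_map(c(1, 1), c("a", "b")), "injective")
})
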