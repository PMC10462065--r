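# Shared fixtures, built once per test run. All geometry is generated in
# code; nothing is read from disk except temp files the tests write.

test_scaffold <- make_scaffold()
test_fit <- scaffold_fit_spec(test_scaffold)

# a deliberately non-helical 9-residue conformer for helicity tests
extended_icl2 <- make_ideal_helix(9, phi = -135, psi = 135, start_resid = 110)

# small random polar-atom structure for hydrogen-bond oracle tests
random_polar_structure <- function(n, box = 8, with_h = FALSE, seed_offset = 0) {
  # caller is expected to have seeded the RNG
  elements <- sample(c("N", "O", "C"), n, replace = TRUE)
  atoms <- data.frame(
    serial = seq_len(n),
    atom_name = paste0(elements, seq_len(n)),
    residue_name = "UNK",
    chain_id = "A",
    residue_seq = seq_len(n),
    x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
    z = stats::runif(n, 0, box),
    element = elements,
    stringsAsFactors = FALSE)
  s <- structure3d(atoms)
  if (with_h) {
    polar <- which(elements %in% c("N", "O"))
    h <- atoms[polar, , drop = FALSE]
    h$atom_name <- paste0("H", h$residue_seq)
    h$element <- "H"
    dirs <- matrix(stats::rnorm(3 * nrow(h)), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    h[, c("x", "y", "z")] <- h[, c("x", "y", "z")] + dirs
    all <- rbind(atoms, h)
    all$serial <- seq_len(nrow(all))
    s <- structure3d(all)
  }
  s
}
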