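#' Build a run configuration
#'
#' Collects every tunable of the analysis in one list so that printed-method
#' numbers are defaults, never hard-coded literals. `reference` and
#' `trajectories` may be file paths (PDB / multi-model PDB) or live objects.
#'
#' @param reference reference structure: path or `structure3d` (the
#'   starting frame / crystal structure; defines angle offset and RMSD
#'   references).
#' @param trajectories replica trajectories: character paths or list of
#'   [frame_source()] objects.
#' @param out_dir output directory (created if needed).
#' @param fit_spec TM1-4 C-alpha fit selection.
#' @param thresholds [state_thresholds()] list.
#' @param criteria [hbond_criteria()]; heavy-only by default because MD
#'   interchange files often lack hydrogens.
#' @param oh_spec,cg_spec,d_specs,chain angle/distance atom selections (see
#'   [state_trace()]).
#' @param pairs optional named list of `list(a=, b=)` selections for the
#'   hydrogen-bond frequency table.
#' @param folded_only_pairs count frequency only over frames where ICL2 is
#'   helical (the folded-frames mask).
#' @param g_chain,g_alpha_range,loop_resids G-protein metric settings;
#'   G-protein metrics are computed only when `g_chain` resolves.
#' @param pca_window residue window (integer vector) for dihedral PCA, or
#'   `NULL` to skip PCA.
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(reference, trajectories, out_dir,
                       fit_spec,
                       thresholds = state_thresholds(),
                       criteria = hbond_criteria(heavy_only = TRUE),
                       oh_spec = "resid 114 and name OH",
                       cg_spec = "resid 112 and name CG",
                       d_specs = c("resid 114 and name OH",
                                   "resid 39 and name CB"),
                       chain = "A",
                       pairs = NULL, folded_only_pairs = TRUE,
                       g_chain = "B", g_alpha_range = c(519, 530),
                       loop_resids = c(504, 508),
                       pca_window = NULL, seed = 1L) {
  structure(list(reference = reference, trajectories = trajectories,
                 out_dir = out_dir, fit_spec = fit_spec,
                 thresholds = thresholds, criteria = criteria,
                 oh_spec = oh_spec, cg_spec = cg_spec, d_specs = d_specs,
                 chain = chain, pairs = pairs,
                 folded_only_pairs = folded_only_pairs,
                 g_chain = g_chain, g_alpha_range = g_alpha_range,
                 loop_resids = loop_resids, pca_window = pca_window,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_reference <- function(x) {
  if (inherits(x, "structure3d")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("reference structure not found: ", x)
    return(read_pdb(x))
  }
  stop("reference must be a path or a structure3d")
}

load_trajectories <- function(x) {
  if (is.character(x)) {
    missing <- x[!file.exists(x)]
    if (length(missing) > 0L) {
      stop("trajectory file(s) not found: ", paste(missing, collapse = ", "))
    }
    return(lapply(x, read_frames))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "frame_source"))) {
    return(x)
  }
  stop("trajectories must be file paths or a list of frame_source objects")
}

#' Per-frame geometric metric table for one replica
#'
#' Composes the state trace (angle, distance, RMSD, helicity, state label)
#' with the remaining per-frame scalars: TM5 vertical shift, the four
#' inter-helix C-alpha distances, the multi-RMSD collective variable, and
#' (when a G-alpha chain is present) helix-5 displacement and the
#' beta6-alpha5 loop end-to-end distance. Metrics whose atoms are absent
#' from the roster are reported as NA columns with a message, never
#' fabricated.
#'
#' @param frames a [frame_source()].
#' @param ref reference `structure3d`.
#' @param config a [run_config()].
#' @return data.frame, one row per frame.
#' @export
trajectory_metrics <- function(frames, ref, config) {
  ros <- frames$roster
  tr <- state_trace(frames, ref, config$fit_spec,
                    thresholds = config$thresholds,
                    criteria = config$criteria,
                    oh_spec = config$oh_spec, cg_spec = config$cg_spec,
                    d_specs = config$d_specs, chain = config$chain)
  nf <- frames$n_frames
  ca_pair <- function(r1, r2) {
    c(sprintf("chain %s and resid %d and name CA", config$chain, r1),
      sprintf("chain %s and resid %d and name CA", config$chain, r2))
  }
  pair_cols <- list(tm3_tm6_intra = ca_pair(105, 222),
                    tm3_tm5_intra = ca_pair(104, 208),
                    tm3_tm6_extra = ca_pair(83, 184),
                    tm3_tm5_extra = ca_pair(83, 244))
  for (nm in names(pair_cols)) {
    sp <- pair_cols[[nm]]
    idx <- tryCatch(c(resolve_selection(sp[1], ros)[1L],
                      resolve_selection(sp[2], ros)[1L]),
                    error = function(e) NULL)
    if (is.null(idx)) {
      message("metric ", nm, ": atoms missing, reported as NA")
      tr[[nm]] <- NA_real_
    } else {
      tr[[nm]] <- vapply(seq_len(nf), function(i) {
        fr <- frames$coords[, , i]
        sqrt(sum((fr[idx[1L], ] - fr[idx[2L], ])^2))
      }, numeric(1))
    }
  }
  tr$tm5_shift <- tryCatch({
    vapply(seq_len(nf), function(i)
      tm5_vertical_shift(frame_structure(frames, i), ref,
                         chain = config$chain), numeric(1))
  }, error = function(e) {
    message("metric tm5_shift: ", conditionMessage(e)); rep(NA_real_, nf)
  })
  tr$multi_rmsd_cv <- tryCatch({
    vapply(seq_len(nf), function(i)
      multi_rmsd_cv(frame_structure(frames, i), ref, chain = config$chain),
      numeric(1))
  }, error = function(e) {
    message("metric multi_rmsd_cv: ", conditionMessage(e)); rep(NA_real_, nf)
  })
  has_g <- config$g_chain %in% ros$chain_id
  if (has_g) {
    tr$helix5_displacement <- vapply(seq_len(nf), function(i)
      helix5_displacement(frame_structure(frames, i), ref, config$fit_spec,
                          config$g_alpha_range, config$g_chain), numeric(1))
    tr$loop_end_to_end <- vapply(seq_len(nf), function(i)
      loop_end_to_end(frame_structure(frames, i), config$loop_resids,
                      config$g_chain), numeric(1))
  } else {
    tr$helix5_displacement <- NA_real_
    tr$loop_end_to_end <- NA_real_
  }
  tr
}

#' Run the full analysis over a replica set
#'
#' Validates the configuration fail-fast (every selection must resolve on
#' the reference and the first trajectory roster before any frame is
#' processed), then writes per-replica metric tables, the cross-replica
#' occupancy summary, the hydrogen-bond frequency table (if pairs are
#' configured), the dihedral PCA model and scores (if a window is
#' configured), and a reproducibility manifest.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `metrics` (per replica), `occupancy`,
#'   `frequency`, `pca`, and the output file paths.
#' @export
cmd_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ref <- load_reference(config$reference)
  reps <- load_trajectories(config$trajectories)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ## fail fast: resolve every configured selection before frame 1
  for (sp in c(config$fit_spec, config$oh_spec, config$cg_spec,
               config$d_specs)) {
    resolve_selection(sp, ref)
    resolve_selection(sp, reps[[1L]]$roster)
  }
  if (!is.null(config$pairs)) {
    for (p in config$pairs) {
      resolve_selection(p$a, reps[[1L]]$roster)
      resolve_selection(p$b, reps[[1L]]$roster)
    }
  }

  metrics <- vector("list", length(reps))
  for (r in seq_along(reps)) {
    metrics[[r]] <- trajectory_metrics(reps[[r]], ref, config)
    utils::write.csv(metrics[[r]],
                     file.path(config$out_dir,
                               sprintf("metrics_replica%02d.csv", r)),
                     row.names = FALSE)
  }
  occ <- occupancy(lapply(metrics, function(m) m$state))
  occ_path <- file.path(config$out_dir, "occupancy.json")
  jsonlite::write_json(unclass(occ), occ_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  freq <- NULL
  if (!is.null(config$pairs)) {
    masks <- if (config$folded_only_pairs) {
      lapply(metrics, function(m) m$helical)
    } else NULL
    freq <- interaction_frequency(reps, config$pairs, config$criteria,
                                  frame_masks = masks)
    utils::write.csv(freq, file.path(config$out_dir, "hbond_frequency.csv"),
                     row.names = FALSE)
  }

  pca <- NULL
  if (!is.null(config$pca_window)) {
    mats <- lapply(reps, compute_dihedrals,
                   residue_window = config$pca_window, chain = config$chain)
    merged <- do.call(rbind, mats)
    mask <- unlist(lapply(metrics, function(m) m$helical))
    pca <- fit_pca(merged, mask = mask)
    scores <- project_pca(pca, merged, n_components = min(5L,
                                                          nrow(pca$components)))
    utils::write.csv(data.frame(replica = rep(seq_along(reps),
                                              vapply(mats, nrow, integer(1))),
                                helical = mask, scores),
                     file.path(config$out_dir, "pca_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(mean = pca$mean,
                              components = pca$components,
                              explained_variance = pca$explained_variance,
                              embed = pca$embed),
                         file.path(config$out_dir, "pca_model.json"),
                         digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package = "gpcrtraj",
    version = as.character(utils::packageVersion("gpcrtraj")),
    seed = config$seed,
    n_replicas = length(reps),
    n_frames = vapply(reps, function(x) x$n_frames, integer(1)),
    input_md5 = if (is.character(config$trajectories)) {
      as.list(tools::md5sum(config$trajectories))
    } else "in-memory trajectories",
    fit_spec = config$fit_spec,
    thresholds = config$thresholds,
    criteria = unclass(config$criteria))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metrics = metrics, occupancy = occ, frequency = freq,
                 pca = pca, out_dir = config$out_dir))
}

#' Generate a synthetic dataset on disk
#'
#' Runs the generator and writes one multi-model PDB per replica, the
#' reference scaffold, and the ground-truth table, in a layout
#' [cmd_analyze()] can consume directly.
#'
#' @param spec a [trajectory_spec()].
#' @param out_dir output directory.
#' @param scaffold scaffold structure (default [make_scaffold()]).
#' @return (invisibly) list with `reference`, `trajectories` (paths) and
#'   `truth` path.
#' @export
cmd_synth <- function(spec, out_dir, scaffold = make_scaffold()) {
  stopifnot(inherits(spec, "trajectory_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_trajectory(spec, scaffold)
  ref_path <- file.path(out_dir, "reference.pdb")
  write_pdb(scaffold, ref_path)
  traj_paths <- character(spec$n_replicas)
  for (r in seq_len(spec$n_replicas)) {
    traj_paths[r] <- file.path(out_dir, sprintf("replica%02d.pdb", r))
    write_frames(sim$replicas[[r]], traj_paths[r])
  }
  truth_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  invisible(list(reference = ref_path, trajectories = traj_paths,
                 truth = truth_path))
}

#' TM5 vertical-shift difference between two structures
#'
#' Applies the TM5 projection metric to structure `a` using structure `b`
#' as the zero reference, optionally after superposing `a` onto `b` on a
#' TM1-4 C-alpha fit set. (The projection is computed from atoms internal
#' to each structure, so it is invariant to the superposition; the
#' alignment is retained for protocol fidelity and for visual outputs.)
#'
#' @param pdb_a,pdb_b paths or `structure3d` objects; `b` defines zero.
#' @param fit_spec optional TM1-4 C-alpha selection used to superpose `a`
#'   onto `b` first.
#' @param ... passed to [tm5_vertical_shift()] (`tm5_resid`, `tm4_resids`,
#'   `chain`).
#' @return signed shift in Angstrom.
#' @export
cmd_crystal_shift <- function(pdb_a, pdb_b, fit_spec = NULL, ...) {
  a <- load_reference(pdb_a)
  b <- load_reference(pdb_b)
  if (!is.null(fit_spec)) {
    ia <- resolve_selection(fit_spec, a)
    ib <- resolve_selection(fit_spec, b)
    fit <- kabsch(coords(a)[ia, , drop = FALSE], coords(b)[ib, , drop = FALSE])
    a <- set_coords(a, apply_alignment(coords(a), fit))
  }
  tm5_vertical_shift(a, b, ...)
}
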