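# Orchestration: run the full wild-vs-variant trajectory comparison and
# the consensus variant screen with one reproducible configuration.

#' Build a run configuration
#'
#' Collects every tunable of the comparison pipeline in one validated
#' object; the same object is echoed into the output manifest, so a run
#' can be reproduced from its manifest alone.
#'
#' @param wild path to a multi-model PDB, or a [trajectory()], for the
#'   wild-type system.
#' @param variants named list of paths or trajectories, one per variant
#'   system.
#' @param score_table optional path to a predictor score table for
#'   [run_screen()].
#' @param selection_rmsd atom selection for the RMSD series (default
#'   `"backbone"`).
#' @param selection_profile one-atom-per-residue selection for
#'   RMSF/DCCM/PCA (default `"CA"`).
#' @param equilibration_fraction leading fraction of frames discarded
#'   before analysis, in `[0, 1)` (default 0.4).
#' @param rin_cutoff residue-network contact cutoff, Angstrom (default
#'   6.7).
#' @param fel_bins bins per FEL axis (default `c(50, 50)`).
#' @param temperature FEL temperature, Kelvin (default 300).
#' @param hbond_max,hbond_angle_min hydrogen-bond criteria (Angstrom /
#'   degrees; defaults 3.5 / 120).
#' @param sasa_points Shrake-Rupley sphere points per atom (default 960).
#' @param min_tools consensus threshold for the screen (default 7).
#' @param seed integer seed recorded in the manifest.
#' @param output_dir directory for the report bundle, or `NULL` to keep
#'   results in memory only.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(wild = NULL, variants = list(), score_table = NULL,
                       selection_rmsd = "backbone",
                       selection_profile = "CA",
                       equilibration_fraction = 0.4, rin_cutoff = 6.7,
                       fel_bins = c(50, 50), temperature = 300,
                       hbond_max = 3.5, hbond_angle_min = 120,
                       sasa_points = 960, min_tools = 7, seed = 1,
                       output_dir = NULL) {
  if (equilibration_fraction < 0 || equilibration_fraction >= 1)
    stop("config error: equilibration_fraction must be in [0, 1)")
  for (p in Filter(is.character, c(list(wild), variants,
                                   list(score_table))))
    if (!file.exists(p)) stop("config error: file not found: ", p)
  if (length(variants) && is.null(names(variants)))
    names(variants) <- paste0("variant", seq_along(variants))
  structure(list(wild = wild, variants = variants,
                 score_table = score_table,
                 selection_rmsd = selection_rmsd,
                 selection_profile = selection_profile,
                 equilibration_fraction = equilibration_fraction,
                 rin_cutoff = rin_cutoff, fel_bins = fel_bins,
                 temperature = temperature, hbond_max = hbond_max,
                 hbond_angle_min = hbond_angle_min,
                 sasa_points = sasa_points, min_tools = min_tools,
                 seed = seed, output_dir = output_dir),
            class = "run_config")
}

.as_traj <- function(x) {
  if (inherits(x, "trajectory")) x else read_multimodel_pdb(x)
}

# analyse one system over its equilibration window
.analyse_system <- function(traj, cfg) {
  win <- equilibration_window(traj, cfg$equilibration_fraction)
  wtraj <- subset_frames(traj, win)
  rmsd <- rmsd_series(wtraj, "first_frame", cfg$selection_rmsd)
  rg <- rg_series(wtraj, "heavy")
  sasa <- sasa_series(wtraj, n_sphere_points = cfg$sasa_points)
  hb <- hbond_count_series(wtraj, cfg$hbond_max, cfg$hbond_angle_min)
  rmsf <- rmsf_per_residue(wtraj, cfg$selection_profile)
  pca <- compute_pca(wtraj, cfg$selection_profile)
  fel <- compute_fel(rmsd, rg, cfg$fel_bins, cfg$temperature)
  list(window = win,
       rmsd = rmsd, rg = rg, sasa = sasa, hbonds = hb,
       rmsf = rmsf, bfactor = bfactor_from_rmsf(rmsf),
       dccm = compute_dccm(wtraj, cfg$selection_profile),
       pca = pca,
       bc = betweenness_profile(wtraj, cutoff = cfg$rin_cutoff),
       L = shortest_path_profile(wtraj, cutoff = cfg$rin_cutoff),
       delta_bc = delta_vs_first_frame(wtraj, "BC", cutoff = cfg$rin_cutoff),
       delta_L = delta_vs_first_frame(wtraj, "L", cutoff = cfg$rin_cutoff),
       sse = assign_sse(wtraj),
       fel = fel,
       basins = extract_basins(fel, rmsd, rg),
       traj = wtraj)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_series <- function(s, path) {
  .write_tsv(data.frame(frame = seq_along(s$values), value = s$values), path)
}

.write_profile <- function(p, path) {
  .write_tsv(data.frame(residue = names(p), value = as.numeric(p)), path)
}

.write_system <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_series(res$rmsd, file.path(dir, "rmsd.tsv"))
  .write_series(res$rg, file.path(dir, "rg.tsv"))
  .write_series(res$sasa, file.path(dir, "sasa.tsv"))
  .write_series(res$hbonds, file.path(dir, "hbonds.tsv"))
  .write_profile(res$rmsf, file.path(dir, "rmsf.tsv"))
  .write_profile(res$bfactor, file.path(dir, "bfactor.tsv"))
  .write_profile(res$bc, file.path(dir, "bc.tsv"))
  .write_profile(res$L, file.path(dir, "avg_shortest_path.tsv"))
  .write_profile(res$delta_bc, file.path(dir, "delta_bc.tsv"))
  .write_profile(res$delta_L, file.path(dir, "delta_avg_shortest_path.tsv"))
  .write_profile(res$pca$pc1_residue_mobility,
                 file.path(dir, "pc1_mobility.tsv"))
  utils::write.table(format(res$dccm, digits = 6),
                     file.path(dir, "dccm.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  .write_tsv(data.frame(component = seq_along(res$pca$variance_fractions),
                        fraction = res$pca$variance_fractions),
             file.path(dir, "pca_fractions.tsv"))
  .write_tsv(as.data.frame(res$pca$projections[, 1:3, drop = FALSE]),
             file.path(dir, "pca_projections.tsv"))
  utils::write.table(unclass(res$sse), file.path(dir, "sse_timeline.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  .write_tsv(cbind(residue = rownames(sse_fractions(res$sse)),
                   as.data.frame(sse_fractions(res$sse))),
             file.path(dir, "sse_fractions.tsv"))
  grid <- res$fel
  cx <- (head(grid$rmsd_edges, -1) + tail(grid$rmsd_edges, -1)) / 2
  cy <- (head(grid$rg_edges, -1) + tail(grid$rg_edges, -1)) / 2
  .write_tsv(data.frame(rmsd_bin_center = rep(cx, times = length(cy)),
                        rg_bin_center = rep(cy, each = length(cx)),
                        count = as.vector(grid$counts),
                        G = as.vector(grid$G)),
             file.path(dir, "fel.tsv"))
  for (k in seq_along(res$basins)) {
    write_multimodel_pdb(res$traj,
                         file.path(dir, sprintf("basin%d_representative.pdb",
                                                k)),
                         frames = res$basins[[k]]$representative_frame)
  }
}

#' Run the wild-vs-variant comparison pipeline
#'
#' For the wild-type and each variant system: equilibration windowing,
#' RMSD/Rg/SASA/H-bond series, RMSF and B-factor profiles, DCCM, PCA,
#' residue-network BC/L and delta profiles, secondary-structure timeline
#' and free-energy landscape with basins; plus wild-minus-variant delta
#' tables (RMSF, BC, L, residue usage). With an `output_dir`, every
#' result is written as plain TSV (representative basin frames as PDB)
#' together with a JSON manifest of all parameters.
#'
#' @param config a [run_config()].
#' @return list with `systems` (per-system results), `deltas`
#'   (wild-vs-variant profiles) and `config`, invisibly when writing.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$wild)) stop("config error: no wild-type input")
  systems <- c(list(wild = .as_traj(config$wild)),
               lapply(config$variants, .as_traj))
  # residue numbering must agree across systems on the profile selection
  resnos <- lapply(systems, function(tr)
    profile_resno(select_atoms(tr, config$selection_profile)))
  for (nm in names(resnos)[-1]) {
    bad <- c(setdiff(resnos[[nm]], resnos$wild),
             setdiff(resnos$wild, resnos[[nm]]))
    if (length(bad))
      stop("alignment error: residue numbering mismatch between wild and ",
           nm, " at residue(s) ", paste(sort(unique(bad)), collapse = ", "))
  }
  results <- lapply(systems, .analyse_system, cfg = config)
  deltas <- list()
  for (nm in names(results)[-1]) {
    deltas[[nm]] <- list(
      rmsf = delta_profile(results$wild$rmsf, results[[nm]]$rmsf,
                           "vs_other_system"),
      bc = delta_profile(results$wild$bc, results[[nm]]$bc,
                         "vs_other_system"),
      L = delta_profile(results$wild$L, results[[nm]]$L,
                        "vs_other_system"),
      residue_usage = residue_usage(results$wild$delta_bc,
                                    results[[nm]]$delta_bc))
  }
  out <- list(systems = results, deltas = deltas, config = config)
  if (!is.null(config$output_dir)) {
    for (nm in names(results))
      .write_system(results[[nm]], file.path(config$output_dir, nm))
    for (nm in names(deltas)) {
      ddir <- file.path(config$output_dir, paste0("wild_vs_", nm))
      dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
      for (what in names(deltas[[nm]]))
        .write_profile(deltas[[nm]][[what]],
                       file.path(ddir, paste0(what, ".tsv")))
    }
    manifest <- config
    manifest$wild <- if (is.character(config$wild)) config$wild else
      "<in-memory trajectory>"
    manifest$variants <- lapply(config$variants, function(v)
      if (is.character(v)) v else "<in-memory trajectory>")
    jsonlite::write_json(unclass(manifest),
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(out))
  }
  out
}

#' Run the consensus variant screen
#'
#' Delegates to [consensus()] and [tool_agreement_matrix()]; with an
#' `output_dir` the consensus table and agreement matrix are written as
#' TSV. An empty score table yields an empty report with a warning.
#'
#' @param config a [run_config()] with `score_table` set, or a path to a
#'   score table.
#' @param min_tools consensus threshold when `config` is a path.
#' @return list with `consensus` and `agreement` (NULL for < 2 variants).
#' @export
run_screen <- function(config, min_tools = 7) {
  if (is.character(config))
    config <- run_config(score_table = config, min_tools = min_tools)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$score_table))
    stop("config error: no score table configured")
  tab <- read_score_table(config$score_table)
  if (nrow(tab) == 0) {
    warning("score table is empty; writing an empty report")
    res <- list(consensus = data.frame(), agreement = NULL)
  } else {
    res <- list(consensus = consensus(tab, min_tools = config$min_tools),
                agreement = if (nrow(tab) >= 2) tool_agreement_matrix(tab))
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(res$consensus, file.path(config$output_dir, "consensus.tsv"))
    if (!is.null(res$agreement))
      utils::write.table(format(res$agreement, digits = 4),
                         file.path(config$output_dir, "tool_agreement.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
  }
  res
}
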